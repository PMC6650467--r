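test_that("min_pair_distance matches geometry and is symmetric", {
  a <- matrix(c(0, 0, 0), ncol = 3)
  b <- rbind(c(3, 0, 0), c(0, 4, 0))
  expect_equal(min_pair_distance(a, b), 3)
  expect_equal(min_pair_distance(b, a), 3)

  # identical selections overlap: zero with a warning
  expect_warning(d0 <- min_pair_distance(b, b), "overlap")
  expect_equal(d0, 0)

  expect_error(
    min_pair_distance(matrix(c(NA, 0, 0), ncol = 3), b),
    "non-finite"
  )
})

test_that("min_pair_distance equals the brute-force pairwise minimum", {
  set.seed(101)
  for (i in 1:25) {
    na <- sample(1:12, 1)
    nb <- sample(1:12, 1)
    ca <- matrix(rnorm(3 * na, sd = 5), ncol = 3)
    cb <- matrix(rnorm(3 * nb, sd = 5) + 4, ncol = 3)
    expect_equal(min_pair_distance(ca, cb), brute_min_dist(ca, cb))
    # never below the closest single pair by construction; symmetric
    expect_equal(min_pair_distance(cb, ca), brute_min_dist(ca, cb))
  }
})

test_that("scan_trajectory emits aligned series over frames", {
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  pdb <- bio3d::read.pdb(write_toy_pdb(pdb_path))
  map <- toy_residue_map()
  sel_y <- resolve_selection(map, pdb, "2.64")
  sel_c <- resolve_selection(map, pdb, "45.50")
  sel_e <- resolve_selection(map, pdb, "7.36")

  # constant multi-model trajectory -> constant series with default 0.2 ns
  traj_path <- withr::local_tempfile(fileext = ".pdb")
  traj <- bio3d::read.pdb(write_toy_traj_pdb(traj_path, n_frames = 10),
    multi = TRUE
  )
  out <- scan_trajectory(pdb, traj, metrics = list(
    "Y2.64-C45.50" = list(sel_y, sel_c),
    "Y2.64-E7.36" = list(sel_y, sel_e)
  ))
  expect_length(out, 2L)
  expect_length(out[[1]]$distance, 10L)
  expect_equal(out[[1]]$time_ns, (0:9) * 0.2)
  expect_equal(out[[1]]$time_ns, out[[2]]$time_ns)
  expect_equal(diff(range(out[[1]]$distance)), 0)

  # selection B translating 1 A/frame away from contact along x:
  # two single-atom selections over raw xyz frames
  base <- pdb$xyz[1, ]
  one_atom_a <- sel_y
  one_atom_a$xyz <- sel_y$xyz[1:3]
  one_atom_b <- sel_c
  one_atom_b$xyz <- sel_c$xyz[1:3]
  frames <- do.call(rbind, lapply(0:4, function(k) {
    f <- base
    f[one_atom_b$xyz] <- f[one_atom_a$xyz] + c(k, 0, 0)
    f
  }))
  expect_equal(
    suppressWarnings(scan_trajectory(pdb, frames,
      metrics = list(sep = list(one_atom_a, one_atom_b))
    )$sep$distance),
    c(0, 1, 2, 3, 4)
  )

  # structural errors
  expect_error(
    scan_trajectory(pdb, frames[, 1:30], metrics = list(
      sep = list(one_atom_a, one_atom_b)
    )),
    "atoms"
  )
  expect_error(
    scan_trajectory(pdb, frames[0, , drop = FALSE], metrics = list(
      sep = list(one_atom_a, one_atom_b)
    )),
    "zero frames"
  )
})

test_that("moving_average does centered clipped-window smoothing", {
  s <- distance_series("d", time_ns = 1:5, distance = c(1, 2, 3, 4, 5))
  sm <- moving_average(s, window_ns = 3)
  expect_equal(sm$distance, c(1.5, 2, 3, 4, 4.5))
  expect_match(sm$metric, "ma3")
  expect_equal(sm$time_ns, s$time_ns) # same grid, same length

  # constant series unchanged
  cs <- distance_series("d", 1:10, rep(2.5, 10))
  expect_equal(moving_average(cs, 4)$distance, rep(2.5, 10))

  # window covering the full span -> global mean everywhere
  wide <- moving_average(s, window_ns = 100)
  expect_equal(wide$distance, rep(3, 5))
  expect_equal(mean(wide$distance), mean(s$distance))

  # window below the frame interval: unchanged with a warning
  expect_warning(same <- moving_average(s, 0.5), "narrower")
  expect_equal(same$distance, s$distance)
  expect_error(moving_average(s, -1), "positive")
})

test_that("distance tables round-trip and reject malformed input", {
  s1 <- distance_series("Y2.64-C45.50", (0:49) * 0.2, runif(50, 2, 9),
    replicate = "1", condition = "active-apo", subtype = "M1"
  )
  s2 <- distance_series("Y2.64-E7.36", (0:49) * 0.2, runif(50, 2, 9),
    replicate = "1", condition = "active-apo", subtype = "M1"
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_table(list(s1, s2), path)
  back <- load_distance_table(path)
  expect_length(back, 2L)
  expect_equal(back[[1]]$distance, s1$distance)
  expect_equal(back[[2]]$metric, "Y2.64-E7.36")
  expect_equal(back[[1]]$condition, "active-apo")
  expect_equal(back[[1]]$subtype, "M1")

  # tsv dialect round-trips too
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_distance_table(list(s1), tsv)
  expect_equal(load_distance_table(tsv)[[1]]$distance, s1$distance)

  # missing header
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,d", "0,1", "1,2"), bad)
  expect_error(load_distance_table(bad), "time_ns")
  # non-numeric cell named with its row
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_ns,d", "0,1", "0.2,oops", "0.4,2"), bad2)
  expect_error(load_distance_table(bad2), "row 2")
  # unsorted times
  bad3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_ns,d", "0,1", "0.4,2", "0.2,3"), bad3)
  expect_error(load_distance_table(bad3), "increasing")
})

test_that("series constructors enforce their invariants", {
  expect_error(distance_series("d", c(0, 1), c(1, 2, 3)), "equal length")
  expect_error(distance_series("d", c(0, 0.2, 0.2), c(1, 2, 3)), "increasing")
  expect_error(distance_series("d", c(0, 1), c(1, -2)), "non-negative")
  expect_error(state_series(c(0, 1), c(TRUE, NA)), "NA")
})
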