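ref_params <- atcm_params(
  pKA = 9.7, pKI = 4.7, pKB = 6.5, logAlpha = 1.5, logAlphaPrime = 0.2
)

test_that("atcm_predict reproduces closed-form limiting cases", {
  KA <- 10^-9.7
  KI <- 10^-4.7
  # A = KA with nothing else bound: half-maximal binding
  expect_equal(atcm_predict(ref_params, A = KA, B = 0, I = 0), 50)
  # I = KI doubles the competition term: 100/3
  expect_equal(atcm_predict(ref_params, A = KA, B = 0, I = KI), 100 / 3)

  # neutral cooperativity cancels the modulator algebraically
  neutral <- atcm_params(9.7, 4.7, 6.5, logAlpha = 0, logAlphaPrime = 0)
  grid <- expand.grid(
    A = c(2e-10, 1e-9), B = 10^seq(-9, -4), I = c(0, 10^seq(-7, -3))
  )
  y_b <- atcm_predict(neutral, grid$A, grid$B, grid$I)
  y_0 <- atcm_predict(neutral, grid$A, 0, grid$I)
  expect_lt(max(abs(y_b - y_0)), 1e-9)

  # B = 0 reduces exactly to two-ligand competition
  y <- atcm_predict(ref_params, A = 2e-10, B = 0, I = grid$I)
  expect_equal(y, 100 * 2e-10 / (2e-10 + KA * (1 + grid$I / KI)))

  # input validation
  expect_error(atcm_predict(ref_params, A = 0, B = 0, I = 0), "A must")
  expect_error(atcm_predict(ref_params, A = 1e-9, B = -1, I = 0), ">= 0")
  expect_error(atcm_params(pKA = Inf, pKI = 4, pKB = 6), "non-finite")
})

test_that("atcm_predict agrees with the mass-action species solver", {
  set.seed(19)
  for (i in 1:50) {
    p <- atcm_params(
      pKA = runif(1, 4, 10), pKI = runif(1, 4, 10), pKB = runif(1, 4, 10),
      logAlpha = runif(1, -2, 2), logAlphaPrime = runif(1, -2, 2)
    )
    A <- 10^runif(1, -12, -4)
    B <- sample(c(0, 10^runif(1, -9, -3)), 1)
    I <- sample(c(0, 10^runif(1, -9, -3)), 1)
    expect_equal(
      atcm_predict(p, A, B, I),
      occupancy_oracle(p, A, B, I),
      tolerance = 1e-8
    )
  }
})

test_that("binding falls monotonically in competitor and a PAM shifts the curve left", {
  I_grid <- 10^seq(-8, -2, length.out = 60)
  y <- atcm_predict(ref_params, A = 2e-10, B = 0, I = I_grid)
  expect_true(all(diff(y) < 0))

  # alpha > 1, alpha' = 1: IC50 of the competitor decreases with PAM present
  pam <- atcm_params(9.7, 4.7, 6.5, logAlpha = 1.5, logAlphaPrime = 0)
  ic50 <- function(B) {
    yy <- atcm_predict(pam, A = 2e-10, B = B, I = I_grid)
    top <- yy[1]
    10^stats::approx(yy, log10(I_grid), xout = top / 2)$y
  }
  expect_lt(ic50(1e-5), ic50(0))
})

test_that("global fit recovers noise-free generators exactly and shares parameters", {
  d1 <- simulate_binding(ref_params, n_replicates = 1, noise_sd = 0)
  fit1 <- global_fit(d1, fixed = c(pKA = 9.7))
  expect_lt(
    max(abs(fit1$coef - unclass(ref_params)[fit1$free])), 1e-6
  )

  # replicating identical noise-free data leaves the estimates unchanged
  d3 <- rbind(d1, transform(d1, replicate = "2"), transform(d1, replicate = "3"))
  fit3 <- global_fit(d3, fixed = c(pKA = 9.7))
  expect_equal(fit3$coef, fit1$coef, tolerance = 1e-6)

  # co-estimating pKA instead of fixing it also recovers the generator
  fit5 <- suppressWarnings(global_fit(d1, free = c(
    "pKA", "pKI", "pKB", "logAlpha", "logAlphaPrime"
  )))
  expect_lt(max(abs(fit5$coef - unclass(ref_params)[fit5$free])), 1e-4)
})

test_that("fits are invariant to concentration unit rescaling", {
  d <- simulate_binding(ref_params, n_replicates = 2, noise_sd = 2, seed = 5)
  fit_m <- global_fit(d, fixed = c(pKA = 9.7))
  d_nm <- transform(d, A = A * 1e9, B = B * 1e9, I = I * 1e9)
  # nanomolar concentrations with correspondingly shifted pK parameters
  fit_nm <- global_fit(d_nm,
    fixed = c(pKA = 9.7 - 9),
    start = c(pKI = 4.7 - 9, pKB = 6.5 - 9, logAlpha = 1, logAlphaPrime = 0)
  )
  shift <- c(pKI = 9, pKB = 9, logAlpha = 0, logAlphaPrime = 0)
  expect_equal(fit_nm$coef + shift[names(fit_nm$coef)], fit_m$coef,
    tolerance = 1e-4
  )
  expect_equal(fit_nm$rss, fit_m$rss, tolerance = 1e-6)
})

test_that("non-identifiable designs fail fast with interpretable errors", {
  d <- suppressWarnings(simulate_binding(ref_params,
    design = binding_design(B = 0, I = c(0, 1e-6, 1e-5, 1e-4)),
    n_replicates = 1, noise_sd = 0
  ))
  expect_error(
    global_fit(d, fixed = c(pKA = 9.7)),
    "B does not vary"
  )
  # B varies but never together with competitor: logAlpha unidentifiable
  d2 <- rbind(
    suppressWarnings(simulate_binding(ref_params,
      design = binding_design(B = c(0, 1e-6, 1e-5), I = 0),
      n_replicates = 1, noise_sd = 0
    )),
    suppressWarnings(simulate_binding(ref_params,
      design = binding_design(B = 0, I = c(1e-5, 1e-4)),
      n_replicates = 1, noise_sd = 0
    ))
  )
  expect_error(global_fit(d2, fixed = c(pKA = 9.7)), "logAlpha")
  d3 <- suppressWarnings(simulate_binding(ref_params,
    design = binding_design(B = c(0, 1e-6, 1e-5), I = 1e-5),
    n_replicates = 1, noise_sd = 0
  ))
  expect_error(
    global_fit(d3, fixed = c(pKA = 9.7)),
    "I does not vary"
  )
})

test_that("derived occupied affinities propagate error from the covariance", {
  # hand-built fit object: pKB = 7 (SE 0.1), logAlpha = 1 (SE 0.1), cov 0
  fit <- structure(
    list(
      estimates = atcm_params(9.7, 4.7, 7, 1, 0.2),
      coef = c(pKB = 7, logAlpha = 1),
      se = c(pKB = 0.1, logAlpha = 0.1),
      vcov = diag(c(0.01, 0.01)) |>
        (\(m) {
          dimnames(m) <- list(
            c("pKB", "logAlpha"), c("pKB", "logAlpha")
          )
          m
        })(),
      free = c("pKB", "logAlpha"),
      fixed = c(pKA = 9.7, pKI = 4.7, logAlphaPrime = 0.2),
      df_residual = 50
    ),
    class = "atcm_fit"
  )
  ach <- derive_occupied_affinity(fit, "ACh")
  expect_equal(ach$estimate, 8)
  expect_equal(ach$se, sqrt(0.02))

  # neutral cooperativity: occupied equals apo affinity
  fit0 <- fit
  fit0$estimates <- atcm_params(9.7, 4.7, 7, 0, 0.2)
  expect_equal(derive_occupied_affinity(fit0, "ACh")$estimate, 7)

  # a fixed component carries no variance and is flagged
  expect_warning(
    nms <- derive_occupied_affinity(fit, "NMS"),
    "logAlphaPrime"
  )
  expect_equal(nms$se, 0.1)
  expect_equal(nms$fixed_components, "logAlphaPrime")
})

test_that("linear error propagation matches Monte-Carlo propagation", {
  skip_if_not_installed("MASS")
  d <- simulate_binding(ref_params, n_replicates = 3, noise_sd = 3, seed = 21)
  fit <- global_fit(d, fixed = c(pKA = 9.7))
  ach <- derive_occupied_affinity(fit, "ACh")
  set.seed(22)
  draws <- MASS::mvrnorm(50000, mu = fit$coef, Sigma = fit$vcov)
  mc_se <- stats::sd(draws[, "pKB"] + draws[, "logAlpha"])
  expect_equal(ach$se, mc_se, tolerance = 0.05)
})

test_that("construct comparison flags real shifts and matches a permutation oracle", {
  # identical groups: nothing significant
  same <- data.frame(
    construct = rep(c("WT", "mutA", "mutB"), each = 4),
    estimate = rep(c(7, 7, 7), each = 4) + rep(c(0, 0.01, -0.01, 0.02), 3)
  )
  cmp_same <- compare_to_wildtype(same, reference = "WT")
  expect_false(any(cmp_same$table$significant))

  # a 2-log-unit drop at tight SD is unmissable
  set.seed(31)
  big <- data.frame(
    construct = rep(c("WT", "mut"), each = 4),
    estimate = c(rnorm(4, 7, 0.1), rnorm(4, 5, 0.1))
  )
  cmp_big <- compare_to_wildtype(big, reference = "WT")
  expect_true(cmp_big$table$significant)
  expect_lt(cmp_big$table$p_adj, 0.001)
  expect_equal(cmp_big$table$diff, -2, tolerance = 0.3)

  # Dunnett adjusted p-values vs label-permutation many-to-one oracle
  set.seed(33)
  dat <- data.frame(
    construct = rep(c("WT", "mutA", "mutB"), each = 5),
    estimate = c(rnorm(5, 7, 0.3), rnorm(5, 6.6, 0.3), rnorm(5, 7.1, 0.3))
  )
  cmp <- compare_to_wildtype(dat, reference = "WT")
  perm <- dunnett_perm(dat$estimate, dat$construct, "WT", n_perm = 4000)
  ord <- match(cmp$table$construct, names(perm$p_adj))
  expect_equal(cmp$table$p_adj, unname(perm$p_adj[ord]), tolerance = 0.05)

  # degenerate inputs
  expect_error(
    compare_to_wildtype(data.frame(construct = "WT", estimate = 7)),
    "at least two"
  )
  single <- data.frame(
    construct = c("WT", "mut"), estimate = c(7, 5), se = c(0.2, 0.2)
  )
  expect_warning(cmp1 <- compare_to_wildtype(single), "z-test")
  expect_true(cmp1$table$significant)
  expect_error(
    compare_to_wildtype(single[, c("construct", "estimate")]),
    "no 'se' column"
  )
})
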