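#' Minimum inter-selection distance in one frame
#'
#' The elementary pocket metric: the minimum Euclidean distance over all
#' cross pairs between two atom selections, in Angstrom. Coordinates are
#' assumed pre-imaged (no periodic-boundary correction is applied).
#'
#' @param coords_a,coords_b Numeric n x 3 coordinate matrices (Angstrom).
#'   [selection_coords()] extracts these from a frame.
#' @return The minimum pairwise distance (Angstrom). Symmetric in its
#'   arguments. If the selections share an atom position the result is 0
#'   with a warning.
#' @examples
#' a <- matrix(c(0, 0, 0), ncol = 3)
#' b <- rbind(c(3, 0, 0), c(0, 4, 0))
#' min_pair_distance(a, b) # 3
#' @export
min_pair_distance <- function(coords_a, coords_b) {
  coords_a <- as_coord_matrix(coords_a)
  coords_b <- as_coord_matrix(coords_b)
  if (any(!is.finite(coords_a)) || any(!is.finite(coords_b))) {
    stop("non-finite coordinates in distance computation", call. = FALSE)
  }
  # ||a-b||^2 = |a|^2 + |b|^2 - 2 a.b over all cross pairs
  a2 <- rowSums(coords_a^2)
  b2 <- rowSums(coords_b^2)
  cross <- tcrossprod(coords_a, coords_b)
  d2 <- outer(a2, b2, "+") - 2 * cross
  d2min <- max(min(d2), 0) # clamp negative rounding residue
  if (d2min == 0) {
    warning(
      "selections overlap (shared atom position); minimum distance is 0",
      call. = FALSE
    )
  }
  sqrt(d2min)
}

as_coord_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 3, byrow = TRUE)
  if (ncol(x) != 3L) stop("coordinates must be n x 3", call. = FALSE)
  x
}

#' Scan a trajectory into distance series
#'
#' Computes one [distance_series] per requested metric across all frames of
#' a trajectory. Frame times are `frame_index * frame_interval_ns` starting
#' at 0, with a default interval of 0.2 ns (snapshots every 200 ps).
#'
#' @param topology A `bio3d` `pdb` object the selections were resolved
#'   against.
#' @param trajectory Either a multi-model `bio3d` `pdb` object (read with
#'   `multi = TRUE`) or a numeric matrix of xyz frames (n_frames rows,
#'   3 * n_atoms columns, e.g. from [bio3d::read.dcd()]).
#' @param metrics A named list; each element is a list or pair
#'   `list(sel_a, sel_b)` of [resolve_selection()] results. Names become
#'   metric names.
#' @param frame_interval_ns Time between frames, ns.
#' @param replicate,condition,subtype Labels attached to every series.
#' @return A list of `distance_series`, one per metric, all on the same
#'   time grid.
#' @export
scan_trajectory <- function(topology, trajectory, metrics,
                            frame_interval_ns = 0.2,
                            replicate = NA_character_,
                            condition = NA_character_,
                            subtype = NA_character_) {
  xyz <- if (inherits(trajectory, "pdb")) trajectory$xyz else trajectory
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0L) stop("trajectory contains zero frames", call. = FALSE)
  n_atoms_top <- nrow(topology$atom)
  if (ncol(xyz) != 3L * n_atoms_top) {
    stop(
      "trajectory frames have ", ncol(xyz) / 3, " atoms but the topology has ",
      n_atoms_top, call. = FALSE
    )
  }
  if (is.null(names(metrics)) || any(!nzchar(names(metrics)))) {
    stop("every metric must be named", call. = FALSE)
  }
  times <- (seq_len(nrow(xyz)) - 1L) * frame_interval_ns
  lapply(setNames(names(metrics), names(metrics)), function(m) {
    sels <- metrics[[m]]
    sel_a <- sels[[1L]]
    sel_b <- sels[[2L]]
    stopifnot(
      inherits(sel_a, "atom_selection"),
      inherits(sel_b, "atom_selection")
    )
    d <- vapply(seq_len(nrow(xyz)), function(i) {
      frame <- xyz[i, ]
      min_pair_distance(
        matrix(frame[sel_a$xyz], ncol = 3, byrow = TRUE),
        matrix(frame[sel_b$xyz], ncol = 3, byrow = TRUE)
      )
    }, numeric(1))
    distance_series(
      metric = m, time_ns = times, distance = d,
      frame_interval_ns = frame_interval_ns,
      replicate = replicate, condition = condition, subtype = subtype
    )
  })
}
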