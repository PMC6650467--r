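#' Open/closed pocket decision rules
#'
#' A pocket rule names the distance metric(s) it watches, how multiple
#' components are combined (`"single"` or `"min-of"`), the threshold in
#' Angstrom (default 5), and the comparator that declares a frame open.
#' The default comparator is strict `">"`: a frame sitting exactly at the
#' threshold is closed. The comparator is centralized here so a `">="`
#' dialect is a single configuration switch.
#'
#' @param name Rule name.
#' @param components Character vector of metric names the rule consumes.
#' @param combiner `"single"` (exactly one component) or `"min-of"` (the
#'   effective distance is the per-frame minimum over components).
#' @param threshold_A Threshold, Angstrom (> 0).
#' @param open_when `">"` (default) or `">="`.
#' @return An object of class `pocket_rule`.
#' @export
pocket_rule <- function(name, components, combiner = c("single", "min-of"),
                        threshold_A = 5, open_when = c(">", ">=")) {
  combiner <- match.arg(combiner)
  open_when <- match.arg(open_when)
  components <- as.character(components)
  if (length(components) == 0L) {
    stop("a pocket rule needs at least one component metric", call. = FALSE)
  }
  if (combiner == "single" && length(components) != 1L) {
    stop(
      "combiner 'single' requires exactly one component metric",
      call. = FALSE
    )
  }
  if (!is.numeric(threshold_A) || threshold_A <= 0) {
    stop("threshold must be a positive distance in Angstrom", call. = FALSE)
  }
  structure(
    list(
      name = name, components = components, combiner = combiner,
      threshold_A = threshold_A, open_when = open_when
    ),
    class = "pocket_rule"
  )
}

#' @export
print.pocket_rule <- function(x, ...) {
  eff <- if (x$combiner == "min-of") {
    paste0("min(", paste(x$components, collapse = ", "), ")")
  } else {
    x$components
  }
  cat(
    "Pocket rule '", x$name, "': open when ", eff, " ", x$open_when, " ",
    x$threshold_A, " A\n",
    sep = ""
  )
  invisible(x)
}

#' Canonical metric names used by the subtype rules
#' @keywords internal
POCKET_METRICS <- c(
  y264_c4550 = "Y2.64-C45.50",
  k732_e4549 = "K7.32-E45.49",
  y264_ecl2 = "Y2.64-ECL2"
)

#' Subtype- and condition-specific pocket rules
#'
#' Returns the open/closed rule used for one mAChR subtype under one
#' simulated condition:
#'
#' * **M1, M2** (all conditions) and **M4** (except Inactive-Apo): open when
#'   the minimum heavy-atom distance `Y2.64-C45.50` exceeds 5 Angstrom.
#' * **M3** (all conditions): the effective distance is the minimum of
#'   `Y2.64-C45.50` and `K7.32-E45.49`, because a K7.32/E45.49 salt bridge
#'   can keep the pocket closed even after Y2.64 releases ECL2.
#' * **M4, Inactive-Apo**: open when the minimum distance from Y2.64 to any
#'   ECL2 residue in the 45.49-45.51 range (`Y2.64-ECL2`) exceeds 5
#'   Angstrom, accommodating an ECL2 register shift in which Y2.64 engages
#'   the backbone of Q45.49 instead of C45.50.
#'
#' @param subtype One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param condition One of `"active-apo"`, `"active-ach"`, `"inactive-apo"`,
#'   `"inactive-tio"`.
#' @param threshold_A Threshold, Angstrom; 5 by default for every rule.
#' @param open_when Comparator dialect, `">"` by default.
#' @return A `pocket_rule`.
#' @export
make_subtype_rule <- function(subtype, condition, threshold_A = 5,
                              open_when = ">") {
  subtype <- match.arg(toupper(subtype), c("M1", "M2", "M3", "M4"))
  condition <- match.arg(
    tolower(condition),
    c("active-apo", "active-ach", "inactive-apo", "inactive-tio")
  )
  if (subtype == "M3") {
    pocket_rule(
      name = paste0("M3-minof-", condition),
      components = unname(POCKET_METRICS[c("y264_c4550", "k732_e4549")]),
      combiner = "min-of", threshold_A = threshold_A, open_when = open_when
    )
  } else if (subtype == "M4" && condition == "inactive-apo") {
    pocket_rule(
      name = "M4-ecl2range-inactive-apo",
      components = unname(POCKET_METRICS["y264_ecl2"]),
      combiner = "single", threshold_A = threshold_A, open_when = open_when
    )
  } else {
    pocket_rule(
      name = paste0(subtype, "-single-", condition),
      components = unname(POCKET_METRICS["y264_c4550"]),
      combiner = "single", threshold_A = threshold_A, open_when = open_when
    )
  }
}

#' Classify trajectory frames as pocket-open or pocket-closed
#'
#' Applies a [pocket_rule] to a set of raw distance series sharing one time
#' grid. The effective per-frame distance is the single component or the
#' minimum over components; a frame is open when the effective distance
#' satisfies the rule's comparator against its threshold. Classification is
#' defined on raw distances only; smooth with [moving_average()] for
#' display, never before classifying.
#'
#' @param series_list A list of `distance_series` (extra metrics beyond the
#'   rule's components are ignored).
#' @param rule A `pocket_rule`.
#' @return A [state_series] carrying the labels of the component series.
#' @export
classify_states <- function(series_list, rule) {
  stopifnot(inherits(rule, "pocket_rule"))
  if (inherits(series_list, "distance_series")) {
    series_list <- list(series_list)
  }
  metrics <- vapply(series_list, function(s) s$metric, character(1))
  missing <- setdiff(rule$components, metrics)
  if (length(missing) > 0L) {
    stop(
      "rule '", rule$name, "' needs metric(s) not present in the input: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  comp <- series_list[match(rule$components, metrics)]
  t0 <- comp[[1L]]$time_ns
  for (s in comp[-1L]) {
    if (!isTRUE(all.equal(s$time_ns, t0))) {
      stop(
        "component series of rule '", rule$name,
        "' are on different time grids",
        call. = FALSE
      )
    }
  }
  eff <- do.call(pmin, lapply(comp, function(s) s$distance))
  open <- if (rule$open_when == ">") {
    eff > rule$threshold_A
  } else {
    eff >= rule$threshold_A
  }
  s1 <- comp[[1L]]
  state_series(
    time_ns = t0, open = open, rule = rule$name,
    replicate = s1$replicate, condition = s1$condition, subtype = s1$subtype
  )
}

#' Open-fraction summaries across replicates and conditions
#'
#' Aggregates per-frame open/closed states into open fractions. Pooled
#' rows are frame-weighted (sum of open frames over sum of frames: "open
#' X% of the time" taken literally); the unweighted mean of per-replicate
#' fractions is reported alongside, since the two differ when replicate
#' lengths differ.
#'
#' @param states A list of [state_series] (or a single one).
#' @param pooling `"per-replicate"` (no pooling), `"per-condition"` (pool
#'   replicates within subtype x condition), or `"per-subtype"` (pool
#'   conditions and replicates within subtype).
#' @return A data.frame with columns `subtype`, `condition`, `replicate`,
#'   `n_frames`, `n_open`, `open_fraction`, and, for pooled rows,
#'   `mean_of_fractions`.
#' @export
open_fraction <- function(states,
                          pooling = c(
                            "per-replicate", "per-condition", "per-subtype"
                          )) {
  pooling <- match.arg(pooling)
  if (inherits(states, "state_series")) states <- list(states)
  if (length(states) == 0L) stop("no state series supplied", call. = FALSE)
  per_rep <- do.call(rbind, lapply(states, function(s) {
    data.frame(
      subtype = s$subtype, condition = s$condition, replicate = s$replicate,
      n_frames = length(s$open), n_open = sum(s$open),
      stringsAsFactors = FALSE
    )
  }))
  if (sum(per_rep$n_frames) == 0L) {
    stop("zero frames in total", call. = FALSE)
  }
  per_rep$open_fraction <- per_rep$n_open / per_rep$n_frames
  if (pooling == "per-replicate") {
    return(per_rep[order(per_rep$subtype, per_rep$condition, per_rep$replicate), ,
      drop = FALSE
    ])
  }
  keys <- if (pooling == "per-condition") {
    c("subtype", "condition")
  } else {
    "subtype"
  }
  agg <- stats::aggregate(
    per_rep[c("n_frames", "n_open")],
    by = per_rep[keys], FUN = sum
  )
  frac <- stats::aggregate(
    list(mean_of_fractions = per_rep$open_fraction),
    by = per_rep[keys], FUN = mean
  )
  out <- merge(agg, frac, by = keys, sort = TRUE)
  if (pooling == "per-subtype") out$condition <- "pooled"
  out$replicate <- "pooled"
  out$open_fraction <- out$n_open / out$n_frames
  out[c(
    "subtype", "condition", "replicate", "n_frames", "n_open",
    "open_fraction", "mean_of_fractions"
  )]
}

#' Distance histograms per subtype and condition
#'
#' Bins raw distances into half-open bins `[lo, hi)` of constant width,
#' pooled over the series that share a subtype x condition label, so
#' that the per-group counts sum to the group's total frame count.
#'
#' @param series_list A list of `distance_series`.
#' @param bin_width_A Bin width, Angstrom (> 0).
#' @param range Optional `c(lo, hi)` covering all distances; by default the
#'   bins start at 0 and extend to cover the data.
#' @return A data.frame with columns `subtype`, `condition`, `metric`,
#'   `bin_lo`, `bin_hi`, `count`.
#' @export
distance_histogram <- function(series_list, bin_width_A = 0.5, range = NULL) {
  if (inherits(series_list, "distance_series")) {
    series_list <- list(series_list)
  }
  if (length(series_list) == 0L) {
    stop("no distance series supplied", call. = FALSE)
  }
  if (!is.numeric(bin_width_A) || bin_width_A <= 0) {
    stop("bin width must be positive", call. = FALSE)
  }
  all_d <- unlist(lapply(series_list, function(s) s$distance))
  lo <- if (is.null(range)) 0 else range[1L]
  if (is.null(range)) {
    n_bins <- max(1L, ceiling((max(all_d) - lo) / bin_width_A))
    # a value exactly on the top edge needs one more half-open bin
    if (max(all_d) >= lo + n_bins * bin_width_A) n_bins <- n_bins + 1L
  } else {
    if (any(all_d < range[1L]) || any(all_d >= range[2L])) {
      stop(
        "distances fall outside the requested histogram range",
        call. = FALSE
      )
    }
    n_bins <- ceiling((range[2L] - lo) / bin_width_A)
  }
  key <- vapply(series_list, function(s) {
    paste(s$subtype, s$condition, s$metric, sep = "\r")
  }, character(1))
  out <- lapply(unique(key), function(k) {
    grp <- series_list[key == k]
    d <- unlist(lapply(grp, function(s) s$distance))
    idx <- pmin(floor((d - lo) / bin_width_A) + 1L, n_bins)
    counts <- tabulate(idx, nbins = n_bins)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    data.frame(
      subtype = parts[1L], condition = parts[2L], metric = parts[3L],
      bin_lo = lo + (seq_len(n_bins) - 1L) * bin_width_A,
      bin_hi = lo + seq_len(n_bins) * bin_width_A,
      count = counts, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
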