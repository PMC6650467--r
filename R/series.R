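#' Per-frame distance series
#'
#' A `distance_series` holds one distance metric sampled over trajectory
#' frames: strictly increasing times in nanoseconds and non-negative
#' distances in Angstrom, with replicate/condition/subtype labels used by
#' the pooling stage.
#'
#' @param metric Metric name, e.g. `"Y2.64-C45.50"`.
#' @param time_ns Numeric vector of frame times (ns), strictly increasing.
#' @param distance Numeric vector of distances (Angstrom), same length.
#' @param frame_interval_ns Sampling interval (ns); defaults to the median
#'   time step.
#' @param replicate,condition,subtype Optional labels.
#' @return An object of class `distance_series`.
#' @export
distance_series <- function(metric, time_ns, distance,
                            frame_interval_ns = NULL,
                            replicate = NA_character_,
                            condition = NA_character_,
                            subtype = NA_character_) {
  time_ns <- as.numeric(time_ns)
  distance <- as.numeric(distance)
  if (length(time_ns) != length(distance)) {
    stop("time and distance vectors must have equal length", call. = FALSE)
  }
  if (length(time_ns) == 0L) stop("empty distance series", call. = FALSE)
  if (any(diff(time_ns) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(distance)) || any(distance < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  if (is.null(frame_interval_ns)) {
    frame_interval_ns <- if (length(time_ns) > 1L) {
      stats::median(diff(time_ns))
    } else {
      NA_real_
    }
  }
  structure(
    list(
      metric = metric, time_ns = time_ns, distance = distance,
      frame_interval_ns = frame_interval_ns,
      replicate = as.character(replicate),
      condition = as.character(condition),
      subtype = as.character(subtype)
    ),
    class = "distance_series"
  )
}

#' @export
print.distance_series <- function(x, ...) {
  cat(
    "Distance series", x$metric, "-", length(x$time_ns), "frames,",
    sprintf("%.1f-%.1f ns,", min(x$time_ns), max(x$time_ns)),
    sprintf("range %.2f-%.2f A", min(x$distance), max(x$distance)), "\n"
  )
  if (!is.na(x$subtype)) {
    cat(
      " labels:", x$subtype, "/", x$condition, "/ replicate",
      x$replicate, "\n"
    )
  }
  invisible(x)
}

#' Per-frame open/closed state series
#'
#' @param time_ns Frame times (ns), strictly increasing.
#' @param open Logical vector, `TRUE` = pocket open.
#' @param rule Name of the classification rule that produced the states.
#' @param replicate,condition,subtype Optional labels.
#' @return An object of class `state_series`.
#' @export
state_series <- function(time_ns, open, rule = NA_character_,
                         replicate = NA_character_,
                         condition = NA_character_,
                         subtype = NA_character_) {
  time_ns <- as.numeric(time_ns)
  open <- as.logical(open)
  if (length(time_ns) != length(open)) {
    stop("time and state vectors must have equal length", call. = FALSE)
  }
  if (length(time_ns) == 0L) stop("empty state series", call. = FALSE)
  if (any(diff(time_ns) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (anyNA(open)) stop("states must be TRUE/FALSE, not NA", call. = FALSE)
  structure(
    list(
      time_ns = time_ns, open = open, rule = as.character(rule),
      replicate = as.character(replicate),
      condition = as.character(condition),
      subtype = as.character(subtype)
    ),
    class = "state_series"
  )
}

#' @export
print.state_series <- function(x, ...) {
  cat(
    "State series (rule ", x$rule, "): ", length(x$open), " frames, ",
    sprintf("%.1f%% open", 100 * mean(x$open)), "\n",
    sep = ""
  )
  invisible(x)
}

#' Moving-average smoothing of a distance series
#'
#' Smooths a distance time trace with a centered moving average of the
#' given window (default 50 ns). At the series ends the window is clipped
#' to the available frames (it shrinks rather than dropping frames), so the
#' output covers the same time grid as the input. Smoothing is a
#' presentation device for time traces; open/closed classification always
#' operates on raw distances.
#'
#' @param series A `distance_series`.
#' @param window_ns Window width in ns (full width, centered).
#' @return A `distance_series` on the same time grid, with the metric name
#'   suffixed by `"|ma<window>"`.
#' @examples
#' s <- distance_series("d", time_ns = 1:5, distance = c(1, 2, 3, 4, 5))
#' moving_average(s, window_ns = 3)$distance # 1.5 2 3 4 4.5
#' @export
moving_average <- function(series, window_ns = 50) {
  stopifnot(inherits(series, "distance_series"))
  if (!is.numeric(window_ns) || window_ns <= 0) {
    stop("window_ns must be positive", call. = FALSE)
  }
  dt <- series$frame_interval_ns
  if (!is.na(dt) && window_ns < dt) {
    warning(
      "smoothing window (", window_ns, " ns) is narrower than the frame ",
      "interval (", dt, " ns); returning the series unchanged"
    )
    return(series)
  }
  t <- series$time_ns
  v <- series$distance
  half <- window_ns / 2
  eps <- sqrt(.Machine$double.eps) * max(abs(t), 1)
  cs <- c(0, cumsum(v))
  i_lo <- findInterval(t - half - eps, t) + 1L
  i_hi <- findInterval(t + half + eps, t)
  out <- (cs[i_hi + 1L] - cs[i_lo]) / (i_hi - i_lo + 1L)
  distance_series(
    metric = paste0(series$metric, "|ma", window_ns),
    time_ns = t, distance = out,
    frame_interval_ns = series$frame_interval_ns,
    replicate = series$replicate, condition = series$condition,
    subtype = series$subtype
  )
}

#' Read distance series from a delimited table
#'
#' Reads a CSV/TSV file with a `time_ns` column, one numeric column per
#' distance metric, and optional `replicate`, `condition` and `subtype`
#' label columns (constant within a file). This is the first-class
#' alternative input for users who compute distances elsewhere.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; inferred from the extension by default
#'   (`.tsv` -> tab, else comma).
#' @return A list of `distance_series`, one per metric column.
#' @export
load_distance_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.csv(path,
    sep = sep, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  if (!"time_ns" %in% names(df)) {
    stop(
      "distance table ", path, " lacks the required 'time_ns' header",
      call. = FALSE
    )
  }
  label_cols <- intersect(c("replicate", "condition", "subtype"), names(df))
  metric_cols <- setdiff(names(df), c("time_ns", label_cols))
  if (length(metric_cols) == 0L) {
    stop("distance table ", path, " has no metric columns", call. = FALSE)
  }
  for (col in c("time_ns", metric_cols)) {
    bad <- which(!is.na(df[[col]]) & is.na(suppressWarnings(
      as.numeric(df[[col]])
    )) | is.na(df[[col]]))
    if (length(bad) > 0L) {
      stop(
        "non-numeric value in column '", col, "' of ", path,
        " at data row ", bad[1L],
        call. = FALSE
      )
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  if (any(diff(df$time_ns) <= 0)) {
    stop("times in ", path, " are not strictly increasing", call. = FALSE)
  }
  labels <- lapply(setNames(label_cols, label_cols), function(col) {
    u <- unique(df[[col]])
    if (length(u) > 1L) {
      stop(
        "label column '", col, "' is not constant within ", path,
        call. = FALSE
      )
    }
    as.character(u)
  })
  lapply(metric_cols, function(m) {
    distance_series(
      metric = m, time_ns = df$time_ns, distance = df[[m]],
      replicate = labels$replicate %||% NA_character_,
      condition = labels$condition %||% NA_character_,
      subtype = labels$subtype %||% NA_character_
    )
  })
}

#' Write distance series to a delimited table
#'
#' Inverse of [load_distance_table()]: all series must share one time grid
#' and one set of labels; each series becomes a metric column.
#'
#' @param series_list A list of `distance_series`.
#' @param path Output path (`.tsv` for tab-separated, else comma).
#' @return The path, invisibly.
#' @export
write_distance_table <- function(series_list, path) {
  if (inherits(series_list, "distance_series")) {
    series_list <- list(series_list)
  }
  t0 <- series_list[[1L]]$time_ns
  for (s in series_list) {
    stopifnot(inherits(s, "distance_series"))
    if (!isTRUE(all.equal(s$time_ns, t0))) {
      stop("all series must share one time grid", call. = FALSE)
    }
  }
  df <- data.frame(time_ns = t0, check.names = FALSE)
  for (s in series_list) df[[s$metric]] <- s$distance
  s1 <- series_list[[1L]]
  if (!is.na(s1$replicate)) df$replicate <- s1$replicate
  if (!is.na(s1$condition)) df$condition <- s1$condition
  if (!is.na(s1$subtype)) df$subtype <- s1$subtype
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path,
    sep = sep, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
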