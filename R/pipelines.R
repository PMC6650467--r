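#' Run the full pocket-classification pipeline on a directory of distance
#' tables
#'
#' Loads every `dist_*.csv` distance table in `input_dir` (the layout
#' written by [make_fixture_suite()], or any tables with `subtype`,
#' `condition` and `replicate` labels), applies the subtype- and
#' condition-specific open/closed rule to the raw distances, and writes
#' tidy result tables plus a reproducibility manifest to `out_dir`:
#'
#' * `states.csv` — per-frame open/closed calls;
#' * `open_fraction_by_replicate.csv`, `open_fraction_by_condition.csv`,
#'   `open_fraction_by_subtype.csv` — open-fraction summaries, pooled rows
#'   carrying both the frame-weighted fraction and the mean of
#'   per-replicate fractions;
#' * `histograms.csv` — pooled distance histograms per subtype x
#'   condition;
#' * `smoothed_traces.csv` — moving-average traces for display;
#' * `manifest.json` — package version, configuration echo, seed and input
#'   file hashes. Reruns on identical inputs are byte-identical.
#'
#' @param input_dir Directory containing `dist_*.csv` tables.
#' @param out_dir Output directory (created if needed).
#' @param threshold_A Open/closed threshold override, Angstrom.
#' @param open_when Comparator dialect, `">"` (default) or `">="`.
#' @param window_ns Moving-average window for the display traces.
#' @param bin_width_A Histogram bin width.
#' @param seed Seed echoed into the manifest (the pipeline itself is
#'   deterministic; the seed records how the inputs were generated).
#' @return Invisibly, a list with the summary tables and output paths.
#' @export
run_pocket_pipeline <- function(input_dir, out_dir,
                                threshold_A = 5, open_when = ">",
                                window_ns = 50, bin_width_A = 0.5,
                                seed = NULL) {
  files <- sort(list.files(input_dir, pattern = "^dist_.*\\.csv$",
    full.names = TRUE
  ))
  if (length(files) == 0L) {
    stop(
      "stage 'load': no dist_*.csv tables found in ", input_dir,
      call. = FALSE
    )
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  series_sets <- with_stage("load", lapply(files, load_distance_table))

  states <- with_stage("classify", lapply(series_sets, function(set) {
    s1 <- set[[1L]]
    rule <- make_subtype_rule(s1$subtype, s1$condition,
      threshold_A = threshold_A, open_when = open_when
    )
    classify_states(set, rule)
  }))

  summaries <- with_stage("summarise", list(
    by_replicate = open_fraction(states, "per-replicate"),
    by_condition = open_fraction(states, "per-condition"),
    by_subtype = open_fraction(states, "per-subtype")
  ))

  all_series <- unlist(series_sets, recursive = FALSE)
  hist_tab <- with_stage(
    "histogram",
    distance_histogram(all_series, bin_width_A = bin_width_A)
  )
  smoothed <- with_stage("smooth", lapply(all_series, function(s) {
    sm <- suppressWarnings(moving_average(s, window_ns = window_ns))
    data.frame(
      subtype = s$subtype, condition = s$condition, replicate = s$replicate,
      metric = sm$metric, time_ns = sm$time_ns, distance = sm$distance,
      stringsAsFactors = FALSE
    )
  }))
  smoothed <- do.call(rbind, smoothed)

  states_tab <- do.call(rbind, lapply(states, function(s) {
    data.frame(
      subtype = s$subtype, condition = s$condition, replicate = s$replicate,
      rule = s$rule, time_ns = s$time_ns, open = s$open,
      stringsAsFactors = FALSE
    )
  }))

  paths <- c(
    states = file.path(out_dir, "states.csv"),
    by_replicate = file.path(out_dir, "open_fraction_by_replicate.csv"),
    by_condition = file.path(out_dir, "open_fraction_by_condition.csv"),
    by_subtype = file.path(out_dir, "open_fraction_by_subtype.csv"),
    histograms = file.path(out_dir, "histograms.csv"),
    smoothed = file.path(out_dir, "smoothed_traces.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  with_stage("write", {
    utils::write.csv(states_tab, paths[["states"]], row.names = FALSE)
    utils::write.csv(summaries$by_replicate, paths[["by_replicate"]],
      row.names = FALSE
    )
    utils::write.csv(summaries$by_condition, paths[["by_condition"]],
      row.names = FALSE
    )
    utils::write.csv(summaries$by_subtype, paths[["by_subtype"]],
      row.names = FALSE
    )
    utils::write.csv(hist_tab, paths[["histograms"]], row.names = FALSE)
    utils::write.csv(smoothed, paths[["smoothed"]], row.names = FALSE)
    write_manifest(paths[["manifest"]],
      pipeline = "pocket",
      config = list(
        threshold_A = threshold_A, open_when = open_when,
        window_ns = window_ns, bin_width_A = bin_width_A
      ),
      seed = seed, inputs = files
    )
  })
  invisible(list(
    summaries = summaries, histograms = hist_tab, states = states,
    paths = paths
  ))
}

#' Run the interaction-binding pipeline on per-construct tables
#'
#' For each construct: a global shared-parameter ATCM fit pooled over its
#' replicates, derived occupied-receptor affinities pKB(ACh) and pKB(NMS)
#' with propagated standard errors, and per-replicate fits feeding a
#' one-way ANOVA + Dunnett comparison of the chosen parameter against the
#' reference construct. A construct whose fit fails is reported in the
#' output and the remaining constructs are still processed.
#'
#' @param binding_files Named character vector of CSV paths (names are
#'   construct ids) or a single data.frame with a `construct` column.
#'   Tables need columns `A`, `B`, `I` (molar), `Y` (percent) and
#'   `replicate`.
#' @param out_dir Output directory.
#' @param reference Reference (wild-type) construct id; comparison is
#'   skipped with a notice if absent or if only one construct is supplied.
#' @param free,fixed Passed to [global_fit()].
#' @param compare_parameter Parameter compared across constructs: a free
#'   parameter name, or `"pKB_ACh"` for the derived occupied affinity.
#' @param seed Seed echoed into the manifest.
#' @return Invisibly, a list with `fits`, `derived`, `comparison` (or
#'   `NULL`), `errors`, and output paths. Writes `fits.json`,
#'   `derived_affinities.csv`, `comparison.csv` and `manifest.json`.
#' @export
run_binding_pipeline <- function(binding_files, out_dir, reference = "WT",
                                 free = c(
                                   "pKI", "pKB", "logAlpha", "logAlphaPrime"
                                 ),
                                 fixed = c(pKA = 9.7),
                                 compare_parameter = "pKB",
                                 seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(binding_files)) {
    if (!"construct" %in% names(binding_files)) {
      stop(
        "stage 'load': data.frame input needs a 'construct' column",
        call. = FALSE
      )
    }
    datasets <- split(binding_files, binding_files$construct)
    input_files <- character(0)
  } else {
    if (is.null(names(binding_files)) || any(!nzchar(names(binding_files)))) {
      stop(
        "stage 'load': binding_files must be named by construct",
        call. = FALSE
      )
    }
    datasets <- lapply(binding_files, read_binding_table)
    input_files <- unname(binding_files)
  }

  fits <- list()
  derived <- list()
  per_rep <- list()
  errors <- list()
  for (cid in names(datasets)) {
    d <- datasets[[cid]]
    res <- tryCatch(
      {
        fit <- global_fit(d, free = free, fixed = fixed)
        list(
          fit = fit,
          ach = derive_occupied_affinity(fit, "ACh"),
          nms = derive_occupied_affinity(fit, "NMS")
        )
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      errors[[cid]] <- conditionMessage(res)
      next
    }
    fits[[cid]] <- res$fit
    derived[[cid]] <- data.frame(
      construct = cid,
      pKB_apo = res$fit$estimates[["pKB"]],
      pKB_apo_se = unname(res$fit$se["pKB"]),
      pKB_ACh = res$ach$estimate, pKB_ACh_se = res$ach$se,
      pKB_NMS = res$nms$estimate, pKB_NMS_se = res$nms$se,
      rss = res$fit$rss, n_obs = res$fit$n_obs,
      stringsAsFactors = FALSE
    )
    # per-replicate fits supply the independent estimates the ANOVA needs
    reps <- split(d, d$replicate)
    per_rep[[cid]] <- do.call(rbind, lapply(names(reps), function(r) {
      rf <- tryCatch(global_fit(reps[[r]], free = free, fixed = fixed),
        error = function(e) NULL
      )
      if (is.null(rf)) {
        return(NULL)
      }
      est <- if (compare_parameter == "pKB_ACh") {
        rf$estimates[["pKB"]] + rf$estimates[["logAlpha"]]
      } else {
        rf$estimates[[compare_parameter]]
      }
      data.frame(
        construct = cid, replicate = r, estimate = est,
        stringsAsFactors = FALSE
      )
    }))
  }
  if (length(fits) == 0L) {
    stop(
      "stage 'fit': no construct could be fitted; first error: ",
      errors[[1L]],
      call. = FALSE
    )
  }

  derived_tab <- do.call(rbind, derived)
  rownames(derived_tab) <- NULL

  comparison <- NULL
  notice <- NULL
  est_tab <- do.call(rbind, per_rep)
  if (length(fits) < 2L || !reference %in% names(fits)) {
    notice <- paste0(
      "comparison skipped: need >= 2 fitted constructs including the ",
      "reference '", reference, "'"
    )
  } else {
    comparison <- with_stage(
      "compare",
      compare_to_wildtype(est_tab, reference = reference)
    )
  }

  paths <- c(
    fits = file.path(out_dir, "fits.json"),
    derived = file.path(out_dir, "derived_affinities.csv"),
    comparison = file.path(out_dir, "comparison.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  with_stage("write", {
    fit_records <- lapply(fits, function(f) {
      list(
        estimates = as.list(unclass(f$estimates)),
        se = as.list(f$se), fixed = as.list(f$fixed),
        rss = f$rss, n_obs = f$n_obs,
        convergence = f$convergence["info"]
      )
    })
    jsonlite::write_json(fit_records, paths[["fits"]],
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    utils::write.csv(derived_tab, paths[["derived"]], row.names = FALSE)
    if (!is.null(comparison)) {
      utils::write.csv(comparison$table, paths[["comparison"]],
        row.names = FALSE
      )
    }
    write_manifest(paths[["manifest"]],
      pipeline = "binding",
      config = list(
        reference = reference, free = free, fixed = as.list(fixed),
        compare_parameter = compare_parameter, notice = notice
      ),
      seed = seed, inputs = input_files
    )
  })
  invisible(list(
    fits = fits, derived = derived_tab, comparison = comparison,
    per_replicate_estimates = est_tab, errors = errors, notice = notice,
    paths = paths
  ))
}

read_binding_table <- function(path) {
  if (!file.exists(path)) {
    stop("binding table not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("A", "B", "I", "Y")
  if (!all(need %in% names(df))) {
    stop(
      "binding table ", path, " lacks column(s): ",
      paste(setdiff(need, names(df)), collapse = ", "),
      call. = FALSE
    )
  }
  for (col in need) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0L) {
      stop(
        "non-numeric value in column '", col, "' of ", path,
        " at data row ", bad[1L],
        call. = FALSE
      )
    }
    df[[col]] <- as.numeric(df[[col]])
  }
  if (!"replicate" %in% names(df)) df$replicate <- "1"
  df
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

write_manifest <- function(path, pipeline, config, seed, inputs) {
  manifest <- list(
    package = "allopocket",
    version = as.character(utils::packageVersion("allopocket")),
    pipeline = pipeline,
    config = config,
    seed = seed,
    inputs = if (length(inputs) > 0L) {
      data.frame(
        file = basename(inputs), md5 = unname(tools::md5sum(inputs)),
        stringsAsFactors = FALSE
      )
    } else {
      list()
    }
  )
  jsonlite::write_json(manifest, path,
    auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(path)
}
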