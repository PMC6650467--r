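#' Simulate a two-state pocket trajectory with known open probability
#'
#' Emulates the statistical structure the pocket classifier consumes: a
#' hidden open/closed process and per-frame residue-pair distances. The
#' hidden process is a discrete-time two-state Markov chain at frame
#' resolution. The per-frame probability of leaving the open state is
#' `frame_interval_ns / mean_dwell_open_ns`, and the closed-to-open
#' probability is chosen so the chain's stationary open probability equals
#' `p_open` exactly; the initial state is drawn from the stationary
#' distribution. Distances are emitted per state from Gaussian
#' distributions truncated at zero; by default the closed state sits at
#' 3.0 A (sd 0.4) and the open state at 8.0 A (sd 1.5), straddling the 5 A
#' classification threshold the way bimodal pocket-distance histograms do.
#' Several metrics can be emitted from the one shared hidden state (with
#' independent emission noise) to exercise min-of rules.
#'
#' @param p_open Stationary open probability, strictly between 0 and 1.
#' @param n_frames Number of frames.
#' @param mean_dwell_open_ns Mean dwell time of the open state (ns); must
#'   exceed the frame interval.
#' @param frame_interval_ns Frame spacing (ns), default 0.2.
#' @param emission List with elements `closed` and `open`, each
#'   `c(mean = , sd = )` in Angstrom.
#' @param metrics Character vector of metric names to emit.
#' @param seed Optional integer seed.
#' @param replicate,condition,subtype Labels attached to the output.
#' @return A list with `states` (the hidden truth as a [state_series]) and
#'   `distances` (list of [distance_series], one per metric).
#' @export
simulate_pocket_trajectory <- function(p_open, n_frames,
                                       mean_dwell_open_ns = 10,
                                       frame_interval_ns = 0.2,
                                       emission = list(
                                         closed = c(mean = 3.0, sd = 0.4),
                                         open = c(mean = 8.0, sd = 1.5)
                                       ),
                                       metrics = "Y2.64-C45.50",
                                       seed = NULL,
                                       replicate = NA_character_,
                                       condition = NA_character_,
                                       subtype = NA_character_) {
  if (!is.numeric(p_open) || p_open <= 0 || p_open >= 1) {
    stop("p_open must lie strictly between 0 and 1", call. = FALSE)
  }
  if (n_frames < 1L) stop("n_frames must be positive", call. = FALSE)
  if (mean_dwell_open_ns <= frame_interval_ns) {
    stop(
      "mean open dwell time must exceed the frame interval",
      call. = FALSE
    )
  }
  q_oc <- frame_interval_ns / mean_dwell_open_ns # P(open -> closed)
  q_co <- p_open * q_oc / (1 - p_open) # P(closed -> open), stationarity
  if (q_co > 1) {
    stop(
      "stationarity is unattainable: the implied closed->open probability ",
      "exceeds 1; lengthen mean_dwell_open_ns or lower p_open",
      call. = FALSE
    )
  }
  mu_c <- emission$closed[["mean"]]
  mu_o <- emission$open[["mean"]]
  if (mu_o <= 5 || mu_c >= 5) {
    warning(
      "emission means do not straddle the conventional 5 A threshold; ",
      "classification will not track the hidden state",
      call. = FALSE
    )
  }
  if (!is.null(seed)) set.seed(seed)

  open <- logical(n_frames)
  open[1L] <- stats::runif(1) < p_open
  u <- stats::runif(n_frames)
  for (i in seq_len(n_frames)[-1L]) {
    open[i] <- if (open[i - 1L]) u[i] >= q_oc else u[i] < q_co
  }
  times <- (seq_len(n_frames) - 1L) * frame_interval_ns

  dists <- lapply(setNames(metrics, metrics), function(m) {
    mu <- ifelse(open, mu_o, mu_c)
    sd <- ifelse(open, emission$open[["sd"]], emission$closed[["sd"]])
    d <- pmax(stats::rnorm(n_frames, mu, sd), 0)
    distance_series(
      metric = m, time_ns = times, distance = d,
      frame_interval_ns = frame_interval_ns,
      replicate = replicate, condition = condition, subtype = subtype
    )
  })
  list(
    states = state_series(
      time_ns = times, open = open, rule = "generator-truth",
      replicate = replicate, condition = condition, subtype = subtype
    ),
    distances = dists
  )
}

#' Full-factorial interaction-binding design
#'
#' @param A Radioligand concentration(s), molar.
#' @param B Modulator concentrations, molar (include 0 for the
#'   no-modulator curves).
#' @param I Competitor concentrations, molar (include 0 for the top of
#'   the curve).
#' @return A data.frame with one row per concentration combination.
#' @export
binding_design <- function(A = 2e-10,
                           B = c(0, 1e-7, 1e-6, 1e-5, 1e-4),
                           I = c(0, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2)) {
  expand.grid(A = A, B = B, I = I, KEEP.OUT.ATTRS = FALSE)
}

#' Simulate replicate interaction-binding datasets
#'
#' Generates percentage-specific-binding observations as
#' `atcm_predict(true_params, A, B, I)` plus additive Gaussian noise, for
#' `n_replicates` independent replicates of a design. Defaults mirror a
#' typical mAChR interaction assay: 0.2 nM radioligand, six competitor
#' concentrations including zero, five modulator concentrations including
#' zero, and noise of 3 percentage points.
#'
#' @param true_params An [atcm_params] object.
#' @param design A data.frame with columns `A`, `B`, `I` (see
#'   [binding_design()]).
#' @param n_replicates Number of replicates.
#' @param noise_sd Additive Gaussian noise, percentage points (>= 0).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   datasets.
#' @param construct Construct label stored with the data.
#' @return A data.frame with columns `construct`, `replicate`, `A`, `B`,
#'   `I`, `Y`.
#' @export
simulate_binding <- function(true_params, design = binding_design(),
                             n_replicates = 3L, noise_sd = 3,
                             seed = NULL, construct = "synthetic") {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(unique(design$B)) < 2L || length(unique(design$I)) < 2L) {
    warning(
      "degenerate design: B or I does not vary; cooperativity and ",
      "competitor parameters will not be identifiable downstream",
      call. = FALSE
    )
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- atcm_predict(true_params, design$A, design$B, design$I)
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(
      construct = construct, replicate = as.character(r),
      A = design$A, B = design$B, I = design$I,
      Y = mu + stats::rnorm(nrow(design), 0, noise_sd),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Deterministic fixture suite for end-to-end runs
#'
#' Writes a small, seed-reproducible set of synthetic inputs exercising
#' both pipelines:
#'
#' * distance tables for four synthetic "subtypes" labelled M1-M4 with
#'   stationary open probabilities 0.50, 0.005, 0.035 and 0.045 — the
#'   qualitative ordering M1 >> M4 ~ M3 > M2 — three replicates in each of
#'   the four conditions, with the metric columns each subtype's rule
#'   needs (M3 emits two correlated metrics; the M4 Inactive-Apo files
#'   emit the ECL2-range metric);
#' * wild-type-like and mutant-like interaction-binding tables, the mutant
#'   generated with pKB reduced by 1 log unit.
#'
#' Everything here is synthetic: the files emulate the statistical
#' structure of the real analyses, not any measured system.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed; the whole suite derives from it.
#' @param n_frames Frames per trajectory replicate.
#' @param mean_dwell_open_ns Open-state dwell time used for every subtype.
#' @param binding_params True ATCM parameters of the wild-type-like tables.
#' @param mutant_dpKB Log-unit reduction of pKB in the mutant-like tables.
#' @param noise_sd Binding noise, percentage points.
#' @return Invisibly, a data.frame manifest (file, md5, role) also written
#'   to `manifest.csv` in `outdir`.
#' @export
make_fixture_suite <- function(outdir, seed = 1L, n_frames = 5000L,
                               mean_dwell_open_ns = 5,
                               binding_params = atcm_params(
                                 pKA = 9.7, pKI = 4.7, pKB = 6.5,
                                 logAlpha = 1.5, logAlphaPrime = 0.2
                               ),
                               mutant_dpKB = 1.0,
                               noise_sd = 3) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p_open <- c(M1 = 0.50, M2 = 0.005, M3 = 0.035, M4 = 0.045)
  conditions <- c("active-apo", "active-ach", "inactive-apo", "inactive-tio")
  files <- character(0)
  roles <- character(0)
  k <- 0L
  for (st in names(p_open)) {
    for (cond in conditions) {
      metrics <- if (st == "M3") {
        unname(POCKET_METRICS[c("y264_c4550", "k732_e4549")])
      } else if (st == "M4" && cond == "inactive-apo") {
        unname(POCKET_METRICS["y264_ecl2"])
      } else {
        unname(POCKET_METRICS["y264_c4550"])
      }
      for (rep in 1:3) {
        k <- k + 1L
        sim <- simulate_pocket_trajectory(
          p_open = p_open[[st]], n_frames = n_frames,
          mean_dwell_open_ns = mean_dwell_open_ns,
          metrics = metrics,
          seed = derive_seed(seed, k),
          replicate = as.character(rep), condition = cond, subtype = st
        )
        f <- file.path(outdir, sprintf("dist_%s_%s_rep%d.csv", st, cond, rep))
        write_distance_table(sim$distances, f)
        files <- c(files, f)
        roles <- c(roles, "distance-table")
      }
    }
  }
  wt <- simulate_binding(binding_params,
    n_replicates = 3, noise_sd = noise_sd,
    seed = derive_seed(seed, 9001L), construct = "WT"
  )
  mut_params <- atcm_params(
    pKA = binding_params[["pKA"]], pKI = binding_params[["pKI"]],
    pKB = binding_params[["pKB"]] - mutant_dpKB,
    logAlpha = binding_params[["logAlpha"]],
    logAlphaPrime = binding_params[["logAlphaPrime"]]
  )
  mut <- simulate_binding(mut_params,
    n_replicates = 3, noise_sd = noise_sd,
    seed = derive_seed(seed, 9002L), construct = "mutant"
  )
  f_wt <- file.path(outdir, "binding_WT.csv")
  f_mut <- file.path(outdir, "binding_mutant.csv")
  utils::write.csv(wt, f_wt, row.names = FALSE, quote = FALSE)
  utils::write.csv(mut, f_mut, row.names = FALSE, quote = FALSE)
  files <- c(files, f_wt, f_mut)
  roles <- c(roles, "binding-table", "binding-table")

  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    role = roles,
    seed = seed,
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
    row.names = FALSE, quote = FALSE
  )
  invisible(manifest)
}

# Deterministic per-task seed derived from a master seed, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(k) * 101) %% 2147483647)
}
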