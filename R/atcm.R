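#' Allosteric ternary complex model parameters
#'
#' All affinities and cooperativities are carried as base-10 logarithms,
#' the scale on which they are estimated:
#'
#' * `pKA`: -log10 of the radioligand's equilibrium dissociation constant
#'   (molar); here the orthosteric antagonist radioligand
#'   (e.g. \[3H\]NMS).
#' * `pKI`: -log10 of the orthosteric competitor's dissociation constant
#'   (e.g. acetylcholine).
#' * `pKB`: -log10 of the modulator's dissociation constant at the *free*
#'   receptor, also written pKB(Apo).
#' * `logAlpha`: log10 of the binding cooperativity alpha between the
#'   modulator and the competitor, alpha = KB(Apo)/KB(competitor-occupied);
#'   positive values mean positive modulation.
#' * `logAlphaPrime`: log10 of the cooperativity alpha' between the
#'   modulator and the radioligand, alpha' = KB(Apo)/KB(radioligand-occupied).
#'
#' Derived occupied-state affinities follow as `pKB(ACh) = pKB + logAlpha`
#' and `pKB(NMS) = pKB + logAlphaPrime`; see [derive_occupied_affinity()].
#'
#' @param pKA,pKI,pKB Negative log10 molar dissociation constants.
#' @param logAlpha,logAlphaPrime Log10 cooperativity factors.
#' @return An object of class `atcm_params` (a named numeric vector).
#' @export
atcm_params <- function(pKA, pKI, pKB, logAlpha = 0, logAlphaPrime = 0) {
  p <- c(
    pKA = pKA, pKI = pKI, pKB = pKB,
    logAlpha = logAlpha, logAlphaPrime = logAlphaPrime
  )
  if (any(!is.finite(p))) {
    stop(
      "non-finite parameter(s): ",
      paste(names(p)[!is.finite(p)], collapse = ", "),
      call. = FALSE
    )
  }
  structure(p, class = "atcm_params")
}

ATCM_PARAM_NAMES <- c("pKA", "pKI", "pKB", "logAlpha", "logAlphaPrime")

#' @export
print.atcm_params <- function(x, ...) {
  cat("ATCM parameters (log10 scale):\n")
  print(unclass(x))
  invisible(x)
}

#' Predicted percentage specific binding under the allosteric ternary
#' complex model
#'
#' Computes
#' \deqn{Y = \frac{100\,[A]}{[A] + \left(\frac{K_A K_B}{\alpha' [B] + K_B}\right)
#'   \left(1 + \frac{[I]}{K_I} + \frac{[B]}{K_B} +
#'   \frac{\alpha [I][B]}{K_I K_B}\right)}}
#' the equilibrium fractional occupancy of the receptor by the radioligand
#' A (in percent) in the presence of an orthosteric competitor I and an
#' allosteric modulator B, under mass action with no ligand depletion
#' (free concentrations equal totals). With `B = 0` it reduces exactly to
#' two-ligand competition, `Y = 100 A / (A + KA (1 + I/KI))`; with
#' alpha = alpha' = 1 the modulator cancels algebraically and Y is
#' independent of B.
#'
#' @param params An [atcm_params] object (or named vector with the same
#'   five elements).
#' @param A Radioligand concentration(s), molar, > 0.
#' @param B Modulator concentration(s), molar, >= 0.
#' @param I Competitor concentration(s), molar, >= 0.
#' @return Percentage specific binding in (0, 100]; vectors recycle.
#' @examples
#' p <- atcm_params(pKA = 9.7, pKI = 4.7, pKB = 6, logAlpha = 1.5)
#' atcm_predict(p, A = 10^-9.7, B = 0, I = 0) # 50
#' @export
atcm_predict <- function(params, A, B, I) {
  p <- as_atcm_params(params)
  n <- max(length(A), length(B), length(I))
  A <- rep_len(as.numeric(A), n)
  B <- rep_len(as.numeric(B), n)
  I <- rep_len(as.numeric(I), n)
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop("radioligand concentration A must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(B)) || any(B < 0) || any(!is.finite(I)) || any(I < 0)) {
    stop("B and I concentrations must be finite and >= 0", call. = FALSE)
  }
  KA <- 10^(-p[["pKA"]])
  KI <- 10^(-p[["pKI"]])
  KB <- 10^(-p[["pKB"]])
  alpha <- 10^p[["logAlpha"]]
  alpha_p <- 10^p[["logAlphaPrime"]]
  for (nm in c("KA", "KI", "KB", "alpha", "alpha_p")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0) {
      stop(
        "parameter ", nm, " is not a finite positive number on the ",
        "linear scale; check ", switch(nm,
          KA = "pKA", KI = "pKI", KB = "pKB",
          alpha = "logAlpha", alpha_p = "logAlphaPrime"
        ),
        call. = FALSE
      )
    }
  }
  app_KA <- (KA * KB) / (alpha_p * B + KB)
  denom_poly <- 1 + I / KI + B / KB + (alpha * I * B) / (KI * KB)
  Y <- 100 * A / (A + app_KA * denom_poly)
  if (any(!is.finite(Y))) {
    stop(
      "non-finite predicted binding; parameter/concentration ",
      "combination overflows",
      call. = FALSE
    )
  }
  Y
}

as_atcm_params <- function(params) {
  if (inherits(params, "atcm_params")) {
    return(params)
  }
  p <- unlist(params)
  if (!all(ATCM_PARAM_NAMES %in% names(p))) {
    stop(
      "params must provide ", paste(ATCM_PARAM_NAMES, collapse = ", "),
      call. = FALSE
    )
  }
  atcm_params(
    p[["pKA"]], p[["pKI"]], p[["pKB"]],
    p[["logAlpha"]], p[["logAlphaPrime"]]
  )
}

#' Global shared-parameter fit of the allosteric ternary complex model
#'
#' Fits [atcm_predict()] to one or more interaction-binding datasets by
#' ordinary (unweighted) least squares on Y in percentage points, with each
#' free parameter constrained to a single value shared across all rows —
#' the pooled "global fit" that yields one best estimate per parameter and
#' its standard error from the regression. Optimization is
#' Levenberg-Marquardt on the log-scale parameters; when no starting
#' values are given, a coarse log-grid multistart (pK in 5..10,
#' log-cooperativities in -2..2) is screened by residual sum of squares
#' and the best few starts are polished.
#'
#' Identifiability is pre-checked from the design before any optimization:
#' freeing `pKB`, `logAlpha` or `logAlphaPrime` requires the modulator
#' concentration B to vary (with some B > 0), freeing `logAlpha`
#' additionally requires rows where both B and I are positive, and freeing
#' `pKI` requires I to vary.
#'
#' @param data A data.frame with columns `A`, `B`, `I` (molar) and `Y`
#'   (percent specific binding), or a list of such data.frames (replicates)
#'   that are pooled. An optional `replicate` column is kept for records.
#' @param free Character vector of parameter names to estimate.
#' @param fixed Named numeric vector of parameters held fixed (e.g.
#'   `c(pKA = 9.7)` from saturation binding). `free` and `fixed` must
#'   together cover all five parameters.
#' @param start Optional [atcm_params] (or named vector covering the free
#'   parameters) used as the single start; otherwise multistart.
#' @param n_starts Number of grid starts to polish when multistarting.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @return An object of class `atcm_fit`: estimates (all five parameters),
#'   `coef`/`se`/`vcov` for the free parameters, `rss`, `sigma`, `n_obs`,
#'   `df_residual`, `fixed`, and a `convergence` record.
#' @export
global_fit <- function(data, free = c("pKI", "pKB", "logAlpha", "logAlphaPrime"),
                       fixed = NULL, start = NULL, n_starts = 3L,
                       max_iter = 200L) {
  df <- pool_binding_data(data)
  free <- match.arg(free, ATCM_PARAM_NAMES, several.ok = TRUE)
  fixed_v <- unlist(fixed)
  if (length(intersect(free, names(fixed_v))) > 0L) {
    stop(
      "parameter(s) listed both free and fixed: ",
      paste(intersect(free, names(fixed_v)), collapse = ", "),
      call. = FALSE
    )
  }
  missing_p <- setdiff(ATCM_PARAM_NAMES, c(free, names(fixed_v)))
  if (length(missing_p) > 0L) {
    stop(
      "parameter(s) neither free nor fixed: ",
      paste(missing_p, collapse = ", "),
      call. = FALSE
    )
  }
  check_identifiability(df, free)

  full_params <- function(theta) {
    p <- c(theta, fixed_v)[ATCM_PARAM_NAMES]
    atcm_params(
      p[["pKA"]], p[["pKI"]], p[["pKB"]],
      p[["logAlpha"]], p[["logAlphaPrime"]]
    )
  }
  resid_fn <- function(theta) {
    names(theta) <- free
    df$Y - atcm_predict(full_params(theta), df$A, df$B, df$I)
  }

  starts <- if (!is.null(start)) {
    s <- unlist(start)[free]
    if (anyNA(s)) {
      stop("start must cover every free parameter", call. = FALSE)
    }
    list(s)
  } else {
    multistart_grid(free, resid_fn, n_starts)
  }

  best <- NULL
  tried <- 0L
  for (s in starts) {
    tried <- tried + 1L
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = max_iter)
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || !(fit$info %in% 1:4)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop(
      "global ATCM fit failed to converge from ", tried, " start(s); ",
      "check the design and consider fixing poorly informed parameters",
      call. = FALSE
    )
  }

  theta <- setNames(as.numeric(best$par), free)
  n <- nrow(df)
  p <- length(free)
  rss <- best$deviance
  df_res <- n - p
  if (df_res <= 0) {
    stop("more free parameters than observations", call. = FALSE)
  }
  sigma2 <- rss / df_res
  J <- numeric_jacobian(resid_fn, theta)
  JtJ <- crossprod(J)
  vc <- tryCatch(sigma2 * solve(JtJ), error = function(e) {
    stop(
      "singular information matrix at the optimum; the design does not ",
      "identify all free parameters jointly",
      call. = FALSE
    )
  })
  dimnames(vc) <- list(free, free)
  se <- sqrt(pmax(diag(vc), 0))

  structure(
    list(
      estimates = full_params(theta),
      coef = theta, se = se, vcov = vc,
      free = free, fixed = fixed_v,
      rss = rss, sigma = sqrt(sigma2), n_obs = n, df_residual = df_res,
      convergence = list(
        info = best$info, message = best$message,
        iterations = best$niter, starts_tried = tried
      )
    ),
    class = "atcm_fit"
  )
}

pool_binding_data <- function(data) {
  if (is.data.frame(data)) data <- list(data)
  dfs <- lapply(seq_along(data), function(i) {
    d <- data[[i]]
    if (!all(c("A", "B", "I", "Y") %in% names(d))) {
      stop(
        "binding data needs columns A, B, I (molar) and Y (percent)",
        call. = FALSE
      )
    }
    if (!"replicate" %in% names(d)) d$replicate <- as.character(i)
    d[c("A", "B", "I", "Y", "replicate")]
  })
  df <- do.call(rbind, dfs)
  if (nrow(df) == 0L) stop("no binding observations", call. = FALSE)
  num <- c("A", "B", "I", "Y")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  if (any(!is.finite(as.matrix(df[num])))) {
    stop("non-finite values in binding data", call. = FALSE)
  }
  if (any(df$A <= 0) || any(df$B < 0) || any(df$I < 0)) {
    stop("require A > 0, B >= 0, I >= 0", call. = FALSE)
  }
  df
}

check_identifiability <- function(df, free) {
  b_varies <- length(unique(df$B)) > 1L && any(df$B > 0)
  i_varies <- length(unique(df$I)) > 1L
  a_varies <- length(unique(df$A)) > 1L
  if (any(c("pKB", "logAlpha", "logAlphaPrime") %in% free) && !b_varies) {
    stop(
      "design not identifiable: modulator concentration B does not vary ",
      "(or is never positive) but ",
      paste(intersect(free, c("pKB", "logAlpha", "logAlphaPrime")),
        collapse = ", "
      ),
      " is free",
      call. = FALSE
    )
  }
  if ("logAlpha" %in% free && !any(df$B > 0 & df$I > 0)) {
    stop(
      "design not identifiable: logAlpha is free but no observation has ",
      "both B > 0 and I > 0",
      call. = FALSE
    )
  }
  if ("pKI" %in% free && !i_varies) {
    stop(
      "design not identifiable: competitor concentration I does not vary ",
      "but pKI is free",
      call. = FALSE
    )
  }
  if ("pKA" %in% free && !a_varies) {
    warning(
      "pKA is free but the radioligand concentration does not vary; ",
      "it is only weakly identified by the curve asymptotes",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

multistart_grid <- function(free, resid_fn, n_starts) {
  vals <- lapply(free, function(p) {
    if (p %in% c("logAlpha", "logAlphaPrime")) seq(-2, 2, by = 1) else 5:10
  })
  grid <- do.call(expand.grid, setNames(vals, free))
  if (nrow(grid) > 5000L) {
    grid <- grid[seq(1L, nrow(grid), length.out = 5000L), , drop = FALSE]
  }
  rss <- vapply(seq_len(nrow(grid)), function(i) {
    r <- tryCatch(resid_fn(as.numeric(grid[i, ])), error = function(e) NULL)
    if (is.null(r)) Inf else sum(r^2)
  }, numeric(1))
  ord <- order(rss)[seq_len(min(n_starts, nrow(grid)))]
  lapply(ord, function(i) setNames(as.numeric(grid[i, ]), free))
}

numeric_jacobian <- function(fn, theta, h = 1e-6) {
  f0 <- fn(theta)
  J <- matrix(NA_real_, nrow = length(f0), ncol = length(theta))
  for (j in seq_along(theta)) {
    step <- h * max(1, abs(theta[j]))
    up <- theta
    up[j] <- up[j] + step
    dn <- theta
    dn[j] <- dn[j] - step
    J[, j] <- (fn(up) - fn(dn)) / (2 * step)
  }
  J
}

#' @export
print.atcm_fit <- function(x, ...) {
  cat(
    "Global ATCM fit:", x$n_obs, "observations,", length(x$free),
    "free parameter(s), RSS =", signif(x$rss, 5), "\n"
  )
  tab <- data.frame(
    estimate = x$coef, std_error = x$se,
    row.names = x$free
  )
  print(round(tab, 4))
  if (length(x$fixed) > 0L) {
    cat(
      "Fixed:",
      paste(names(x$fixed), "=", x$fixed, collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' @export
coef.atcm_fit <- function(object, ...) object$coef

#' @export
vcov.atcm_fit <- function(object, ...) object$vcov

#' Wald confidence intervals for a global ATCM fit
#'
#' @param object An `atcm_fit`.
#' @param parm Parameters (default all free).
#' @param level Confidence level.
#' @param ... Unused.
#' @return A matrix of lower/upper bounds (t quantiles on the residual
#'   degrees of freedom).
#' @export
confint.atcm_fit <- function(object, parm = object$free, level = 0.95, ...) {
  q <- stats::qt(1 - (1 - level) / 2, df = object$df_residual)
  est <- object$coef[parm]
  se <- object$se[parm]
  out <- cbind(lower = est - q * se, upper = est + q * se)
  rownames(out) <- parm
  out
}

#' Modulator affinity at the occupied receptor, with propagated error
#'
#' The modulator's affinity at the competitor-occupied receptor follows
#' from the fit as `pKB(ACh) = pKB(Apo) + log10(alpha)`, and at the
#' radioligand-occupied receptor as `pKB(NMS) = pKB(Apo) + log10(alpha')`.
#' The standard error is linearly propagated from the fit covariance,
#' `sqrt(var(pKB) + var(logAlpha) + 2 cov)`; a component that was fixed in
#' the fit contributes no variance and the result is flagged accordingly.
#'
#' @param fit An `atcm_fit`.
#' @param which `"ACh"` (uses `logAlpha`) or `"NMS"` (uses `logAlphaPrime`).
#' @return A list with `estimate`, `se`, `which`, and `fixed_components`
#'   (character vector of components that carried no variance).
#' @export
derive_occupied_affinity <- function(fit, which = c("ACh", "NMS")) {
  stopifnot(inherits(fit, "atcm_fit"))
  which <- match.arg(which)
  coop <- if (which == "ACh") "logAlpha" else "logAlphaPrime"
  est <- fit$estimates[["pKB"]] + fit$estimates[[coop]]
  comps <- c("pKB", coop)
  free_comps <- intersect(comps, fit$free)
  fixed_comps <- setdiff(comps, free_comps)
  v <- 0
  if (length(free_comps) > 0L) {
    vc <- fit$vcov[free_comps, free_comps, drop = FALSE]
    v <- sum(vc)
  }
  if (length(fixed_comps) > 0L) {
    warning(
      "component(s) ", paste(fixed_comps, collapse = ", "),
      " were fixed in the fit; their variance is not propagated",
      call. = FALSE
    )
  }
  list(
    estimate = unname(est), se = sqrt(v), which = which,
    fixed_components = fixed_comps
  )
}
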