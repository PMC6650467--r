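#' Compare fitted parameters across constructs against a reference
#'
#' Many-to-one comparison of a fitted ATCM parameter (typically pKB(Apo)
#' or pKB(ACh)) between mutant constructs and a wild-type reference:
#' one-way ANOVA across constructs followed by Dunnett's post hoc test
#' against the reference, reporting adjusted p-values and a significance
#' flag at 0.05.
#'
#' The usual input is one estimate per independent experiment (e.g. from
#' per-experiment fits). When every construct contributes only a single
#' pooled estimate, no within-group variance exists; if a `se` column is
#' supplied the function falls back to unadjusted two-sample z-tests on
#' the pooled estimates and flags the caveat prominently.
#'
#' @param estimates A data.frame with columns `construct` and `estimate`
#'   (one row per independent experiment), optionally `se` (used only by
#'   the single-estimate fallback).
#' @param reference Construct name treated as wild type.
#' @param alpha Significance level for the flag.
#' @return An object of class `construct_comparison`: list with `anova`
#'   (the one-way ANOVA table, `NULL` in the fallback), `table` (per
#'   non-reference construct: mean difference from reference, standard
#'   error, test statistic, adjusted p, flag), `method`, and `caveat`.
#' @export
compare_to_wildtype <- function(estimates, reference = "WT", alpha = 0.05) {
  if (!all(c("construct", "estimate") %in% names(estimates))) {
    stop(
      "estimates needs 'construct' and 'estimate' columns",
      call. = FALSE
    )
  }
  estimates$construct <- as.character(estimates$construct)
  groups <- unique(estimates$construct)
  if (length(groups) < 2L) {
    stop("need at least two constructs to compare", call. = FALSE)
  }
  if (!reference %in% groups) {
    stop("reference construct '", reference, "' not present", call. = FALSE)
  }
  n_per <- table(estimates$construct)

  if (all(n_per == 1L)) {
    if (!"se" %in% names(estimates)) {
      stop(
        "single estimate per construct and no 'se' column: neither ANOVA ",
        "nor a z-test fallback is possible",
        call. = FALSE
      )
    }
    ref <- estimates[estimates$construct == reference, ]
    others <- estimates[estimates$construct != reference, ]
    diff <- others$estimate - ref$estimate
    se_d <- sqrt(others$se^2 + ref$se^2)
    z <- diff / se_d
    p <- 2 * stats::pnorm(-abs(z))
    tab <- data.frame(
      construct = others$construct, diff = diff, se = se_d,
      statistic = z, p_adj = p, significant = p < alpha,
      stringsAsFactors = FALSE
    )
    warning(
      "only one pooled estimate per construct: falling back to ",
      "unadjusted z-tests on estimate +/- SE; interpret with caution",
      call. = FALSE
    )
    return(structure(
      list(
        anova = NULL, table = tab, method = "z-test fallback",
        reference = reference,
        caveat = "single pooled estimate per construct; no ANOVA possible"
      ),
      class = "construct_comparison"
    ))
  }

  estimates$construct <- stats::relevel(
    factor(estimates$construct),
    ref = reference
  )
  fit <- stats::aov(estimate ~ construct, data = estimates)
  dunnett <- multcomp::glht(
    fit,
    linfct = multcomp::mcp(construct = "Dunnett")
  )
  sm <- summary(dunnett)
  tab <- data.frame(
    construct = sub(paste0(" - ", reference, "$"), "", names(sm$test$coefficients)),
    diff = as.numeric(sm$test$coefficients),
    se = as.numeric(sm$test$sigma),
    statistic = as.numeric(sm$test$tstat),
    p_adj = as.numeric(sm$test$pvalues),
    stringsAsFactors = FALSE
  )
  tab$significant <- tab$p_adj < alpha
  structure(
    list(
      anova = summary(fit), table = tab,
      method = "one-way ANOVA + Dunnett", reference = reference,
      caveat = NULL
    ),
    class = "construct_comparison"
  )
}

#' @export
print.construct_comparison <- function(x, ...) {
  cat(
    "Construct comparison vs '", x$reference, "' (", x$method, ")\n",
    sep = ""
  )
  if (!is.null(x$caveat)) cat("CAVEAT:", x$caveat, "\n")
  tab <- x$table
  tab$p_adj <- signif(tab$p_adj, 3)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}
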