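# Independent oracles used to cross-check the package's computations.

# Exhaustive double-loop minimum cross-pair distance.
brute_min_dist <- function(coords_a, coords_b) {
  best <- Inf
  for (i in seq_len(nrow(coords_a))) {
    for (j in seq_len(nrow(coords_b))) {
      d <- sqrt(sum((coords_a[i, ] - coords_b[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# Mass-action equilibrium species solver for the ternary-complex scheme
# R + A + B + I with species R, RA, RI, RB, RAB (cooperativity alpha') and
# RIB (cooperativity alpha), in the no-depletion limit (free ligand =
# total ligand). Solves the receptor conservation equation numerically for
# free R, then reports radioligand occupancy in percent. Shares only the
# equilibrium constants with the closed-form model, not its algebra.
occupancy_oracle <- function(params, A, B, I) {
  KA <- 10^-params[["pKA"]]
  KI <- 10^-params[["pKI"]]
  KB <- 10^-params[["pKB"]]
  alpha <- 10^params[["logAlpha"]]
  alpha_p <- 10^params[["logAlphaPrime"]]
  Rtot <- 1e-15
  # Solve the receptor conservation equation for free R on the log scale:
  # the fraction free spans many orders of magnitude, and a log-scale
  # root keeps the solution's *relative* precision uniform.
  species_total <- function(u) {
    R <- Rtot * exp(u)
    RA <- R * A / KA
    RI <- R * I / KI
    RB <- R * B / KB
    RAB <- R * alpha_p * A * B / (KA * KB)
    RIB <- R * alpha * I * B / (KI * KB)
    R + RA + RI + RB + RAB + RIB
  }
  u <- stats::uniroot(
    function(u) log(species_total(u)) - log(Rtot),
    lower = -80, upper = 0, tol = 1e-12
  )$root
  R <- Rtot * exp(u)
  bound <- R * A / KA + R * alpha_p * A * B / (KA * KB)
  100 * bound / Rtot
}

# Dunnett-style many-to-one adjusted p-values by label permutation:
# the null distribution of the maximum absolute many-to-one t statistic.
dunnett_perm <- function(values, groups, reference, n_perm = 4000L) {
  groups <- as.character(groups)
  tstats <- function(v, g) {
    lev <- unique(g)
    means <- tapply(v, g, mean)
    ns <- tapply(v, g, length)
    mse <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) /
      (length(v) - length(lev))
    others <- setdiff(lev, reference)
    vapply(others, function(o) {
      (means[[o]] - means[[reference]]) /
        sqrt(mse * (1 / ns[[o]] + 1 / ns[[reference]]))
    }, numeric(1))
  }
  obs <- tstats(values, groups)
  maxnull <- vapply(seq_len(n_perm), function(i) {
    max(abs(tstats(values, sample(groups))))
  }, numeric(1))
  p <- vapply(obs, function(t) mean(maxnull >= abs(t)), numeric(1))
  list(statistic = obs, p_adj = p)
}
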