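# allopocket

Tools for two linked analyses of muscarinic acetylcholine receptor
(mAChR) allosteric pharmacology:

1. **Cryptic-pocket classification of MD trajectories.** The mAChR
   extracellular vestibule can transiently open a cryptic sub-pocket
   between TM2 and ECL2 when Y2.64 releases its hydrogen bond to the
   ECL2 backbone (C45.50). `allopocket` resolves Ballesteros–Weinstein
   residue labels against a PDB topology, computes per-frame minimum
   heavy-atom distances, classifies each frame open/closed with
   subtype-specific rules (open when the effective distance exceeds
   5 Å, strictly; a min-of rule for M3, an ECL2-range rule for the M4
   Inactive-Apo condition), and summarises open fractions, histograms
   and smoothed time traces across replicates and conditions.
2. **Allosteric ternary complex model (ATCM) fitting.** For
   radioligand interaction binding with an orthosteric competitor I and
   an allosteric modulator B,

   $$Y = \frac{100\,[A]}{[A] + \dfrac{K_A K_B}{\alpha'[B] + K_B}\left(1 + \dfrac{[I]}{K_I} + \dfrac{[B]}{K_B} + \dfrac{\alpha[I][B]}{K_I K_B}\right)}$$

   fitted globally (parameters shared across replicates) by
   least squares on log-scale parameters, with derived
   cooperativity-adjusted affinities pKB(ACh) = pKB(Apo) + log α and
   propagated standard errors, and wild-type-vs-mutant comparison by
   one-way ANOVA with Dunnett's post hoc test.

A synthetic-data module (two-state Markov pocket trajectories with
known stationary open probability; binding curves with known
parameters) makes every stage verifiable without MD trajectories or
lab data. The package is aimed at computational pharmacologists and
structural biologists who want these two analyses as tested, reusable
building blocks.

## Worked example

```r
library(allopocket)

# --- pocket side: a synthetic trajectory with known open probability ---
sim <- simulate_pocket_trajectory(p_open = 0.3, n_frames = 10000,
                                  mean_dwell_open_ns = 2, seed = 42)
rule <- make_subtype_rule("M1", "active-apo")  # Y2.64-C45.50 > 5 A
states <- classify_states(sim$distances, rule)
open_fraction(states)
#>   subtype condition replicate n_frames n_open open_fraction
#> 1    <NA>      <NA>      <NA>    10000   3107        0.3107

# --- binding side: simulate, fit globally, derive pKB(ACh) ---
truth <- atcm_params(pKA = 9.7, pKI = 4.7, pKB = 6.5,
                     logAlpha = 1.5, logAlphaPrime = 0.2)
d <- simulate_binding(truth, n_replicates = 3, noise_sd = 3, seed = 42)
fit <- global_fit(d, fixed = c(pKA = 9.7))
fit
#> Global ATCM fit: 90 observations, 4 free parameter(s), RSS = 840.35
#>               estimate std_error
#> pKI             4.6385    0.0590
#> pKB             6.3746    0.1167
#> logAlpha        1.6124    0.0744
#> logAlphaPrime   0.2298    0.0220
#> Fixed: pKA = 9.7
derive_occupied_affinity(fit, "ACh")[c("estimate", "se")]
#> $estimate
#> [1] 7.987072
#> $se
#> [1] 0.1152083
```

The classified open fraction (31.1%) estimates the generator's
stationary open probability (30%); the global fit recovers the
generating parameters to within roughly one standard error on this
draw (over 100 simulated experiments the fitter recovers pKB with
negligible bias and an RMSE of about 0.12 log units — see
`analysis/04_recovery_benchmarks.R`). pKB(ACh) is the
cooperativity-adjusted affinity pKB + log α with its error propagated
from the fit covariance.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic
data and write tidy tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R        # fixture suite (48 trajectories + 2 binding tables)
Rscript analysis/02_pocket_analysis.R      # classify + summarise
Rscript analysis/03_fit_binding.R          # global ATCM fits + Dunnett comparison
Rscript analysis/04_recovery_benchmarks.R  # recovery and coverage benchmarks
```

`02_pocket_analysis.R` prints, for the shipped generator settings
(stationary open probabilities 0.50 / 0.005 / 0.035 / 0.045):

```
pooled open fractions (frame-weighted over 12 trajectories each):
  M1:  47.1%  (28282 of 60000 frames open)
  M2:   0.7%  (428 of 60000 frames open)
  M3:   3.3%  (1962 of 60000 frames open)
  M4:   4.5%  (2682 of 60000 frames open)
ordering: M1 > M4 > M3 > M2
```

and `03_fit_binding.R`:

```
derived affinities (estimate +/- SE):
  WT      pKB(Apo) 6.44 +/- 0.12 | pKB(ACh) 7.93 +/- 0.12 | pKB(NMS) 6.65 +/- 0.11
  mutant  pKB(Apo) 5.64 +/- 0.11 | pKB(ACh) 7.01 +/- 0.11 | pKB(NMS) 5.80 +/- 0.10
wild-type-vs-mutant comparison (Dunnett-adjusted):
 construct   diff     se statistic  p_adj significant
    mutant -0.912 0.2653    -3.437 0.0264        TRUE
```

recovering the injected 1-log-unit pKB drop and flagging it.

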