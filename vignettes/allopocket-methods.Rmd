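---
title: "Methods: cryptic-pocket classification and the allosteric ternary complex model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cryptic-pocket classification and the allosteric ternary complex model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allopocket)
```

`allopocket` implements two linked analyses of muscarinic acetylcholine
receptor (mAChR) allosteric pharmacology, together with the synthetic-data
generators that make both verifiable end to end. This vignette is the
package's account of the underlying science: the models, their
assumptions, the tunable parameters and the numerical choices.

## 1. The cryptic-pocket classifier

### Model

The extracellular vestibule of the mAChRs — the allosteric site above the
orthosteric pocket, framed by ECL2 and TMs 2, 6 and 7 — can transiently
open a *cryptic* sub-pocket between TM2 and ECL2 when the conserved
tyrosine at Ballesteros–Weinstein position 2.64 releases its hydrogen
bond to the ECL2 backbone (C45.50) and rotates toward TM7. The classifier
reduces each trajectory frame to one effective distance and thresholds
it:

* a frame is **open** when the minimum distance over all non-hydrogen
  atom pairs between the rule's residue selections exceeds **5 Å**,
  strictly (`>`): a frame at exactly 5.000 Å is closed. The comparator
  is centralized in `pocket_rule()`, so a `>=` dialect is one switch.
* **M1, M2** (all conditions) and **M4** (all but Inactive-Apo) watch the
  single Y2.64–C45.50 distance.
* **M3** uses the *minimum* of Y2.64–C45.50 and K7.32–E45.49: an
  M3-specific salt bridge between K7.32 and E45.49 can keep the pocket
  closed even after Y2.64 releases ECL2. A min-of rule can only lower
  the effective distance, so its open fraction is bounded above by each
  component's single-rule fraction — a property the tests assert.
* **M4, Inactive-Apo** uses the minimum distance from Y2.64 to any ECL2
  residue in the 45.49–45.51 range, accommodating an ECL2 register
  shift in which Y2.64 engages the backbone of Q45.49 instead of
  C45.50. The range rule is applied to the whole condition, not to a
  single replicate, so the condition is summarised under one metric.

Residue addressing is deliberately configuration-driven:
Ballesteros–Weinstein labels are resolved through a user-supplied
`residue_map` (YAML or list), because BW label → residue number tables
are construct-specific. The example maps shipped under
`inst/extdata/` are *illustrative* and must be verified against the
user's construct. Automatic BW assignment from sequence is out of scope.

### Distances and smoothing

Distances are minimum heavy-atom (non-hydrogen) cross-pair Euclidean
distances in Å, computed on coordinates assumed to be already re-imaged
and centred — no periodic-boundary correction is applied, matching the
usual practice of imaging trajectories before analysis. Frame times are
`frame_index × frame_interval_ns` with a 0.2 ns default (snapshots every
200 ps); the interval is user-supplied rather than read from trajectory
metadata, for format portability. Pre-computed distance tables
(CSV/TSV with a `time_ns` column) are a first-class input, so users can
compute distances with any MD toolchain.

Display traces are smoothed with a **centred moving average, 50 ns
window**, clipped (shrinking) at the series ends so no frames are
discarded. Smoothing is presentation-only: classification always
operates on raw distances, and a test constructs a spiky trace whose
smoothed version classifies differently to pin this down.

### Pooling and histograms

Open fractions are aggregated at three levels (replicate, condition,
subtype). Pooled rows are **frame-weighted** — summed open frames over
summed frames, which is the literal reading of "open X% of the time" —
and the unweighted mean of per-replicate fractions is always reported
alongside, since the two differ when replicate lengths differ. Distance
histograms use half-open bins `[lo, hi)` of constant width (0.5 Å
default in the pipeline) and conserve frame counts within each
subtype × condition × metric group.

## 2. The allosteric ternary complex model (ATCM)

### Model

Interaction binding of a radioligand A (an orthosteric antagonist such
as [³H]NMS), an orthosteric competitor I (acetylcholine) and an
allosteric modulator B is described by the equilibrium allosteric
ternary complex model:

$$Y = \frac{100\,[A]}{[A] + \dfrac{K_A K_B}{\alpha'[B] + K_B}
 \left(1 + \dfrac{[I]}{K_I} + \dfrac{[B]}{K_B} +
 \dfrac{\alpha[I][B]}{K_I K_B}\right)}$$

with $K_A$, $K_I$, $K_B$ the dissociation constants of A, I and the
modulator at the *free* receptor, and $\alpha$, $\alpha'$ the binding
cooperativities of the modulator with I and with A
($\alpha = K_B(\mathrm{Apo})/K_B(\mathrm{I\text{-}occupied})$, and
analogously $\alpha'$ for the radioligand). The model assumes
equilibrium, mass action, and **no ligand depletion** (free ≈ total
concentrations); Y is fractional radioligand occupancy in percent.
Three limits anchor the implementation and are asserted numerically:
at $B = 0$ the equation reduces exactly to two-ligand competition; at
$\alpha = \alpha' = 1$ the modulator cancels algebraically and Y is
independent of B; and Y is strictly decreasing in I. The tests also
check the closed form against an independent mass-action species solver
that obtains free receptor by numerically solving the conservation
equation.

### Parameterization and fitting

All five parameters are carried and estimated as base-10 logarithms
(pKA, pKI, pKB, log α, log α′), which symmetrizes the sampling
distributions and stabilizes the optimization; concentrations are
handled internally in molar. `global_fit()` performs ordinary
(unweighted) least squares on Y in percentage points — the data are
percent specific binding with no stated heteroscedasticity model — with
each free parameter **shared across all pooled replicates** ("global
fit"), by Levenberg–Marquardt (`minpack.lm`). The error model is
exposed only through the choice of loss; weighting variants are
deliberately not implemented.

Numerical choices:

* **Starting values.** When no start is given, a coarse log-grid
  (pK ∈ {5,…,10}, log-cooperativities ∈ {−2,…,2}) is screened by
  residual sum of squares and the best three points are polished by
  Levenberg–Marquardt; the lowest-RSS converged solution wins. Ties are
  broken by grid order, which is deterministic.
* **Identifiability pre-check.** Before any optimization the design is
  inspected: freeing pKB/log α/log α′ requires B to vary with some
  B > 0; freeing log α additionally requires rows with both B > 0 and
  I > 0; freeing pKI requires I to vary. Violations raise an
  interpretable error rather than returning a degenerate covariance.
* **Uncertainty.** The covariance is $\hat\sigma^2 (J^\top J)^{-1}$ with
  $J$ the central-difference Jacobian at the optimum; a singular
  information matrix is an error, not an NA. Confidence intervals use t
  quantiles on the residual degrees of freedom.
* **pKA.** Typically fixed from saturation binding (the default in the
  pipeline); co-estimating it is supported but it is only weakly
  identified when the radioligand concentration does not vary, and the
  fit warns accordingly.

### Derived affinities and construct comparison

The modulator's affinity at the occupied receptor follows from the fit
as pKB(ACh) = pKB(Apo) + log α and pKB(NMS) = pKB(Apo) + log α′, with
standard errors linearly propagated from the covariance,
$\sqrt{\operatorname{var}(\mathrm{pKB}) + \operatorname{var}(\log\alpha)
+ 2\operatorname{cov}}$. Linear propagation is checked against
Monte-Carlo propagation from the fitted covariance (5% agreement on
well-conditioned fits). A component fixed in the fit contributes no
variance and the result is flagged.

`compare_to_wildtype()` compares per-experiment parameter estimates
across constructs by one-way ANOVA followed by Dunnett's many-to-one
test against the reference (multivariate-t critical values via
`multcomp`), reporting adjusted p-values at the 0.05 level; a
label-permutation oracle reproduces the adjusted p-values in the tests.
When each construct contributes only a single pooled estimate the
function falls back to unadjusted z-tests on estimate ± SE, with a
prominent caveat — a fallback, not a recommendation.

## 3. The synthetic-data generators

### Two-state pocket trajectories

`simulate_pocket_trajectory()` emulates the *statistical* structure the
classifier consumes — bistable residue-pair distance traces — not
molecular realism. The hidden open/closed process is a **discrete-time
two-state Markov chain at frame resolution**: the per-frame probability
of leaving the open state is `frame_interval / mean_dwell_open`, and the
closed→open probability is set so the stationary open probability equals
`p_open` exactly; the initial state is drawn from the stationary
distribution. A continuous-time (Gillespie) formulation would add
nothing at fixed frame spacing and is harder to verify. Distances are
drawn per state from Gaussians truncated at zero — defaults: closed
3.0 ± 0.4 Å, open 8.0 ± 1.5 Å, straddling the 5 Å threshold the way
bimodal pocket-distance histograms do. Several metrics can be emitted
from one shared hidden state (independent noise) to exercise min-of
rules.

Two calibration points matter when interpreting test results:

* With the default open-state width (σ = 1.5 Å, i.e. the open mean sits
  2σ above the threshold), about 2.3% of open frames fall below 5 Å;
  under a two-component min-of rule the per-metric miss rate compounds
  to ≈4.5%, a visible downward bias in the open fraction. The
  classifier-consistency benchmark therefore uses emissions separated
  from the threshold by >3σ on both sides (open 8.0 ± 0.9 Å), under
  which misclassification is negligible (<0.1%) and the classified open
  fraction is a consistent estimator of the chain's stationary
  probability. The statement "the classifier recovers p_open" is
  conditional on that separation; with overlapping emissions the bias
  is a property of the data, not of the classifier.
* The sampling error of an open-fraction estimate is governed by the
  number of independent opening excursions, not the frame count: for a
  chain with per-frame switching probabilities $q$,
  $\operatorname{var}(\hat p) \approx p(1-p)(1+\rho)/[n(1-\rho)]$ with
  $\rho = 1 - q_{oc} - q_{co}$. The consistency benchmark uses a 2 ns
  mean open dwell at 0.2 ns frames (10-frame excursions) so that 10,000
  frames contain enough excursions for a ±2-percentage-point check;
  the fixture suite uses a 5 ns dwell over 5,000-frame (1 μs)
  replicates for the same reason at its smaller per-subtype
  probabilities.

### The fixture suite

`make_fixture_suite()` writes a deterministic end-to-end input set: four
synthetic "subtypes" with stationary open probabilities 0.50, 0.005,
0.035 and 0.045 — chosen to mirror the qualitative ordering
M1 ≫ M4 ≈ M3 > M2 — three replicates in each of four conditions
(the generator does not vary p_open across conditions), with exactly the
metric columns each subtype's rule needs; plus wild-type-like and
mutant-like binding tables, the mutant generated with pKB reduced by
1 log unit. Binding tables use a reference interaction design of one
radioligand concentration (0.2 nM against pKA 9.7), six competitor
concentrations (0 and 1 µM–10 mM against pKI 4.7) and five modulator
concentrations (0 and 0.1–100 µM against pKB 6.5, log α 1.5, log α′
0.2), three replicates, additive Gaussian noise of 3 percentage
points. All randomness flows from one seed through fixed per-file
sub-seeds, and the manifest records md5 hashes.

### What the generators do not emulate

No atomic coordinates, no force-field realism, no correlation between
conditions, no autocorrelated emission noise (only the hidden state is
autocorrelated), no heteroscedastic or non-Gaussian binding error, no
ligand depletion. Passing tests therefore demonstrate that the
*analysis* machinery is correct and statistically calibrated under its
stated assumptions — they cannot certify conclusions about any real
receptor's trajectories or assays.

## 4. Degenerate inputs and edge behaviour

* Empty atom selections (e.g. side-chain heavy atoms of glycine),
  unknown BW labels, residues absent from the topology, and multi-chain
  topologies without a configured chain are errors, never silent.
* A residue-name disagreement between map and topology warns by default
  and can be promoted to an error.
* Overlapping distance selections return 0 Å with a warning; NaN
  coordinates are an error.
* A smoothing window narrower than the frame interval returns the input
  unchanged with a warning.
* A frame exactly at the threshold is closed (strict `>`).
* Histogram values exactly on the top data edge still land in a bin
  (an extra half-open bin is added), so counts are conserved.
* `open_fraction()` on zero total frames, histograms on empty input,
  and comparisons with fewer than two constructs are errors.

## 5. Problem sizes used in the shipped analyses

The `analysis/` drivers and the verification suite run entirely on
synthetic data at sizes chosen to give stable statistics: 5,000 frames
per trajectory replicate (1 μs at 0.2 ns; 60,000 frames per pooled
subtype), 100 simulated experiments for the recovery benchmark, 50 for
the coverage benchmark, 1,000 random draws for the species-solver
cross-check, and 10,000-frame chains over 20 seeds for classifier
consistency.

## 6. Interfaces and repository shape

The package is organised as an analysis workflow: every computation
lives in exported package functions (so it is installable, testable and
reusable), and thin numbered drivers under `analysis/` narrate the
study — simulate, classify, fit, benchmark — writing tidy tables under
`results/`. The pipeline entry points `run_pocket_pipeline()` and
`run_binding_pipeline()` are the programmatic equivalents of a
command-line interface; a shell wrapper would add nothing for the
intended interactive-R audience, so none is shipped. Both pipelines
write a JSON manifest (package version, configuration echo, seed, input
md5 hashes) and their outputs are byte-identical across reruns on
identical inputs.

## 7. Known limitations

* The open/closed rules are the fixed residue-pair rules described
  above; the package does not detect cryptic pockets de novo, fit
  kinetic models of opening/closing, or compute free energies.
* Trajectory input is multi-model PDB or a bare coordinate matrix
  (plus first-class distance tables); compressed binary trajectory
  formats require conversion or an external distance computation.
* The ATCM is the equilibrium binding model only: no operational model
  of agonism, no kinetic binding, no depletion correction, no Schild
  analysis.
* Dunnett comparison assumes approximately normal per-experiment
  estimates with homogeneous variance; with very few experiments per
  construct the permutation approach used as a test oracle is the
  safer reading.
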