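---
title: "Energy landscape analysis of binarized brain-state dynamics: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy landscape analysis of binarized brain-state dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elandscape)
```

This vignette documents the statistical model behind `elandscape`, the
conventions and numerical choices the implementation commits to, what the
synthetic cohort generator does and does not emulate, and the limitations a
user should keep in mind when interpreting results on real data.

## The model

### From signals to states

Each participant contributes an ROI-by-time matrix of continuous signals.
Every ROI is thresholded at its mean; a timepoint's joint on/off pattern
across the `n` ROIs of a network is one of `2^n` brain states. Two
threshold conventions exist in the ELA literature and both are exposed in
`binarize()`:

* `threshold_mode = "participant"` (default): each ROI's mean within one
  participant's own series. This is robust to between-participant intensity
  offsets, which matter because group models are fitted on concatenated
  series.
* `threshold_mode = "group"`: one mean per ROI across the combined group
  data (or explicit `group_means`).

The two conventions genuinely disagree when participants have different
baselines, and published group analyses are not always explicit about which
was used; we default to the per-participant mean precisely because of the
concatenation-bias argument, and keep the group mean available for
sensitivity analyses.

Committed conventions, chosen because the field's descriptions leave them
open:

* **Bit encoding.** The ROI at position `i` of the channel ordering
  contributes `2^(i-1)` to the state code; `encode_state(c(1,0,1)) == 5`.
* **Threshold ties.** A value exactly equal to the threshold is inactive
  (0). Ties have measure zero for continuous data; the rule only matters
  for degenerate synthetic inputs and makes binarization deterministic.
* **Missing timepoints are not supported.** Motion scrubbing and other
  gap-producing preprocessing happen upstream; transition counting assumes
  contiguous samples within a participant.

### The pairwise maximum entropy model

Group dynamics are modeled by the Ising / pairwise maximum entropy
distribution over states, with the `{0,1}` activation convention:

$$E(\sigma) = -\sum_i h_i \sigma_i - \tfrac12 \sum_{i \ne j} J_{ij}\sigma_i\sigma_j,
\qquad P(\sigma) = \frac{e^{-E(\sigma)}}{\sum_{\sigma'} e^{-E(\sigma')}}.$$

This is the maximum-entropy distribution matching the empirical activation
rates and pairwise co-activation rates. Note the convention: much of the
statistical-physics literature uses spins in `{-1,+1}`; parameters are not
directly comparable across conventions, and `spin_to_activation()` /
`activation_to_spin()` translate exactly. The partition function in the
denominator is always the sum of `exp(-E)` over all `2^n` states.

`fit_pmem()` maximizes the average log-likelihood. Because the family is a
full-rank exponential family, the likelihood is concave and the maximum is
the unique parameter set whose model moments equal the data moments. The
implementation:

* computes model moments by **full enumeration** of the `2^n` states, with
  log-sum-exp stabilization — no approximate inference. An enumeration
  guard (default `n <= 20`, configurable via
  `options(elandscape.n_guard = )`) refuses larger problems outright rather
  than silently approximating; the networks this package targets have 5–9
  ROIs;
* iterates **damped Newton** steps: the Hessian is the exact covariance
  matrix of the sufficient statistics under the current model, also by
  enumeration, with a halving line search and a plain gradient step as
  fallback if the linear solve fails. Newton was chosen over fixed-step
  gradient ascent because convergence is quadratic: iteration stops at the
  first moment gap below `tol` (default `1e-6`), and the Newton step that
  crosses the threshold typically lands orders of magnitude below it, so
  the parameter error inherits none of the tolerance. On the package's
  six-channel reference model the recovered parameters are within ~2e-7 of
  truth in five iterations;
* raises immediately when a channel is never (or always) active — there the
  MLE does not exist (`h` diverges) — and raises with the last gap on
  non-convergence.

The empirical state distribution (`empirical_distribution()`) assigns
`-log p(σ)` as a frequency-based energy for observed states; unobserved
states get `NA`, **not** `+Inf`. All landscape construction uses model
energies, which are finite everywhere; empirical energies are a diagnostic
overlay only. `fit_quality()` reports KL(empirical ‖ model) with the
`0 log 0 = 0` convention, the per-sample log-likelihood, and the largest
moment gap.

### The landscape

Two states are neighbours if they differ in exactly one ROI, making the
state space an `n`-hypercube. On it:

* **Basins** (`find_basins()`) are states strictly below all `n`
  neighbours. Ties are broken by lower state code everywhere in the
  package: a state tied with a neighbour is a basin only if its code is
  lower. Under this rule a perfectly flat landscape has exactly one basin
  (code 0) — degenerate inputs stay deterministic instead of inflating the
  basin count.
* **Assignment** (`assign_to_basins()`) is steepest descent: repeatedly
  move to the lowest-energy neighbour (ties by lower code) while it
  improves on the current state. The alternative reading — assignment by
  lowest barrier — is ambiguous in parts of the literature; descent is the
  reading consistent with "nearest basin" cluster descriptions, and it
  guarantees a partition whose fixed points are exactly the basins.
  Implementation detail: states are processed in increasing (energy, code)
  order, so every descent step lands on an already-assigned state and the
  map is computed in one pass.
* **Saddles** (`saddle_energies()`) are minimax path energies: over all
  hypercube paths between two basins, the minimum of the maximum energy en
  route, endpoints included. Dijkstra with the widest-path relaxation
  `new_cost = max(cost_so_far, E(neighbour))` is exact for this objective.
  The one-way barrier out of basin `a` toward `b` is
  `saddle(a,b) − E(a)`; the deeper basin always has the larger outgoing
  barrier, by the identity `barrier(a→b) − barrier(b→a) = E(b) − E(a)`.
* The **disconnectivity dendrogram** (`build_dendrogram()`) is
  single-linkage agglomeration on the saddle matrix, delegated to
  `stats::hclust`; this is exact because minimax saddles satisfy
  `saddle(a,c) ≤ max(saddle(a,b), saddle(b,c))`. Newick export uses a
  small dedicated writer because leaf branch lengths must equal the merge
  saddle minus the basin's energy, a quantity `hclust`-to-phylo converters
  (which put all leaves at height zero) cannot express.
* **Major basins** are the two lowest-energy basins (ties by code). The
  `landscape_profile()` of a basin reports, for each Hamming radius from
  the basin state within its cluster, the minimum energy on that ring —
  the concentric-circle depiction of basin shape. Depth at radius 0 is
  below depth at radius 1 by the basin definition; beyond radius 1 the
  profile need not be monotone.

### Dynamics and scores

Scores are computed per participant on a fixed group landscape, from
consecutive timepoint pairs that do not straddle a participant boundary
(boundaries are carried as the `participant_id` column; a "transition"
between the last sample of one participant and the first of the next is
physically meaningless and never counted). With major basins A1, A2 and
clusters P1, P2:

* `tr_major`: pairs sitting exactly on (A1, A2) or (A2, A1), divided by T;
* `tr_peripheral`: cross-cluster pairs (P1→P2 or P2→P1), divided by T —
  major-basin pairs are cross-cluster pairs too, so
  `tr_major ≤ tr_peripheral` always holds in direct mode;
* `sr_major`: pairs staying exactly on a major basin state;
* `sr_peripheral`: pairs staying within one major cluster, **excluding**
  those already counted in `sr_major` (no double counting);
* traveling = `tr_major / tr_peripheral`, reported as `NA` with an explicit
  `traveling_defined` flag when no cross-cluster pair occurs (never
  silently 0, and written as an empty field in TSV output);
* lingering = `sr_major + sr_peripheral`.

The denominator is the raw series length `T`, not `T − 1`, matching the
printed rate definitions in the ELA literature; the distinction is a
common factor within a participant and immaterial for group contrasts.
"Entered state U and arrived at V" admits a first-passage reading, so
`mode = "first_passage"` is provided (episodes counted between consecutive
visits to the two targets, optionally voided by minor-cluster excursions
via `first_passage_strict`); direct consecutive-pair counting is the
default because it is the only reading that puts the staying counts of the
same equations on the same footing. Basin occurrence frequency defaults to
cluster membership (`count = "cluster"`), with exact basin-state visits as
an option.

A conservation identity ties the categories together: per participant,
staying pairs + cross-cluster pairs + pairs touching minor clusters equals
`(T − 1)/T`. The test suite asserts it on random series.

### Group statistics

`compare_groups()` wraps base R: one-way ANOVA (`aov`), all pairwise
**Welch** t-tests with Bonferroni multiplication (the robust default when
only "Bonferroni correction" is specified), and Kruskal–Wallis as the
distribution-free check; significance flags mirror the 0.05 / 0.01 / 0.005
star levels conventional in this literature. `two_way_anova()` uses
`car::Anova` type-II sums of squares for group × site designs and refuses
empty cells by name. `symptom_regression()` is OLS with an intercept;
predictors default to the major-basin frequencies, the "basin
characteristic" most directly interpretable, and rank-deficient designs
are refused with the collinear columns named. When every group has zero
variance the F statistic is reported as `NA` with a note, not fabricated.

## The synthetic cohort generator

`simulate_cohort()` exists so that every pipeline stage can be tested
against ground truth; its defaults are the package's reference study
conditions and are not meant to be tuned per analysis.

* **Planted landscape.** `planted_model()` stores one activation pattern
  Hopfield-style in spin space (couplings `K = c·ξξᵀ/n` with
  `ξ = 2p − 1`, coupling strength `c = 1.2` by default) plus a small spin
  field (`0.05·ξ`) and converts exactly to the `{0,1}` convention. In spin
  space the pattern and its complement are energy-degenerate and the field
  splits them asymmetrically — this yields the antisynchronized major-basin
  pair that real resting-state landscapes show, with the pattern strictly
  deepest. The construction matters: storing the pattern directly in the
  `{0,1}` parameters would not make the complement a deep state, since the
  complement symmetry only exists in spin space. Every constructed model is
  verified by full enumeration; if the two planted states are not the two
  lowest, construction fails loudly rather than returning a landscape with
  different topology.
* **Sampling.** `sampler = "exact"` draws i.i.d. states from the enumerated
  Boltzmann distribution; `sampler = "metropolis"` (the cohort default)
  runs a single-flip Metropolis chain with burn-in `10·2^n` flip attempts
  and one recorded state per `n` attempts — enough decorrelation to match
  the exact sampler's stationary histogram (asserted by a chi-squared
  test) while retaining the temporal autocorrelation that staying rates
  measure. An i.i.d. sampler would make lingering scores a pure function
  of the marginal distribution; the Metropolis default keeps them dynamic
  quantities.
* **BOLD rendering.** `states_to_bold()` emits
  `baseline + amplitude·(2σ−1) + N(0, noise_sd)` per ROI with defaults
  amplitude 1 and `noise_sd = 0.3`, at which mean-threshold binarization
  recovers the true state sequence for ≈ 99.9 % of timepoints — a clean
  regime chosen so that generator-level effects, not thresholding noise,
  dominate downstream tests.
* **Cohort structure.** Default three groups × 20 participants × 158
  timepoints, six ROIs, four acquisition sites assigned round-robin.
  158 timepoints matches the per-participant series lengths typical of the
  resting-state protocols this pipeline targets; 20 per group keeps the
  full validation battery runnable in about a minute while leaving the
  group tests well powered. Per-group models add Gaussian perturbations
  (SD `perturbation`, default 0.1) to the base parameters, and an optional
  per-group `coupling_strength` plants landscape-depth contrasts. Symptom
  scores are `10 + 2·f(A1) + N(0, 0.1)` with `f(A1)` the participant's
  true deepest-cluster occupancy, giving the regression stage a
  recoverable planted slope.
* **Reproducibility.** All randomness flows from one integer seed through
  `split_seed()`, a fixed multiplicative-congruential splitter: group
  perturbations, each participant's chain, BOLD noise and symptom noise
  use separate child streams. Identical seeds give byte-identical cohorts,
  and the pipeline itself is deterministic, so end-to-end reruns produce
  byte-identical TSV/JSON/Newick outputs.

What the generator does **not** emulate: hemodynamic response convolution,
head motion, physiological noise, scanner/site intensity artifacts
(site labels are pure metadata), spatial correlation beyond the planted
couplings, or any slow nonstationarity. Passing tests on synthetic cohorts
therefore validate the *estimators and bookkeeping* — they do not show that
a six-ROI Ising model is an adequate description of any particular real
network, nor that group differences of a given size are detectable under
realistic artifact loads.

## Design decisions taken where the method description was open

* Group-level models, participant-level dynamics: one landscape is fitted
  per (network, group) on concatenated data, and each participant is scored
  against **their own group's** landscape. Scoring everyone against a
  common landscape is a legitimate sensitivity analysis (pass a shared
  `landscape` to `cohort_dynamics()`), but the default mirrors the
  published convention.
* The pipeline's statistics stage compares major-basin frequency,
  traveling and lingering across groups; regressions of symptom scores on
  basin frequencies are available through `symptom_regression()` on the
  joined metrics table.
* The interface is the R API: `run_pipeline()` orchestrates
  simulate/binarize/fit/landscape/dynamics/stats from one call, and the
  stage functions are individually exported; all outputs are plain-text
  TSV/JSON/Newick.

## Numerical details worth knowing

* Boltzmann probabilities are computed via log-sum-exp; probabilities sum
  to 1 within 1e-12 regardless of energy offsets, and adding a constant to
  all energies leaves them unchanged.
* The saddle matrix is symmetrized exactly (`(S + Sᵀ)/2`) to remove
  floating-point asymmetry from independent Dijkstra runs.
* Tie-breaking by state code is used identically in basin detection,
  descent, and major-basin selection, so all landscape outputs are total
  functions of the energy vector.
* `fit_pmem(tol = 1e-6, max_iter = 20000)`: `tol` is a moment-gap (i.e.
  probability-scale) tolerance; `max_iter` exists for pathological inputs
  near the family boundary, where the error message carries the last gap.

## Validation battery and problem sizes

The test suite and `scripts/acceptance.R` validate, at these sizes chosen
as the package's reference conditions: exact-distribution recovery of the
planted six-ROI model (error ~2e-7); recovery from 1e5 exact samples
(error < 0.1, and the fitted model's KL to the empirical distribution never
exceeds the generating model's, the defining MLE property); equality of
basins, assignments (100 random four-ROI landscapes) and saddles (50
landscapes) with exhaustive brute-force oracles; exact reproduction of
hand-computed two-ROI landscape and six-timepoint dynamics examples;
conservation identities; type-I error of the ANOVA layer at the nominal 5 %
over 200 null cohorts (3 × 20 × 150) and power ≥ 0.8 for a coupling
contrast of 0.3 over 30 replicate cohorts; and byte-identical pipeline
reruns.

## Known limitations

* Exhaustive enumeration restricts networks to roughly a dozen ROIs;
  there is deliberately no pseudo-likelihood or MCMC-gradient fallback for
  larger `n`.
* The model is memoryless and assumes stationarity within and across the
  concatenated participants; slow drifts or state-dependent noise violate
  it and are not modeled.
* Empirical energies of unobserved states are undefined; with short series
  and large `n`, most states are unobserved and only model energies are
  meaningful.
* Scores depend on the landscape partition: a participant's lingering
  score on a different group's landscape is a different quantity. Between
  groups, score differences conflate landscape differences with dynamics
  differences — the published convention, but worth remembering.
* `traveling` is a ratio of rare-event rates; at typical series lengths it
  is frequently 0 or undefined per participant, and group comparisons of
  it are accordingly low-powered.
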