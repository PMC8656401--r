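# elandscape

Energy landscape analysis (ELA) of binarized brain-state dynamics in R.

Resting-state fMRI gives, for each functional brain network, a small set of
region-of-interest (ROI) BOLD time series. After binarizing each ROI at its
mean signal, every timepoint becomes one of `2^n` binary brain states
σ ∈ {0,1}^n. `elandscape` fits the pairwise maximum entropy (Ising) model to
these state sequences,

    P(σ | h, J) = exp[ −E(σ) ] / Σ_σ' exp[ −E(σ') ]
    E(σ)        = − Σ_i h_i σ_i − ½ Σ_{i≠j} J_ij σ_i σ_j ,

and treats `E` as an energy landscape over the state hypercube: **basin
states** are states below all single-bit-flip neighbours, every state is
assigned to a basin by steepest descent, **energy barriers** between basins
are minimax path energies (Dijkstra with a widest-path relaxation), and the
basin hierarchy is summarized as a disconnectivity dendrogram and
concentric-circle landscape profiles. Participant-level dynamics on a fixed
group landscape are quantified by basin occurrence frequencies `f(A)` and by
transition/staying rates of the two lowest-energy ("major") basins A1, A2
and their attraction clusters P1, P2:

    TR(A→A′) = [n(A1→A2) + n(A2→A1)] / T      traveling score = TR(A→A′) / TR(P→P′)
    SR(·)    = staying-pair counts / T         lingering score = SR(A→A′) + SR(P→P′)

Group contrasts (e.g. healthy vs. non-melancholic vs. melancholic
depression) use one-way ANOVA with Bonferroni-corrected pairwise Welch
tests, verified by Kruskal–Wallis, plus chi-squared tests, two-way
(group × site) type-II ANOVA, and OLS regression of symptom scores on basin
characteristics.

Because suitable clinical rs-fMRI is rarely shareable, the package includes
a first-class synthetic cohort generator: planted Ising models whose two
deepest basins are a chosen activation pattern and its bitwise complement
(the antisynchronized major-basin pair seen in real landscapes), exact and
Metropolis samplers, BOLD-like signal rendering that inverts mean-threshold
binarization, and planted symptom effects — so every stage of the pipeline
can be validated against known ground truth.

The package is written tidyverse-style: data frames in, tibbles out,
`tidy()`/`glance()` methods on fitted objects, `autoplot()` for landscapes
and dendrograms.

## Who it is for

Researchers analyzing small-n (≈ 5–9 ROI) network dynamics with pairwise
maximum entropy models — in rs-fMRI psychiatry studies and beyond — and
methodologists who want a fully tested, deterministic reference
implementation of basin/barrier analysis with a ground-truth simulator.

## Worked example

```r
library(elandscape)

co  <- simulate_cohort(seed = 42)                 # 3 groups x 20 participants, 6 ROIs, T = 158
run <- run_pipeline(co, networks = list(dmn = paste0("roi", 1:6)))

tidy(run$results$dmn_melancholic$landscape)
#> # A tibble: 2 × 5
#>   basin energy  size fraction major
#> 1     7  -4.11    42    0.656 TRUE
#> 2    56  -3.16    22    0.344 TRUE
```

The fitted melancholic-group landscape has two basins: state 7
(`111000`, the planted pattern) at energy −4.11 whose attraction cluster
covers 65.6 % of the 64 states, and its antisynchronized complement, state
56 (`000111`), at −3.16. `glance()` on the fit shows moment matching to
6.6e−7 after 5 Newton iterations (KL of the empirical distribution from the
model: 0.0078).

```r
dplyr::select(run$dynamics$dmn, participant_id, group, f_major1, traveling, lingering)
#> # A tibble: 60 × 5
#>   participant_id group   f_major1 traveling lingering
#> 1 sub001         healthy    0.481         0     0.810
#> 2 sub002         healthy    0.715         0     0.804
#> ...

run$stats$dmn
#> network metric    statistic df_between df_within  p.value  ...
#> dmn     f_major1      15.9           2        57  3.28e-6
#> dmn     lingering      6.08          2        57  0.00403
```

Each participant spends 48–72 % of timepoints in the deepest basin's
cluster and lingers (stays on a major basin or inside its cluster) on
~80 % of consecutive timepoint pairs; the between-group ANOVA picks up the
perturbation-induced differences in major-basin frequency and lingering.
The dendrogram exports as Newick — `(S7:3.611770,S56:2.657770);` — with
branch lengths equal to the barrier each basin must climb to the saddle.

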