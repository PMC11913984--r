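---
title: "Rapid-cycling genomic selection: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rapid-cycling genomic selection: models, simulator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rapidgs` re-creates, at desk scale, a replicated rapid-cycling genomic
selection experiment in a landrace-derived population: train a GBLUP
model once on a DH library, select and recombine on genomic breeding
values for two further cycles without phenotypes, extract DH lines from
every cycle, and analyse the result the way a field experiment would be
analysed. This vignette documents the models, the assumptions baked into
the synthetic-data generator, the numerical choices, and the design
decisions made where the design was genuinely open. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## 1. The simulated world

**Genome.** `make_genetic_map()` places markers uniformly at random on
chromosomes measured in centimorgans; the default scheme uses 10
chromosomes × 500 markers × 160 cM. This stands in for an ~11k SNP
genotyping set; positions are genetic, not physical.

**Founders.** `simulate_founders()` draws per-marker alternate-allele
frequencies from Beta(1, 1) truncated to [0.05, 0.95] and then
haplotypes independently per individual under Hardy–Weinberg and linkage
equilibrium. A real landrace has ancestral LD and some allele-frequency
spectrum; neither is reported for the population the scheme emulates, so
the defaults are *stated assumptions, not estimates*. Two consequences
worth keeping in mind: (i) under LE the GBLUP training signal is pure
relationship/co-segregation — there is no ancestral-LD component of
accuracy to lose across cycles, which if anything makes the simulated
accuracy decline conservative; (ii) an optional mode
(`ancestral = list(n_pool, n_gen)`) descends founders from a small
random-mating pool to create ancestral LD, kept OFF by default so every
generator property remains analytically checkable.

**Traits.** `assign_architecture()` samples QTL (default 300) from the
markers and draws each QTL's vector of additive effects from a
multivariate normal whose correlation matrix is the target genetic
correlation: 0.8 between early plant height at stages V4 and V6, 0.35
between each of those and final plant height, 0 with flowering. Effect
columns are rescaled so the *expected* founder-population TBV standard
deviations (Σ 2p(1−p)e² under LE) hit the configured `trait_sds` —
defaults 4, 6, 12 cm and 3 days, the order of magnitude of
landrace-derived DH populations. The model is strictly additive; no
dominance or epistasis (a stated non-goal), so "TBV" and "genotypic
value" coincide.

**Meiosis.** `gamete()` implements the Haldane model: crossover counts
per chromosome Poisson(length/100), positions uniform, no interference,
fair-coin start phase. Chosen because it has closed-form oracles (the
recombination fraction `r = (1 − e^{−2d})/2` is asserted in the tests at
10,000 gametes). Obligate chiasma and interference are not modelled.
DH induction doubles one gamete; selfing draws two independent gametes
from the same parent.

**Phenotypes.** `simulate_trial()` generates plot values = TBV +
environment + G×E + replication + block + residual under a randomized
incomplete-block layout (blocks of 10), with a per-plot plant count
~ Binomial(20, 0.9) so the "at least five plants" filter has something
to do, and optional gross outliers (residual × 10) for the Grubbs
filter. `variance_for_h2()` converts a target entry-mean heritability
into G×E and residual variances.

**What a green test does and does not establish.** The generator
reproduces the *statistical structure* the analyses assume (balanced
multi-environment data, known variance components, known breeding
values), not any particular field experiment. Green acceptance tests
establish that the machinery recovers what was simulated and that the
scheme's qualitative mechanisms (diminishing gains, selective accuracy
decline, stabilizing selection limiting drift) emerge; they do not
certify the empirical magnitudes of any real experiment, whose data are
not available.

## 2. GBLUP engine

Single-trait REML is computed on the eigenbasis of K: with
K = UDU′, the restricted likelihood profiles analytically over the error
variance, leaving a 1-D search in λ = σ²_g/σ² (log-scale bounded search
in [1e−6, 1e6], tolerance 1e−8). This gives a deterministic, monotone,
oracle-checkable fit: the test suite asserts exact equivalence with
ridge-regression SNP-BLUP when K = ZZ′/c.

The multi-trait extension replaces the prescribed EM-REML with *direct
maximization of the restricted likelihood over Cholesky factors of the
genetic and residual covariance matrices* (Nelder–Mead then BFGS
polish). For each candidate (G₀, R₀) the pair is simultaneously
diagonalized, reducing every eigen-component of K to independent
weighted least squares, so one likelihood evaluation costs O(nt). Two
reasons for the substitution: the Cholesky parameterization keeps both
matrices positive semi-definite *by construction* (no ad-hoc eigenvalue
flooring), and the direct objective cannot decrease across iterations
the way an mis-stepped EM can. A fallback to independent single-trait
fits exists for optimizer failure and is itself tested.

`fit_gblup()` reports `h2` on the *population scale*:
σ²_g·mean(diag K)/(σ²_g·mean(diag K)+σ²). For VanRaden method 1 with
own-population frequencies, fully inbred lines have diag(K) ≈ 2, and the
naive ratio σ²_g/(σ²_g+σ²) would systematically miss the simulated
heritability — the parameter-recovery oracle in the acceptance suite is
what forced this definition to be made explicit.

**Prediction.** Candidate GEBVs come from the cross-covariance formula
σ²_g·K_ct′V⁻¹(y−Xμ̂). A genuinely different second route solves the
joint mixed-model equations with missing candidate records. Because
centering by the training set's own allele frequencies always leaves K
rank-deficient (the rows of Z sum to zero), the MME are formed on the
positive eigenbasis of the joint K rather than through K⁻¹; the two
routes agree to 1e−8 in the tests.

**Reference allele frequencies are always explicit.** Selection-time
GRMs use training-set frequencies; reporting uses base-population (C0)
frequencies, which anchors the mean GEBV of C0 at exactly zero (the
column sums of Z vanish, so GEBVs — which live in the column space of
K — average to zero over the training set). In the default synthetic
world the training set *is* the C0 DH library, so the two conventions
coincide; the argument stays mandatory because with a multi-landrace
training set they would not.

## 3. The selection scheme

Per candidate set, GEBVs are centered and scaled with divisor n; final
height is transformed `PH_trans = max(g) − |g|` and the criterion is
`SC = V4 + V6 + 2·PH_trans`. Open question resolved: "maximum value"
could mean max of the scaled GEBVs or of their absolute values — the
choice shifts every candidate equally and cannot change the ranking
(property-tested), so the package defaults to max of the scaled values
with a flag (`max_of_abs`) for the other reading.

Structure of `run_scheme()` (defaults): 402 founder S0 plants → 402 C0
DH lines (one per plant); training phenotypes = TBV + noise at
entry-mean h² 0.7; multi-trait GBLUP for the three height traits and a
single-trait fit for flowering; top 20 by SC; even/odd split (odd ranks
seed replication 1 — a fixed convention, the real assignment being
unknown); per replication: diallel of the 10 founders (45 families), one
selfing, ~1000 S1; GBLUP prediction through the cross-GRM (the model is
never refit); ~40 selected under a cap of 15 per founder line
(contribution caps apply at this selection only); 20 MRD-maximizing
pairs → ~1000 S0; ~30 selected; 15 pairs → C3; 100 DH per cycle from
random members of each cycle's population plus a random C0 sample of
105. Family sizes are allocated as evenly as possible (the real
per-family sizes are in an unavailable supplement).

**Mate allocation** maximizes modified Rogers' distance greedily (take
the largest unused pair, ids break ties). The objective is stated in the
source experiment, the algorithm is not; greedy is deterministic, O(k²
log k), and achieves at least half the optimal matching weight — an
exhaustive matching oracle for ≤ 12 candidates backs the tests.
`MRD = sqrt(mean((p_a − p_b)²))` is a metric and Euclidean-embeddable,
so PCoA on MRD matrices has non-negative eigenvalues (tested).

**Contribution caps** trace each candidate's set of C0sel founder
ancestors through the recorded pedigree; a candidate is skipped when any
ancestor would exceed the cap; infeasible configurations (cap ×
founders < selections) error out rather than silently under-deliver.

## 4. Trial analysis

The plot-level mixed model — population + genotype(population) +
environment + G×E(population) + replication(environment) +
block(replication) + residual — is fit by REML with *heterogeneous*
genetic and G×E variances per population, the analytical wrinkle the
whole module exists for. The prescribed average-information algorithm
was replaced by direct L-BFGS-B maximization of the restricted
likelihood on log-variances through the sparse mixed-model equations
(one sparse Cholesky per evaluation, symbolic factorization reused).
Same estimator, and the safeguarded quasi-Newton search cannot accept a
likelihood decrease; at the module's scale (≈ 3,000 equations for 300
genotypes × 7 environments × 2 replications) a fit takes seconds.
Boundary handling: variances are parameterized on the log scale, so
estimates cannot go negative; estimates pinned at the lower bound
(1e−8 × var(y)) are reported as 0.

Adjusted entry means treat genotype as fixed (BLUEs); variance
components treat genotype as random except for configured fixed
populations (checks). Design connectivity is verified first and
disconnected genotype groups are named in the error. Entry-mean
heritability uses the standard formula with a Knapp-style F-quantile
confidence interval on the balanced-design approximation
(F = 1/(1−h²), df (n_g−1) and (n_g−1)(E−1)).

Outlier handling: plots with fewer than five plants are dropped
(boundary kept); then an iterative two-sided Grubbs test per trait ×
environment at α = 0.05 (the stratification is an assumption — the
source does not state it). Population comparisons: Welch one-way global
test gating Welch–Satterthwaite pairwise t-tests with Bonferroni–Holm
adjustment and a compact letter display. Variance-heterogeneity LRT:
pooled vs separate σ²_g for a population pair (G×E stays
population-specific in both fits so the models nest), statistic referred
to χ²(1).

## 5. Response metrics

`response_regression()` fits per-replication intercepts and slopes with
cycle as numeric predictor. Because the predictor is constant within a
cycle, individual-level OLS is *exactly* the size-weighted regression of
cycle means — the identity is tested to 1e−12 and is what lets printed
population means and sizes serve as regression inputs. Slope p-values
are one-sided (γ > 0) per the selection-response null, two-sided by
flag; the equal-slopes LRT uses the Gaussian n·log(RSS₀/RSS₁) statistic
against χ²(df = replications − 1), which is only meaningful for
individual-level data. Open question resolved: regressions weight
individuals (equivalently cycles by size), not cycles equally.

Ability is the Pearson correlation between GEBVs and adjusted means;
accuracy divides by √h² and is reported as computed even when > 1.
`retrain()` shifts each era by the difference in common-check means
before concatenation and keeps the newest record per genotype.
`bootstrap_compare()` implements both resampling modes (paired indices
for one population phenotyped twice; independent resampling otherwise),
with the significance rule "zero outside the 2.5%–97.5% interval"; B
defaults to 10,000 (unstated in the source; tests use smaller B, which
affects only Monte-Carlo noise, never the decision rule).

## 6. Numerical and testing choices

* Tolerances: REML convergence 1e−8 (single-trait profile), reltol
  1e−12 (multi-trait simplex); PSD tolerance for K −1e−6 relative;
  dual prediction routes 1e−8; weighted/individual OLS identity 1e−12.
* Tie-breaks are deterministic everywhere (candidate id in rankings and
  pairings), so a master seed fully reproduces a run; every stochastic
  stage draws its own sub-seed derived from the master seed.
* Degenerate inputs: constant responses warn and return σ²_g = 0; zero
  SD traits error by name in `scale_gebvs()`; Grubbs passes through
  n < 3 or zero-SD strata; empty candidate sets error.
* Printed-precision comparisons in the acceptance tests use half a unit
  in the last printed place (±0.05 on one-decimal slopes). One
  published slope is an exact half-way case (a computed 1.95 printed as
  2.0), which rounding-based comparison would spuriously fail.
* Monte-Carlo sizes in the suite (e.g. 20 seeds for h² recovery, 10
  scaled scheme runs, B = 600 bootstrap inside the calibration check)
  are runtime-budget choices made before looking at outcomes; the
  assertion thresholds come from the acceptance criteria, not from the
  observed draws.

## 7. Known limitations

* No dominance, epistasis, mutation, or segregation distortion; no
  genotyping error (pedigree validation rates are exactly 1 for true
  trios) and no missing-genotype imputation beyond an explicit error.
* Founder LE by default means ancestral-LD-driven accuracy is absent;
  the ancestral-LD mode exists but is unvalidated against any real LD
  spectrum.
* The trial model has no spatial trend component and no multi-trait
  mode; the DH-loss that reduced one real replication to 8 founders is
  modelled only by configuring 8 founders, not by a stochastic failure
  process.
* Greedy MRD pairing is a heuristic; optimal matching is provided only
  as a small-n test oracle.
* Empirical magnitudes of the reference experiment (absolute
  accuracies, realized gains in SD) are not reproducible from first
  principles and are deliberately covered by qualitative/mechanism
  surrogates only.
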