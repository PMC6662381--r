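---
title: "Models and methods behind habshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind habshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habshape)
```

habshape implements a complete phylogenetic comparative workflow for
studying how a discrete microhabitat character (here, salamander
microhabitat use, with arboreality as the focal state) evolves on a
time-calibrated phylogeny, and how microhabitat structures morphological
diversification in body proportions and foot shape. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The discrete-character model

Microhabitat use is modelled as an unordered K-state continuous-time
Markov chain (an Mk model) running along the branches of a rooted
chronogram. The instantaneous rate matrix Q has nonnegative off-diagonal
entries $q_{ij}$ (transitions per Myr) and rows summing to zero; the
transition probabilities over a branch of length $t$ are $P(t) = e^{Qt}$.
Three nested constraint structures are supported: ER (one shared rate),
SYM (one rate per unordered state pair), and ARD (all $K(K-1)$ rates
free). Models are compared by AIC, with ties broken toward the model with
fewer parameters.

The likelihood of the observed tip states is computed by Felsenstein's
pruning algorithm: post-order conditional likelihood vectors, per-branch
propagation through $P(t)$, per-edge rescaling to avoid underflow, and a
root prior. The root prior defaults to flat ($1/K$), which matches the
convention of the standard ML machinery in this field; a
stationary-distribution prior and arbitrary fixed priors are available
through the `root_prior` argument of `fit_mk()`,
`marginal_ancestral_states()` and `sample_history()`.

### Optimization

ARD on six states has 30 free rates on a rugged, partially flat surface:
beyond the rate magnitude that saturates the chain, the likelihood is
nearly constant, and quasi-Newton steps that overshoot into that plateau
stall there. Fitting therefore works on log-rates, bounded in
$[10^{-9}, 10^3]$ per Myr, and every start is first placed at the best
overall rate magnitude by a coarse line scan over a global scaling of Q
(13 points spanning six orders of magnitude) before L-BFGS-B runs.
`n_starts` controls the number of starts (the first is deterministic, the
rest log-uniform around the initial guess); the convergence tolerance on
the log-likelihood is $10^{-8}$. Rates estimated at the lower bound print
as 0 at four decimals. Zero-length branches use the identity transition
matrix. Matrix exponentials use the eigendecomposition of Q, with a
scaling-and-squaring series fallback when Q is numerically defective.

With rare states, the ARD maximum-likelihood solution can place fast
"flicker" rates on the rare state's row: this is a genuine property of
the likelihood (cross-checks against an independent implementation find
the same or slightly worse optima), not an optimizer artefact, and it is
why realized transition counts from stochastic maps routinely exceed the
parsimony-style count of distinct origins.

## Stochastic character mapping

`sample_history()` draws complete character histories conditioned on the
tips and a Q-matrix. Node states are sampled root-to-tips from their
joint conditional distribution; each branch path is then sampled given
its endpoint states by uniformization: a dominating Poisson process at
rate $\Omega = \max_i(-q_{ii})$ proposes jump counts and times, the
embedded chain $R = I + Q/\Omega$ is bridged between the endpoints, and
virtual (self) jumps are removed. A forward-simulation-with-rejection
sampler is retained in the package internals purely as a test oracle;
uniformization is used everywhere else because rejection stalls on long
branches with unlikely endpoint pairs. Summaries over a set of maps
(default 1,000) give per-node state frequencies, mean realized transition
counts, mean counts of independent origins of a focal state (every gain
event counts, including regains after a loss), and the edges on which
gains concentrate.

## Morphometric processing

Linear measurements (SVL, TL, HL, BW, SE, FLL, HLL in mm) may have
missing entries; `impute_missing_measurements()` fills them from a
least-squares regression of the missing variables on the observed ones,
on the natural-log scale, fitted over complete cases from the narrowest
taxonomic pool that supports the regression (conspecifics, else
congeners, else the whole table). Observed entries are never touched and
the procedure is deterministic. Species mean measurements are divided by
mean SVL and natural-log transformed into six Mosimann shape ratios; the
natural log is the field convention for these ratios.

Foot shape uses 21 two-dimensional points: 11 fixed landmarks and 10
semilandmarks, each semilandmark bracketed by two neighbours along its
curve (the `curves` matrix). Missing points are completed by thin-plate
spline interpolation from a complete conspecific consensus (or a
sister-species consensus when no complete conspecific exists).
`gpa()` then removes position, scale and rotation: configurations are
centered, scaled to unit centroid size, and rotated onto the running
consensus by orthogonal least squares. Reflections are allowed in the
rotation, which transparently corrects specimens digitized in mirror
orientation. With `slide = TRUE`, a fixed number of sliding passes
(default 3) follows: each pass slides every semilandmark along the chord
between its neighbours to minimize thin-plate-spline bending energy
against the consensus — an exact quadratic minimization, so the energy
cannot increase within a pass — and then re-aligns to convergence
(consensus change below $10^{-8}$). A fixed number of passes is used
because iterating sliding to a fixed point lets semilandmarks drift
slowly along their chords without improving the fit meaningfully.
Species means are produced in two stages (align within species, then
align the species consensuses), retaining mean centroid size per species
for allometry.

## Comparative statistics

All statistics share one construction: under Brownian motion the tip
covariance is the matrix C of shared path lengths, and premultiplying
data and design by $C^{-1/2}$ (from the eigendecomposition) turns GLS
into OLS on transformed data.

* `phylogenetic_anova()` computes R² and F from traced sums of squares
  of the transformed data and evaluates them against `n_perm`
  randomizations of the reduced-model (intercept-only) residuals (RRPP).
  The effect size Z is the standard deviate of log F within the
  permutation distribution (observed value included). On a star tree
  with equal depths the transformation is scalar and the statistics
  reduce exactly to ordinary MANOVA-trace statistics.
* `pairwise_group_distances()` evaluates Euclidean distances between GLS
  group means against the same residual-randomization null.
* `sigma_mult()` is the multivariate Brownian rate: squared transformed
  deviations from the GLS phylogenetic mean summed over species and
  dimensions, divided by $Np$. `compare_rates_by_group()` keeps the
  full-tree transformation, subsets transformed squared deviations by
  group, and compares the max/min ratio against Brownian simulations at
  the pooled rate with the empirical trait covariance (so trait
  correlations are preserved under the null).
* `convergence_c1()` implements C1: for each focal pair,
  $1 - D_{tip}/D_{max}$, where $D_{max}$ is the largest distance among
  the node values (GLS ancestral estimates, tips included) on the two
  root-ward paths to the pair's most recent common ancestor. C5
  (`convergence_c5()`) ordinates tips and ancestral estimates onto the
  first two principal axes and counts root-to-tip lineages whose path
  enters the convex hull of the focal tips' scores (entry by an
  inside endpoint, by a segment crossing, or by starting inside at the
  root; each lineage counts once). Hulls are two-dimensional; the planar
  hull is also what published morphospace figures show. Both p-values
  come from Brownian simulations with the trait covariance estimated
  from the data.
* `allometric_convergence()` regresses shape on log size within each of
  two groups, predicts both groups' shapes at the shared smallest and
  largest observed sizes, and permutes group labels (species keep their
  size and shape) to test whether $D_{small} - D_{large}$ exceeds
  chance; a positive statistic means the groups are closer in shape at
  large size.

Every permutation or simulation p-value uses the
$(1 + \text{exceedances})/(1 + \text{draws})$ convention and is exactly
reproducible given a seed. Draw counts default to 999; the calibration
and power checks in the test suite run at reduced counts (199
permutations, 99 simulations per synthesis) over many syntheses, which
estimates rejection rates just as well at a fraction of the cost.

## The synthetic-data generators

Because the empirical specimen data live in an external repository, every
stage is exercised on synthetic data whose structure mirrors the study:

* `simulate_yule_tree()` draws pure-birth chronograms, by default
  rescaled to unit height; analyses at the empirical scale use height
  200 Myr, the approximate depth of the salamander chronogram.
* `simulate_discrete_character()` runs the exact forward CTMC and keeps
  the true history, enabling round-trip checks of rate recovery,
  transition counting and mapping.
* `simulate_multivariate_bm()` adds independent Gaussian increments per
  branch segment with variance = duration × the segment state's rate, so
  state-dependent rate regimes follow any painted history.
* `simulate_convergent_traits()` adds an Ornstein–Uhlenbeck-style pull
  toward a common attractor on branches whose descendants are all focal
  (Euler steps of at most 1% of tree height); strength 0 is exactly
  plain BM. This produces tunable convergence rather than literal trait
  copying.
* `generate_landmark_dataset()` perturbs a stylized five-toed foot
  template (11 landmarks, 10 semilandmarks with a bracketing `curves`
  map) by species-level deviations (Gaussian or Brownian on a supplied
  tree), specimen-level digitizing noise, random similarity transforms,
  and optional masking (at most 6 points per specimen so spline
  completion stays well-posed).
* `generate_measurement_table()` draws lognormal SVL and power-law
  allometries for the other six variables with lognormal noise and
  optional masking; SVL is never masked, since it anchors both size and
  imputation.

Every generator is a pure function of its seed and restores the caller's
RNG state. What the generators do **not** emulate: measurement error
correlated across variables, non-Brownian trait evolution (other than
the attraction regime), biased taxon sampling, digitization artefacts
beyond isotropic noise, and intraspecific microhabitat variation beyond
the primary/secondary record. Passing tests on synthetic data therefore
validate the algorithms and their calibration, not the biological
conclusions one would draw from any particular empirical dataset.

## Design choices on genuinely open points

* **Semiaquatic state.** The seven-state schemes derive SA from species
  whose two categories are exactly terrestrial and aquatic, in either
  order — the standard meaning of semiaquatic. Explicit SA assignments
  can be supplied by editing the records before classification.
* **External arboreal classifications.** The McEntire-style schemes
  override arboreality only for species the external classification
  covers: under the majority-rule variant a facultative species loses
  arboreality (falling back to its secondary category, or T), while
  species without a status keep their base-scheme state; this keeps all
  six schemes in agreement on species with a single microhabitat record.
* **Two non-terrestrial categories under lenient schemes.** The primary
  is kept and a warning names the species; no published rule covers this
  case.
* **Per-analysis pruning.** Morphological subsets rarely cover all
  classified species; each analysis prunes the tree to the intersection
  of tree tips and available data.
* **Posterior-tree sensitivity.** `sensitivity_analysis()` refits the
  Q-matrix on every tree (repeating all analyses), reporting 2.5%/97.5%
  quantiles per statistic; a fixed-Q shortcut is deliberately not the
  default.
* **Problem sizes.** The validation battery runs at 400 tips for rate
  recovery, 300 tips for rate-ratio recovery (p = 6), 100 tips for
  type-I calibration (1,000 syntheses for the ANOVA, 1,000 for the rate
  ratio at 99 simulations each), and 100 syntheses for C1 power; these
  sizes bracket the empirical dimensions while keeping the suite quick
  on a single CPU.

## Known limitations

* C5 hulls are two-dimensional only; no full-dimensional convex-hull
  backend is provided.
* Hidden-rate models, OU/EB trait models, correlated-character tests and
  diversification-rate analyses are out of scope.
* The multi-group rate comparison inherits the usual attenuation when
  group membership changes recently on the tree: a tip's residual
  reflects its whole root-to-tip history, so groups that arose recently
  under-express their generating rate. The forward simulators make this
  visible (and testable) by painting rates on true histories.
* ARD fits with very rare states are weakly identified in the rare
  state's row; model comparison and the loss/gain rate ratio are far
  more stable than the individual rates.
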