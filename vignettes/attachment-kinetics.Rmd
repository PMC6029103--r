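---
title: "Attachment kinetics and phenotypic heterogeneity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attachment kinetics and phenotypic heterogeneity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attachkin)
```

## The scientific problem

When a well-mixed planktonic culture of *Pseudomonas aeruginosa* is placed
over a glass surface, cells do not attach uniformly. Single-cell time-lapse
experiments show that the bulk-cell fraction decays as a *mixture* of
exponentials: a large subpopulation attaches within minutes while a smaller
one lingers for an hour, a phenotypic split driven by heterogeneous
production of the adhesive exopolysaccharide Psl. The same heterogeneity
shapes early biofilm development: after a surface-attached cell divides, the
two daughters often adopt different fates (one stays, one leaves).

`attachkin` implements the quantitative layer of such experiments:

* a **kinetics module** that evaluates and fits the exponential-mixture
  attachment model and selects the number of phenotypes objectively;
* a **track-processing module** that converts per-cell tracking tables into
  bulk/surface count series, attachment/detachment event balances, and
  genealogical forests;
* a **heterogeneity module** for single-cell fluorescence statistics (CV,
  threshold proportions, channel correlations, kernel densities);
* a **lineage module** that classifies postdivision fates and estimates fate
  probabilities with uncertainty;
* **biofilm summary metrics** (average thickness, roughness coefficient) on
  local-thickness grids;
* a **synthetic-data generator** that produces every input the pipeline
  consumes, with the statistical structure the analyses assume.

## The attachment model

Let $N$ cells split into $k$ phenotypes with number fractions $f_i$,
attachment rates $\alpha_i$ (s$^{-1}$) and detachment rates $\beta_i$.
The bulk count $N_b(t)$ and surface count $N_s(t)$ obey

$$\frac{dN_b}{dt} = -\frac{dN_s}{dt}
  = -\sum_i \alpha_i N_b^i(t) + \sum_i \beta_i N_s^i(t),
  \qquad N_b(t) + N_s(t) = N .$$

In the experimental regime this emulates, detachment events are rare
(attachment outnumbers detachment by far more than tenfold), so the
$\beta_i$ terms are dropped. With $N_b(0) = N$ the solution is the mixture
decay

$$\frac{N_b(t)}{N} = \sum_{i=1}^{k} f_i\, e^{-\alpha_i t},$$

implemented by `model_nb()`. `flux_check()` is the admissibility guard for
the simplification: it counts both transition types on the data at hand and
raises a flag whenever the attach/detach event ratio falls below 10. The
model is checked in the test suite against a brute-force ODE integration of
the full system to $10^{-8}$.

The two-phenotype regime reported for later-exponential-phase cultures
($f \approx 0.8/0.2$, $\alpha_{\text{fast}} = 5.45\times10^{-3}$ s$^{-1}$,
$\alpha_{\text{slow}} = 2.52\times10^{-4}$ s$^{-1}$, a $\sim$21-fold rate
separation) ships as `mix_late_exponential()` and is the default scenario of
the examples.

```{r model}
dq <- derived_quantities(kinetics_fit(c(0.8, 0.2), c(5.45e-3, 2.52e-4)))
dq$rate_ratio
dq$percent_attached_at(900)   # % attached within 15 min
```

## Fitting and model selection

`fit_mixture()` minimizes the residual sum of squares of the mixture decay
against the observed bulk fraction, **on the untransformed $N_b/N$ scale**.
This is a deliberate choice: late-time counts are small, and a log-scale
objective would overweight the slow tail where counting noise is relatively
largest. Constraints are handled by parameterization rather than by a
constrained optimizer: fractions through a softmax (so they are positive and
sum to one exactly) and rates through logs (so they stay positive). The
resulting smooth unconstrained problem is solved with BFGS from 20 random
starts whose rates are drawn log-uniformly on $[10^{-5}, 10^{-1}]$ s$^{-1}$
— multi-starting is essential because exponential mixtures have well-known
local minima when components are close. The fit is deterministic given its
seed. Standard errors are Gauss–Newton estimates mapped through the delta
method; they are indicative rather than exact.

`select_k()` fits $k = 1..k_\max$ and minimizes a small-sample corrected
information criterion (AICc under a Gaussian working likelihood,
$p = 2k$ parameters). Because an information criterion alone can prefer a
decorative extra component, two identifiability guards are applied to the
selected fit, and a violating $k$ collapses to $k-1$:

* adjacent rates must differ by at least 3$\times$ (a two-component fit with
  nearly equal rates is a single exponential in disguise);
* every fraction must be at least 0.02 (smaller amplitudes are not
  distinguishable from baseline noise at realistic counts).

The thresholds are fixed package defaults chosen a priori from the
magnitude of the published rate separation ($\sim$20$\times$) and the
smallest subpopulation one could credibly claim from a few hundred tracked
cells; they are not tuning knobs.

```{r fit}
trk <- simulate_attachment(mix_late_exponential(),
                           sim_config(n_cells = 2000, seed = 1))
sel <- select_k(count_series(trk), k_max = 3, seed = 1)
sel$k
sel$fractions
sel$rates
```

## The synthetic-data generator

No raw microscopy data are distributed with the experiments this package
models, so the generator is a first-class module: it encodes the study
conditions and provides ground truth for every estimator.

**Attachment tracks.** `simulate_attachment()` is event-driven: each cell
draws its phenotype from the number fractions, then an exponential waiting
time at rate $\alpha_i$ (and, when $\beta_i > 0$, alternating detach/attach
renewals). Waiting times are drawn exactly and only then discretized to the
frame grid, avoiding the bias a per-frame Bernoulli scheme incurs at coarse
frame intervals. Defaults mirror the experimental protocol: 3-s frames,
~1-h movies, a 165 × 139 µm field. Mobile cells random-walk with per-frame
step SD $\sqrt{2D\,\Delta t}$ ($D$ = 1 µm²/s by default); attached cells
jitter by 0.05 µm around their anchoring point.

**Fluorescence.** The latent single-cell expression variable is log-normal —
observed intensity distributions are unimodal and right-skewed, but no
distribution family is established, so this is a documented modeling choice,
not a measured fact. Channel transfers are monotone power laws with
multiplicative log-normal noise: increasing for a product stain (lectin),
decreasing for an inverted reporter (EGFP falls as operon expression rises).
The two channels are coupled by a Gaussian copula on the latent scale, and
the copula correlation is calibrated by a one-dimensional root find so the
*population Pearson correlation of the measured intensities* hits the target
(default −0.45, the reported reporter-validation value). Because the
transfers are log-linear, the channels are jointly log-normal and the
Pearson correlation of the copula correlation is available in closed form,
which makes the calibration exact; heavily skewed marginals bound the
attainable anticorrelation, and unreachable targets raise an error rather
than silently undershooting. `fluor_presets()` additionally provides the
bulk-population EGFP marginal (20% of cells above 500 a.u., 10% above
1000 a.u.) and the surface-attached marginal (2% above 500 a.u.).

**Lineages.** `simulate_lineage()` grows trees from attached founders.
Division intervals are exponential with a configurable mean (default 40 min)
— the interval distribution is not reported, so exponential is the
minimal-assumption choice and is isolated behind one parameter. At each
division an independent fate is drawn from the three-category distribution
(both daughters stay / one stays / both leave). A leaving daughter receives
a truncated-exponential surface-residence time so its detach event always
falls inside the observation window; this keeps the realized category of
every division identical to the drawn one, which is what makes the
generator usable as an exact oracle for the fate classifier. Only the
headline component of each published strain distribution is a reported
number (wild type: one-stays > 40%; uniform-Psl strain: both-stay ≈ 80%;
Psl-deficient strain: both-leave = 60%); the split of the remaining mass in
`fate_presets()` is a fixed package choice consistent with those statements
(both-stay ≈ 80%/3 for the wild type).

**Height maps.** `simulate_heightmap()` draws a (optionally 3 × 3 smoothed)
log-normal thickness field. For a log-normal field the expected roughness
coefficient is $2\,(2\Phi(\sigma/2) - 1)$, which is inverted for the
log-scale $\sigma$ — the calibration is exact in expectation, and since
$Ra^*$ of any nonnegative field is below 2, targets $\ge 2$ are rejected as
incompatible with nonnegativity.

All generator randomness flows from one explicit integer seed per call;
the per-frame position materialization (`track_table()`) uses a stream
derived from the same seed, so identical configurations reproduce
bit-identical outputs.

## From tracks to counts and trees

Real tracking pipelines decide "attached" with dedicated pole-tracking
algorithms; the package's surrogate (`classify_attached()`) is deliberately
the simplest auditable rule: a frame is attached iff the maximum pairwise
displacement within the trailing 5-frame (15-s) window is below 1 µm. The
window and threshold are explicit arguments; the rule localizes a true
attachment switch to within one window, which the tests verify against
generator truth. `count_series()` then sums classifications per frame
(conservation $N_b + N_s = N$ is asserted on every series) — or, given a
simulation object, uses the generator's own event bookkeeping, which is the
exact-truth path the estimator studies rely on.

`extract_division_events()` rebuilds genealogical forests from parent-linked
tracks. Daughter fates follow the track endings: an explicit final mobile
frame is a detach ("leave"); reaching the movie end is "stay" when the
daughter was observed for at least 3 frames after division and "censored"
otherwise — the movie-edge rule that prevents fate misclassification at the
boundary. Divisions with a censored daughter are excluded from $N_{div}$.
Orphan daughters (unknown parent, or no temporal adjacency with the parent
track) are returned explicitly rather than dropped, and parent cycles are a
structural error.

## Fate probabilities and their uncertainty

`fate_probabilities()` divides category counts by $N_{div}$. Uncertainty is
reported **two ways**: the figure-legend convention of the source
experiments, $1/N_{div}$ (kept verbatim for reproduction — it is most
plausibly a shorthand for $1/\sqrt{N_{div}}$), and the per-category binomial
standard error $\sqrt{p(1-p)/N_{div}}$, which is what should be used for
inference. Probabilities are per *division* (the three categories partition
division events), not per daughter.

## Heterogeneity statistics

Conventions, each fixed where the source protocol is silent:

* **Background subtraction** clips at zero and reports the clip count; the
  CV is computed on the clipped values.
* **CV** uses the sample ($n-1$) SD and requires a positive mean.
* **Threshold proportions** use strict `>`, matching "greater than X a.u."
  phrasing, with binomial SEs.
* **KDE** (`kde_100()`) uses a Gaussian kernel with Silverman's
  rule-of-thumb bandwidth, evaluated at 100 equally spaced points spanning
  the data range, the standard presentation for intensity distributions; the
  trapezoid integral over the extended support is reported and sits within a
  few percent of 1.
* **Two-sample comparison** is the classic equal-variance unpaired two-sided
  t test, wrapped from `stats::t.test()` — plumbing, not new statistics.

Intensities are arbitrary units throughout; no cross-experiment intensity
calibration is attempted.

## Biofilm summaries

On a local-thickness grid $L$, `mean_thickness()` is the arithmetic mean
and `roughness_coefficient()` is
$Ra^* = \frac{1}{N}\sum_i |L_i - \bar L| / \bar L$ — zero for a flat film,
scale-invariant, bounded by 2 for nonnegative maps. Inputs are 2-D
thickness grids, not confocal stacks: reducing a z-stack to local thickness
is upstream image processing and out of scope. Published
thickness/roughness values for specific strains are figure-level statistics
without numeric tables, so the package reproduces their *ordering*
(thicker/smoother for uniformly attaching strains) on calibrated synthetic
fixtures rather than absolute values.

## Numerical and statistical choices

* **Ensemble validation band.** The simulated bulk fraction is an empirical
  survival function of the attach times, so "the ensemble mean matches the
  closed form at every frame" is tested with the exact simultaneous band for
  an ECDF — the Kolmogorov–Smirnov 99.9% band
  ($\sqrt{n}\,\sup_t|\hat F - F| \le 1.95$) — plus a pointwise check that at
  least 99% of frames sit within 3 per-frame SE. A naive simultaneous
  3-SE-at-every-frame rule is violated by a provably exact simulator about
  half the time once ~1200 correlated frames are scanned, so it would test
  the multiplicity artifact, not the simulator.
* **Problem sizes.** The test suite and the acceptance script run at
  $10^4$ cells for the headline recovery, 60 replicates of $10^3$ cells for
  the estimator-accuracy study, $\ge$ 300 (typically ~1000) divisions for
  fate recovery, 2000 cells for the correlation target, and 64 × 64 grids
  for roughness calibration — sizes at which the binomial/Monte-Carlo SEs
  are a few percent, matching the precision of the published values they
  are compared to.
* **Degenerate inputs** fail loudly and early: zero-variance channels,
  non-positive means, empty grids, all-zero maps, inconsistent frame grids,
  divisions without exactly two daughters, $N_{div}=0$ forests (absent
  result with a reason, not NaN).

## Known limitations

The generator reproduces the *statistical signatures* of the real data, not
the data themselves: no pixel-level imaging noise, no segmentation or
tracking errors, no drift, no cell-shape information, no gene-regulatory
dynamics behind the expression heterogeneity (only its measured marginal and
correlation structure), and independent fates across divisions (real
daughters may be correlated through inherited Psl). Passing recovery tests
therefore validates the estimators under the stated model assumptions; they
cannot certify the upstream microscopy pipeline. The displacement-threshold
classifier is a stand-in for dedicated two-point pole tracking, and the
exact operational definition of "surface-attached" in the original counting
protocol is not stated — the surrogate rule is documented and configurable
precisely because of that.
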