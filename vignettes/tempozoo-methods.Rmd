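---
title: "Methods: simulating and measuring segmentation-clock tempo across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring segmentation-clock tempo across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempozoo)
```

The mammalian segmentation clock — oscillatory HES7 expression in presomitic
mesoderm (PSM) cells — runs at a species-specific pace: roughly two hours per
cycle in mouse, more than six in marmoset. `tempozoo` packages the
quantitative machinery for comparative ("stem cell zoo") studies of this
tempo: a delay-differential-equation model of the HES7 feedback loop, the
three kinetics estimators applied to luminescence reporter recordings
(period, protein half-life, intron delay), cross-species scaling statistics,
and a rank-based cross-species expression profile. A synthetic-data module
generates inputs with the statistical structure the estimators assume, so the
entire pipeline is testable end to end without any external data.

This vignette explains the models, the estimators, the tunable parameters and
their defaults, and the design decisions taken where more than one reasonable
choice existed.

## The HES7 delayed negative-feedback model

HES7 represses its own transcription, but only after a delay: the nascent
transcript must be spliced (the *intron delay*) and the protein must be
transcribed and translated. The package models this with the standard
two-variable delay system

$$
\frac{dM}{dt} = \frac{a_m}{1 + \left(P(t-\tau_M)/p_0\right)^h} - b_m M(t),
\qquad
\frac{dP}{dt} = a_p\, M(t-\tau_P) - b_p P(t),
$$

where $M$ is mRNA, $P$ is protein, $b_m$ and $b_p$ are first-order
degradation rates, and the total regulatory delay $\tau_M + \tau_P$ is the
intron delay plus the transcription/translation delay. Four parameters are
measured quantities and form the human reference defaults of
`dde_parameters()`: $b_m = 0.044\,\mathrm{min}^{-1}$,
$b_p = 0.0175\,\mathrm{min}^{-1}$, $\tau_\text{intron} = 36.7$ min,
$\tau_\text{txtl} = 29.8$ min. The production-side constants are not
constrained by those measurements; the defaults ($a_m = 30$ units/min,
$a_p = 2\,\mathrm{min}^{-1}$, $p_0 = 200$ units, $h = 3$) were chosen once so
that the reference set oscillates robustly with a large repression gain
(operating point well above $p_0$, logarithmic Hill gain near $-h$), and are
fully configurable for users who want to match a specific published
parameterization.

Two structural choices were genuinely open:

* **Delay placement.** Only the *total* delay is identifiable from the period;
  the split between the mRNA equation and the protein equation is a modelling
  convention. The package default assigns the whole delay to mRNA production
  (`delay_split = 1`, so $\tau_P = 0$), the simplest identifiable choice. The
  closed-form period estimate below is invariant to the split, and
  `delay_split` is exposed for anyone wanting the alternative convention.
* **Scaling convention.** `scaling_sweep()` multiplies both degradation rates
  by $s$ and divides both delays by $s$ jointly. Scaling the two delays
  separately would introduce a second, unidentifiable degree of freedom.

### Integration

`simulate_hes7()` integrates with fixed-step fourth-order Runge–Kutta and the
method of steps (compiled code), with constant history $M = P = 1$ for
$t \le 0$ and delayed stage values linearly interpolated from the stored
solution. The default step $dt = 0.05$ min resolves the shortest delay in the
$s = 3$ sweep (about 7 min) with more than a hundred steps; halving $dt$
changes the measured period by well under 0.5%, which is the convergence
bar the tests enforce. A step larger than any positive delay is rejected, and
a negative or non-finite state aborts integration (it indicates instability,
which RK4 at the default step does not exhibit for any tested parameter set).

### Period measurement and the closed form

`period_peak_to_peak()` reports the mean interval between local maxima of
$P(t)$ after a 2000-min transient, with a prominence floor of 5% of the
post-transient range to reject numerical ripple. Fewer than three qualifying
peaks is a *non-oscillating result*, not an error — damped relaxation to the
fixed point is a legitimate model outcome.

As an internal oracle the package uses the standard closed-form estimate for
strongly nonlinear delayed negative feedback,

$$T \approx 2\left(\tau_\text{intron} + \tau_\text{txtl} + \frac{1}{b_m} + \frac{1}{b_p}\right),$$

which gives 292.74 min at the human reference; the simulated peak-to-peak
period lands within a fraction of a percent of it. Every term scales as
$1/s$, so the sweep prediction $T(s)\,s \approx \text{const}$ follows
directly; the simulation satisfies it within a few percent over
$s \in [0.5, 3]$, with the residual drift reflecting the finite repression
gain rather than integration error.

`species_fold_change()` converts measured kinetics into a sweep scale: the
mean of the half-life fold-change and the delay fold-change relative to the
reference species, in rate space (reference/species).

## Kinetics estimators

### Period: sinc detrending, amplitude normalization, Morlet wavelet

Raw luminometer traces drift (medium depletion, cell growth) and damp.
`estimate_period()` therefore (1) removes a slow trend, (2) normalizes the
amplitude envelope, (3) runs a continuous Morlet wavelet transform
($\omega_0 = 2\pi$) over a linear grid of 200 periods between 100 and
500 min, averages wavelet power over time at each period — excluding samples
inside the cone of influence, where edge effects corrupt the estimate — and
returns the period of maximum average power. The scan grid gives a
resolution of about 2 min, which is the recovery tolerance used throughout
the tests.

The trend is estimated as the least-squares line plus the low-pass component
of the line-free residual, using a Blackman-windowed sinc kernel of length
$\min(n, 3\,T_c/dt)$ with cutoff period $T_c$ (500 min by default, 250 min
for clocks faster than \~200 min so the oscillation itself is not absorbed
into the trend). Subtracting the fitted line *first* is deliberate: it makes
a pure ramp detrend to exactly zero and prevents the filter's edge padding
from bending around ramps or oscillation peaks — with naive reflection
padding the detrended signal acquires edge artifacts large enough to bias
the downstream cross-correlation delay by several minutes. Amplitude
normalization divides by a sliding-window SD envelope ($\times\sqrt{2}$,
window = cutoff period), floored at a small epsilon so flat segments cannot
blow up.

A result whose peak power is less than ten times the median power across the
grid is flagged `low_power`: white noise produces a ratio near one, a clean
rhythm a ratio in the hundreds. The same pyBOAT-style convention (one
threshold for both detrending and normalization window) is used because the
two operations target the same slow timescale.

### Protein half-life: RANSAC on the log-linear decay

In the degradation assay, transcription of a luciferase-tagged HES7 is
halted and the luminescence decay recorded. Early time points are
contaminated by residual mRNA still being translated (a plateau), and late
points approach the instrument noise floor, so the informative region is the
*most linear part* of the log2-transformed curve. `estimate_halflife()`
finds it with RANSAC: the candidate window starts at the global signal
maximum ("later time points only"); 200 random two-point lines are scored by
their inlier consensus, with the inlier threshold set adaptively to
$1.5\times$ the MAD of the first-differenced log2 signal (floored at
$10^{-6}$ so exact data still classifies); the final slope is an ordinary
least-squares refit on the largest contiguous inlier segment, and the
half-life is $-1/\text{slope}$. A non-negative fitted slope is a *no-decay*
error, and fewer inliers than 25% of the window is an unstable fit. The
sampler is seeded (default 0) for reproducibility; at the 1% noise level of
the test fixtures the recovered half-life sits within a fraction of a
percent of truth, and across 100 noise seeds at 5% noise the RMSE stays
under 1% of truth.

### Intron delay: non-negative-lag cross-correlation

The intron delay is the phase lag between simultaneously recorded intronless
and intron-containing reporters. Both channels are detrended and normalized
with the same settings, then the normalized cross-correlation is scanned
over non-negative lags only — intron processing can only delay, and for
near-periodic signals lags beyond one period alias onto `lag + period`, so
`max_lag` should stay below the oscillation period. The discrete argmax is
refined by parabolic interpolation through its two neighbours, giving
sub-sample resolution (errors well under half the 10-min sampling interval
on noiseless fixtures). A peak correlation below 0.2 flags the estimate
unreliable. Following the source protocol, no reporter-maturation correction
is subtracted. Whether the correlation should be computed on raw or
detrended signals was not fully pinned down by the protocol; detrended is
used because drift otherwise dominates the correlation at long lags.

## Cross-species scaling

`linear_scaling_fit()` is ordinary least squares of the clock period on one
trait, with body weight fitted on $\log_{10}$ scale and other traits on
identity scale. No phylogenetic correction is applied — with six species and
clade labels as annotation only, ordinary fits are the transparent choice.
Rows missing either field are dropped *and counted* (`n_dropped`); nothing
is imputed. `somite_period()` converts staged-embryo somite counts to an in
vivo period as $1440/\text{slope}$ minutes from the somites-per-day
regression. `period_ratio_extremes()` reports the max/min period ratio
rounded to one decimal — 3.2 for the packaged six-species table.
`kinetics_scaling_report()` runs the three kinetics fits (period ~
half-life, period ~ delay, half-life ~ delay); the packaged table carries
measured kinetics for four species, and externally published values for the
other two can be supplied via `extra_kinetics` rather than being baked in.

## Cross-species expression profiling

The profiling pipeline mirrors the transcriptomic arm of a stem-cell-zoo
analysis:

1. **Ortholog gluing** (`glue_orthologs()`): per-species count matrices are
   joined on human anchor ids, keeping only genes with a one-to-one ortholog
   in *every* species. Rows labelled with a non-one-to-one relationship type
   are discarded up front; a duplicated anchor within a species is treated
   as a map violation (error), and anchors missing from any species are
   dropped and counted.
2. **GeTMM normalization** (`rpk()`, `tmm_factors()`, `getmm()`): counts
   become reads-per-kilobase, TMM scaling factors are computed *on the RPK
   matrix*, and each sample is rescaled to an effective library of one
   million. The trimmed mean uses the standard double trim (30% on M, 5% on
   A) against the upper-quartile-closest reference sample. The default is
   the *unweighted* trimmed mean: it makes the factors exactly invariant to
   rescaling any library (proportions, M, A and the trim set are all
   unchanged), which is the invariance the pipeline's tests demand to 0.1%.
   Delta-method precision weighting (`weighted = TRUE`) reproduces
   `edgeR::calcNormFactors()` to better than $10^{-3}$ but, because the
   weights depend on absolute counts, shifts factors by 0.5–1% under library
   rescaling — a property of the weighted estimator itself, which the
   package documents rather than hides. On realistic fixtures the
   unweighted and weighted factors agree within about 1%.
3. **Expression floor** (`filter_low_expression()`): a gene is kept iff it
   reaches 10 GeTMM units in at least one sample (`>=` at the boundary).
4. **Spearman tempo profile** (`spearman_profile()`): replicates are
   averaged within species (the correlation is across species means — one
   point per species, matching the $n = 6$ semantics of the published
   per-gene scatterplots; replicate-level correlation would inflate $n$ with
   pseudo-replicates), species means are rank-correlated with the period
   vector, and the two-sided p-value comes from full enumeration of all
   $n! = 720$ permutations. At $n = 6$ the large-sample approximation is
   meaningless; enumeration is exact and costs nothing (a single
   $720 \times n_\text{genes}$ matrix product). A perfectly monotone gene
   has $p = 2/720 \approx 0.00278$. Note that monotone-transform invariance
   holds for the species means; with replicates, averaging happens on the
   GeTMM scale before ranking.
5. **Tempo gene set** (`select_tempo_genes()`): genes with $\rho$ strictly
   below −0.8 (the strongest anticorrelated set, expressed higher in faster
   species), exported as a two-column pre-ranked list for external
   enrichment tools. Enrichment analysis itself (GSEA, network layout) is
   out of scope.
6. **Condition ratio** (`ratio_comparison()`): per-gene log2 ratios of the
   selected set between two expression tables versus a seeded size-matched
   random set, with medians and a Wilcoxon comparison — the design of the
   fast-versus-slow progenitor check.

## The synthetic-data module

The generators define the conditions under which the pipeline is validated:

* **Oscillation traces**: baseline + linear drift + exponentially damped
  cosine + additive Gaussian noise (additive because these traces are
  analysed after normalization). Default cadence is one sample per 10 min,
  a plate-luminometer-like rate that resolves the fastest (122-min) clock
  with >12 samples per cycle; the actual instrument cadence and noise level
  are not published, so these are package choices.
* **Decay traces**: a constant plateau (residual-mRNA phase) followed by
  exact exponential decay, under multiplicative lognormal noise
  (luminescence is positive). Specs require the decay phase to span at
  least four half-lives.
* **Dual-reporter pairs**: channel B is channel A's deterministic part
  shifted by the lag, with independent noise per channel; lags must stay
  below one period for identifiability.
* **Expression matrices**: negative-binomial counts (edgeR
  parameterization) whose log2 means are, for planted genes, linear in the
  species' period *rank* — strictly decreasing for the anticorrelated
  module, increasing for the correlated one. `effect_size` is the log2
  fold-change between adjacent period ranks (a planted gene spans
  `effect_size * (n_species - 1)` log2 units overall); at the default
  effect size of 2 and dispersion 0.1 the planted anticorrelated module is
  recovered essentially completely at the $\rho < -0.8$ threshold, and the
  recovery-rate tests run at exactly these settings. Expected counts are
  proportional to expression × gene length × library factor, so RPK
  correctly inverts the length effect.

What the generators deliberately do **not** emulate: cell-to-cell coupling
or synchronization dynamics in the oscillation traces, instrument-specific
noise spectra, GC/mappability biases or ortholog-annotation errors in the
count matrices, and any form of raw-read-level structure. Passing the
closed-loop tests therefore shows that the estimators are correct and
well-calibrated for data with the assumed structure — it does not certify
performance on any particular real instrument or genome annotation.

## Reproducibility and problem sizes

Every generator and every stochastic estimator takes an explicit seed;
`run_pipeline()` fans a single global seed out to per-stage seeds through a
stable arithmetic hash (`stage_seed()`), so each stage can be reproduced in
isolation and a repeated run is bit-identical. The packaged demo sizes —
2000-gene expression matrices, 2–3-day trace durations, 6000-min DDE
horizons with a 2000-min transient, 100-seed Monte-Carlo loops — were chosen
so the whole suite exercises every code path in well under a minute of
computation while leaving estimator errors an order of magnitude below their
test tolerances.

## Known limitations

* The DDE model is deterministic and single-cell; stochastic (Gillespie)
  dynamics and Delta–Notch coupling are out of scope, as is fitting the DDE
  to measured traces.
* The wavelet estimator reports only the time-averaged spectrum; full
  ridge-tracking (instantaneous period over time) is not implemented.
* Exact Spearman enumeration is designed for small $n$; beyond $n = 8$
  species the $n!$ enumeration should be replaced by the standard exact
  null tables or sampling.
* The somite-staging regression ignores staging uncertainty, which for
  unconventional species is substantial; its output should be read as a
  rough in vivo anchor, not a precise period.
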