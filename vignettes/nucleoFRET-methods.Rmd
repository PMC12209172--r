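---
title: "Models and methods behind nucleoFRET"
author: "nucleoFRET authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nucleoFRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoFRET)
```

# The measurement and its statistic

In solution spFRET, nucleosomes carrying a Cy3/Cy5 pair on neighbouring
DNA gyres diffuse through a confocal volume; each transit (a "burst")
yields a donor-channel intensity $I_3$ and an acceptor-channel intensity
$I_5$. The per-particle statistic is the proximity ratio

$$E_{PR} = \frac{I_5 - \alpha I_3}{I_5 + \beta I_3}, \qquad
\alpha = 0.19,\; \beta = 1 - \alpha = 0.81,$$

where $\alpha$ is the fraction of donor emission leaking into the
acceptor channel. $E_{PR}$ is deliberately *not* corrected for quantum
yields or the instrument (gamma) factor, so it is a relative, not an
absolute, FRET efficiency; all comparisons in this package are between
conditions measured with the same statistic. For non-negative channel
intensities $E_{PR}$ is confined to $[-\alpha/\beta, 1] \approx
[-0.2346, 1]$ and is invariant under common rescaling of both channels
(`computeEpr`, `eprRange`).

Distributions of $E_{PR}$ over thousands of particles ("profiles")
resolve conformational subpopulations: intact nucleosomes with adjacent
gyres (center near 0.8), open or histone-free particles (near 0.03),
and — in the presence of PARP2 and Zn²⁺ — a reorganized state with
increased inter-gyre distance (near 0.4 for boundary-region labels, 0.5
for the distal pair).

# The synthetic measurement model

`simulateBursts` emits data at the granularity the analysis consumes:
per-burst channel intensities, not photon streams. For each burst

1. a species is drawn according to its mixing fraction;
2. a true proximity ratio $e$ is drawn from
   $\mathcal N(e_\text{center}, e_\text{width}^2)$ truncated to the
   attainable range (resampling until valid);
3. total signal photons $N \sim \text{Exponential}(\text{brightness})$,
   the standard heavy-tailed phenomenology of diffusing-particle bursts;
4. donor and acceptor emissions are $D = N(1-e)$, $A = Ne$; channel
   expectations are $I_3 = D + b_3$ and $I_5 = A + \alpha D + b_5$.
   On the attainable range $A + \alpha D = N(\alpha + \beta e) \ge 0$,
   so expectations are always physical;
5. with noise on, observed counts are Poisson around these expectations
   and burst durations are lognormal around the species mean with
   cv 0.3 (transit times are peaked, not memoryless — this matters for
   aggregate filtering, below); with noise off the expectations and the
   mean duration are returned exactly.

With noise off and zero background the algebra collapses:
$(I_5 - \alpha I_3)/(I_5 + \beta I_3) = A/(A+D) = e$, so the pipeline
must return every drawn $e$ to machine precision — the package's
strongest round-trip invariant, tested at $10^{-9}$.

The species are parameterised directly by proximity-ratio centers (an
identity mapping between $e$ and the underlying FRET fraction, no gamma
factor anywhere), matching the uncorrected statistic. Aggregates — the
slowly diffusing, very bright contaminants that PARP2 promotes at high
concentration — are a species with brightness and duration multiplied
by 10 (configurable). True species labels and true $e$ ride along in
the output table purely as test oracles.

What the generator does **not** emulate: photon-by-photon trajectories,
triplet blinking, diffusion through a 3-D Gaussian volume, gel
mobility. Passing tests therefore demonstrate correctness of the
*analysis* under a faithful statistical abstraction of the measurement,
not instrument-level realism.

Default study conditions (`npScenario`, `znScenario`): 3000 bursts per
experiment, 3 replicates — the reported scale of one measurement series
— with intact/open weights 0.7/0.3 in the baseline and
open/reorganized/intact = 0.25/0.45/0.30 under Zn²⁺, 100 photons per
burst mean brightness, 5% aggregate contamination.

# Aggregate rejection

`rejectAggregates` applies two independent upper cuts — on total
intensity $I_3 + I_5$ and on duration — plus a lower total-intensity
floor (default 20 counts) below which a proximity ratio is mostly shot
noise. The upper cuts are percentile-based by default so they adapt to
brightness units; absolute cuts are available and make the filter
idempotent.

The default percentile is the 95th. The choice is forced by arithmetic:
a cut at the $p$-th percentile of the observed mixture removes exactly
$(100-p)\%$ of bursts, so with a contaminant population of a few
percent a 99th-percentile cut cannot remove it; 95th-percentile cuts
bracket the ~5% contamination regime this pipeline targets. At the
default study conditions the measured operating point is 100%
aggregate sensitivity with ~2.5% false rejection of bright normal
bursts; the dim-burst floor is a separate, intended cut and is not
counted as false rejection.

# Profiles and replicate averaging

`buildProfile` bins $E_{PR}$ on a fixed uniform grid, default width
0.05 on $[-0.25, 1.05]$ (26 bins), wide enough to separate the closest
reported subpopulations (0.03 vs 0.4) by seven bins. Values outside the
grid are clipped into the terminal bins rather than dropped, keeping
the normalisation to 1 exact, and the clip counts are reported.
`aggregateReplicates` averages profiles over independent experiments
and attaches the per-bin SEM over replicates, mirroring the mean ± SEM
presentation of replicated profile figures.

# Subpopulation decomposition

`fitMixture` fits 1-D Gaussian mixtures to the raw per-particle
$E_{PR}$ values (the binned profile is a presentation device; the
particles carry the information). For each candidate component count
$k \in \{1..3\}$ by default it runs EM from 10 starts (one quantile
start, nine random), with a width floor of 0.01 against spike
components; every restart's final log-likelihood is recorded and must
dominate its starting value (a tested invariant). Components lighter
than 0.02 are pruned and the model refit, and no two centers in an
accepted model may sit closer than 0.05 (the identifiability gap) —
violating models fall back to the next smaller $k$.

Model selection uses ICL — BIC plus twice the classification entropy —
rather than plain BIC. The reason is a property of the measurement
itself: per-burst shot noise scales as $\sqrt{e(1-e)/N}$ with
exponentially distributed $N$, so each physical state is a *variance
mixture* with heavier-than-Gaussian tails. Plain BIC, which rewards any
density improvement, reproducibly splits the intact 0.8 state into two
strongly overlapping Gaussians; ICL charges that split for its
unassignable particles and keeps one component per resolvable state,
while still selecting three well-separated components in the Zn²⁺
condition. BIC selection remains available (`criterion = "bic"`), and
both scores are reported in the fit's selection table. One caveat
inherited from fitting mixtures to overlapping states: reported centers
are component means, which for overlapping Gaussians differ slightly
from the modes ("maxima") a profile plot would show.

`subpopulationFractions` maps components to named states via half-open
$E_{PR}$ windows (defaults: open $[-0.25, 0.2)$, reorganized
$[0.2, 0.6)$, intact $[0.6, 1.06)$, bracketing the reported centers)
and sums weights; `compareConditions` matches components across
conditions by nearest centers within 0.1 and reports shifts, appeared
and disappeared peaks.

# Binding fits

Fluorescence titrations follow the one-site isotherm
$$I_{fl}(C) = \frac{I_m C}{K_d + C} + I_{fl0},$$
fitted by Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`) with data-driven starting values and wide
parameter bounds; hitting a bound flags the fit non-identifiable
instead of returning a silent boundary estimate. Intensities measured
under stepwise dilution must pass through `correctDilution` first —
the correction divides by the recorded dilution factor exactly once
and a second application is an error. Unweighted least squares is the
default; a SEM-weighted replicate-mean mode is available. Ion
concentrations are totals as added: residual chelators (EDTA/TCEP)
compete for free ions in real buffers, so fitted $K_d$ values are
apparent constants and upper bounds on the free-ion affinity; modelling
chelation would require stability constants this package does not
assume.

Gel-shift binding series (fraction of free nucleosomes vs protein
concentration) are interpolated with a Hill form
$f(C) = 1/(1 + (C/c_{50})^h)$, $h$ bounded to $[0.5, 4]$ — a minimal
monotone family used only to read off the 50% point, not a mechanistic
binding model. The bootstrap CI on $c_{50}$ resamples data rows and
uses expanded percentile end points (percentile levels widened by the
$t$-to-normal quantile ratio at the observed $n$): on the short tables
typical of such series (15 rows) the plain percentile interval
undercovers (~88% measured at nominal 95%), while the expanded interval
restores ~90–91% coverage of the half-saturation truth in repeated
simulation; at large $n$ the two coincide. Series that never cross 0.5
yield an extrapolation warning and a flagged estimate.

Units are part of the interface: titration tables are labelled µM and
binding series nM by the generators, and the fitters refuse a
mislabelled table rather than guessing a conversion.

# Stoichiometry from in-gel intensities

`simulateGelIntensities` models a complex's acceptor intensity as the
sum of $k$ independent lognormal nucleosome units (mean 100 counts,
cv 0.3 by default; an optional dropout fraction, default 0, allows
sensitivity checks for partial labelling, which is otherwise not
modelled). `compareBands` judges two bands by the ratio of median
intensities with a bootstrap CI and a two-sample Kolmogorov–Smirnov
test, then issues a categorical call: same unit count (CI within
[0.75, 1.33]), doubled (CI within [1.6, 2.5]), otherwise indeterminate.
Medians and ratio windows make the call invariant to common rescaling —
absolute intensity calibration is explicitly out of scope. At the
default conditions ($n = 5000$ per band) 1-vs-2-nucleosome
discrimination succeeds in >95% of seeded repetitions, and
same-generator pairs stay within the nominal test size.

# Numerical choices and degenerate inputs

* Truncated-normal draws resample until valid; with width 0 the center
  is returned exactly.
* `computeEpr` refuses $I_3 = I_5 = 0$ and negative intensities.
* All-equal mixture input returns a single floor-width component;
  fewer than 200 values is an error.
* Flat titrations ($I_m \approx 0$) raise a non-identifiability error.
* EM convergence: relative log-likelihood change below $10^{-8}$,
  cap 1000 iterations; density underflow guarded at the smallest
  positive double.
* All generators take explicit seeds and restore the caller's RNG
  state; identical configuration plus seed reproduces identical tables
  byte for byte.

# Problem sizes

The shipped tests and the reproduction script use the study-scale
conditions: 3 replicates × 3000 bursts for profile/mixture work
(≈10⁴ bursts for filter characterisation), 100-repetition Monte-Carlo
ensembles for the titration recoveries, 100 seeded repetitions at
$n = 5000$ per band for stoichiometry power, and $10^5$ random channel
pairs for the range-law property.

# Known limitations

* No gamma correction: centers are comparable across conditions on the
  same instrument model, not across instruments.
* The mixture model is a phenomenological decomposition; it does not
  model shot-noise width explicitly (no photon-statistics likelihood)
  nor dynamic interconversion within a burst.
* Apparent $K_d$ only (chelator competition unmodelled).
* The burst-search step that turns photon streams into burst tables is
  upstream of this package; its selection thresholds are instrument
  settings, not package parameters.
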