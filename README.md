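# nucleoFRET

Single-particle FRET analysis of nucleosome conformational states.

PARP2, a DNA-damage sensor, binds nucleosomes and — in the presence of
Zn²⁺ ions — reorganizes their structure, increasing the distance between
the two superhelical turns (gyres) of nucleosomal DNA. `nucleoFRET`
implements the quantitative pipeline behind that kind of study, for
anyone analysing single-particle FRET (spFRET) measurements of
Cy3/Cy5-labelled nucleosomes diffusing in solution:

* **Proximity ratios.** Each detected particle yields donor- and
  acceptor-channel intensities `I3`, `I5`. The crosstalk-corrected
  proximity ratio is

  ```
  E_PR = (I5 − 0.19·I3) / (I5 + 0.81·I3)
  ```

  a FRET-efficiency proxy (uncorrected for quantum yields and the
  detection factor) bounded in [−0.19/0.81, 1]. The 0.19/0.81
  coefficients correct Cy3 bleed-through into the Cy5 channel and are
  configurable.
* **Aggregate rejection.** Nucleosome–protein aggregates are recognised
  by slow diffusion and/or abnormally high intensity; upper percentile
  cuts on burst duration and total intensity remove them, and a
  minimum-intensity floor drops bursts too dim to carry information.
* **E_PR profiles and subpopulations.** Relative-frequency histograms
  (2000–5000 particles per experiment, mean ± SEM over replicates) are
  decomposed into Gaussian subpopulations by maximum-likelihood EM with
  ICL model selection: intact nucleosomes (E_PR ≈ 0.8), open/histone-free
  particles (≈ 0.03) and the Zn²⁺-induced reorganized state (≈ 0.4–0.5).
* **Binding isotherms.** Fluorescence titrations are fitted with the
  one-site equation `I_fl(C) = I_m·C/(K_d + C) + I_fl0` (with stepwise
  dilution correction) to estimate dissociation constants; gel-shift
  binding series are interpolated with a Hill form to read off the
  concentration at which half of the nucleosomes remain free.
* **Stoichiometry from gels.** Per-complex Cy5 intensity distributions
  of different gel bands are compared (median-ratio bootstrap CI plus a
  Kolmogorov–Smirnov test) to decide whether bands differ in nucleosome
  count.
* **Synthetic data.** A generator emulates all four measurement types
  with known ground truth (species labels, true proximity ratios,
  pre-noise intensities), so every stage of the pipeline is testable
  without instrument data.

## Worked example

Simulate a baseline nucleosome experiment and a PARP2 + Zn²⁺ condition,
run the pipeline on both, and compare:

```r
library(nucleoFRET)

base <- processBursts(simulateBursts(npScenario(seed = 1)), seed = 1)
zn   <- processBursts(simulateBursts(znScenario(seed = 2)), seed = 2)

base$fit
#> MixtureFit: 2 component(s), n = 2308, logLik = 981.98, BIC = -1925.24
#>  weight center   width
#>  0.2968 0.0291 0.07925
#>  0.7032 0.8013 0.08913
```

The baseline decomposes into the two expected subpopulations: ~70 % of
particles intact (center 0.80) and ~30 % open/histone-free (center 0.03).
Under Zn²⁺ a third, reorganized state appears:

```r
zn$fit
#> MixtureFit: 3 component(s), n = 2315, logLik = -7.49, BIC = 76.96
#>  weight  center  width
#>  0.2485 0.02609 0.0762
#>  0.4543 0.39597 0.1035
#>  0.2972 0.80716 0.0812

subpopulationFractions(zn$fit)
#>        open reorganized      intact       other
#>   0.2484742   0.4543404   0.2971854   0.0000000

compareConditions(base$fit, zn$fit)$appeared
#>      weight    center     width
#> 2 0.4543404 0.3959665 0.1035266
```

`compareConditions` flags the 0.40 component as an appeared peak — the
signature of Zn²⁺-dependent reorganization of the PARP2–nucleosome
complex.

Binding analysis uses the same generator-plus-fit pattern. A simulated
Zn²⁺ titration of the WGR domain (true Kd 2.0 µM, 3 % noise) and a
nucleosome binding series (true half-saturation 40 nM, 10 % noise):

```r
tt <- simulateTitration(kd = 2.0, im = 100, ifl0 = 10, zincLadder(),
                        cvNoise = 0.03, seed = 3)
fitOneSite(tt)
#> OneSiteFit: Kd = 2 +/- 0.18, Im = 100.6, Ifl0 = 9.638

bs <- simulateBindingSeries(40, 1, c(12.5, 25, 50, 100, 200),
                            cvNoise = 0.10, seed = 4, replicates = 3)
estimateHalfSaturation(bs, seed = 4)
#> HalfSaturationFit: c50 = 41.75 [37.02, 46.49], hill = 0.966
```

## Command line

A thin wrapper script `inst/scripts/nucleofret` exposes the pipeline as
subcommands (`simulate`, `process`, `fit-mixture`, `fit-kd`, `fit-c50`,
`compare-bands`) operating on CSV/YAML/JSON files; see the header of the
script for the exact flags.

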