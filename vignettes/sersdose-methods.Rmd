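---
title: "Methods: simulation, calibration and validation in sersdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, calibration and validation in sersdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersdose)
```

`sersdose` quantifies a drug (meropenem) in serum from SERS chip scans.
This vignette records the package's modelling assumptions, the tunable
parameters that matter, and the design decisions taken where more than one
defensible choice existed.

## The synthetic-data model

A SERS map is a grid of pixel spectra from one chip. The generator's
intensity model for a pixel with enhancement factor $g$ at concentration
$c$ (µM) is

$$ I(\nu) = B(\nu) + g\left[c \sum_k r_k L_k(\nu) + s_{\text{cleanup}}
\sum_j a_j L_j(\nu)\right] + \varepsilon(\nu), $$

where $L(\nu)$ are peak-normalised line profiles, $r_k$ are analyte
responses (intensity · µM⁻¹), $a_j$ fixed interferent amplitudes,
$B(\nu)$ a low-order polynomial substrate baseline, and
$\varepsilon \sim N(0, \sigma^2)$ additive, homoscedastic channel noise.

Choices, and why:

* **Line shape.** Lorentzian by default — the usual Raman line shape;
  Gaussian is selectable per band.
* **Band set.** Meropenem bands at 1559 (dominant), 1387, 1052, 890, 771,
  709, 670 cm⁻¹; relative responses (1.00 down to 0.18) were fixed once so
  the 1559 cm⁻¹ band dominates every spectrum, which is what makes it the
  quantification band. Interferents sit at 640 (uric acid, largest), 1003
  and 1450 cm⁻¹.
* **Concentration response.** Linear through the origin. Adsorption
  saturation (Langmuir-type flattening at high concentration) is
  deliberately omitted: the generator defines a clean linear truth so that
  calibration bias is attributable to the pipeline, not the simulation.
* **Cleanup methods.** Protein precipitation (PP), ultrafiltration (3 and
  10 kDa) and mono-spin solid-phase extraction (ms-SPE) differ only in
  their spectral consequences: interferent scale 1.00 / 0.80 / 0.50 / 0.12
  and noise scale 2.0 / 1.6 / 1.3 / 1.0 respectively. This reproduces the
  qualitative ordering (ms-SPE cleanest, highest SNR; PP worst) without
  modelling any surface chemistry.
* **Pixel heterogeneity.** Per-pixel multiplicative enhancement
  $g \sim \text{lognormal}$ with unit mean and log-SD 0.25 — hotspot
  strength varies across a chip but has no spatial correlation. Heat-map
  texture, not plasmonics.
* **Noise.** $\sigma = 5$ intensity units by default against a dominant
  band response of 1 unit·µM⁻¹ — roughly 5 µM of single-channel noise,
  a realistic scale for a compact Raman system after cleanup.
* **Axis.** 696 channels over 600–1800 cm⁻¹, matching the working data
  shape of the assay (30-row × 696-channel calibration matrices).
* **Paired cohorts.** True concentrations uniform over the 20–450 µM
  therapeutic window; defaults (reference error SD 5 µM, test error SD
  30.4 µM, test bias −14.55 µM) make the paired differences match the
  assay's reported agreement conditions (difference SD ≈ 30.8 µM).

What the generator does **not** emulate: wavenumber miscalibration between
instruments, cosmic-ray spikes, heteroscedastic or correlated noise,
adsorption competition between analyte and matrix, and drift within a
scan. Tests passing on synthetic data therefore demonstrate correctness of
the *computations*, not robustness to every artefact of real spectra.

## Preprocessing

* **Background correction** is asymmetric least squares (AsLS): a
  Whittaker smoother with second-difference penalty $\lambda$ (default
  10⁵) and asymmetry $p = 0.01$, iterated to convergence (cap 20). The
  solver is a banded Cholesky in C++ (O(n) per iteration), which keeps
  per-pixel correction cheap enough to run inside resampling loops.
  $\lambda$ trades baseline tracking against peak erosion: ~10³ follows a
  peak-free quadratic to <1% of range, ~10⁵–10⁶ preserves peak heights to
  within 5% over a sloping background.
* **Map reduction** ranks pixels by their maximum *baseline-corrected*
  intensity in a ±10 cm⁻¹ window around 1559 cm⁻¹ and averages the top
  ⌈0.2 · n⌉ pixels channelwise (minimum one pixel). Ranking on corrected
  heights rather than raw intensities prevents bright baselines from
  masquerading as hotspots; "~1559" is operationalised as the window
  maximum, making the statistic robust to a few cm⁻¹ of band-position
  jitter. Ties in the ranking are broken by pixel order, which only
  matters in the exactly-degenerate noise-free case.
* **Scaling.** Six dataset-level methods are provided; min-max (each
  training column to [0, 1]) is the default used by the PLSR stage, as the
  best performer for this assay. Column statistics are always frozen on
  the training set and applied unchanged to prediction rows. Policy
  decisions: a constant column under min-max maps to 0; autoscale raises
  an error on a constant column rather than silently patching a zero SD;
  `log` uses log(1+x) after clipping negatives (AsLS-corrected spectra are
  near zero off-peak, so an offset-free log would be undefined);
  derivatives are Savitzky–Golay, order 2, 9-channel window.
* **Crop default** 600–1800 cm⁻¹ covers every configured band.

## Calibration

PLSR is single-response NIPALS on the scaled, mean-centered matrix. At
full component count on a full-rank problem it coincides with ordinary
least squares, which the tests use as an oracle.

* **Cross-validation** is venetian blinds with 5 splits. Each row of a
  calibration set is the reduced spectrum of one physical replicate map,
  so rows are the natural leakage unit; fold $r$ holds replicate $r$ of
  every level, so every training fold still spans the full concentration
  range. Without replicate structure, rows are interleaved along
  increasing concentration. Scaling is refit inside each training fold.
* **LV selection** uses the one-standard-error parsimony rule: the
  smallest count whose RMSECV is within one SE (over folds) of the global
  minimum. This mirrors the usual practice of reading the RMSECV curve
  conservatively rather than chasing its minimum.
* **Figures of merit** use the pseudounivariate convention. Blank (0 µM)
  replicate spectra are pushed through the full prediction pipeline; the
  SD of the resulting pseudo-concentrations is the inverse analytical
  sensitivity γ⁻¹, so LoD = 3.3 γ⁻¹ and LoQ = 10 γ⁻¹, with SEN = 1/‖b‖
  and the equivalent instrumental noise σₓ = γ⁻¹ · SEN. Projecting blanks
  through the model was preferred over channelwise noise pooling because
  it measures exactly the noise the model transmits to a concentration.
  The leverage-corrected, sample-specific LoD variant is out of scope.
  By construction RMSEP² = bias² + SEP²·(n−1)/n.
* **PCA** is mean-centered; the suggested component count is the elbow of
  the cross-validated reconstruction RMSE curve, located as the point with
  maximum perpendicular distance below the chord joining the curve's
  endpoints — a deterministic rule that needs no tuning threshold.

## Validation

* **Fold plans** partition n samples into k held-out groups of size 2 or
  3 (27 samples, 12 groups ⇒ nine pairs, three triples — forced by
  arithmetic). Group memberships are drawn uniformly at random given the
  size multiset, since the original grouping is not specified.
* **Leave-group-out** re-selects the LV count inside every fold, and the
  **permutation test** re-runs the entire pipeline (scaling, LV selection,
  CV) on every shuffled response — both choices prevent information
  leaking from the full dataset into the resampling. The permutation
  statistic defaults to cross-validated R² with B = 999 (B = 199 in the
  bundled pipeline driver, enough to resolve p at the 0.005 level);
  p = (1 + #{null ≥ observed})/(B + 1), so p is never smaller than
  1/(B+1) and is super-uniform under the null.

## Agreement

Bland–Altman differences use the test − reference sign convention. The
minimal detectable change is defined as MDC = 1.96 · SD(differences), i.e.
the half-width of the 95% limits of agreement — the unique definition
consistent with the reported agreement interval; the alternative
1.96·√2·SEM does not reproduce it and was rejected. The multiplier is
fixed at z = 1.96 rather than a small-sample t quantile for the same
reason. Unit conversion uses 383.46 g/mol (meropenem free acid). The
scatter regression's band is the pointwise 95% confidence band for the
mean response, not a prediction band.

## Numerical and degenerate-input policies

* Negative model predictions are reported as-is with a flag — truncation
  would bias agreement statistics.
* Constant response vectors, single calibration levels, zero blank noise,
  empty crop windows and infeasible fold plans raise errors instead of
  returning NaN.
* All generators accept an integer seed and restore the caller's RNG
  state; the pipeline driver fans one global seed out to stages by fixed
  offsets so each stage is independently reproducible.

## Problem sizes in the test-suite and acceptance runs

The default design (6 levels × 5 replicates, 696 channels) is used
wherever the data shape itself is under test. Simulation-heavy checks use
25 pixels per map and, for resampling-intensive properties (permutation
level, reduction oracles), a 150-channel axis — sizes chosen so the full
property suites (50-seed recovery, 100 × B = 199 permutations, 100-seed
sorting oracles) complete in minutes while leaving every statistical
property intact.

## Known limitations

* The pseudounivariate LoD/LoQ ignore sample leverage; values are
  model-level, not sample-specific.
* The linear, homoscedastic generator cannot probe saturation-induced
  calibration curvature or variance heterogeneity.
* Venetian-blinds CV assumes exchangeable replicates; drift between
  replicate maps would require contiguous-block CV instead.
* Quantities computed on synthetic data characterise the pipeline under
  the stated simulation conditions only; they are not estimates of any
  physical instrument's figures of merit.
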