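---
title: "Methods: FTIR chemometrics for skin electrical-mark detection"
author: "ftirmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FTIR chemometrics for skin electrical-mark detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirmark)
```

## The problem and the model

An electrical mark is the skin lesion at the contact point of an electrical
conductor. Histologically it shows elongated, polarised epidermal cells, but
that reading is subjective. The molecular signal exploited here is protein
secondary structure: the Amide I absorption band (1710–1585 cm⁻¹, dominated
by protein C=O stretching) decomposes into sub-bands whose positions track
conformation — α-helix near 1650 cm⁻¹, antiparallel β-sheet near
1695 cm⁻¹, β-sheet near 1619 cm⁻¹ and β-turn near 1681 cm⁻¹. Joule heating
denatures epidermal protein, lowering helix content and raising β-sheet
content, so the Amide I sub-band pattern separates electrical marks from
normal epidermis, and the dermis (collagen-rich, Amide I near 1660 cm⁻¹
with strong amide II/III bands) forms a third class.

The pipeline is: simulate (or read) absorbance spectra → EMSC → 9-point
Savitzky–Golay second derivative → Amide I window → PCA (exploration) and
dummy-coded PLS1 (classification) → per-pixel classification of
hyperspectral maps.

## The synthetic-data generator

No spectra were deposited with the original study, so the generator is a
first-class, tested module that emulates the study conditions rather than a
test fixture.

Each tissue class is a `ClassProfile`: a sum of Gaussian (optionally
Lorentzian) bands, each with a centre (cm⁻¹), FWHM (cm⁻¹) and mean
amplitude (absorbance). A drawn spectrum is

\[ z(\nu) = s \sum_j A_j g_j(\nu) + a + c_1\nu_* + c_2\nu_*^2 +
\varepsilon(\nu), \]

with amplitudes \(A_j\) jittered multiplicatively (CV 0.10), a log-normal
path-length scale \(s\) (`scaleLogSd` 0.15), an additive offset and a
linear + quadratic baseline in the rescaled wavenumber
\(\nu_* \in [-1, 1]\), and white noise (\(\sigma\) = 0.005 absorbance).
These spreads are the generator's definition of the study conditions: they
produce visible scatter distortion that EMSC must remove, and enough class
overlap that preprocessing is exercised, while the qualitative Amide I
contrasts of the published second-derivative spectra (helix-dominated
epidermis, β-sheet-elevated mark, collagen-like dermis) remain
reproducible. The published work gives no quantitative amplitudes or
variances, so the defaults encode only those qualitative contrasts and are
fixed once here, not tuned per analysis. The baseline is drawn on the same
\(\nu_*\) basis that EMSC fits, which makes "EMSC removes the simulated
distortion" an exact property rather than an approximation.

The wavenumber grid is 900–4000 cm⁻¹ at 4 cm⁻¹ spacing — finer than the
16 cm⁻¹ instrument resolution, emulating standard zero-filled
interpolation — so the Amide I window holds 31 channels and a 9-point
filter spans 36 cm⁻¹, wide enough to smooth but narrow relative to band
widths. Band shape defaults to Gaussian; the Lorentzian option behaves
equivalently under the second derivative for every property tested.

The study design (`studyDesign()`) fixes the published split sizes: 35
electrical + 46 epidermal spectra for PCA; 35/34/27 electrical /
epidermis / dermis for PLS calibration; 48 internal-prediction spectra
(the published total; the per-class split is not stated, so it is divided
16/16/16); 17/20/14 for external validation. One integer seed drives every
draw, and a dataset is bit-reproducible from its design.

Hyperspectral maps follow the published scan geometry — 140 × 200 µm² at
10 µm step, i.e. a 14 × 20 grid of 280 spectra — with two built-in truth
layouts: `electrical_lesion` (background band, epidermis with a central
electrical region, dermis below) and `normal_skin`. Pixels are simulated
independently; a real 40 × 40 µm aperture stepped at 10 µm overlaps
neighbouring pixels and induces spatial correlation the generator does not
emulate. Passing map-classification tests therefore demonstrates the
per-pixel pipeline, not robustness to spatially correlated optics. Other
fidelity limits: no Mie scattering or water-vapour lines (instrumental
background subtraction is assumed), and within-class variation is
unimodal — real inter-individual variation is likely broader.

## Preprocessing

**EMSC.** Each spectrum is regressed on
\([1, m(\nu), \nu_*, \nu_*^2]\) (reference \(m\), default the calibration
set mean; baseline degree 2 by default, matching standard practice and the
scatter model) and corrected as \((z - a - d_1\nu_* - d_2\nu_*^2)/b\).
The fit is solved by QR least squares. A constant reference is a singular
design and an explicit error; a fitted \(b \le 0\) flags the spectrum and
leaves it uncorrected instead of silently dividing by a non-positive
scale. EMSC is idempotent against a fixed reference. Correction is applied
to the full 900–4000 cm⁻¹ range before windowing — the full-range fit is
better conditioned, and the original preprocessing order (normalise, then
derive) is preserved. Prediction and map spectra are always corrected
against the *stored calibration reference*, never their own mean, so no
information leaks from validation data into the correction.

**Second derivative.** The 9-point Savitzky–Golay second derivative uses
polynomial order 3 (the order is not stated alongside "9 points" in the
source workflow; orders 2 and 3 give identical second-derivative filter
coefficients, so the choice is presentational). Edge channels use the
polynomial fitted on the one-sided window. The derivative is computed per
channel index and scaled by \(1/\Delta\nu^2\), exact on the uniform grids
required (non-uniform grids are rejected). The filter is applied through
`signal::sgolayfilt`; tests verify it against an independent per-window
polynomial refit and exactness on polynomials up to the filter order. The
derivative output is not re-normalised.

**Windowing.** `extractWindow(set, 1710, 1585)` keeps the closed interval;
on the default grid that is the 31 channels 1588–1708 cm⁻¹.

## Band analysis

In second-derivative spectra, band centres appear as negative minima.
Every strict interior local minimum with a negative value becomes a peak;
its position is refined with a three-point parabola (the 4 cm⁻¹ grid is
coarse relative to the 2–3 cm⁻¹ band distinctions that matter, and the
nominal centres 1650 and 1619 cm⁻¹ do not even lie on the grid), and its
depth is the magnitude of the interpolated minimum. Assignment to the four
structures is greedy deepest-first with a ±8 cm⁻¹ tolerance (two grid
steps): observed minima and loadings drift 2–3 cm⁻¹ from nominal centres,
so exact matching would be wrong, while ±8 keeps the 1681/1695 pair
separable. Structure intensity maps offer both a raw-absorbance mode
(value at the channel nearest the nominal centre) and the default
second-derivative depth mode, since either convention is found in imaging
practice.

## Chemometrics

**PCA** is the SVD of the column-centred spectra-by-channels matrix;
explained variance per component is \(100\,\sigma_k^2/\sum\sigma^2\).
Loadings are sign-ambiguous, so a fixed convention is applied: each
loading's largest-magnitude element is made positive, then PC1 is
re-oriented so its loading at the channel nearest 1621 cm⁻¹ is positive.
With that convention, on second-derivative Amide I data the PC1 loading is
negative at 1650 cm⁻¹ and positive at 1621 cm⁻¹, and the two calibration
classes separate completely in PC1-score sign. Score plots carry
normal-theory confidence ellipses: semi-axes
\(\sqrt{\lambda_i \chi^2_2(0.95)}\) along the covariance eigenvectors.

**PLS1.** The response is a single dummy-coded axis (epidermis 1,
electrical 2, dermis 3) rather than a one-hot PLS2, because classification
thresholds a single predicted-Y axis (0–1.5 / 1.5–2.5 / > 2.5; the
electrical interval is closed, so Y = 1.5 and Y = 2.5 both classify as
electrical). NIPALS extracts factors \(w = X^\top y/\lVert X^\top
y\rVert\), \(t = Xw\), \(p = X^\top t/t^\top t\), \(q = y^\top t/t^\top
t\), deflating \(X\) and \(y\) each round; the regression vector is
\(W(P^\top W)^{-1}q\). X is mean-centred but not variance-scaled —
spectroscopic convention, and EMSC has already normalised scale. At full
rank the solution equals ordinary least squares (tested against a direct
solve).

**Factor selection.** The source workflow does not state its factor count,
so it is chosen by leave-one-out cross-validation: RMSECV is computed for
1–10 factors and the *first local minimum* taken (ties toward fewer
factors) — a standard guard against overfitting later, noise-driven
minima. LOOCV predictions are order-invariant. On the default simulated
study this selects 6 factors with RMSECV ≈ 0.065.

## Map classification

Pixels whose mean raw Amide I absorbance falls below a threshold are
labelled background *before* EMSC (fitting a multiplicative scale to a
near-zero spectrum is ill-posed). The threshold defaults to 10 % of the
map's median Amide I mean absorbance — a heuristic, documented as such,
since the original figures do not state their background rule. Remaining
pixels run the standard chain against the stored calibration reference and
are classified by thresholded PLS prediction. Classification is per-pixel
independent, and raising the background threshold only grows the
background region; no spatial smoothing is applied, matching the raw
per-pixel presentation of classified maps in this field. Rendering uses a
fixed bijective legend (yellow electrical, light blue epidermis, brown
dermis, dark blue background; nearest standard named colors to the
published description), so a rendered PNG decodes losslessly back to its
labels.

## Numerical and design notes

* EMSC solves one QR decomposition per set, shared across spectra;
  tolerance for the idempotence property is 1e−9.
* Parabolic peak refinement clamps the vertex offset to ±half a grid step;
  a degenerate (non-convex) three-point stencil falls back to the grid
  minimum.
* `accuracyTable` reports percent accuracy rounded to 0.1 %.
* PCA requires `nComponents ≤ min(n − 1, channels)`; eight components are
  the exploration default.
* All randomness flows from one seed (`StudyDesign@seed`, or the pipeline
  config seed); the generator restores the caller's RNG state.
* Problem sizes used in the test-suite properties: convergence of class
  means is checked at n = 200 draws; ellipse coverage at n = 5000 points;
  pipeline determinism on a reduced design (tens of spectra) and a 6 × 8
  map — sizes chosen so each property is sharp enough to fail on a real
  defect while the whole suite stays quick to run.

## Known limitations

* Simulated classes are far cleaner than patient spectra: the default
  study reaches 100 % external-validation accuracy and ~99 % PC1 variance,
  whereas real tissue shows 79–88 % accuracies and 69.8 % PC1 variance.
  The simulation bounds therefore validate the machinery, not clinical
  performance.
* No Fourier self-deconvolution, curve-fitted band deconvolution, PLS2 /
  OPLS-DA, outlier diagnostics beyond the score ellipse, or proprietary
  instrument formats. JCAMP-DX support covers the plain AFFN dialect only;
  compressed (SQZ/DIF) files are rejected explicitly.
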