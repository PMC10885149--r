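---
title: "plaquemap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plaquemap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(plaquemap)
```

`plaquemap` quantifies the lipid microenvironment of individual amyloid-β
plaques in MALDI mass spectrometry imaging data. This vignette explains the
models and procedures behind each stage, the parameters that matter and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical and design choices that were genuinely
open.

## Mass chemistry

Shorthand lipid names are parsed into molecular formulas through residue
construction rules on two backbones:

* **Sphingolipids** (d-sphingoid base): a ceramide of total composition
  `C:D` has formula `C(C) H(2C−2D+1) N O3`; then CerP = Cer + HPO₃,
  HexCer = Cer + C₆H₁₀O₅ (anhydrohexose), ST = HexCer + SO₃,
  PE-Cer = Cer + C₂H₆NO₃P, GM3 = Cer + 2 Hex + NeuAc (C₁₁H₁₇NO₈),
  GM2 = GM3 + HexNAc (C₈H₁₃NO₅), GM1 = GM2 + Hex, and `(2OH)` adds one O.
* **Glycerophospholipids**: diacyl PA(C:D) = `C(C+3) H(2C+5−2D) O8 P`;
  monoacyl (lyso) LPA(C:D) = `C(C+3) H(2C+7−2D) O7 P`; PE/LPE add C₂H₅N;
  PI/LPI add C₆H₁₀O₅; CPA (cyclic PA) = LPA − H₂O; the plasmalogen
  PE(P-a:b/c:d) is diacyl PE(a+c:b+d) − O (vinyl-ether bond).

Masses use standard monoisotopic element masses (C exactly 12). The
deprotonated adduct subtracts the *electron-corrected* proton mass,
1.00727646 Da: at ±2 ppm above m/z ~500, the electron mass (0.00055 Da) is
larger than the matching budget, so using the hydrogen atom mass would
silently consume most of the tolerance.

Two naming conventions in the built-in panel deserve note. Species listed
with a single chain under a diacyl class name (`PE(18:0)`, `PI(20:4)`) are
parsed as the lyso species (LPE/LPI), which is what their masses correspond
to; and the panel row printed as `LPA(18:0)` carries the mass of the cyclic
form, so it is stored canonically as `CPA(18:0)` with the original spelling
kept as an alias. One panel row (`PA(16:0/18:1)`) is internally
inconsistent — its printed theoretical mass corresponds to a 34:2 species
while its observed value matches the correct 34:1 mass — and is excluded
from library construction; a second row (`PI(20:4)`) has a corrupt printed
theoretical value but a consistent observed one, so it stays in the library
with its parser-computed mass. These flags are data, not code: see
`brain_lipid_panel(include_excluded = TRUE)`.

Peak matching is a sorted binary search over library m/z with exact ppm
verification; a brute-force all-pairs oracle in the test suite checks the
two agree exactly. Best-hit ties break by smaller absolute ppm error, then
lexicographic species name, so annotation is deterministic.

## imzML I/O

Continuous mode stores one shared m/z axis (64-bit float) and per-pixel
intensities (32-bit float, the common vendor-converter layout); processed
mode stores per-pixel axes. The ibd companion starts with the 16-byte UUID
also declared in the XML; the declared SHA-1 is verified on read, and
declared offsets are checked against the file length so truncation is
caught even when checksum validation is off. Coordinates are 1-based in
imzML and 0-based internally, with the offset recorded so files round-trip
exactly. Missing grid positions are represented as absent pixels, never
zero-filled. The writer derives the UUID deterministically from the payload,
which makes seeded runs produce bit-identical file pairs. An independent
Python imzML reader is used in the test suite to confirm interoperability.

## Preprocessing

**TIC normalization** scales each pixel's spectrum so its total ion current
equals the dataset's mean raw TIC (rather than 1), preserving the intensity
scale for plots. Profile TICs use trapezoid quadrature; on a *windowed*
axis (see the generator below) segments wider than 10× the native spacing
are excluded from the quadrature, because such gaps carry no sampled signal
and would otherwise dominate the integral with interpolated noise. Zero-TIC
pixels are dropped with a logged reason code.

**Peak detection** runs on the whole-dataset mean spectrum by default so
that one global bin set defines a single feature space for pixel-level
clustering (a per-ROI mode is available). Local maxima are kept when their
topographic prominence exceeds `snr_threshold` (default 5) times a robust
noise level, 1.4826 × MAD of the first difference / √2. Peak width is the
FWHM by linear interpolation at half the apex height above the local base;
integration borders sit at the nearest flanking minima, clipped to
center ± 3 FWHM, and overlapping borders are truncated at the midpoint
between adjacent centers so bins partition the axis — this is what makes
AUC integration exactly additive over adjacent bins. `min_fwhm_points`
(default 3) discards single-sample spikes.

**AUC integration** integrates the piecewise-linear interpolant of each
profile spectrum over `[left, right]`, including fractional edge segments;
centroid spectra sum sticks in the bin. Each bin is a weight vector, so the
feature matrix is one matrix product per dataset.

## Segmentation and ROIs

Bisecting k-means starts from one cluster and repeatedly splits the cluster
with the largest within-cluster sum of squares using 2-means (best of
`n_restarts = 10` seeded initializations), until `k` leaves. `k` defaults
to 8: small enough that a distinct plaque population survives as its own
cluster(s) on synthetic data, large enough to absorb background
heterogeneity. Features are z-scored per bin before clustering so abundant
background lipids do not dominate the Euclidean metric (`scaling = "none"`
is available). Total within-SS is non-increasing in `k` by construction.

Plaque clusters are selected either by the **marker** rule — clusters whose
mean intensity in designated marker bins (by default the annotated
GM/CerP/PE-Cer bins) exceeds 1.2× the grand mean; spatially featureless
data select nothing — or by the **punctate** rule, which accepts clusters
whose 8-connected components have a median area within plaque-scale bounds.
Individual plaques are the 8-connected components of the selected clusters,
filtered to `[min_area, max_area] = [5, 200]` px and id-ordered by centroid.
Controls are per-plaque annuli at Euclidean distance 2–6 px (20–60 µm at
10 µm pixels) — the local microenvironment rather than distant tissue —
with overlap resolved to the nearer plaque and an area-matched random
tissue patch (logged) when a plaque sits at the tissue edge. Connected
components and annulus distances are computed in-package because the
required 8-connectivity semantics differ from what the available image
libraries provide.

## Statistics

Per plaque and species, enrichment is the ratio of the plaque-pixel mean to
that plaque's control-pixel mean on TIC-normalized AUCs; an alternative
reference normalizes to the subject grand mean instead (`reference =
"grand_mean"`), since either convention is found in practice. Ratios with a
zero control mean are dropped and logged.

Group-level inference takes the subject-level mean log2 ratio per species
and applies a two-sided one-sample test against zero. The default is the
*exact* Wilcoxon signed-rank test: with typically n = 5 subjects, normality
is unverifiable and the exact null is enumerable (the smallest attainable
two-sided level at n = 5 is 1/16 = 0.0625, attained when all subjects agree
in sign). Student's t is available. Raw p-values are primary;
Benjamini–Hochberg adjusted values are reported alongside but not used for
gating.

SPSC is the Pearson correlation of two species' AUC vectors over the union
of plaque-ROI pixels (default) or over per-ROI means. Constant vectors have
undefined correlation; those entries are set to 0 and flagged. Ion-image
rendering clips the display range at the 99th intensity quantile — a
display convention only, never applied to statistics.

## The synthetic generator

The generator emulates negative-ion-mode MSI of plaque-bearing brain tissue
at 10 µm pixels: non-overlapping circular plaques (radius 3–6 px, i.e.
30–60 µm) on a 128×128 grid; a species panel in which GM species are
enriched 3-fold, CerP/PE-Cer 2.5-fold, HexCer and the phospholipid classes
2-fold, sulfatides depleted to 0.5, plus 10 decoy background peaks at fold
1; per-pixel log-normal gain (σ = 0.3) to exercise TIC normalization;
Gamma-perturbed peak areas with shape SNR² (SNR = 10, the counting-noise
analogue that keeps profile sampling independent of the noise); and peaks
laid down as Gaussians of FWHM = m/z / 120000. Per-plaque strength
multipliers (log-normal, σ = 0.4) emulate plaque-to-plaque heterogeneity;
real single-plaque bar plots span roughly 1–6× for the same species, and
without this heterogeneity plaque-masked correlation analysis would have no
signal to find. A Gaussian rim blur (σ = 1 px) is available to emulate
diffuse halos but is off by default so that the planted fold is exactly the
in-mask expectation.

The profile axis is sampled only in windows of ±4 FWHM around panel peaks,
at a uniform spacing of FWHM/6 evaluated at the panel's median m/z: a full
axis at that spacing would need ~10⁶ points per pixel, and the windows
contain all signal. Consequences of the windowed axis (gap handling in TIC
quadrature) are described above.

What the generator does **not** emulate: isotope envelopes, matrix cluster
peaks, mass-calibration drift, chemical background ridges, tissue-type
mosaics, or registration error against a second modality. Tests passing on
synthetic data therefore demonstrate the pipeline's correctness and its
statistical behaviour under the stated noise model — not robustness to
every artefact of real acquisitions.

Two systematic effects are worth understanding when interpreting recovery
numbers. First, TIC normalization is *compositional*: if most panel species
are enriched in plaques, the plaque TIC rises and every measured ratio is
shrunk by the TIC fold (~×0.6 in log2 under the default panel). This is a
property of TIC normalization itself, not a bug; fold-recovery experiments
therefore plant a few changed species against a large unchanged background
(TIC fold ≈ 1.04), mirroring the real situation where most of the lipidome
is unchanged. Second, per-plaque heterogeneity makes single-ROI ratios
scatter; recovery uses the per-ROI *median*, whose expectation is the
planted fold because the strength multiplier has median 1.

## Problem sizes used in validation

Segmentation and SPSC recovery run the full default conditions (128×128,
20 plaques) over 10 seeds. Fold recovery plants log2 folds
{−1, 0, 1, 1.585} over 10 seeds at the default grid, quantified on
ground-truth masks so the quantification property is isolated from
segmentation (which is validated separately). The type-I error study runs
200 five-subject studies on 24×24 grids with an all-null panel — small
grids chosen as the smallest at which the enrichment sampling distribution
is well behaved. Unit fixtures use 12–64 px grids.

## Known limitations

* Only the [M−H]⁻ adduct is implemented; positive-mode adducts, isotope
  scoring and MS/MS identification are out of scope, and isomers are not
  resolved.
* Bisecting k-means with random restarts is deterministic given a seed, but
  pixel-order invariance is only guaranteed when cluster structure is
  well separated; the restarts make violations rare, not impossible.
* The marker selection rule needs at least one annotated enriched bin; on
  panels with no annotations it falls back to all bins, which weakens it.
* Processed-mode (per-pixel axis) data are resampled to the median native
  spacing for mean spectra; pathological axes with wildly varying spacing
  will lose resolution.
* No baseline subtraction, recalibration or deisotoping is performed.
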