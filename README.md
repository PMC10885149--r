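# plaquemap

Spatial lipidomics of amyloid-β (Aβ) plaques from MALDI mass spectrometry
imaging (MSI).

Aβ plaques — the focal extracellular amyloid deposits of Alzheimer's disease —
sit in a lipid microenvironment that differs from the surrounding tissue:
gangliosides (GM1/GM2/GM3), ceramide-1-phosphates (CerP), ceramide
phosphoethanolamines (PE-Cer) and hexosylceramides accumulate in and around
plaques, while sulfatides (ST) are depleted. Negative-ion-mode MALDI-MSI at
~10 µm pixel size resolves these changes at the level of *individual*
plaques, each only a few tens of micrometres across. `plaquemap` is an open,
tested pipeline for exactly this analysis, aimed at MSI practitioners who
want a scriptable, reproducible alternative to point-and-click vendor tools:

- **imzML 1.1 I/O** — continuous and processed binary mode, profile and
  centroid spectra, ibd UUID and SHA-1 verification.
- **Preprocessing** — total-ion-current (TIC) normalization; peak and
  peak-width (FWHM) detection on mean spectra; per-pixel area-under-curve
  integration of peak bins into a pixels × bins feature matrix.
- **Segmentation** — bisecting k-means spatial segmentation (repeatedly
  2-means-splitting the cluster with the largest within-cluster sum of
  squares), plaque-cluster selection, individual plaque ROIs as 8-connected
  components, and per-plaque annulus control ROIs.
- **Statistics** — per-plaque enrichment ratios (plaque mean / matched
  control mean), exact Wilcoxon signed-rank group tests across subjects with
  Benjamini–Hochberg adjustment, and single-pixel signal correlation (SPSC):
  the Pearson correlation of two species' intensities over plaque pixels.
- **Lipid annotation** — a shorthand-nomenclature parser
  (`"ST(d18:1/24:0(2OH))"`, `"PE(P-18:0/22:6)"`, `"GM1(d18:1/18:0)"`, …)
  that builds molecular formulas from class construction rules, computes
  monoisotopic masses and [M−H]⁻ m/z, and matches observed peaks at ±2 ppm.
- **Synthetic data** — a generator that plants circular plaques with known
  fold changes, per-pixel gain and counting-like noise, so every stage can
  be validated against ground truth.

## The core quantities

For a species with molecular formula built from its shorthand name (e.g.
sulfatide ST = ceramide + hexose + SO₃), the neutral monoisotopic mass is
the sum of monoisotopic element masses, and the deprotonated ion is

    m/z([M−H]⁻) = M − 1.00727646 Da

matched against observed peaks at a signed error of
`1e6 × (observed − theoretical) / theoretical` ppm. Per plaque ROI *p* and
species *s*, enrichment is

    ratio(p, s) = mean AUC over plaque pixels / mean AUC over annulus control pixels

on TIC-normalized intensities, and SPSC is `cor(AUC_s, AUC_t)` over the
union of plaque pixels.

## Worked example

```r
library(plaquemap)

# --- mass chemistry and annotation ---------------------------------------
sp <- parse_lipid_name("ST(d18:1/24:0)")
sp
#> <lipid_species> ST(d18:1/24:0)  class ST  C48H93NO11S  891.6469 Da
adduct_mz(sp$neutral_mass)
#> [1] 890.6397

lib <- build_mass_library(brain_lipid_panel())
best_hits(c(890.6398, 1572.8992, 500.0), lib, tol_ppm = 2)
#>   observed_mz            name adduct theoretical_mz  ppm_error
#> 1    890.6398  ST(d18:1/24:0) [M-H]-       890.6397  0.1607272
#> 2   1572.8992 GM1(d18:1/20:0) [M-H]-      1572.9007 -0.9395635
#> 3    500.0000            <NA>   <NA>             NA         NA

# --- synthetic end-to-end run --------------------------------------------
res <- run_pipeline(plaque_config(seed = 42,
                                  simulate = list(grid = c(64, 64),
                                                  n_plaques = 8)),
                    out_dir = "plaquemap_demo")
m <- res$metrics$subject01
m$segmentation$dice; m$segmentation$n_recovered
#> [1] 0.944
#> [1] 7
head(subset(res$subjects$subject01$enrichment, bin == "GM1(d18:1/18:0)"), 4)
#>     roi_id plaque_mean control_mean    ratio log2_ratio
#> 47       1    213.3423     100.1418 2.130402  1.0911258
#> 95       2    208.6806     102.6288 2.033354  1.0238614
#> 143      3    157.4986     100.8637 1.561498  0.6429311
#> 191      4    233.8988     101.4223 2.306188  1.2055101
```

The first block parses the sulfatide name into C48H93NO11S (891.6469 Da),
and the ±2 ppm annotation engine assigns the observed 890.6398 to that
species at +0.16 ppm while an arbitrary 500.0000 finds no match. The
synthetic run recovers 7 of 8 planted plaques with a Dice overlap of 0.94
against the ground-truth masks, and the per-plaque GM1 enrichment ratios
scatter around the planted 3-fold contrast (reduced to ~2 by the TIC
compositional shift of the almost-everywhere-enriched default panel — see
the methods vignette). The output directory holds ion images, the
segmentation map, ROI masks and CSVs, `spsc.csv`/`spsc_heatmap.png`, a
manifest with checksums, and `metrics.json` with the recovery scores.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/plaquemap.R simulate -c cfg.yml -o out/ --seed 1
Rscript inst/cli/plaquemap.R run      -c cfg.yml -o out/
Rscript inst/cli/plaquemap.R annotate --mz 890.6398,644.5025
```

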