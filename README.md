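# ihcscore

Computer-aided scoring of chromogenic immunohistochemistry (IHC) on
tissue-microarray cores, and the cohort statistics that turn those scores
into prognostic evidence.

Manual IHC reading suffers from inter- and intra-observer variation: two
pathologists rarely agree on what counts as a "positive" cell, and the same
observer drifts between slides. `ihcscore` implements the quantitative
alternative for H-DAB stained brightfield images: every pixel is unmixed
into stain concentrations, every nucleus is detected and paired with a
cytoplasm estimate, and a **single global intensity cut-off** — applied
unchanged to every image of a run — decides positivity. The package targets
studies of subcellularly localised markers (the worked examples use the
chemokine receptors CXCR3, CXCR4 and CXCR7 in gallbladder carcinoma tissue),
where the *nuclear vs cytoplasmic* and *glandular vs interstitial*
distribution of a marker carries prognostic information that a whole-core
average destroys.

## What it computes

**Colour deconvolution.** Transmitted light follows the Beer–Lambert model,
so per channel `c`:

    OD_c = -log10(I_c / I0_c),   OD = Mᵀ · conc

with `M` the 3×3 matrix of unit-norm stain OD vectors (hematoxylin, DAB,
and a residual completing the basis by cross product; Ruifrok–Johnston
H-DAB constants by default). Per-pixel concentrations are the 3×3 solve
`conc = (Mᵀ)⁻¹ · OD`, negatives clamped to zero.

**Single-cell compartment scoring.** Nuclei are detected in the hematoxylin
channel (Gaussian smooth → Otsu threshold → hole filling → area filter →
distance-transform watershed); each nucleus gets a cytoplasm ring of width
`w` partitioned by nearest nucleus, and a region label (glandular /
interstitial) by strict majority vote over an annotated mask. A cell is
positive in a compartment when its **mean DAB concentration** exceeds the
global cut-off (default 0.15 OD). Per core and region:

    pct_pos = 100 · (# positive cells) / (# cells in region)

**Cohort statistics.** Paired Wilcoxon signed-rank contrasts (nucleus vs
cytoplasm, glandular vs interstitial), Mann-Whitney group comparisons across
clinicopathological categories (T1-2 vs T3-4, N=0 vs N>0, TNM 0-2 vs 3-4,
differentiation and invasion splits), logistic regression with apparent ROC
AUC, and multivariate Cox proportional-hazards models (Efron ties) for
overall and disease-free survival.

**Synthetic data.** Because cohort imaging data of this kind is rarely
shareable, the package generates stained cores with per-cell ground truth
(rendered through the same Beer–Lambert model the scorer inverts) and
patient cohorts with known effect sizes, so every stage is testable against
a known answer.

## Worked example

```r
library(ihcscore)

# a synthetic 400x800 core: 150 glandular + 150 interstitial cells with
# planted positive fractions (gland nuc 0.6, gland cyt 0.3, inter nuc 0.4,
# inter cyt 0.1)
spec <- image_spec(n_cells = c(glandular = 150, interstitial = 150), seed = 11)
core <- gen_core_image(spec)

score_core(core$img, core$mask, positivity_config("CXCR4"),
           patient_id = "P001")
#> <core_score> patient P001, marker CXCR4
#>              nucleus cytoplasm
#> glandular       60.0      25.3
#> interstitial    44.7       6.7
#> cells: glandular 150, interstitial 150
```

The four percentages are the fraction of cells whose nuclear (resp.
cytoplasmic) mean DAB concentration exceeds the global cut-off, per region;
they match this core's planted per-cell truth (60.0, 25.3, 44.7, 6.7)
exactly.

```r
cohort <- gen_cohort(cohort_spec(seed = 42))   # 55 synthetic patients
report <- run_full_analysis(cohort)
report$paired[1, c("comparison", "mean_x", "mean_y", "p_value")]
#>                          comparison   mean_x   mean_y      p_value
#> 1 CXCR3 gland: nucleus vs cytoplasm 46.25047 33.61522 4.864757e-07
```

Nuclear CXCR3 in glandular regions (46.3%) exceeds cytoplasmic (33.6%) with
a Wilcoxon signed-rank p of 4.9e-7 — the generator plants exactly this kind
of nucleus-dominant expression. `report$cox` carries hazard ratios with 95%
Wald intervals per endpoint (e.g. the planted T-stage effect comes back as
HR 3.18, CI 1.24–8.15, p = 0.016 for OS on this seed).

A command-line wrapper with `simulate` / `score` / `stats` subcommands
lives at `inst/cli/ihcquant.R`.

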