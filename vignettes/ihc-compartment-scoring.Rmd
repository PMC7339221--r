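---
title: "Compartment-resolved IHC scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-resolved IHC scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcscore)
```

This vignette is the package's own account of its science: the optical
model, the segmentation and scoring procedure, the statistical program, the
synthetic-data generator that stands in for patient material, and the
choices made where the design was genuinely open.

## The optical model

Brightfield IHC imaging is transmission imaging, so pixel intensity is
multiplicative in stain amount. Working in optical density (OD) makes it
additive: for channel $c$ with white reference $I_{0,c}$,

$$\mathrm{OD}_c = -\log_{10}\!\frac{\max(I_c,\varepsilon)}{I_{0,c}},
\qquad \mathrm{OD} = M^\top \mathbf{c},$$

where the rows of $M$ are unit-norm OD vectors of hematoxylin (blue nuclear
counterstain), DAB (the brown marker chromogen) and a residual channel
(normalised cross product of the first two), and $\mathbf{c}$ holds the
per-pixel stain concentrations. Unmixing is the per-pixel $3\times 3$ solve
$\mathbf{c} = (M^\top)^{-1}\,\mathrm{OD}$ with negative components clamped
to zero.

Assumptions worth stating: stains obey Beer–Lambert superposition (true to
good approximation for hematoxylin and moderately thick DAB deposits, less
so for very dense DAB, which scatters rather than absorbs); the stain
vectors are constant across the slide; and the camera is linear with a
known white point. Numerical choices:

* base-10 logarithm throughout (OD convention);
* white reference $I_0 = 255$ per channel, intensity floor
  $\varepsilon = 1$ — a saturated-dark 8-bit pixel then maps to the finite
  maximum OD $\log_{10} 255 \approx 2.407$;
* default stain vectors are the Ruifrok–Johnston H-DAB constants,
  hematoxylin $(0.650, 0.704, 0.286)$ and DAB $(0.268, 0.570, 0.776)$.
  They are config-overridable; automatic stain-vector estimation
  (Macenko-style) is out of scope;
* negatives are clamped after the solve rather than solving a constrained
  least-squares problem: simpler, standard, and exactly testable — on
  in-gamut images the clamp never activates and the compose→deconvolve
  round trip is exact to $10^{-9}$.

`reconstruction_error()` reports the max absolute difference between the
observed OD and the stain-composed reconstruction; large values flag
out-of-gamut colours or a wrong basis.

## Nuclei, cytoplasm, regions

The nucleus detector is deliberately classical and fully deterministic:
Gaussian smoothing, a global threshold, hole filling, an area filter, then
a Euclidean distance-transform watershed to split touching nuclei
(local-maximum seeds with non-maximum suppression over a disc, grown as a
spatial Voronoi partition restricted to the foreground). Parameters, with
defaults chosen for nuclei of roughly 5–11 px radius at typical TMA
magnifications:

| parameter | default | unit | role |
|---|---|---|---|
| `smooth_sigma` | 1.5 | px | suppress pixel noise before thresholding |
| `threshold_method` | otsu | — | global foreground threshold on the smoothed hematoxylin channel (`fixed` available) |
| `min_area`, `max_area` | 30, 1500 | px² | reject debris and confluent sheets |
| `seed_min_distance` | 7 | px | minimum separation of watershed seeds; below twice this, peaks merge |
| `ring_width` | 4 | px | cytoplasm ring width |
| `exclude_border` | true | — | drop nuclei touching the image edge |

The area filter runs both before the watershed (so oversized merged blobs
still reach the splitter) and after it (so every reported nucleus satisfies
the area contract). Labels are 4-connected; coordinates are 0-based
(row, col).

No membrane stain exists in H-DAB material, so the cytoplasm is estimated
geometrically: the ring of non-nucleus pixels within `ring_width` of a
nucleus, with contested pixels assigned to the nearest nucleus (ties to the
lower label id). Rings are pairwise disjoint, never overlap any nucleus,
and clip at image borders.

Tissue regions (tumour gland epithelium vs intervening stroma) enter as an
annotated mask — the package takes no position on whether such annotations
are drawn by hand or produced upstream. Each cell is assigned by strict
majority vote of its nucleus pixels; exact ties and unannotated majorities
are `excluded` and count toward neither region, mirroring scoring that only
trusts outlined ROIs.

## Positivity and percent-positive

A cell is positive in a compartment when the **arithmetic mean DAB
concentration** over that compartment's pixels reaches the global cut-off
(default 0.15 OD-equivalent). One cut-off per run, applied unchanged to
every image — this is the property that removes observer variation from the
read-out. The per-region score is the percentage of positive *cells* (not
positive-pixel area; the single-cell reading matches the per-cell
quantification the method is built around — the area reading would weight
large cells more and is noted as a possible alternative). Cells with an
empty cytoplasm ring count in the denominator as negative. Replicate cores
of one patient aggregate by cell-count-weighted means.

Raising the cut-off can only shrink every percentage (monotonicity), which
the tests verify by sweep.

## The statistical program

The cohort table carries 12 measurements per patient (3 markers × 2
compartments × 2 regions) plus clinicopathological covariates and OS/DFS
outcomes. The report has three parts:

1. **Paired contrasts** (12): nucleus vs cytoplasm within each
   marker × region, and glandular vs interstitial within each
   marker × compartment. Default test: Wilcoxon signed-rank — robust for
   bounded, skewed percentages at cohort sizes around 55 — exact when the
   number of non-zero differences is ≤ 25 and tie-free, continuity-corrected
   normal approximation otherwise; paired *t* by config. All-zero (or
   zero-variance) differences return a flagged degenerate result rather
   than dividing by zero.
2. **Group comparisons and prediction** per binary categorisation
   (differentiation and invasion median splits with ties to "low"; T1-2 vs
   T3-4; N = 0 vs N > 0; TNM 0–2 vs 3–4): Mann-Whitney U per measurement
   (same exactness rule on the pooled n), plus one multivariate logistic
   model per categorisation with apparent (in-sample) ROC AUC. AUC is the
   midrank statistic — exactly the concordant-pairs count with half credit
   for ties. Complete separation is detected from the glm fit and flagged.
3. **Cox models** for OS and DFS with sex, dichotomised T and N, and the
   six glandular measurements as covariates (Efron ties, Wald CIs on the
   log scale). Interstitial measurements are excluded from survival models
   — at 55 patients, 12 marker covariates invite overfitting — and the
   same six-predictor set is used for the logistic fits for the same
   reason. Fewer than 10 events flags the fit as `low_events`.

Raw p-values are reported by default (Benjamini-Hochberg by config);
analyses that cannot run (single-class outcomes, groups under 3) are
returned as flagged rows and never abort the rest of the report.

## What the generator emulates — and what it does not

`gen_core_image()` renders discs (ellipses behind a flag; discs keep the
area oracles analytic) of hematoxylin 0.6 OD with DAB at 0.8 (positive
compartment) or 0.05 (negative) — levels chosen so the default cut-off 0.15
separates the classes with wide margin — composed to RGB through the same
Beer–Lambert model the scorer inverts, plus Gaussian pixel noise (sd 2
intensity units) and 8-bit quantisation. Positivity flags are independent
Bernoulli draws per compartment; nuclei keep a minimum center spacing
(default $2(\mu_r + 3\sigma_r)+1$, guaranteeing non-overlap), or form
touching pairs at 1.4 × radius when stressing the watershed. With zero
noise, scoring recovers the planted per-cell flags *exactly* for any
cut-off between the two DAB levels.

`gen_cohort()` draws categories by prevalence, the 12 measurements from
truncated normals clipped to [0, 100], and OS/DFS from an exponential
proportional-hazards model with exponential censoring whose rate is solved
numerically (uniroot on the expected censored fraction) to hit the target
censoring rate (default 0.3). Default means are the nucleus-dominant,
gland-dominant pattern typical of these receptors (e.g. glandular CXCR3
45.3% nuclear vs 32.4% cytoplasmic); the corresponding spreads treat the
reported error terms of such studies as standard errors at n = 55, so
between-patient SDs are $SE\sqrt{55}$. Two structural choices deserve
explanation:

* **Within-patient compartment correlation (0.8).** Nuclear and cytoplasmic
  positivity of one marker in one region are measured on the same cells of
  the same core and are strongly coupled biologically. Modelling them as
  independent would make the paired nucleus-vs-cytoplasm differences far
  noisier than real cores show, and a 13-point contrast at n = 55 would no
  longer reach p < 0.005 reliably. A shared latent factor with loading
  $\sqrt{0.8}$ restores realistic pairing.
* **Centered group shifts.** A group effect (say +10 points in T3-4
  patients) is applied centered on the category flag, so the marginal mean
  of the measurement stays at its configured value while the between-group
  difference equals the shift. Uncentered shifts would silently move the
  marginal means and distort the paired contrasts.

`cohort_spec_null()` equalises all 12 means and SDs besides zeroing every
shift and log-HR: a calibration null must make each paired contrast a true
null, which zero *effects* alone would not (the default means differ
between compartments by design).

What the image generator does **not** emulate: chromatin texture and
intensity gradients within compartments, staining artefacts (folds, edge
effects, uneven illumination), spatially correlated expression, overlapping
cytoplasm without a gap, and stain-vector drift between slides. Passing the
recovery tests therefore demonstrates that the measurement chain is
correct and unbiased under the stated optical model — not that the
segmentation would meet the same recall on real, messy tissue. On real
material the detector's parameters (and possibly a learned detector) would
need tuning against annotated ground truth.

## Problem sizes and determinism

The package's own verification runs at desk scale, chosen to keep the full
suite in the low minutes: 50 seeded cores of 100–300 nuclei (plus 10
overlapping-pair cores) for detection recall; 20 cores at 150 cells/region
for percent-positive recovery; 100 replicates of n = 500 for Cox recovery
(log-HR 0.7, 30% censoring); 2000 null cohorts of n = 55 for test
calibration; 2000 random pixels for the unmixing oracle. Every generator
takes an explicit seed and restores the caller's RNG state, so
simulate → score → stats is byte-identical across reruns; all tabular
outputs carry a provenance header (package version, seed, config hash —
a 32-bit FNV-1a over the serialised configuration).

## Known limitations

* The cytoplasm ring is a geometric proxy; in densely packed epithelium it
  under-covers true cytoplasm and can bleed across cell boundaries.
* A single global DAB cut-off presumes comparable staining batches;
  between-slide stain normalisation is explicitly out of scope.
* Otsu thresholding assumes a bimodal hematoxylin histogram; nearly empty
  or confluent cores may need the `fixed` threshold.
* Apparent (in-sample) AUCs are optimistic relative to cross-validated
  ones; they are reported because single-cohort biomarker studies
  conventionally do so.
* The exponential survival model has constant baseline hazard; it is a
  calibration vehicle for the Cox machinery, not a realistic disease
  model.
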