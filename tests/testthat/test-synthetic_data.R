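# planted cells only (skips rendering for speed)
with_seed_cells <- function(spec) {
  ns <- asNamespace("ihcscore")
  get("with_seed", ns)(spec$seed,
                       get("place_nuclei", ns)(spec,
                                               get("region_mask_impl", ns)(spec)))
}

test_that("split-halves masks cover exact halves; polygon masks keep a margin", {
  spec <- image_spec(height = 100, width = 100, seed = 1)
  m <- gen_region_mask(spec)
  expect_true(all(m[, 1:50] == 1L))
  expect_true(all(m[, 51:100] == 2L))
  expect_identical(gen_region_mask(spec), m)  # seed determinism

  spec_p <- image_spec(height = 120, width = 240,
                       layout = "annotated_polygons", seed = 6)
  mp <- gen_region_mask(spec_p)
  expect_setequal(sort(unique(as.vector(mp))), c(0L, 1L, 2L))
  expect_identical(gen_region_mask(spec_p), mp)
})

test_that("core images are seed-deterministic with faithful geometry", {
  spec <- image_spec(height = 220, width = 440,
                     n_cells = c(glandular = 25, interstitial = 25), seed = 13)
  a <- gen_core_image(spec)
  b <- gen_core_image(spec)
  expect_identical(a$img, b$img)
  expect_identical(a$truth$cells, b$truth$cells)
  tr <- a$truth$cells
  expect_identical(nrow(tr), 50L)
  # planted fractions are the mean of per-cell flags
  gl <- tr[tr$region == "glandular", ]
  expect_equal(a$truth$planted_frac["glandular", "nucleus"],
               mean(gl$nuc_positive))
  # centers respect the minimum spacing
  dmat <- as.matrix(dist(tr[, c("center_row", "center_col")]))
  diag(dmat) <- Inf
  expect_gte(min(dmat), spec$min_center_spacing)
})

test_that("an empty spec renders a blank white image", {
  spec <- image_spec(height = 60, width = 120,
                     n_cells = c(glandular = 0, interstitial = 0),
                     noise_sd = 0, seed = 1)
  core <- gen_core_image(spec)
  expect_true(all(core$img == 255L))
  expect_identical(nrow(core$truth$cells), 0L)
})

test_that("noise-free rendering decodes back to the planted DAB level", {
  spec <- image_spec(height = 150, width = 300,
                     n_cells = c(glandular = 5, interstitial = 5),
                     true_pos_frac = matrix(1, 2, 2, dimnames = list(
                       c("glandular", "interstitial"),
                       c("nucleus", "cytoplasm"))),
                     noise_sd = 0, seed = 3)
  core <- gen_core_image(spec)
  dab <- deconvolve(rgb_to_od(core$img))[, , 2]
  nuc_mean <- mean(dab[core$truth$nucleus_labels > 0])
  expect_lt(abs(nuc_mean - spec$dab_pos_level), 0.01)  # 8-bit quantisation only
})

test_that("render-score round trip is exact at zero noise for in-gamut thresholds", {
  spec <- image_spec(height = 250, width = 500,
                     n_cells = c(glandular = 40, interstitial = 40),
                     noise_sd = 0, seed = 29)
  core <- gen_core_image(spec)
  for (thr in c(0.1, 0.15, 0.4)) {   # between dab_neg_level and dab_pos_level
    cs <- score_core(core$img, core$mask,
                     positivity_config(dab_threshold = thr))
    expect_equal(unname(cs$pct), unname(core$truth$planted_frac * 100))
  }
})

test_that("planted fractions converge to spec fractions as cells grow", {
  frac <- matrix(0.5, 2, 2, dimnames = list(
    c("glandular", "interstitial"), c("nucleus", "cytoplasm")))
  err <- sapply(c(50, 200, 800), function(n) {
    devs <- sapply(1:5, function(s) {
      spec <- image_spec(height = 60 * ceiling(sqrt(n)),
                         width = 120 * ceiling(sqrt(n)),
                         n_cells = c(glandular = n, interstitial = 0),
                         true_pos_frac = frac, seed = s, noise_sd = 0)
      tr <- with_seed_cells(spec)
      abs(mean(tr$nuc_positive) - 0.5)
    })
    mean(devs)
  })
  # binomial SE scaling: mean deviation shrinks roughly as 1/sqrt(n)
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.05)
})

test_that("cohort generation honours effect-free nulls and censoring targets", {
  co <- gen_cohort(cohort_spec_null(n_patients = 5000, seed = 11))
  # no group effects: mean difference between T categories near zero
  t34 <- categorize_t(co$t_score) == "T3-4"
  for (mc in c("cxcr3_cyt_gland", "cxcr4_cyt_gland"))
    expect_lt(abs(mean(co[[mc]][t34]) - mean(co[[mc]][!t34])), 0.5 * 2)
  # censoring fraction near target 0.3
  expect_lt(abs(mean(1 - co$os_event) - 0.3), 0.02)
  # determinism and validity
  co2 <- gen_cohort(cohort_spec_null(n_patients = 5000, seed = 11))
  expect_identical(co, co2)
  expect_silent(validate_cohort(co))
  expect_error(cohort_spec(censoring_rate = 1.2),
               class = "ihc_validation_error")
})

test_that("group shifts move group means by the configured amount", {
  # means/SDs far from the [0, 100] clip so the shift passes through intact
  ge <- data.frame(variable = "node_pos", column = "cxcr4_cyt_gland",
                   shift = 8, stringsAsFactors = FALSE)
  co <- gen_cohort(cohort_spec(
    n_patients = 5000,
    marker_mean = setNames(rep(50, 12), marker_columns()),
    marker_sd = setNames(rep(10, 12), marker_columns()),
    group_effects = ge, seed = 21))
  np <- categorize_n(co$n_score) == "node_positive"
  diff_obs <- mean(co$cxcr4_cyt_gland[np]) - mean(co$cxcr4_cyt_gland[!np])
  expect_lt(abs(diff_obs - 8), 1)
})
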