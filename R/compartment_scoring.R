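# Per-cell DAB quantification and percent-positive scoring. Each cell's
# nuclear and cytoplasmic mean DAB concentration is compared against one
# global cut-off, applied unchanged to every image of a run, so positivity
# calls are observer-independent and comparable across cores.

#' Positivity configuration
#'
#' @param marker marker name, one of `"CXCR3"`, `"CXCR4"`, `"CXCR7"`.
#' @param dab_threshold global positivity cut-off on the mean compartment DAB
#'   concentration (OD-equivalent units). One threshold per run, applied to
#'   every image.
#' @param statistic per-compartment aggregation of pixel DAB; only `"mean"`
#'   is supported.
#' @return a list of class `positivity_config`.
#' @export
positivity_config <- function(marker = c("CXCR3", "CXCR4", "CXCR7"),
                              dab_threshold = 0.15,
                              statistic = "mean") {
  marker <- match.arg(marker)
  statistic <- match.arg(statistic, "mean")
  if (!is.numeric(dab_threshold) || length(dab_threshold) != 1 || dab_threshold <= 0)
    err_parameter("dab_threshold must be a single positive number")
  structure(list(marker = marker, dab_threshold = dab_threshold,
                 statistic = statistic), class = "positivity_config")
}

#' Mean DAB concentration per cell compartment
#'
#' @param cells an `ihc_cells` object from [extract_cells()].
#' @param dab numeric matrix of DAB concentrations (same shape as the image).
#' @return data frame with one row per cell: `id`, `nuc_dab`, `cyt_dab`
#'   (`cyt_dab` is `NA` for cells with an empty cytoplasm ring).
#' @export
cell_compartment_intensity <- function(cells, dab) {
  stopifnot(inherits(cells, "ihc_cells"))
  if (!is.matrix(dab) || !identical(dim(dab), dim(cells$nucleus_labels)))
    err_format("dab channel and label image dimensions disagree")
  K <- nrow(cells$cells)
  if (K == 0)
    return(data.frame(id = integer(0), nuc_dab = numeric(0), cyt_dab = numeric(0)))
  labs <- cells$nucleus_labels
  n_area <- tabulate(labs[labs > 0], K)
  if (any(n_area == 0)) err_integrity("cell with empty nucleus pixel set")
  nuc_sum <- numeric(K)
  s <- rowsum(dab[labs > 0], labs[labs > 0])
  nuc_sum[as.integer(rownames(s))] <- s
  rl <- cells$cytoplasm_labels
  c_area <- tabulate(rl[rl > 0], K)
  cyt_sum <- numeric(K)
  if (any(rl > 0)) {
    s <- rowsum(dab[rl > 0], rl[rl > 0])
    cyt_sum[as.integer(rownames(s))] <- s
  }
  data.frame(id = cells$cells$id,
             nuc_dab = nuc_sum / n_area,
             cyt_dab = ifelse(c_area > 0, cyt_sum / pmax(c_area, 1), NA_real_))
}

#' Score every cell against the global DAB cut-off
#'
#' @inheritParams cell_compartment_intensity
#' @param cfg a [positivity_config()].
#' @return data frame of cell scores: `id`, `nuc_dab`, `cyt_dab`,
#'   `nuc_positive`, `cyt_positive`, `region`. A missing cytoplasm mean
#'   counts as not positive.
#' @export
score_cells <- function(cells, dab, cfg = positivity_config()) {
  ints <- cell_compartment_intensity(cells, dab)
  data.frame(ints,
             nuc_positive = ints$nuc_dab >= cfg$dab_threshold,
             cyt_positive = !is.na(ints$cyt_dab) & ints$cyt_dab >= cfg$dab_threshold,
             region = cells$cells$region,
             stringsAsFactors = FALSE)
}

#' Percent of positive cells in one region x compartment
#'
#' `100 * positive / total` over the cells of the requested region; cells
#' with a missing compartment value stay in the denominator as negative.
#' Returns `NA` when the region holds no cells.
#'
#' @param scores a cell-score data frame from [score_cells()].
#' @param region `"glandular"` or `"interstitial"`.
#' @param compartment `"nucleus"` or `"cytoplasm"`.
#' @param cfg a [positivity_config()] (kept for interface symmetry; the
#'   flags in `scores` already encode its threshold).
#' @return percent in \[0, 100\], or `NA` if no cells in the region.
#' @export
percent_positive <- function(scores, region = c("glandular", "interstitial"),
                             compartment = c("nucleus", "cytoplasm"),
                             cfg = NULL) {
  region <- match.arg(region)
  compartment <- match.arg(compartment)
  sub <- scores[scores$region == region, , drop = FALSE]
  if (nrow(sub) == 0) return(NA_real_)
  flag <- if (compartment == "nucleus") sub$nuc_positive else sub$cyt_positive
  100 * sum(flag, na.rm = TRUE) / nrow(sub)
}

#' Score one stained core image end to end
#'
#' Runs colour deconvolution, nuclei segmentation, cytoplasm-ring
#' construction, region assignment and positivity calls, and summarises the
#' four percent-positive values (region x compartment) with cell counts.
#' Deterministic for identical inputs.
#'
#' @param img 8-bit RGB array `H x W x 3`.
#' @param mask region mask matrix (0/1/2), same height/width.
#' @param cfg a [positivity_config()].
#' @param seg a [seg_params()].
#' @param stains 3x3 stain matrix, default H-DAB.
#' @param patient_id optional identifier carried into the result.
#' @param keep_cells keep the per-cell score table in the result.
#' @return a list of class `core_score` with elements `patient_id`, `marker`,
#'   `pct` (2x2 matrix regions x compartments, `NA` for empty regions),
#'   `n_cells` (named counts), and optionally `cell_scores`.
#' @export
score_core <- function(img, mask, cfg = positivity_config(),
                       seg = seg_params(), stains = hdab_stain_matrix(),
                       patient_id = NA_character_, keep_cells = FALSE) {
  check_rgb_image(img)
  check_region_mask(mask)
  if (!identical(dim(img)[1:2], dim(mask)))
    err_format("image and mask dimensions disagree")
  conc <- deconvolve(rgb_to_od(img), stains)
  labels <- segment_nuclei(conc[, , 1], seg)
  rings <- make_cytoplasm_rings(labels, seg$ring_width)
  cells <- extract_cells(labels, rings, mask, seg)
  scores <- score_cells(cells, conc[, , 2], cfg)
  pct <- matrix(NA_real_, 2, 2,
                dimnames = list(c("glandular", "interstitial"),
                                c("nucleus", "cytoplasm")))
  for (r in rownames(pct)) for (cc in colnames(pct))
    pct[r, cc] <- percent_positive(scores, r, cc)
  n_cells <- c(glandular = sum(scores$region == "glandular"),
               interstitial = sum(scores$region == "interstitial"))
  out <- list(patient_id = patient_id, marker = cfg$marker, pct = pct,
              n_cells = n_cells)
  if (keep_cells) out$cell_scores <- scores
  structure(out, class = "core_score")
}

#' @export
print.core_score <- function(x, ...) {
  cat(sprintf("<core_score> patient %s, marker %s\n", x$patient_id, x$marker))
  print(round(x$pct, 1))
  cat(sprintf("cells: glandular %d, interstitial %d\n",
              x$n_cells[["glandular"]], x$n_cells[["interstitial"]]))
  invisible(x)
}

#' Flatten a core score to a one-row data frame
#' @param x a `core_score`.
#' @return data frame with columns `patient_id`, `marker`, `pct_gland_nuc`,
#'   `pct_gland_cyt`, `pct_inter_nuc`, `pct_inter_cyt`, `n_gland`, `n_inter`.
#' @export
as.data.frame.core_score <- function(x, ...) {
  data.frame(patient_id = x$patient_id, marker = x$marker,
             pct_gland_nuc = x$pct["glandular", "nucleus"],
             pct_gland_cyt = x$pct["glandular", "cytoplasm"],
             pct_inter_nuc = x$pct["interstitial", "nucleus"],
             pct_inter_cyt = x$pct["interstitial", "cytoplasm"],
             n_gland = x$n_cells[["glandular"]],
             n_inter = x$n_cells[["interstitial"]],
             stringsAsFactors = FALSE)
}

#' Aggregate replicate core scores of one patient and marker
#'
#' Cell-count-weighted mean of each percentage (weights are the region cell
#' counts); counts are summed. Percentages of empty regions are ignored.
#'
#' @param cores list of `core_score` objects sharing patient and marker.
#' @return a single `core_score`.
#' @export
aggregate_patient <- function(cores) {
  if (length(cores) == 0) err_integrity("no cores to aggregate")
  stopifnot(all(vapply(cores, inherits, logical(1), "core_score")))
  pid <- unique(vapply(cores, `[[`, character(1), "patient_id"))
  mk <- unique(vapply(cores, `[[`, character(1), "marker"))
  if (length(pid) != 1 || length(mk) != 1)
    err_integrity("cores must share one patient_id and one marker")
  pct <- matrix(NA_real_, 2, 2, dimnames = dimnames(cores[[1]]$pct))
  n_cells <- c(glandular = 0L, interstitial = 0L)
  for (r in rownames(pct)) {
    w <- vapply(cores, function(x) x$n_cells[[r]], numeric(1))
    n_cells[r] <- as.integer(sum(w))
    for (cc in colnames(pct)) {
      v <- vapply(cores, function(x) x$pct[r, cc], numeric(1))
      ok <- !is.na(v) & w > 0
      if (any(ok)) pct[r, cc] <- sum(v[ok] * w[ok]) / sum(w[ok])
    }
  }
  structure(list(patient_id = pid, marker = mk, pct = pct, n_cells = n_cells),
            class = "core_score")
}
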