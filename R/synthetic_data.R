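# Synthetic stained-core images with per-cell ground truth, and synthetic
# patient cohorts with known effect sizes. Nuclei are rendered as discs
# (optionally ellipses) of hematoxylin at a fixed concentration; DAB is
# uniform within each compartment at a "positive" or "negative" level chosen
# so that the default scoring cut-off separates the two classes with margin.
# Images are composed through the same Beer-Lambert model the scoring side
# inverts, so with zero noise the render -> deconvolve round trip is exact up
# to 8-bit quantisation.

#' Specification of a synthetic stained core
#'
#' @param height,width image size in pixels.
#' @param n_cells named vector: planted nuclei per region
#'   (`glandular`, `interstitial`).
#' @param radius_mean,radius_sd nucleus radius distribution in px (normal,
#'   truncated to mean +/- 3 sd and at least 3 px).
#' @param ring_width cytoplasm ring width in px.
#' @param layout `"split_halves"` (left half glandular, right half
#'   interstitial) or `"annotated_polygons"` (random star-shaped polygon ROIs
#'   with an unannotated margin).
#' @param true_pos_frac 2x2 matrix (regions x compartments) of per-cell
#'   positivity probabilities.
#' @param dab_pos_level,dab_neg_level,hema_level stain concentrations in
#'   OD-equivalent units.
#' @param noise_sd Gaussian pixel noise, 8-bit intensity units.
#' @param min_center_spacing minimum distance between nucleus centers
#'   (default `2 * (radius_mean + 3 * radius_sd) + 1`, which guarantees
#'   non-overlap).
#' @param overlap_pairs if `TRUE`, nuclei are planted in touching pairs with
#'   center distance `overlap_factor * radius` (for segmentation stress
#'   tests); spacing then applies between pairs.
#' @param overlap_factor pair center distance in units of the radius.
#' @param elliptical render elliptical nuclei (random orientation, aspect
#'   `ellipse_aspect`) instead of discs.
#' @param ellipse_aspect major/minor axis ratio when `elliptical`.
#' @param seed integer RNG seed; every draw derives from it.
#' @return list of class `image_spec`.
#' @export
image_spec <- function(height = 400, width = 800,
                       n_cells = c(glandular = 100, interstitial = 100),
                       radius_mean = 8, radius_sd = 1,
                       ring_width = 4,
                       layout = c("split_halves", "annotated_polygons"),
                       true_pos_frac = matrix(c(0.6, 0.4, 0.3, 0.1), 2, 2,
                                              dimnames = list(
                                                c("glandular", "interstitial"),
                                                c("nucleus", "cytoplasm"))),
                       dab_pos_level = 0.8, dab_neg_level = 0.05,
                       hema_level = 0.6, noise_sd = 2,
                       min_center_spacing = NULL,
                       overlap_pairs = FALSE, overlap_factor = 1.4,
                       elliptical = FALSE, ellipse_aspect = 1.3,
                       seed = 0) {
  layout <- match.arg(layout)
  if (is.null(min_center_spacing))
    min_center_spacing <- 2 * (radius_mean + 3 * radius_sd) + 1
  if (any(true_pos_frac < 0) || any(true_pos_frac > 1))
    err_validation("true_pos_frac values must lie in [0, 1]")
  if (dab_pos_level < 0 || dab_neg_level < 0 || hema_level < 0)
    err_validation("stain levels must be non-negative")
  if (!all(c("glandular", "interstitial") %in% names(n_cells)))
    err_validation("n_cells needs named entries glandular and interstitial")
  structure(list(height = height, width = width, n_cells = n_cells,
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 ring_width = ring_width, layout = layout,
                 true_pos_frac = true_pos_frac,
                 dab_pos_level = dab_pos_level, dab_neg_level = dab_neg_level,
                 hema_level = hema_level, noise_sd = noise_sd,
                 min_center_spacing = min_center_spacing,
                 overlap_pairs = isTRUE(overlap_pairs),
                 overlap_factor = overlap_factor,
                 elliptical = isTRUE(elliptical),
                 ellipse_aspect = ellipse_aspect,
                 seed = as.integer(seed)),
            class = "image_spec")
}

#' Generate a region mask for a synthetic core
#'
#' `split_halves` assigns the left half of the image to the glandular region
#' (value 1) and the right half to the interstitial region (value 2).
#' `annotated_polygons` draws one seeded random star-shaped polygon per
#' region inside its half, leaving an unannotated (value 0) margin.
#'
#' @param spec an [image_spec()].
#' @return integer matrix `height x width` with values in `{0, 1, 2}`.
#' @export
gen_region_mask <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  with_seed(spec$seed, region_mask_impl(spec))
}

#' @noRd
region_mask_impl <- function(spec) {
  h <- spec$height; w <- spec$width
  half <- floor(w / 2)
  if (spec$layout == "split_halves") {
    m <- matrix(0L, h, w)
    m[, seq_len(half)] <- 1L
    m[, (half + 1):w] <- 2L
    return(m)
  }
  m <- matrix(0L, h, w)
  m <- fill_star_polygon(m, value = 1L,
                         center = c(h / 2, half / 2),
                         max_radius = 0.42 * min(h, half))
  m <- fill_star_polygon(m, value = 2L,
                         center = c(h / 2, half + half / 2),
                         max_radius = 0.42 * min(h, half))
  m
}

# Star-shaped polygon: 10 vertices at random radii in [0.55, 1] * max_radius.
#' @noRd
fill_star_polygon <- function(m, value, center, max_radius) {
  k <- 10L
  ang <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  rad <- runif(k, 0.55, 1) * max_radius
  vr <- center[1] + rad * sin(ang)
  vc <- center[2] + rad * cos(ang)
  rows <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cols <- matrix(rep(seq_len(ncol(m)), each = nrow(m)), nrow(m), ncol(m))
  inside <- matrix(FALSE, nrow(m), ncol(m))
  # even-odd crossing number, vectorised over pixels
  j <- k
  for (i in seq_len(k)) {
    cross <- ((vr[i] > rows) != (vr[j] > rows)) &
      (cols < (vc[j] - vc[i]) * (rows - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, cross)
    j <- i
  }
  m[inside] <- value
  m
}

#' Generate a synthetic stained core with per-cell ground truth
#'
#' Places nuclei with a minimum center spacing inside their region, draws
#' independent Bernoulli positivity flags per compartment, builds per-pixel
#' hematoxylin/DAB concentration fields, composes 8-bit RGB through the
#' Beer-Lambert model and adds Gaussian pixel noise.
#'
#' @param spec an [image_spec()].
#' @param stains 3x3 stain matrix used for rendering.
#' @return list with elements `img` (8-bit RGB array), `mask` (region mask)
#'   and `truth`: a list holding the per-cell data frame `cells`
#'   (`id, center_row, center_col, radius, region, nuc_positive,
#'   cyt_positive`, 0-based centers), the planted fractions
#'   `planted_frac` (2x2, `NA` where a region holds no cells), and the true
#'   `nucleus_labels` / `cytoplasm_labels` matrices.
#' @export
gen_core_image <- function(spec, stains = hdab_stain_matrix()) {
  stopifnot(inherits(spec, "image_spec"))
  with_seed(spec$seed, {
    mask <- region_mask_impl(spec)
    h <- spec$height; w <- spec$width
    placed <- place_nuclei(spec, mask)
    K <- nrow(placed)
    labels <- matrix(0L, h, w)
    bestd <- matrix(Inf, h, w)
    if (K > 0) {
      theta <- if (spec$elliptical) runif(K, 0, pi) else numeric(K)
      for (k in seq_len(K)) {
        cr <- placed$center_row[k]; cc <- placed$center_col[k]
        r <- placed$radius[k]
        rmax <- if (spec$elliptical) r * sqrt(spec$ellipse_aspect) else r
        r0 <- max(1, floor(cr - rmax)); r1 <- min(h, ceiling(cr + rmax))
        c0 <- max(1, floor(cc - rmax)); c1 <- min(w, ceiling(cc + rmax))
        rows <- matrix(r0:r1, r1 - r0 + 1, c1 - c0 + 1)
        cols <- matrix(rep(c0:c1, each = r1 - r0 + 1), r1 - r0 + 1, c1 - c0 + 1)
        dx <- rows - cr; dy <- cols - cc
        q <- if (spec$elliptical) {
          a <- r * sqrt(spec$ellipse_aspect); b <- r / sqrt(spec$ellipse_aspect)
          u <- dx * cos(theta[k]) + dy * sin(theta[k])
          v <- -dx * sin(theta[k]) + dy * cos(theta[k])
          sqrt((u / a)^2 + (v / b)^2) * r   # radius-equivalent distance
        } else sqrt(dx^2 + dy^2)
        inside <- q <= r
        sub_lab <- labels[r0:r1, c0:c1]
        sub_bd <- bestd[r0:r1, c0:c1]
        upd <- inside & (q < sub_bd)      # overlapping nuclei: nearest center
        sub_lab[upd] <- k
        sub_bd[upd] <- q[upd]
        labels[r0:r1, c0:c1] <- sub_lab
        bestd[r0:r1, c0:c1] <- sub_bd
      }
    }
    rings <- if (K > 0) make_cytoplasm_rings(labels, spec$ring_width)
             else matrix(0L, h, w)
    nuc_pos <- placed$nuc_positive
    cyt_pos <- placed$cyt_positive
    hema <- matrix(0, h, w)
    dab <- matrix(0, h, w)
    if (K > 0) {
      hema[labels > 0] <- spec$hema_level
      lvl_nuc <- ifelse(nuc_pos, spec$dab_pos_level, spec$dab_neg_level)
      lvl_cyt <- ifelse(cyt_pos, spec$dab_pos_level, spec$dab_neg_level)
      dab[labels > 0] <- lvl_nuc[labels[labels > 0]]
      dab[rings > 0] <- lvl_cyt[rings[rings > 0]]
    }
    conc <- array(0, c(h, w, 3))
    conc[, , 1] <- hema
    conc[, , 2] <- dab
    img <- compose_rgb(conc, stains, i0 = 255, noise_sd = spec$noise_sd)
    planted <- matrix(NA_real_, 2, 2,
                      dimnames = list(c("glandular", "interstitial"),
                                      c("nucleus", "cytoplasm")))
    for (rg in rownames(planted)) {
      sel <- placed$region == rg
      if (any(sel)) {
        planted[rg, "nucleus"] <- mean(nuc_pos[sel])
        planted[rg, "cytoplasm"] <- mean(cyt_pos[sel])
      }
    }
    list(img = img, mask = mask,
         truth = list(cells = placed, planted_frac = planted,
                      nucleus_labels = labels, cytoplasm_labels = rings))
  })
}

# Rejection-sample nucleus centers region by region. Centers keep a margin of
# radius + 1 px from the image border and from the region boundary, so every
# planted nucleus lies wholly inside one annotated region.
#' @noRd
place_nuclei <- function(spec, mask) {
  out <- list()
  acc_r <- numeric(0); acc_c <- numeric(0)
  id <- 0L
  for (rg in c("glandular", "interstitial")) {
    val <- if (rg == "glandular") 1L else 2L
    n <- spec$n_cells[[rg]]
    if (n == 0) next
    region_px <- which(mask == val, arr.ind = TRUE)
    if (nrow(region_px) == 0 && n > 0)
      err_validation("region %s is empty in the mask", rg)
    n_units <- if (spec$overlap_pairs) ceiling(n / 2) else n
    placed_units <- 0L
    attempts <- 0L
    max_attempts <- 500L * n_units
    while (placed_units < n_units) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        err_validation(
          "could not place %d nuclei in region %s with spacing %.1f",
          n, rg, spec$min_center_spacing)
      r <- trunc_radius(spec)
      pad <- if (spec$overlap_pairs) spec$overlap_factor * r else 0
      margin <- r + 1 + pad
      cr <- runif(1, 1 + margin, spec$height - margin)
      cc <- runif(1, 1 + margin, spec$width - margin)
      if (!region_clear(mask, val, cr, cc, margin)) next
      spacing <- spec$min_center_spacing +
        (if (spec$overlap_pairs) spec$overlap_factor * spec$radius_mean else 0)
      if (length(acc_r) &&
          min(sqrt((acc_r - cr)^2 + (acc_c - cc)^2)) < spacing) next
      members <- if (spec$overlap_pairs && (2 * placed_units + 2) <= n + 1) {
        ang <- runif(1, 0, 2 * pi)
        d <- spec$overlap_factor * r
        m2 <- c(cr + d * sin(ang), cc + d * cos(ang))
        if (!region_clear(mask, val, m2[1], m2[2], r + 1)) next
        rbind(c(cr, cc, r), c(m2[1], m2[2], r))
      } else cbind(cr, cc, r)
      if (spec$overlap_pairs && nrow(members) == 2 && (2 * placed_units + 2) > n)
        members <- members[1, , drop = FALSE]  # odd n: last unit is a singleton
      for (i in seq_len(nrow(members))) {
        id <- id + 1L
        acc_r <- c(acc_r, members[i, 1]); acc_c <- c(acc_c, members[i, 2])
        out[[id]] <- data.frame(id = id,
                                center_row = members[i, 1] - 1,  # 0-based
                                center_col = members[i, 2] - 1,
                                radius = members[i, 3], region = rg,
                                stringsAsFactors = FALSE)
      }
      placed_units <- placed_units + 1L
    }
  }
  placed <- if (length(out)) do.call(rbind, out)
  else data.frame(id = integer(0), center_row = numeric(0),
                  center_col = numeric(0), radius = numeric(0),
                  region = character(0), stringsAsFactors = FALSE)
  K <- nrow(placed)
  frac <- spec$true_pos_frac
  placed$nuc_positive <- if (K) runif(K) < frac[cbind(placed$region, "nucleus")] else logical(0)
  placed$cyt_positive <- if (K) runif(K) < frac[cbind(placed$region, "cytoplasm")] else logical(0)
  placed
}

#' @noRd
trunc_radius <- function(spec) {
  repeat {
    r <- rnorm(1, spec$radius_mean, spec$radius_sd)
    if (abs(r - spec$radius_mean) <= 3 * spec$radius_sd) break
  }
  max(r, 3)
}

# Is the disc of the given margin around (cr, cc) entirely inside the region?
# Checked on the four compass points plus the center (exact for half-plane
# region boundaries, conservative for polygons).
#' @noRd
region_clear <- function(mask, val, cr, cc, margin) {
  pts <- rbind(c(cr, cc),
               c(cr - margin, cc), c(cr + margin, cc),
               c(cr, cc - margin), c(cr, cc + margin),
               c(cr - margin / sqrt(2), cc - margin / sqrt(2)),
               c(cr - margin / sqrt(2), cc + margin / sqrt(2)),
               c(cr + margin / sqrt(2), cc - margin / sqrt(2)),
               c(cr + margin / sqrt(2), cc + margin / sqrt(2)))
  pr <- round(pts[, 1]); pc <- round(pts[, 2])
  if (any(pr < 1 | pr > nrow(mask) | pc < 1 | pc > ncol(mask))) return(FALSE)
  all(mask[cbind(pr, pc)] == val)
}

# ---- cohort generator -----------------------------------------------------

#' @noRd
default_marker_means <- function() {
  # percent-positive location parameters per measurement
  c(cxcr3_nuc_gland = 45.3, cxcr3_cyt_gland = 32.4,
    cxcr3_nuc_inter = 15.0, cxcr3_cyt_inter = 1.6,
    cxcr4_nuc_gland = 14.9, cxcr4_cyt_gland = 16.7,
    cxcr4_nuc_inter = 5.1, cxcr4_cyt_inter = 0.9,
    cxcr7_nuc_gland = 58.2, cxcr7_cyt_gland = 30.5,
    cxcr7_nuc_inter = 39.3, cxcr7_cyt_inter = 7.6)
}

#' @noRd
default_marker_sds <- function() {
  # between-patient SDs on the percent scale (standard errors at n = 55
  # scaled up by sqrt(55))
  se <- c(cxcr3_nuc_gland = 4.0, cxcr3_cyt_gland = 3.4,
          cxcr3_nuc_inter = 2.0, cxcr3_cyt_inter = 0.3,
          cxcr4_nuc_gland = 2.0, cxcr4_cyt_gland = 2.3,
          cxcr4_nuc_inter = 1.0, cxcr4_cyt_inter = 0.3,
          cxcr7_nuc_gland = 3.9, cxcr7_cyt_gland = 3.0,
          cxcr7_nuc_inter = 4.0, cxcr7_cyt_inter = 1.6)
  se * sqrt(55)
}

#' @noRd
default_group_effects <- function() {
  # additive shifts (percent points) applied to the marker mean of patients
  # in the named category, mirroring the direction of reported associations
  data.frame(
    variable = c("t34", "t34", "t34", "node_pos", "inv_high", "inv_high",
                 "inv_high"),
    column = c("cxcr3_cyt_gland", "cxcr3_cyt_inter", "cxcr3_nuc_inter",
               "cxcr4_cyt_gland", "cxcr3_cyt_gland", "cxcr7_nuc_gland",
               "cxcr7_cyt_gland"),
    shift = c(10, 3, 4, 8, 8, 8, 8),
    stringsAsFactors = FALSE)
}

#' @noRd
default_os_loghr <- function() {
  # per-unit log hazard ratios (markers per percent point)
  c(sex_male = 0.4, t34 = 0.7, node_pos = 0.7,
    cxcr4_nuc_gland = 0.02, cxcr4_cyt_gland = 0.02, cxcr7_nuc_gland = 0.015)
}

#' Specification of a synthetic patient cohort
#'
#' @param n_patients cohort size (default 55).
#' @param marker_mean,marker_sd named length-12 vectors of percent-scale
#'   means and between-patient SDs for the marker measurements (names as in
#'   [marker_columns()]).
#' @param compartment_cor within-patient correlation between the nuclear and
#'   cytoplasmic value of the same marker and region.
#' @param group_effects data frame `variable, column, shift`: additive
#'   percent-point shift on `column` for patients in the category named by
#'   `variable` (`sex_male`, `t34`, `node_pos`, `tnm_advanced`, `diff_high`,
#'   `inv_high`). `NULL` disables group effects.
#' @param sex_male_prev,t_probs,n_probs,tnm_probs,diff_probs,inv_probs
#'   category prevalences (probability vectors over the score levels).
#' @param os_base_rate exponential baseline hazard for overall survival,
#'   events per month.
#' @param dfs_rate_ratio progression hazard as a multiple of `os_base_rate`.
#' @param os_loghr named log-hazard-ratio vector over covariates
#'   (binary categories and marker columns; markers per percent point).
#' @param dfs_extra_loghr additional log-HRs applied to the progression
#'   hazard only.
#' @param censoring_rate target fraction of OS times censored.
#' @param seed integer RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 55,
                        marker_mean = default_marker_means(),
                        marker_sd = default_marker_sds(),
                        compartment_cor = 0.8,
                        group_effects = default_group_effects(),
                        sex_male_prev = 0.4,
                        t_probs = c(0.1, 0.2, 0.4, 0.3),
                        n_probs = c(0.45, 0.3, 0.15, 0.1),
                        tnm_probs = c(0.05, 0.15, 0.3, 0.3, 0.2),
                        diff_probs = c(0.25, 0.5, 0.25),
                        inv_probs = c(0.3, 0.4, 0.3),
                        os_base_rate = log(2) / 20,
                        dfs_rate_ratio = 1.3,
                        os_loghr = default_os_loghr(),
                        dfs_extra_loghr = c(cxcr3_nuc_gland = 0.01),
                        censoring_rate = 0.3,
                        seed = 0) {
  if (n_patients < 2) err_validation("n_patients must be >= 2")
  if (any(marker_sd <= 0)) err_validation("marker_sd values must be positive")
  for (p in list(sex_male_prev, censoring_rate))
    if (p <= 0 || p >= 1) err_validation("prevalences/rates must lie in (0, 1)")
  if (compartment_cor < 0 || compartment_cor >= 1)
    err_validation("compartment_cor must lie in [0, 1)")
  stopifnot(setequal(names(marker_mean), marker_columns()),
            setequal(names(marker_sd), marker_columns()))
  structure(list(n_patients = as.integer(n_patients),
                 marker_mean = marker_mean[marker_columns()],
                 marker_sd = marker_sd[marker_columns()],
                 compartment_cor = compartment_cor,
                 group_effects = group_effects,
                 sex_male_prev = sex_male_prev, t_probs = t_probs,
                 n_probs = n_probs, tnm_probs = tnm_probs,
                 diff_probs = diff_probs, inv_probs = inv_probs,
                 os_base_rate = os_base_rate, dfs_rate_ratio = dfs_rate_ratio,
                 os_loghr = os_loghr, dfs_extra_loghr = dfs_extra_loghr,
                 censoring_rate = censoring_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Null-cohort specification: every effect zero
#'
#' Convenience wrapper around [cohort_spec()] for calibration studies: all
#' 12 measurements share one mean and SD (so every paired contrast is a true
#' null with exchangeable, symmetric differences), group shifts are disabled
#' and all log hazard ratios are zero.
#'
#' @param mean_level,sd_level common percent-scale mean and SD.
#' @param ... passed to [cohort_spec()].
#' @export
cohort_spec_null <- function(mean_level = 30, sd_level = 15, ...) {
  cohort_spec(marker_mean = setNames(rep(mean_level, 12), marker_columns()),
              marker_sd = setNames(rep(sd_level, 12), marker_columns()),
              group_effects = NULL,
              os_loghr = c(sex_male = 0), dfs_extra_loghr = numeric(0), ...)
}

#' Generate a synthetic patient cohort
#'
#' Draws clinicopathological categories by prevalence, marker measurements
#' from correlated truncated normals (clipped to \[0, 100\]) with the
#' configured group shifts, and OS/DFS times from an exponential
#' proportional-hazards model with independent exponential censoring tuned
#' to the target censoring fraction. Fully reproducible from the seed.
#'
#' @param spec a [cohort_spec()].
#' @return data frame, one row per patient, with the schema of
#'   [validate_cohort()].
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    sex <- ifelse(runif(n) < spec$sex_male_prev, "male", "female")
    t_score <- sample.int(4, n, replace = TRUE, prob = spec$t_probs)
    n_score <- sample.int(length(spec$n_probs), n, replace = TRUE,
                          prob = spec$n_probs) - 1L
    tnm <- sample.int(5, n, replace = TRUE, prob = spec$tnm_probs) - 1L
    differentiation <- sample.int(3, n, replace = TRUE, prob = spec$diff_probs)
    invasion <- sample.int(3, n, replace = TRUE, prob = spec$inv_probs)
    age <- round(rnorm(n, 60, 10))

    cat_flags <- data.frame(
      sex_male = as.integer(sex == "male"),
      t34 = as.integer(t_score >= 3),
      node_pos = as.integer(n_score > 0),
      tnm_advanced = as.integer(tnm >= 3),
      diff_high = as.integer(differentiation > median(differentiation)),
      inv_high = as.integer(invasion > median(invasion)))

    markers <- matrix(NA_real_, n, 12,
                      dimnames = list(NULL, marker_columns()))
    rho <- spec$compartment_cor
    for (m in c("cxcr3", "cxcr4", "cxcr7")) for (rg in c("gland", "inter")) {
      z <- rnorm(n)  # shared latent per marker x region
      for (cp in c("nuc", "cyt")) {
        col <- sprintf("%s_%s_%s", m, cp, rg)
        mu <- rep(spec$marker_mean[[col]], n)
        if (!is.null(spec$group_effects) && nrow(spec$group_effects)) {
          ge <- spec$group_effects[spec$group_effects$column == col, ,
                                   drop = FALSE]
          # shifts are centered on the category flag so the marginal mean of
          # the measurement stays at marker_mean while the between-group
          # difference equals the configured shift
          for (i in seq_len(nrow(ge))) {
            fl <- cat_flags[[ge$variable[i]]]
            mu <- mu + ge$shift[i] * (fl - mean(fl))
          }
        }
        e <- rnorm(n)
        v <- mu + spec$marker_sd[[col]] * (sqrt(rho) * z + sqrt(1 - rho) * e)
        markers[, col] <- pmin(pmax(v, 0), 100)
      }
    }

    lp_os <- linear_predictor(spec$os_loghr, cat_flags, markers,
                              spec$marker_mean)
    lp_dfs <- lp_os + linear_predictor(spec$dfs_extra_loghr, cat_flags,
                                       markers, spec$marker_mean)
    rate_os <- spec$os_base_rate * exp(lp_os)
    t_death <- rexp(n, rate_os)
    t_prog <- rexp(n, spec$os_base_rate * spec$dfs_rate_ratio * exp(lp_dfs))
    t_dfs <- pmin(t_prog, t_death)
    # censor rate mu solving mean_i mu / (rate_i + mu) = target
    target <- spec$censoring_rate
    mu_c <- uniroot(function(mu) mean(mu / (rate_os + mu)) - target,
                    lower = 1e-8, upper = 1e4 * max(rate_os))$root
    cens <- rexp(n, mu_c)

    data.frame(patient_id = sprintf("P%03d", seq_len(n)),
               sex = sex, age = age,
               differentiation = differentiation, invasion = invasion,
               t_score = t_score, n_score = n_score, tnm = tnm,
               os_months = pmin(t_death, cens),
               os_event = as.integer(t_death <= cens),
               dfs_months = pmin(t_dfs, cens),
               dfs_event = as.integer(t_dfs <= cens),
               as.data.frame(markers),
               stringsAsFactors = FALSE)
  })
}

# Linear predictor with covariates centered at their generative location, so
# the baseline hazard refers to an average patient.
#' @noRd
linear_predictor <- function(loghr, cat_flags, markers, marker_mean) {
  lp <- numeric(nrow(cat_flags))
  for (nm in names(loghr)) {
    b <- loghr[[nm]]
    if (b == 0) next
    if (nm %in% names(cat_flags)) {
      lp <- lp + b * (cat_flags[[nm]] - mean(cat_flags[[nm]]))
    } else if (nm %in% colnames(markers)) {
      lp <- lp + b * (markers[, nm] - marker_mean[[nm]])
    } else {
      err_validation("unknown covariate \"%s\" in log-HR vector", nm)
    }
  }
  lp
}
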