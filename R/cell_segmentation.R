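# Nuclei detection in the hematoxylin concentration channel and geometric
# construction of per-cell cytoplasm rings. The detector is a deterministic
# classical pipeline: Gaussian smoothing, global threshold (Otsu or fixed),
# hole filling, area filtering, then a distance-transform watershed to split
# touching nuclei. Images are plain R matrices indexed (row, col).

#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian smoothing sigma in pixels (0 disables).
#' @param threshold_method `"otsu"` (global Otsu on the smoothed channel) or
#'   `"fixed"` (use `fixed_threshold`).
#' @param fixed_threshold foreground threshold in OD-equivalent concentration
#'   units, used when `threshold_method = "fixed"`.
#' @param min_area,max_area nucleus area bounds in pixels^2; components (and
#'   post-split fragments) outside the bounds are dropped.
#' @param seed_min_distance minimum separation of watershed seed maxima, px.
#' @param ring_width cytoplasm ring width in pixels.
#' @param exclude_border drop nuclei touching the image border.
#' @return a list of class `seg_params`.
#' @export
seg_params <- function(smooth_sigma = 1.5,
                       threshold_method = c("otsu", "fixed"),
                       fixed_threshold = 0.3,
                       min_area = 30,
                       max_area = 1500,
                       seed_min_distance = 7,
                       ring_width = 4,
                       exclude_border = TRUE) {
  threshold_method <- match.arg(threshold_method)
  if (!is.numeric(smooth_sigma) || smooth_sigma < 0)
    err_parameter("smooth_sigma must be >= 0")
  if (!is.numeric(min_area) || !is.numeric(max_area) || min_area >= max_area)
    err_parameter("need min_area < max_area")
  if (!is.numeric(seed_min_distance) || seed_min_distance < 1)
    err_parameter("seed_min_distance must be >= 1")
  if (!is.numeric(ring_width) || ring_width < 1)
    err_parameter("ring_width must be >= 1")
  structure(list(smooth_sigma = smooth_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area = min_area, max_area = max_area,
                 seed_min_distance = seed_min_distance,
                 ring_width = ring_width,
                 exclude_border = isTRUE(exclude_border)),
            class = "seg_params")
}

#' Detect nuclei in a hematoxylin concentration channel
#'
#' Pipeline: Gaussian smooth, threshold to foreground, fill holes, drop
#' components outside `[min_area, max_area]`, Euclidean distance transform,
#' local-maximum seeds with minimum separation `seed_min_distance`, seeded
#' watershed split, relabel contiguously in raster order. Fully deterministic.
#'
#' @param hema numeric matrix of non-negative hematoxylin concentrations.
#' @param params a [seg_params()] object.
#' @return integer label matrix (0 = background, 1..K = nuclei).
#' @export
segment_nuclei <- function(hema, params = seg_params()) {
  if (!is.matrix(hema) || !is.numeric(hema) || any(hema < 0))
    err_format("hema must be a non-negative numeric matrix")
  stopifnot(inherits(params, "seg_params"))
  sm <- if (params$smooth_sigma > 0)
    EBImage::gblur(hema, sigma = params$smooth_sigma) else hema
  if (max(sm) <= 0) return(matrix(0L, nrow(hema), ncol(hema)))
  thr <- switch(params$threshold_method,
                otsu  = EBImage::otsu(EBImage::Image(sm), range = c(0, max(sm))),
                fixed = params$fixed_threshold)
  fg <- sm > thr
  if (!any(fg)) return(matrix(0L, nrow(hema), ncol(hema)))
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::bwlabel(fg)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  if (length(keep) == 0) return(matrix(0L, nrow(hema), ncol(hema)))
  fg <- matrix(lab %in% keep, nrow(hema), ncol(hema)) & lab > 0
  lab <- watershed_split(fg, params$seed_min_distance)
  # post-split fragments must still satisfy the nucleus-area contract
  areas <- tabulate(lab[lab > 0])
  drop <- which(areas < params$min_area | areas > params$max_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel_raster(lab)
}

# Seeded watershed: distance-transform local maxima (non-maximum suppression
# over a disc of radius seed_min_distance) grown as a spatial Voronoi
# partition restricted to the foreground.
#' @noRd
watershed_split <- function(fg, seed_min_distance) {
  dm <- EBImage::distmap(fg)
  r <- ceiling(seed_min_distance)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  dmax <- EBImage::dilate(dm, brush)
  seeds_mask <- fg & (dm >= dmax - 1e-7)
  seeds <- EBImage::bwlabel(seeds_mask)
  ws <- EBImage::propagate(dm, seeds, mask = fg, lambda = 1e8)
  storage.mode(ws) <- "integer"
  matrix(ws, nrow(fg), ncol(fg))
}

# Relabel 1..K by first occurrence in column-major (raster) order.
#' @noRd
relabel_raster <- function(lab) {
  ids <- unique(lab[lab > 0])
  if (length(ids) == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  storage.mode(out) <- "integer"
  out
}

#' Construct disjoint cytoplasm rings around labelled nuclei
#'
#' The cytoplasm of nucleus `k` is the set of non-nucleus pixels within
#' Euclidean distance `ring_width` of nucleus `k`; pixels reachable from
#' several nuclei go to the nearest one (ties to the lower label id). Rings
#' are clipped at image borders and exclude every nucleus pixel of any cell.
#'
#' @param labels integer nucleus label matrix from [segment_nuclei()].
#' @param ring_width ring width in pixels (>= 1).
#' @return integer matrix of the same shape: 0 = no cytoplasm, k = ring of
#'   nucleus k.
#' @export
make_cytoplasm_rings <- function(labels, ring_width = 4) {
  if (!is.matrix(labels) || any(labels < 0))
    err_format("labels must be a non-negative integer matrix")
  if (!is.numeric(ring_width) || length(ring_width) != 1 || ring_width < 1)
    err_parameter("ring_width must be >= 1")
  nr <- nrow(labels); nc <- ncol(labels)
  K <- max(labels)
  ring <- matrix(0L, nr, nc)
  if (K == 0) return(ring)
  best <- matrix(Inf, nr, nc)
  w <- ceiling(ring_width)
  nucleus_any <- labels > 0
  for (k in seq_len(K)) {
    px <- which(labels == k, arr.ind = TRUE)
    if (nrow(px) == 0) next
    r0 <- max(1L, min(px[, 1]) - w); r1 <- min(nr, max(px[, 1]) + w)
    c0 <- max(1L, min(px[, 2]) - w); c1 <- min(nc, max(px[, 2]) + w)
    sub <- labels[r0:r1, c0:c1, drop = FALSE]
    # distance of every window pixel to nucleus k (exact Euclidean)
    d <- EBImage::distmap(matrix(as.numeric(sub != k), nrow(sub), ncol(sub)))
    cand <- d > 0 & d <= ring_width & !nucleus_any[r0:r1, c0:c1]
    if (!any(cand)) next
    bb <- best[r0:r1, c0:c1]
    upd <- cand & (d < bb - 1e-9)   # strict: equal distance keeps lower id
    if (any(upd)) {
      bb[upd] <- d[upd]
      best[r0:r1, c0:c1] <- bb
      rr <- ring[r0:r1, c0:c1]
      rr[upd] <- k
      ring[r0:r1, c0:c1] <- rr
    }
  }
  ring
}

#' Assign each nucleus to a tissue region by majority vote
#'
#' A cell is `glandular` or `interstitial` when a strict majority of its
#' nucleus pixels carries that mask value; a majority of unannotated pixels
#' or an exact tie yields `excluded`.
#'
#' @param labels integer nucleus label matrix.
#' @param mask region mask matrix with values 0 (unannotated), 1 (glandular),
#'   2 (interstitial).
#' @return character vector of length K with values
#'   `"glandular"`, `"interstitial"`, `"excluded"`, in label order.
#' @export
assign_regions <- function(labels, mask) {
  check_region_mask(mask)
  if (!identical(dim(labels), dim(mask)))
    err_format("labels and mask dimensions disagree")
  K <- max(labels)
  if (K == 0) return(character(0))
  sel <- labels > 0
  counts <- table(factor(labels[sel], levels = seq_len(K)),
                  factor(mask[sel], levels = 0:2))
  vapply(seq_len(K), function(k) {
    n0 <- counts[k, 1]; n1 <- counts[k, 2]; n2 <- counts[k, 3]
    tot <- n0 + n1 + n2
    if (n1 > tot / 2) "glandular"
    else if (n2 > tot / 2) "interstitial"
    else "excluded"
  }, character(1))
}

#' @noRd
check_region_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% 0:2))
    err_format("region mask must be a matrix with values in {0, 1, 2}")
  invisible(TRUE)
}

#' Assemble per-cell records from labels, rings and a region mask
#'
#' @param labels nucleus label matrix from [segment_nuclei()].
#' @param rings cytoplasm label matrix from [make_cytoplasm_rings()].
#' @param mask region mask (values 0/1/2), same shape.
#' @param params a [seg_params()] object (`exclude_border` is honoured here).
#' @return an object of class `ihc_cells`: a list with the (relabelled)
#'   `nucleus_labels` and `cytoplasm_labels` matrices and a data frame
#'   `cells` with columns `id`, `centroid_row`, `centroid_col`,
#'   `nucleus_area`, `cytoplasm_area`, `region`.
#' @export
extract_cells <- function(labels, rings, mask, params = seg_params()) {
  if (!identical(dim(labels), dim(rings)) || !identical(dim(labels), dim(mask)))
    err_format("labels, rings and mask dimensions disagree")
  check_region_mask(mask)
  nr <- nrow(labels); nc <- ncol(labels)
  K <- max(labels)
  if (K > 0 && params$exclude_border) {
    border_ids <- unique(c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc]))
    border_ids <- border_ids[border_ids > 0]
    if (length(border_ids)) {
      labels[labels %in% border_ids] <- 0L
      rings[rings %in% border_ids] <- 0L
      relab <- relabel_raster(labels)
      map <- integer(max(c(labels, rings, 1L)))
      nz <- which(labels > 0)
      map[labels[nz]] <- relab[nz]
      rings[rings > 0] <- map[rings[rings > 0]]
      labels <- relab
      K <- max(labels)
    }
  }
  if (K == 0) {
    cells <- data.frame(id = integer(0), centroid_row = numeric(0),
                        centroid_col = numeric(0), nucleus_area = integer(0),
                        cytoplasm_area = integer(0), region = character(0),
                        stringsAsFactors = FALSE)
    return(structure(list(nucleus_labels = labels, cytoplasm_labels = rings,
                          cells = cells), class = "ihc_cells"))
  }
  sel <- which(labels > 0)
  ids <- labels[sel]
  rows <- (sel - 1) %% nr + 1
  cols <- (sel - 1) %/% nr + 1
  n_area <- tabulate(ids, K)
  c_area <- tabulate(rings[rings > 0], K)
  cen_r <- as.numeric(rowsum(rows - 1, ids)) / n_area  # 0-based coordinates
  cen_c <- as.numeric(rowsum(cols - 1, ids)) / n_area
  region <- assign_regions(labels, mask)
  cells <- data.frame(id = seq_len(K), centroid_row = cen_r,
                      centroid_col = cen_c, nucleus_area = n_area,
                      cytoplasm_area = c_area, region = region,
                      stringsAsFactors = FALSE)
  structure(list(nucleus_labels = labels, cytoplasm_labels = rings,
                 cells = cells), class = "ihc_cells")
}

#' @export
print.ihc_cells <- function(x, ...) {
  cat(sprintf("<ihc_cells> %d cells on a %dx%d image (%s)\n",
              nrow(x$cells), nrow(x$nucleus_labels), ncol(x$nucleus_labels),
              paste(sprintf("%s: %d", names(table(x$cells$region)),
                            as.integer(table(x$cells$region))), collapse = ", ")))
  invisible(x)
}
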