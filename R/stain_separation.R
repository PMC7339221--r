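# Beer-Lambert colour deconvolution of H-DAB stained brightfield images.
#
# Transmitted-light intensity relates to stain amount through
#   I_c = i0_c * 10^(-OD_c),  OD = M' %*% conc
# where M holds one unit-length optical-density vector per stain
# (hematoxylin, DAB, residual) and conc the per-pixel stain concentrations.
# Unmixing is the 3x3 linear solve conc = solve(M') %*% od per pixel, with
# negative components clamped to zero.

#' Convert an 8-bit RGB image to optical density
#'
#' Applies the Beer-Lambert transform `OD_c = -log10(max(I_c, eps) / i0_c)`
#' per channel. Saturated-dark pixels are floored at `eps_intensity` so the
#' OD stays finite.
#'
#' @param img numeric or integer array `H x W x 3` with values in 0..255
#'   (8-bit RGB).
#' @param i0 per-channel white reference (length 1 or 3), default 255.
#' @param eps_intensity intensity floor in (0, 1]; default 1 (the 8-bit floor).
#' @return numeric array `H x W x 3` of non-negative base-10 optical densities.
#' @examples
#' img <- array(255L, c(2, 2, 3))
#' rgb_to_od(img)  # all zero: white absorbs nothing
#' @export
rgb_to_od <- function(img, i0 = 255, eps_intensity = 1) {
  check_rgb_image(img)
  if (!is.numeric(i0) || !length(i0) %in% c(1L, 3L) || any(i0 <= 0))
    err_format("i0 must be a positive per-channel white reference (length 1 or 3)")
  if (!is.numeric(eps_intensity) || length(eps_intensity) != 1 ||
      eps_intensity <= 0 || eps_intensity > 1)
    err_format("eps_intensity must be in (0, 1]")
  i0 <- rep_len(as.numeric(i0), 3L)
  od <- array(0, dim(img))
  for (c in 1:3) od[, , c] <- -log10(pmax(img[, , c], eps_intensity) / i0[c])
  od
}

#' @noRd
check_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    err_format("expected an H x W x 3 RGB array")
  if (!is.numeric(img) || anyNA(img) || any(img < 0) || any(img > 255))
    err_format("expected 8-bit channel values in [0, 255]")
  invisible(TRUE)
}

#' Build a 3-stain unmixing matrix from hematoxylin and DAB OD vectors
#'
#' Rows 1-2 are the normalised inputs; row 3 (the residual channel) is the
#' normalised cross product, completing a full-rank basis.
#'
#' @param h_vec,d_vec length-3 optical-density direction vectors for
#'   hematoxylin and DAB. Defaults are the Ruifrok-Johnston H-DAB constants.
#' @return 3x3 numeric matrix with unit-norm rows named
#'   `hematoxylin`, `dab`, `residual`.
#' @export
build_stain_matrix <- function(h_vec = c(0.650, 0.704, 0.286),
                               d_vec = c(0.268, 0.570, 0.776)) {
  if (length(h_vec) != 3 || length(d_vec) != 3 ||
      !is.numeric(h_vec) || !is.numeric(d_vec))
    err_format("stain vectors must be numeric of length 3")
  nh <- sqrt(sum(h_vec^2)); nd <- sqrt(sum(d_vec^2))
  if (nh == 0 || nd == 0) err_degeneracy("stain vectors must be non-zero")
  h <- h_vec / nh; d <- d_vec / nd
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  nr <- sqrt(sum(r^2))
  if (nr < 1e-9) err_degeneracy("hematoxylin and DAB vectors are collinear")
  m <- rbind(hematoxylin = h, dab = d, residual = r / nr)
  if (kappa(m, exact = TRUE) >= 1e6)
    err_degeneracy("stain matrix is ill-conditioned")
  m
}

#' Default Ruifrok-Johnston H-DAB stain matrix
#' @return 3x3 stain matrix (see [build_stain_matrix()]).
#' @export
hdab_stain_matrix <- function() build_stain_matrix()

#' Unmix an OD image into per-stain concentration maps
#'
#' Per pixel solves `od = t(m) %*% conc` for the concentration vector and
#' clamps negative components to zero.
#'
#' @param od numeric array `H x W x 3` of optical densities.
#' @param m 3x3 stain matrix (rows = stain OD vectors).
#' @return numeric array `H x W x 3` of non-negative concentrations in
#'   channel order (hematoxylin, dab, residual).
#' @export
deconvolve <- function(od, m = hdab_stain_matrix()) {
  check_od_array(od)
  check_stain_matrix(m)
  d <- dim(od)
  flat <- matrix(od, ncol = 3)            # pixels x channels
  conc <- flat %*% t(solve(t(m)))         # = solve(t(m), od) per pixel
  conc[conc < 0] <- 0
  array(conc, d)
}

#' Reconstruction error of a deconvolution
#'
#' Maximum absolute per-pixel difference between the observed OD and the
#' stain-composed reconstruction `t(m) %*% conc`. A quality-control metric:
#' large values signal out-of-gamut colours or a wrong stain basis.
#'
#' @inheritParams deconvolve
#' @param conc concentration array `H x W x 3` as returned by [deconvolve()].
#' @return a single non-negative number.
#' @export
reconstruction_error <- function(od, m, conc) {
  check_od_array(od)
  check_stain_matrix(m)
  if (!is.array(conc) || !identical(dim(conc), dim(od)))
    err_format("conc and od dimensions disagree")
  recon <- matrix(conc, ncol = 3) %*% m
  max(abs(recon - matrix(od, ncol = 3)))
}

#' Compose concentrations back to an 8-bit RGB image
#'
#' Inverse of [rgb_to_od()] + [deconvolve()]: `I_c = i0_c * 10^(-(t(m) conc)_c)`,
#' optionally with additive Gaussian pixel noise, clamped to \[0, 255\] and
#' quantised to whole 8-bit levels. Used by the synthetic-core renderer.
#'
#' @inheritParams reconstruction_error
#' @param i0 per-channel white reference (length 1 or 3).
#' @param noise_sd Gaussian pixel-noise standard deviation in intensity units.
#' @return integer array `H x W x 3` in 0..255.
#' @export
compose_rgb <- function(conc, m = hdab_stain_matrix(), i0 = 255, noise_sd = 0) {
  check_stain_matrix(m)
  if (!is.array(conc) || length(dim(conc)) != 3 || dim(conc)[3] != 3)
    err_format("expected an H x W x 3 concentration array")
  i0 <- rep_len(as.numeric(i0), 3L)
  od <- matrix(conc, ncol = 3) %*% m
  img <- sweep(10^(-od), 2, i0, `*`)
  if (noise_sd > 0) img <- img + rnorm(length(img), sd = noise_sd)
  img <- round(pmin(pmax(img, 0), 255))
  array(as.integer(img), dim(conc))
}

#' @noRd
check_od_array <- function(od) {
  if (!is.array(od) || length(dim(od)) != 3 || dim(od)[3] != 3 || !is.numeric(od))
    err_format("expected an H x W x 3 optical-density array")
  invisible(TRUE)
}

#' @noRd
check_stain_matrix <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(3L, 3L)) || !is.numeric(m))
    err_format("stain matrix must be numeric 3x3")
  norms <- sqrt(rowSums(m^2))
  if (any(abs(norms - 1) > 1e-9))
    err_format("stain matrix rows must have unit Euclidean norm")
  if (abs(det(m)) < .Machine$double.eps || kappa(m, exact = TRUE) >= 1e6)
    err_degeneracy("stain matrix is singular or ill-conditioned")
  invisible(TRUE)
}
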