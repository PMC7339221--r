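# Geometric fixtures are built in code: concentration fields with planted
# discs, scored through the real segmentation path.

draw_disc <- function(m, cr, cc, r, value = 1) {
  for (i in max(1, floor(cr - r)):min(nrow(m), ceiling(cr + r)))
    for (j in max(1, floor(cc - r)):min(ncol(m), ceiling(cc + r)))
      if ((i - cr)^2 + (j - cc)^2 <= r^2) m[i, j] <- value
  m
}

test_that("segment_nuclei finds isolated discs and returns empty on blank input", {
  expect_identical(max(segment_nuclei(matrix(0, 50, 50))), 0L)

  m <- matrix(0, 200, 200)
  centers <- rbind(c(40, 40), c(40, 120), c(100, 80), c(160, 40), c(160, 160))
  for (k in 1:5) m <- draw_disc(m, centers[k, 1], centers[k, 2], 8)
  lab <- segment_nuclei(m, seg_params())
  expect_identical(max(lab), 5L)
  areas <- tabulate(lab[lab > 0])
  expect_true(all(abs(areas - pi * 64) / (pi * 64) < 0.15))
})

test_that("watershed splits two overlapping discs near their true centers", {
  m <- matrix(0, 120, 120)
  m <- draw_disc(m, 60, 53, 10)
  m <- draw_disc(m, 60, 67, 10)
  lab <- segment_nuclei(m, seg_params())
  expect_identical(max(lab), 2L)
  for (k in 1:2) {
    px <- which(lab == k, arr.ind = TRUE)
    cen <- colMeans(px)
    d <- min(sqrt((cen[1] - 60)^2 + (cen[2] - 53)^2),
             sqrt((cen[1] - 60)^2 + (cen[2] - 67)^2))
    expect_lt(d, 3)
  }
})

test_that("segmentation is deterministic and respects area bounds", {
  set.seed(4)
  spec <- image_spec(height = 250, width = 500,
                     n_cells = c(glandular = 30, interstitial = 30), seed = 8)
  core <- gen_core_image(spec)
  hema <- deconvolve(rgb_to_od(core$img))[, , 1]
  l1 <- segment_nuclei(hema)
  l2 <- segment_nuclei(hema)
  expect_identical(l1, l2)
  areas <- tabulate(l1[l1 > 0])
  expect_true(all(areas >= seg_params()$min_area))
  expect_true(all(areas <= seg_params()$max_area))
})

test_that("cytoplasm rings have annulus area, clip at borders, stay disjoint", {
  lab <- matrix(0L, 101, 101)
  lab <- draw_disc(lab, 51, 51, 10, 1L)
  storage.mode(lab) <- "integer"
  ring <- make_cytoplasm_rings(lab, 4)
  expected <- oracle_annulus_area(10, 4)
  expect_lt(abs(sum(ring == 1) - expected) / expected, 0.10)
  expect_identical(sum(ring > 0 & lab > 0), 0L)   # never overlaps nuclei

  # nucleus at the corner: ring clipped in-bounds, no error
  lab2 <- matrix(0L, 40, 40)
  lab2 <- draw_disc(lab2, 2, 2, 6, 1L)
  storage.mode(lab2) <- "integer"
  ring2 <- make_cytoplasm_rings(lab2, 4)
  expect_true(sum(ring2 == 1) > 0)
  expect_true(sum(ring2 == 1) < oracle_annulus_area(6, 4))

  expect_error(make_cytoplasm_rings(lab, 0.5), class = "ihc_parameter_error")
})

test_that("contested ring pixels go to the nearest nucleus, ties to lower id", {
  lab <- matrix(0L, 60, 80)
  lab <- draw_disc(lab, 30, 25, 6, 1L)
  lab <- draw_disc(lab, 30, 41, 6, 2L)   # gap of 16 px between centers
  storage.mode(lab) <- "integer"
  ring <- make_cytoplasm_rings(lab, 4)
  px <- which(ring > 0, arr.ind = TRUE)
  d1 <- sqrt((px[, 1] - 30)^2 + (px[, 2] - 25)^2)
  d2 <- sqrt((px[, 1] - 30)^2 + (px[, 2] - 41)^2)
  owner <- ring[px]
  # distance to assigned disc never exceeds distance to the other disc
  expect_true(all((owner == 1 & d1 <= d2 + 1e-9) |
                  (owner == 2 & d2 <= d1 + 1e-9)))
  # exact mid-line pixels (equidistant) belong to cell 1
  mid <- abs(d1 - d2) < 1e-9
  expect_true(all(owner[mid] == 1))
})

test_that("region assignment follows strict majority with ties excluded", {
  mask <- matrix(0L, 30, 30)
  mask[, 1:15] <- 1L
  mask[, 16:30] <- 2L
  # fully glandular nucleus
  lab <- matrix(0L, 30, 30); lab <- draw_disc(lab, 15, 7, 4, 1L)
  storage.mode(lab) <- "integer"
  expect_identical(assign_regions(lab, mask), "glandular")
  # straddling 60/40: majority wins
  lab2 <- matrix(0L, 30, 30)
  lab2[10:19, 13:17] <- 1L   # 50 px: 3 columns glandular, 2 interstitial
  storage.mode(lab2) <- "integer"
  expect_identical(assign_regions(lab2, mask), "glandular")
  # exact 50/50 tie -> excluded
  lab3 <- matrix(0L, 30, 30)
  lab3[10:19, 14:17] <- 1L   # 2 columns each side
  storage.mode(lab3) <- "integer"
  expect_identical(assign_regions(lab3, mask), "excluded")
  # majority unannotated -> excluded
  mask0 <- matrix(0L, 30, 30); mask0[, 1:5] <- 1L
  expect_identical(assign_regions(lab, mask0), "excluded")
})

test_that("extract_cells drops border nuclei when asked and keeps invariants", {
  mask <- matrix(1L, 80, 80)
  lab <- matrix(0L, 80, 80)
  lab <- draw_disc(lab, 40, 40, 7, 1L)
  lab <- draw_disc(lab, 3, 40, 7, 2L)   # touches the top border
  storage.mode(lab) <- "integer"
  ring <- make_cytoplasm_rings(lab, 4)
  cells_excl <- extract_cells(lab, ring, mask, seg_params(exclude_border = TRUE))
  expect_identical(nrow(cells_excl$cells), 1L)
  cells_keep <- extract_cells(lab, ring, mask, seg_params(exclude_border = FALSE))
  expect_identical(nrow(cells_keep$cells), 2L)
  # nucleus/cytoplasm disjointness after relabelling
  nl <- cells_excl$nucleus_labels; cl <- cells_excl$cytoplasm_labels
  expect_identical(sum(nl > 0 & cl > 0), 0L)
  expect_error(extract_cells(lab, ring, matrix(1L, 10, 10), seg_params()),
               class = "ihc_format_error")
  # empty label image -> empty cell list
  empty <- extract_cells(matrix(0L, 20, 20), matrix(0L, 20, 20),
                         matrix(1L, 20, 20), seg_params())
  expect_identical(nrow(empty$cells), 0L)
})

test_that("planted cells are recovered with correct regions on synthetic cores", {
  spec <- image_spec(height = 300, width = 600,
                     n_cells = c(glandular = 60, interstitial = 60),
                     seed = 21)
  core <- gen_core_image(spec)
  conc <- deconvolve(rgb_to_od(core$img))
  lab <- segment_nuclei(conc[, , 1])
  ring <- make_cytoplasm_rings(lab, 4)
  cells <- extract_cells(lab, ring, core$mask, seg_params())
  expect_identical(nrow(cells$cells), nrow(core$truth$cells))
  # region recall: match each planted center to the detected label under it
  tr <- core$truth$cells
  det_lab <- lab[cbind(round(tr$center_row) + 1, round(tr$center_col) + 1)]
  expect_true(all(det_lab > 0))
  agree <- cells$cells$region[det_lab] == tr$region
  expect_gte(mean(agree), 0.99)
  # disjointness invariants hold exhaustively
  expect_identical(sum(cells$nucleus_labels > 0 & cells$cytoplasm_labels > 0), 0L)
})
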