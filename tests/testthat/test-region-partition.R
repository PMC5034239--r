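test_that("the 10 um band partition is exact on a rectangle and flags thin cells", {
  rect <- matrix(FALSE, 400, 400); rect[101:250, 101:350] <- TRUE  # 30 x 50 um
  part <- partition_cell(rect, band_width = 10, pixel_size = 0.2)
  expect_equal(part$central_area_um2, 300)     # 30 x 10 um core
  expect_equal(part$peripheral_area_um2, 1200)
  expect_identical(part$central_area_px + part$peripheral_area_px,
                   part$cell_area_px)
  expect_false(any(part$central & part$peripheral))
  expect_identical(part$central | part$peripheral, part$cell)

  disk <- simulate_cell_mask(c(120L, 120L), 0.2, "ellipse",
                             list(semi_axes = c(8, 8)))
  p2 <- partition_cell(disk, band_width = 10, pixel_size = 0.2)
  expect_true(p2$central_empty)
})

test_that("the distance-transform band equals the brute-force oracle exactly", {
  for (seed in 1:10) {
    blob <- random_blob(seed)
    part <- partition_cell(blob, band_width = 3, pixel_size = 0.5)
    oracle <- central_oracle(blob, 3, 0.5)
    expect_identical(part$central, oracle)
  }
})

test_that("widening the band never shrinks the peripheral mask", {
  blob <- random_blob(4)
  prev <- partition_cell(blob, band_width = 1, pixel_size = 0.5)
  for (bw in c(2, 3, 4.5)) {
    cur <- partition_cell(blob, band_width = bw, pixel_size = 0.5)
    expect_true(all(cur$peripheral | !prev$peripheral))
    prev <- cur
  }
})

test_that("peripheral signal splits masks and intensities additively", {
  rect <- matrix(FALSE, 200, 300); rect[51:150, 51:250] <- TRUE  # 20 x 40 um
  part <- partition_cell(rect, band_width = 5, pixel_size = 0.2)

  # all signal inside the band
  sig <- part$peripheral & rect
  ps1 <- peripheral_signal(sig, part)
  expect_equal(ps1$central, 0)
  expect_equal(ps1$peripheral, ps1$total)

  # uniform signal: peripheral share equals the band's area share
  ps2 <- peripheral_signal(rect, part)
  expect_equal(ps2$peripheral / ps2$total,
               part$peripheral_area_px / part$cell_area_px)

  # intensity images and out-of-cell signal
  img <- matrix(2, 200, 300)
  ps3 <- peripheral_signal(img, part)
  expect_equal(ps3$total, 2 * part$cell_area_px)
  expect_equal(ps3$out_of_cell, 2 * (200 * 300 - part$cell_area_px))
  expect_equal(ps3$peripheral + ps3$central, ps3$total)
})

test_that("marker area and adhesion ratios are exact on constructions", {
  cell <- matrix(FALSE, 120, 120); cell[11:110, 11:110] <- TRUE
  ves <- matrix(FALSE, 120, 120); ves[20:29, 20:39][1:200] <- TRUE
  expect_equal(rab_area_ratio(ves, cell), 200 / 10000)
  expect_equal(rab_area_ratio(ves & FALSE, cell), 0)

  lab <- matrix(0L, 120, 120)
  for (k in 1:10) lab[15 + 8 * k, 20:44][1:25] <- k
  fr <- fa_ratios(lab, cell, pixel_size = 0.2)
  expect_equal(fr$area_ratio, 250 / 10000)
  expect_equal(fr$count_ratio, 10 / (10000 * 0.04))
  expect_identical(fr$n_adhesions, 10L)
})

test_that("simulated vesicle coverage matches the truth-rendered mask", {
  ps <- 0.2
  acq <- acquisition_spec(n_frames = 2, pixel_size = ps,
                          image_shape = c(220L, 220L), psf_sigma = ps,
                          background_level = 5, poisson_scale = 1)
  cell <- simulate_cell_mask(c(220L, 220L), ps, "ellipse",
                             list(semi_axes = c(19, 15)))
  vf <- simulate_vesicle_field(cell, vesicle_field_spec(60, peripheral_bias = 0.5),
                               acq, seed = 8)
  m <- threshold_mask(vf$stack[1, , ], "otsu")
  ratio <- rab_area_ratio(m, cell)
  expect_gt(ratio, 0.01)
  expect_lt(ratio, 0.2)
})

test_that("per-adhesion vesicle intensity is grouped by the partition", {
  ps <- 0.2
  cell <- matrix(FALSE, 200, 200); cell[21:180, 21:180] <- TRUE  # 32 x 32 um
  part <- partition_cell(cell, band_width = 10, pixel_size = ps)

  # two peripheral and two central reference adhesions
  lab <- matrix(0L, 200, 200)
  lab[30:32, 60:64] <- 1L     # ~2 um from the top edge -> peripheral
  lab[60:62, 30:34] <- 2L     # 8 um from left edge -> peripheral
  lab[100:102, 100:104] <- 3L # centre -> central
  lab[110:112, 90:94] <- 4L   # centre -> central
  nb <- build_neighborhoods(lab, dilation_distance = 0.8, pixel_size = ps)

  img <- matrix(0, 200, 200)
  for (k in 1:4) {
    reg <- nb$regions[[k]]
    img[reg$dilated] <- if (k <= 2) 10 else 5   # 2x peripheral density
  }
  res <- per_fa_rab_intensity(img, nb, part)
  expect_identical(sort(res$per_adhesion$group),
                   c("central", "central", "peripheral", "peripheral"))
  ratio <- mean(res$peripheral) / mean(res$central)
  expect_equal(ratio, 2, tolerance = 0.05)

  # all signal at peripheral adhesions -> central group all zero
  img2 <- matrix(0, 200, 200)
  img2[nb$regions[[1]]$dilated] <- 7
  res2 <- per_fa_rab_intensity(img2, nb, part)
  expect_true(all(res2$central == 0))

  # a centroid exactly on the band boundary belongs to central (>= rule):
  # row 70 sits (50 - 0.5) * 0.2 = 9.9 um deep, exactly the band width
  part99 <- partition_cell(cell, band_width = 9.9, pixel_size = ps)
  labb <- matrix(0L, 200, 200)
  labb[70, 100] <- 1L
  nbb <- build_neighborhoods(labb, pixel_size = ps)
  resb <- per_fa_rab_intensity(matrix(1, 200, 200), nbb, part99)
  expect_identical(resb$per_adhesion$group, "central")
})
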