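test_that("ellipse cell mask has analytic area and blob generation is deterministic", {
  m <- simulate_cell_mask(c(300L, 300L), 0.2, "ellipse",
                          list(semi_axes = c(25, 15)))
  expect_equal(sum(m) * 0.2^2, pi * 25 * 15, tolerance = 0.02)
  lab <- label_regions(m)
  expect_identical(attr(lab, "n_labels"), 1L)

  b1 <- random_blob(7)
  b2 <- random_blob(7)
  expect_identical(b1, b2)

  expect_error(
    simulate_cell_mask(c(100L, 100L), 1, "ellipse", list(semi_axes = c(500, 10))),
    "exceeds the frame")
})

test_that("adhesion truth records the prescribed tip kinetics", {
  acq <- tiny_acq(n_frames = 15, shape = c(150L, 150L))
  cell <- small_cell(c(150L, 150L), semi_axes = c(12, 10))
  kin <- adhesion_kinetics(anchor = c(15, 15), axis_angle = 0,
                           v_assembly = 0.5, v_disassembly = 0.3,
                           t_appear = 0, t_halt_start = 10, t_halt_end = 12,
                           t_disappear = 14)
  sim <- simulate_adhesion_timelapse(cell, kin, acq, seed = 1)
  tt <- sim$truth$tips
  expect_equal(tt$distal_um[11] - tt$distal_um[1], 5.0)
  # distal series non-decreasing up to the halt, proximal non-decreasing after
  expect_true(all(diff(tt$distal_um[1:11]) >= 0))
  expect_true(all(diff(tt$proximal_um[13:15]) >= 0))
})

test_that("zero adhesions give a background-only stack and empty truth", {
  acq <- tiny_acq(n_frames = 3, background = 7)
  cell <- small_cell()
  sim <- simulate_adhesion_timelapse(cell, NULL, acq, seed = 1)
  expect_equal(max(abs(sim$stack - 7)), 0)
  expect_identical(nrow(sim$truth$tips), 0L)
})

test_that("anchors outside the cell are rejected", {
  acq <- tiny_acq()
  cell <- small_cell()
  kin <- adhesion_kinetics(anchor = c(1, 1), axis_angle = 0,
                           v_assembly = 0.5, v_disassembly = 0.3,
                           t_appear = 0, t_halt_start = 5, t_halt_end = 6,
                           t_disappear = 8)
  expect_error(simulate_adhesion_timelapse(cell, kin, acq), "outside the cell")
})

test_that("identical (spec, seed) reproduce stacks bit-identically and intensity is conserved", {
  acq <- tiny_acq(n_frames = 6, psf_sigma = 0, background = 2,
                  poisson_scale = 1, read_noise = 1.5)
  cell <- small_cell()
  kin <- sample_adhesion_field(cell, 3, 0.2, seed = 5,
                               length_range = c(1.5, 2.5))
  s1 <- simulate_adhesion_timelapse(cell, kin, acq, seed = 9)
  s2 <- simulate_adhesion_timelapse(cell, kin, acq, seed = 9)
  expect_identical(s1$stack, s2$stack)
  expect_identical(s1$truth$tips, s2$truth$tips)

  # conservation: noiseless, psf 0 -> total foreground intensity equals the
  # analytic ribbon area times peak intensity (sub-pixel coverage rendering)
  acq0 <- tiny_acq(n_frames = 6, background = 0)
  kin1 <- adhesion_kinetics(anchor = c(12, 12), axis_angle = pi / 6,
                            v_assembly = 0.4, v_disassembly = 0.2,
                            t_appear = 0, t_halt_start = 20, t_halt_end = 30,
                            t_disappear = 40, width = 0.6,
                            peak_intensity = 50)
  s0 <- simulate_adhesion_timelapse(cell, kin1, acq0, seed = 1)
  t_frame4 <- 3  # minutes; length = 0.4 * 3 = 1.2 um
  analytic <- 50 * (1.2 * 0.6) / 0.2^2
  expect_equal(sum(s0$stack[4, , ]), analytic, tolerance = 0.02)
})

test_that("half-max re-detection of ribbon extent reproduces truth tips within 1 px", {
  # brute-force per-frame scan along the known axis, noiseless
  acq <- tiny_acq(n_frames = 12, shape = c(150L, 150L), psf_sigma = 0.2)
  cell <- small_cell(c(150L, 150L), semi_axes = c(12, 10))
  kin <- adhesion_kinetics(anchor = c(12, 15), axis_angle = 0,
                           v_assembly = 0.6, v_disassembly = 0.3,
                           t_appear = 0, t_halt_start = 8, t_halt_end = 10,
                           t_disappear = 11, peak_intensity = 100)
  sim <- simulate_adhesion_timelapse(cell, kin, acq, seed = 1)
  ps <- 0.2
  for (f in c(4, 7, 9)) {
    img <- sim$stack[f, , ]
    s_grid <- seq(-2, 9, by = ps / 4)
    prof <- vapply(s_grid, function(s) {
      x <- 12 + s; y <- 15
      img[round(y / ps + 0.5), round(x / ps + 0.5)]
    }, numeric(1))
    thr <- max(prof) / 2
    run <- range(which(prof >= thr))
    tt <- sim$truth$tips[sim$truth$tips$frame == f, ]
    expect_lt(abs(s_grid[run[2]] - tt$distal_um), ps)
    expect_lt(abs(s_grid[run[1]] - tt$proximal_um), ps)
  }
})

test_that("vesicle placement follows the peripheral bias mixture", {
  ps <- 0.2
  acq <- tiny_acq(n_frames = 2, pixel_size = ps, shape = c(250L, 250L))
  cell <- simulate_cell_mask(c(250L, 250L), ps, "ellipse",
                             list(semi_axes = c(22, 16)))
  dist_um <- fadyn:::edge_distance_um(cell, ps)

  # bias 1: all centres within the 10 um band
  vf <- simulate_vesicle_field(cell, vesicle_field_spec(200, peripheral_bias = 1),
                               acq, seed = 2)
  t1 <- vf$truth[vf$truth$frame == 1, ]
  at <- cbind(ceiling(t1$y_um / ps), ceiling(t1$x_um / ps))
  expect_true(all(dist_um[at] < 10))

  # bias 0: band fraction matches exact band area within 3 binomial sd
  n <- 4000
  vf0 <- simulate_vesicle_field(cell, vesicle_field_spec(n, peripheral_bias = 0),
                                acq, seed = 3)
  t0 <- vf0$truth[vf0$truth$frame == 1, ]
  at0 <- cbind(ceiling(t0$y_um / ps), ceiling(t0$x_um / ps))
  p_hat <- mean(dist_um[at0] < 10)
  p_exp <- sum(cell & dist_um < 10) / sum(cell)
  expect_lt(abs(p_hat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))

  # n = 0: background-only channel, empty truth
  v0 <- simulate_vesicle_field(cell, vesicle_field_spec(0), acq, seed = 1)
  expect_identical(nrow(v0$truth), 0L)
  expect_equal(max(v0$stack), acq$background_level)
})

test_that("bias in a cell thinner than the band is rejected with advice", {
  acq <- tiny_acq(shape = c(120L, 120L))
  cell <- small_cell()  # 9 x 7 um: everywhere within 10 um of the edge
  expect_error(
    simulate_vesicle_field(cell, vesicle_field_spec(10, peripheral_bias = 0.5),
                           acq, seed = 1),
    "peripheral_bias = 0")
})

test_that("coloc triad realises exclusive combination counts exactly", {
  acq <- tiny_acq(shape = c(200L, 200L), background = 2, poisson_scale = 1,
                  psf_sigma = 0.2)
  cell <- simulate_cell_mask(c(200L, 200L), 0.2, "ellipse",
                             list(semi_axes = c(18, 14)))
  spec <- overlap_spec(counts = c(A = 100, AB = 40, ABC = 10))
  tri <- simulate_coloc_triad(cell, spec, acq, seed = 4)
  expect_identical(sum(tri$masks$A), 150L)
  expect_identical(unname(tri$truth$counts),
                   c(100L, 0L, 0L, 40L, 0L, 0L, 10L))
  # recomputing exclusive combinations from the emitted masks reproduces
  # the truth counts exactly
  ex <- exclusive_combinations(tri$masks$A, tri$masks$B, tri$masks$C)
  expect_identical(vapply(ex, sum, integer(1)), tri$truth$counts)

  # all-zero spec -> empty masks
  tri0 <- simulate_coloc_triad(cell, overlap_spec(counts = c(A = 0)), acq, 1)
  expect_false(any(tri0$masks$A | tri0$masks$B | tri0$masks$C))

  # infeasible packing errors with required vs available
  expect_error(
    simulate_coloc_triad(cell, overlap_spec(counts = c(A = 1e6)), acq, 1),
    "infeasible packing")
})
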