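make_ribbon_stack <- function(n_frames = 10, shape = c(120L, 120L),
                              value = 100) {
  # two stationary non-overlapping ribbons
  fr <- matrix(0, shape[1], shape[2])
  fr[40:42, 20:45] <- value
  fr[80:82, 60:85] <- value
  lapply(seq_len(n_frames), function(f) fr)
}

test_that("detection counts synthetic ribbons and ignores speckles", {
  acq <- tiny_acq(n_frames = 8, shape = c(260L, 260L), psf_sigma = 0.2,
                  background = 5)
  cell <- simulate_cell_mask(c(260L, 260L), 0.2, "ellipse",
                             list(semi_axes = c(23, 17)))
  kin <- sample_adhesion_field(cell, 12, 0.2, seed = 2,
                               length_range = c(1.5, 2.5),
                               v_assembly_range = c(0.5, 1))
  kin$t_appear[] <- 0; kin$t_halt_start[] <- 0.5
  kin$t_halt_end[] <- 7; kin$t_disappear[] <- 8
  sim <- simulate_adhesion_timelapse(cell, kin, acq, seed = 1)
  lab <- detect_adhesions(sim$stack[5, , ], min_area = 0.2, pixel_size = 0.2)
  expect_identical(attr(lab, "n_labels"), 12L)

  speck <- matrix(0, 50, 50); speck[25, 25] <- 100
  expect_identical(attr(detect_adhesions(speck, method = "fixed", value = 50,
                                         min_area = 0.2, pixel_size = 0.2),
                        "n_labels"), 0L)
})

test_that("tracking links stationary objects, bridges gaps and matches truth", {
  frames <- make_ribbon_stack(10)
  labs <- lapply(frames, function(f) label_regions(f > 50))
  tracks <- track_adhesions(labs, max_gap = 1)
  expect_length(tracks, 2)
  expect_true(all(vapply(tracks, function(t) length(t$frames) == 10,
                         logical(1))))
  expect_true(all(vapply(tracks, function(t) t$censored_start && t$censored_end,
                         logical(1))))

  # one-frame dropout bridged by max_gap = 1
  labs2 <- labs
  labs2[[5]] <- matrix(0L, 120, 120)
  tr2 <- track_adhesions(labs2, max_gap = 1)
  expect_length(tr2, 2)
  # without gap closing the dropout splits the tracks
  tr0 <- track_adhesions(labs2, max_gap = 0)
  expect_length(tr0, 4)
})

test_that("tracked lifetimes match simulator truth on a staggered field", {
  scn <- turnover_scenario(n_adhesions = 8, seed = 21,
                           image_shape = c(260L, 260L),
                           semi_axes = c(17, 13), n_frames = 45)
  m <- scn$matched
  expect_identical(nrow(m), 8L)
  expect_true(all(abs(m$rec_lifespan - m$true_lifespan) <= 1))
})

test_that("growth axis recovers orientation and distal direction", {
  acq <- tiny_acq(n_frames = 10, shape = c(200L, 200L), psf_sigma = 0.2,
                  background = 2)
  cell <- simulate_cell_mask(c(200L, 200L), 0.2, "ellipse",
                             list(semi_axes = c(17, 13)))
  # ribbon growing at 30 degrees toward the edge
  ang <- pi / 6
  ctr <- c(20, 20)
  anchor <- ctr + 9 * c(cos(ang), sin(ang))
  kin <- adhesion_kinetics(anchor = anchor, axis_angle = ang,
                           v_assembly = 0.4, v_disassembly = 0.2,
                           t_appear = 0, t_halt_start = 8, t_halt_end = 9,
                           t_disappear = 9.5)
  sim <- simulate_adhesion_timelapse(cell, kin, acq, seed = 1)
  res <- adhesion_dynamics_pipeline(sim$stack, cell, acq, min_track_frames = 4)
  expect_gte(length(res$per_track), 1)
  ax <- res$per_track[[1]]$axis
  expect_lt(abs(((ax$angle - ang + pi) %% (2 * pi)) - pi), 3 * pi / 180)
  expect_false(ax$clipped)

  # adhesion close to the image border: clipped flag set
  tr_border <- list(frames = 1:2,
                    footprints = list(c(5 * 200 + 10, 5 * 200 + 11),
                                      c(5 * 200 + 10, 5 * 200 + 11)),
                    centroids = matrix(c(10, 6, 11, 6), 2, byrow = TRUE),
                    dim = c(200L, 200L))
  axb <- growth_axis(tr_border, cell, 0.2)
  expect_true(axb$clipped)
})

test_that("kymograph sampling is calibrated and matches direct pixel reads", {
  img <- matrix(7, 100, 100)
  line <- list(p0 = c(2, 10), p1 = c(12, 10))
  ky <- extract_kymograph(list(img, img), line, width_avg = 3, pixel_size = 0.2)
  expect_identical(nrow(ky$matrix), 51L)   # 10 um at 0.2 um/px
  expect_true(all(ky$matrix == 7))

  # step edge: sampled profile tracks a nearest-neighbour read
  step_img <- matrix(0, 100, 100); step_img[, 41:100] <- 50
  kys <- extract_kymograph(list(step_img), list(p0 = c(4, 10), p1 = c(14, 10)),
                           width_avg = 1, pixel_size = 0.2)
  nn <- vapply(kys$positions_um + 4, function(x)
    step_img[50, max(1, round(x / 0.2 + 0.5))], numeric(1))
  expect_lt(max(abs(kys$matrix[, 1] - nn)), 25 + 1e-9)  # within one step height/2
  expect_equal(kys$matrix[c(1, 51), 1], nn[c(1, 51)])

  expect_error(extract_kymograph(list(img), list(p0 = c(5, 5), p1 = c(5, 5)),
                                 pixel_size = 0.2), "zero-length")
})

test_that("tip localisation finds half-max plateau edges and handles empty columns", {
  pos <- seq(0, 10, by = 0.2)
  col <- ifelse(pos >= 2 & pos <= 6, 100, 0)
  K <- cbind(col, col * 0)   # second frame empty
  ky <- structure(list(matrix = K, positions_um = pos, line = NULL,
                       pixel_size = 0.2), class = "kymograph")
  tp <- locate_tips(ky, background_level = 0)
  expect_equal(tp$proximal_um[1], 2, tolerance = 0.11)
  expect_equal(tp$distal_um[1], 6, tolerance = 0.11)
  expect_true(is.na(tp$distal_um[2]))

  ky0 <- structure(list(matrix = K * 0, positions_um = pos, line = NULL,
                        pixel_size = 0.2), class = "kymograph")
  expect_error(locate_tips(ky0, background_level = 0), "no adhesion on line")

  # two disjoint runs: the one nearest the previous tips is kept
  col2 <- ifelse(pos >= 2 & pos <= 4, 100, ifelse(pos >= 8 & pos <= 9, 90, 0))
  K2 <- cbind(col, col2)
  tp2 <- locate_tips(structure(list(matrix = K2, positions_um = pos,
                                    line = NULL, pixel_size = 0.2),
                               class = "kymograph"), 0)
  expect_lt(tp2$distal_um[2], 5)   # kept the run near the previous plateau
})

test_that("event segmentation recovers rates, halts and ignores jitter", {
  # distal tip: 4 um over 8 min then static 10 min
  t <- 0:18
  distal <- pmin(t * 0.5, 4)
  tips <- data.frame(frame = t + 1, distal_um = distal, proximal_um = 0)
  ev <- segment_events(tips, frame_interval = 1)
  ev_a <- ev[ev$kind == "assembly", ]
  expect_identical(nrow(ev_a), 1L)
  expect_equal(ev_a$rate, 0.5, tolerance = 1e-6)
  expect_equal(ev_a$delta_d, 4, tolerance = 1e-6)

  tr <- list(id = 1, frames = 1:19, first_frame = 1, last_frame = 19,
             censored_start = TRUE, censored_end = FALSE)
  met <- turnover_metrics(ev, tr, tiny_acq(n_frames = 30))
  expect_equal(met$assembly_rate, 0.5, tolerance = 1e-6)
  expect_equal(met$halt_time, 10, tolerance = 1)
  expect_equal(met$lifespan, 19)

  # sub-threshold jitter -> no events, all halt
  set.seed(4)
  jit <- data.frame(frame = 1:20, distal_um = 5 + rnorm(20, 0, 0.02),
                    proximal_um = 1 + rnorm(20, 0, 0.02))
  evj <- segment_events(jit, frame_interval = 1)
  expect_identical(nrow(evj), 0L)
  metj <- turnover_metrics(evj, list(id = 2, frames = 1:20, first_frame = 1,
                                     last_frame = 20, censored_start = TRUE,
                                     censored_end = FALSE),
                           tiny_acq(n_frames = 30))
  expect_equal(metj$halt_time, 20)
  expect_true(is.na(metj$assembly_rate))
})

test_that("per-track time accounting is conservative", {
  scn <- turnover_scenario(n_adhesions = 6, seed = 13,
                           image_shape = c(260L, 260L),
                           semi_axes = c(17, 13), n_frames = 50)
  for (pt in scn$result$per_track) {
    met <- turnover_metrics(pt$events, pt$track, scn$acq, tips = pt$tips)
    iv <- attr(pt$events, "moving_intervals")
    event_time <- if (is.null(iv) || nrow(iv) == 0) 0 else {
      iv <- iv[order(iv$t_start), , drop = FALSE]
      tot <- 0; cur <- c(iv$t_start[1], iv$t_end[1])
      for (i in seq_len(nrow(iv))[-1]) {
        if (iv$t_start[i] <= cur[2]) cur[2] <- max(cur[2], iv$t_end[i])
        else { tot <- tot + diff(cur); cur <- c(iv$t_start[i], iv$t_end[i]) }
      }
      tot + diff(cur)
    }
    expect_equal(event_time + met$halt_time + met$undefined_time,
                 met$lifespan, tolerance = 1e-8)
  }
})

test_that("noiseless parameter recovery stays within tight bounds", {
  scn <- turnover_scenario(n_adhesions = 10, seed = 17)
  m <- scn$matched
  expect_identical(nrow(m), 10L)
  expect_lt(max(abs(m$rec_assembly / m$true_assembly - 1)), 0.1)
  expect_lt(max(abs(m$rec_disassembly / m$true_disassembly - 1)), 0.1)
  expect_true(all(abs(m$rec_lifespan - m$true_lifespan) <= 1))
  expect_true(all(abs(m$rec_halt - m$true_halt) <= 2))
  # recovered distal directions all match the truth orientation
  expect_true(all(cos(m$rec_angle - m$true_angle) > 0))
})

test_that("adhesion density and peripheral region coverage are exact on constructions", {
  lab <- matrix(0L, 100, 100)
  for (k in 1:10) lab[(10 * k - 5):(10 * k - 1), 5:9][1:25] <- k
  cell <- matrix(TRUE, 100, 100)
  dens <- adhesion_density(lab, cell, pixel_size = 0.2)
  expect_identical(dens$count, 10L)
  expect_equal(dens$area_fraction, 250 / 10000)
  expect_equal(dens$count_per_um2, 10 / (10000 * 0.04))

  empty <- adhesion_density(matrix(0L, 10, 10), matrix(TRUE, 10, 10), 0.2)
  expect_identical(empty$count, 0L)
  expect_equal(empty$area_fraction, 0)

  # region half-covered by adhesions -> fraction 0.5
  cellb <- matrix(FALSE, 200, 200); cellb[21:180, 21:180] <- TRUE
  adh <- matrix(FALSE, 200, 200)
  anchor <- c(10, 4.0)  # on the top edge of the cell, um at 0.2 um/px
  # half of the 20x10 um region depth: fill the outer 5 um of the cell top
  adh[21:45, 21:180] <- TRUE
  pf <- peripheral_adhesion_fraction(adh, cellb, 0.2, region_size = c(20, 10),
                                     anchor_um = anchor)
  expect_equal(pf$fraction, 0.5, tolerance = 0.02)

  pf0 <- peripheral_adhesion_fraction(adh & FALSE, cellb, 0.2,
                                      anchor_um = anchor)
  expect_equal(pf0$fraction, 0)
})
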