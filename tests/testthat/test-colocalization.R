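test_that("neighbourhoods have the prescribed geometry", {
  # single 1 px reference at 0.1 um/px: 0.8 um dilation is an 8 px disc
  lab <- matrix(0L, 60, 60); lab[30, 30] <- 1L
  nb <- build_neighborhoods(lab, dilation_distance = 0.8, pixel_size = 0.1)
  expect_identical(nb$dilation_radius_px, 8L)
  dil <- matrix(FALSE, 60, 60); dil[nb$regions[[1]]$dilated] <- TRUE
  rc <- which(dil, arr.ind = TRUE)
  expect_lte(max(sqrt((rc[, 1] - 30)^2 + (rc[, 2] - 30)^2)), 8.5)

  # 5 x 4 um crop at 0.2 um/px covers a 25 x 20 px window
  lab2 <- matrix(0L, 80, 80); lab2[40, 38:42] <- 1L   # horizontal object
  nb2 <- build_neighborhoods(lab2, crop_size = c(5, 4), pixel_size = 0.2)
  expect_identical(length(nb2$regions[[1]]$crop), 500L)

  # two references 1 um apart share pixels; both flagged
  lab3 <- matrix(0L, 60, 60); lab3[30, 20] <- 1L; lab3[30, 30] <- 2L
  nb3 <- build_neighborhoods(lab3, dilation_distance = 0.8, pixel_size = 0.1)
  expect_true(nb3$regions[[1]]$overlaps && nb3$regions[[2]]$overlaps)
  shared <- intersect(nb3$regions[[1]]$dilated, nb3$regions[[2]]$dilated)
  expect_gt(length(shared), 0)

  expect_error(build_neighborhoods(matrix(0L, 10, 10), pixel_size = 0.1),
               "at least one")
})

test_that("exclusive combinations partition the union and match the pixel oracle", {
  m <- matrix(FALSE, 10, 10); m[3:5, 3:5] <- TRUE
  ex_same <- exclusive_combinations(m, m, m)
  expect_identical(sum(ex_same$ABC), 9L)
  expect_identical(sum(ex_same$A) + sum(ex_same$AB) + sum(ex_same$AC), 0L)

  A <- matrix(FALSE, 8, 8); A[1:2, ] <- TRUE
  B <- matrix(FALSE, 8, 8); B[4:5, ] <- TRUE
  C <- matrix(FALSE, 8, 8); C[7:8, ] <- TRUE
  ex_dis <- exclusive_combinations(A, B, C)
  expect_identical(vapply(ex_dis[c("AB", "AC", "BC", "ABC")], sum, integer(1)),
                   c(AB = 0L, AC = 0L, BC = 0L, ABC = 0L))

  expect_error(exclusive_combinations(A, B, matrix(FALSE, 5, 5)),
               "identical dimensions")

  # random masks: partition equals the per-pixel truth-table oracle and
  # the 7 masks are disjoint and cover the union
  for (seed in 1:25) {
    set.seed(seed)
    A <- matrix(runif(256) > 0.5, 16, 16)
    B <- matrix(runif(256) > 0.5, 16, 16)
    C <- matrix(runif(256) > 0.5, 16, 16)
    ex <- exclusive_combinations(A, B, C)
    expect_identical(vapply(ex, function(m) sum(m), integer(1)),
                     vapply(coloc_pixel_oracle(A, B, C), as.integer,
                            integer(1)))
    overlap_sum <- Reduce(`+`, lapply(ex, function(m) m * 1))
    expect_true(all(overlap_sum <= 1))
    expect_identical(sum(overlap_sum == 1), sum(A | B | C))
  }
})

test_that("integrated density equals an explicit loop sum", {
  img <- matrix(5, 6, 6)
  m <- matrix(FALSE, 6, 6); m[2:3, 2:6] <- TRUE
  expect_equal(integrated_density(img, m), 50)
  expect_equal(integrated_density(img, m & FALSE), 0)

  set.seed(9)
  img2 <- matrix(runif(400), 20, 20)
  m2 <- matrix(runif(400) > 0.5, 20, 20)
  loop <- 0
  for (i in seq_along(img2)) if (m2[i]) loop <- loop + img2[i]
  expect_equal(integrated_density(img2, m2), loop)
})

test_that("coloc fractions are additive, symmetric and handle absent channels", {
  set.seed(3)
  dim_rc <- c(32L, 32L)
  A <- matrix(runif(1024) > 0.6, 32, 32)
  B <- matrix(runif(1024) > 0.6, 32, 32)
  C <- matrix(runif(1024) > 0.6, 32, 32)
  imgs <- lapply(1:3, function(i) matrix(sample(0:50, 1024, TRUE), 32, 32))
  rep <- coloc_fractions(imgs, list(A, B, C))
  pr <- rep$per_region

  # exact additivity: the 4 combination densities of a channel sum to the
  # channel's in-mask density (integer images -> bit exact)
  combA <- c("A", "AB", "AC", "ABC")
  expect_equal(sum(pr$density_A[pr$combination %in% combA]),
               sum(imgs[[1]][A]))
  expect_equal(sum(pr$fraction_A[pr$combination %in% combA]), 1)

  # permutation symmetry: swapping channels permutes labels, not values
  rep2 <- coloc_fractions(imgs[c(2, 1, 3)], list(B, A, C))
  pr2 <- rep2$per_region
  expect_equal(pr2$fraction_A[pr2$combination == "A"],
               pr$fraction_B[pr$combination == "B"])
  expect_equal(pr2$fraction_A[pr2$combination == "ABC"],
               pr$fraction_B[pr$combination == "ABC"])

  # full triple overlap: every triple fraction is 1
  m <- matrix(FALSE, 10, 10); m[4:6, 4:6] <- TRUE
  img1 <- matrix(10, 10, 10)
  rep3 <- coloc_fractions(list(img1, img1, img1), list(m, m, m))
  pr3 <- rep3$per_region
  expect_equal(pr3$fraction_A[pr3$combination == "ABC"], 1)
  expect_equal(pr3$fraction_B[pr3$combination == "ABC"], 1)

  # absent channel: its fractions are missing, others unaffected
  rep4 <- coloc_fractions(list(img1, img1, img1), list(m, m, m & FALSE))
  pr4 <- rep4$per_region
  expect_true(all(is.na(pr4$fraction_C)))
  expect_equal(pr4$fraction_A[pr4$combination == "AB"], 1)
})

test_that("prescribed overlap fractions are recovered from rendered channels", {
  ps <- 0.2
  acq <- acquisition_spec(n_frames = 2, pixel_size = ps,
                          image_shape = c(220L, 220L), psf_sigma = ps,
                          background_level = 10, poisson_scale = 1)
  cell <- simulate_cell_mask(c(220L, 220L), ps, "ellipse",
                             list(semi_axes = c(19, 15)))
  spec <- overlap_spec(fractions = c(A = 0.5, AB = 0.3, ABC = 0.2),
                       total_px = 3000)
  tri <- simulate_coloc_triad(cell, spec, acq, seed = 6, intensity = 100)
  masks <- lapply(1:3, function(ch)
    threshold_mask(tri$stack[ch, , ], "otsu"))
  imgs <- lapply(1:3, function(ch) tri$stack[ch, , ])
  rep <- coloc_fractions(imgs, masks, mode = "count")
  pr <- rep$per_region
  fA <- pr$fraction_A
  names(fA) <- pr$combination
  expect_equal(unname(fA["A"]), 0.5, tolerance = 0.06)
  expect_equal(unname(fA["AB"]), 0.3, tolerance = 0.1)
  expect_equal(unname(fA["ABC"]), 0.2, tolerance = 0.1)
})
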