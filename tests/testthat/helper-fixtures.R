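# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

tiny_acq <- function(n_frames = 10, pixel_size = 0.2, shape = c(120L, 120L),
                     psf_sigma = 0, background = 0, poisson_scale = 0,
                     read_noise = 0) {
  acquisition_spec(frame_interval = 1, n_frames = n_frames,
                   pixel_size = pixel_size, image_shape = shape,
                   psf_sigma = psf_sigma, background_level = background,
                   poisson_scale = poisson_scale,
                   read_noise_sigma = read_noise)
}

small_cell <- function(shape = c(120L, 120L), pixel_size = 0.2,
                       semi_axes = c(9, 7)) {
  simulate_cell_mask(shape, pixel_size, shape = "ellipse",
                     shape_params = list(semi_axes = semi_axes))
}

# random blob masks for oracle comparisons
random_blob <- function(seed, shape = c(60L, 60L), pixel_size = 0.5) {
  simulate_cell_mask(shape, pixel_size, shape = "blob",
                     shape_params = list(semi_axes = c(9, 7),
                                         roughness = 0.15),
                     seed = seed)
}

# brute-force flood fill (8-connected) label count, the labelling oracle
flood_fill_count <- function(mask) {
  visited <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0
  for (r in seq_len(nrow(mask))) for (cl in seq_len(ncol(mask))) {
    if (!mask[r, cl] || visited[r, cl]) next
    n <- n + 1
    queue <- list(c(r, cl)); visited[r, cl] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] && !visited[rr, cc]) {
          visited[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  n
}

# per-pixel truth-table oracle for the 7 exclusive combinations
coloc_pixel_oracle <- function(A, B, C) {
  counts <- c(A = 0, B = 0, C = 0, AB = 0, AC = 0, BC = 0, ABC = 0)
  for (i in seq_along(A)) {
    a <- A[i]; b <- B[i]; cc <- C[i]
    if (!a && !b && !cc) next
    key <- if (a && b && cc) "ABC"
    else if (a && b) "AB" else if (a && cc) "AC" else if (b && cc) "BC"
    else if (a) "A" else if (b) "B" else "C"
    counts[key] <- counts[key] + 1
  }
  counts
}

# brute-force min-distance central mask (the O(N^2) distance oracle);
# same boundary convention as the implementation: distance to the nearest
# background pixel centre minus half a pixel
central_oracle <- function(mask, band_width, pixel_size) {
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  fg <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    r <- fg[i, 1]; cl <- fg[i, 2]
    d <- sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - cl)^2))
    out[r, cl] <- (d - 0.5) * pixel_size >= band_width
  }
  out
}
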