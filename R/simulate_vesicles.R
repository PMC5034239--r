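#' Specification of a punctate vesicle field
#'
#' @param n_vesicles number of vesicles (>= 0).
#' @param spot_sigma Gaussian spot s.d. in micrometres.
#' @param peripheral_bias fraction in [0, 1]: probability that a vesicle is
#'   placed uniformly within the outer band (width `band_width`) rather
#'   than uniformly over the whole cell; 0 = uniform over the cell, 1 = all
#'   vesicles in the band.
#' @param diffusion_step per-frame random-walk step length (um).
#' @param intensity peak spot intensity (before PSF blur).
#' @param band_width width of the peripheral band (um), default 10.
#' @return object of class `vesicle_field_spec`.
#' @export
vesicle_field_spec <- function(n_vesicles, spot_sigma = 0.25,
                               peripheral_bias = 0, diffusion_step = 0.1,
                               intensity = 100, band_width = 10) {
  if (n_vesicles < 0) stop("n_vesicles must be >= 0")
  if (peripheral_bias < 0 || peripheral_bias > 1)
    stop("peripheral_bias must be in [0, 1]")
  stopifnot(spot_sigma > 0, diffusion_step >= 0, band_width > 0)
  structure(list(n_vesicles = as.integer(n_vesicles), spot_sigma = spot_sigma,
                 peripheral_bias = peripheral_bias,
                 diffusion_step = diffusion_step, intensity = intensity,
                 band_width = band_width),
            class = "vesicle_field_spec")
}

#' Simulate a vesicle channel with known centre positions
#'
#' Vesicle centres are drawn from the mixture
#' `(1 - peripheral_bias) * uniform(cell) + peripheral_bias * uniform(band)`
#' where the band is the set of cell pixels within `band_width` um of the
#' cell edge. Each vesicle then performs an isotropic random walk with
#' fixed step length, rejected when it would leave the cell. Spots are
#' rendered as Gaussians and passed through the acquisition PSF/noise
#' model. Every vesicle draws from its own seed substream, so the field is
#' reproducible object by object.
#'
#' @param cell_mask logical cell mask.
#' @param spec a [vesicle_field_spec()].
#' @param acq an [acquisition_spec()].
#' @param seed integer seed.
#' @return list with `stack` (frames x rows x cols), `truth` (data.frame:
#'   vesicle, frame, x_um, y_um, in_band), and `band_mask`.
#' @export
simulate_vesicle_field <- function(cell_mask, spec, acq, seed = 1) {
  cell_mask <- as_binary_matrix(cell_mask)
  if (!any(cell_mask)) stop("cell mask is empty")
  ps <- acq$pixel_size
  dist_um <- edge_distance_um(cell_mask, ps)
  band <- cell_mask & dist_um < spec$band_width
  central <- cell_mask & !band
  if (!any(central) && spec$peripheral_bias > 0)
    stop(paste("the cell is thinner than", spec$band_width,
               "um everywhere, so the peripheral band equals the whole cell;",
               "use peripheral_bias = 0"))

  cell_idx <- which(cell_mask, arr.ind = TRUE)
  band_idx <- which(band, arr.ind = TRUE)
  nf <- acq$n_frames
  nv <- spec$n_vesicles

  pos <- vector("list", nv)       # nv x (frame) x (x, y)
  in_band0 <- logical(nv)
  for (k in seq_len(nv)) {
    set.seed(derive_seed(seed, k))
    use_band <- stats::runif(1) < spec$peripheral_bias
    src <- if (use_band) band_idx else cell_idx
    i <- sample.int(nrow(src), 1)
    # uniform jitter within the chosen pixel
    xy <- c((src[i, 2] - 1 + stats::runif(1)) * ps,
            (src[i, 1] - 1 + stats::runif(1)) * ps)
    in_band0[k] <- band[src[i, 1], src[i, 2]]
    traj <- matrix(NA_real_, nf, 2)
    traj[1, ] <- xy
    for (f in seq_len(nf - 1)) {
      ok <- FALSE
      for (try in 1:8) {
        th <- stats::runif(1, 0, 2 * pi)
        cand <- traj[f, ] + spec$diffusion_step * c(cos(th), sin(th))
        r <- ceiling(cand[2] / ps); cl <- ceiling(cand[1] / ps)
        if (r >= 1 && r <= nrow(cell_mask) && cl >= 1 && cl <= ncol(cell_mask) &&
            cell_mask[r, cl]) { ok <- TRUE; break }
      }
      traj[f + 1, ] <- if (ok) cand else traj[f, ]
    }
    pos[[k]] <- traj
  }

  stack <- array(0, dim = c(nf, acq$image_shape[1], acq$image_shape[2]))
  for (f in seq_len(nf)) {
    signal <- matrix(0, acq$image_shape[1], acq$image_shape[2])
    for (k in seq_len(nv)) {
      signal <- add_gaussian_spot(signal, pos[[k]][f, ], spec$spot_sigma,
                                  spec$intensity, ps)
    }
    stack[f, , ] <- render_frame(signal, acq, derive_seed(seed, 100000 + f))
  }

  truth <- if (nv > 0) {
    do.call(rbind, lapply(seq_len(nv), function(k) data.frame(
      vesicle = k, frame = seq_len(nf),
      x_um = pos[[k]][, 1], y_um = pos[[k]][, 2], in_band = in_band0[k])))
  } else {
    data.frame(vesicle = integer(), frame = integer(), x_um = numeric(),
               y_um = numeric(), in_band = logical())
  }
  list(stack = stack, truth = truth, band_mask = band)
}

# Add a Gaussian spot (centre in um) to a signal matrix, truncated at 4 sigma.
add_gaussian_spot <- function(signal, center_um, sigma_um, intensity, pixel_size) {
  ext <- ceiling(4 * sigma_um / pixel_size)
  r0 <- max(1L, ceiling(center_um[2] / pixel_size) - ext)
  r1 <- min(nrow(signal), ceiling(center_um[2] / pixel_size) + ext)
  c0 <- max(1L, ceiling(center_um[1] / pixel_size) - ext)
  c1 <- min(ncol(signal), ceiling(center_um[1] / pixel_size) + ext)
  if (r0 > r1 || c0 > c1) return(signal)
  ys <- ((r0:r1) - 0.5) * pixel_size - center_um[2]
  xs <- ((c0:c1) - 0.5) * pixel_size - center_um[1]
  g <- exp(-outer(ys^2, xs^2, "+") / (2 * sigma_um^2))
  signal[r0:r1, c0:c1] <- signal[r0:r1, c0:c1] + intensity * g
  signal
}
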