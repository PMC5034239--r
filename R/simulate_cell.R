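#' Simulate a single-cell footprint mask
#'
#' Generates the binary "projected cell area" substrate on which adhesions
#' and vesicles are rendered. Two shapes are available: an ellipse
#' (analytically checkable area) and a blob, an ellipse whose radius is
#' modulated by a low-order random Fourier series to emulate an irregular
#' spread cell. The mask is a single 4-connected component and is
#' deterministic given the seed.
#'
#' @param image_shape integer c(rows, cols) in pixels.
#' @param pixel_size micrometres per pixel.
#' @param shape "ellipse" or "blob".
#' @param shape_params list; for both shapes `semi_axes` (um, default
#'   c(20, 14)), `center` (um, default frame centre), `angle` (radians,
#'   default 0); for "blob" additionally `roughness` (relative radial
#'   modulation amplitude, default 0.12) and `n_harmonics` (default 5).
#' @param seed integer seed (used by the blob modulation only).
#' @return logical matrix `[row = y, col = x]` with attribute `pixel_size`.
#' @export
simulate_cell_mask <- function(image_shape, pixel_size,
                               shape = c("ellipse", "blob"),
                               shape_params = list(), seed = 1) {
  shape <- match.arg(shape)
  p <- utils::modifyList(list(
    semi_axes = c(20, 14),
    center = c(image_shape[2], image_shape[1]) * pixel_size / 2,
    angle = 0, roughness = 0.12, n_harmonics = 5L
  ), shape_params)
  if (any(p$semi_axes <= 0)) stop("semi_axes must be > 0")

  amp <- phi <- NULL
  if (shape == "blob") {
    set.seed(derive_seed(seed, 0))
    amp <- stats::runif(p$n_harmonics, 0, p$roughness) / sqrt(seq_len(p$n_harmonics))
    phi <- stats::runif(p$n_harmonics, 0, 2 * pi)
  }

  # precondition: mask must fit inside the frame with >= 2 px margin
  half_extent_um <- max(p$semi_axes) * (if (shape == "blob") 1 + sum(amp) else 1)
  lim_x <- c(2.5, image_shape[2] - 2.5) * pixel_size
  lim_y <- c(2.5, image_shape[1] - 2.5) * pixel_size
  for (ax in 1:2) {
    lim <- if (ax == 1) lim_x else lim_y
    lo <- p$center[ax] - half_extent_um
    hi <- p$center[ax] + half_extent_um
    if (lo < lim[1] || hi > lim[2]) {
      stop(sprintf(
        "cell extent along %s (%.1f..%.1f um) exceeds the frame (allowed %.1f..%.1f um with 2 px margin)",
        c("x", "y")[ax], lo, hi, lim[1], lim[2]))
    }
  }

  cc <- pixel_centers_um(image_shape, pixel_size)
  xg <- matrix(cc$x, image_shape[1], image_shape[2], byrow = TRUE) - p$center[1]
  yg <- matrix(cc$y, image_shape[1], image_shape[2]) - p$center[2]
  ca <- cos(p$angle); sa <- sin(p$angle)
  u <- xg * ca + yg * sa
  v <- -xg * sa + yg * ca

  if (shape == "ellipse") {
    mask <- (u / p$semi_axes[1])^2 + (v / p$semi_axes[2])^2 <= 1
  } else {
    theta <- atan2(v / p$semi_axes[2], u / p$semi_axes[1])
    mod <- 1
    for (k in seq_len(p$n_harmonics)) mod <- mod + amp[k] * cos(k * theta + phi[k])
    mask <- (u / p$semi_axes[1])^2 + (v / p$semi_axes[2])^2 <= mod^2
    # keep a single 4-connected component (radial modulation cannot detach
    # pieces, but rasterisation at the boundary can); retain the largest
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    if (max(lab) > 1) {
      tab <- tabulate(as.integer(EBImage::imageData(lab)))
      mask <- EBImage::imageData(lab) == which.max(tab)
    }
    mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  }
  attr(mask, "pixel_size") <- pixel_size
  mask
}
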