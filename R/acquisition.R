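#' Acquisition settings for simulation and analysis
#'
#' Bundles the physical calibration and noise model of a (synthetic)
#' time-lapse acquisition. Defaults follow a 1 h live acquisition at
#' 1 frame/min; the pixel size default (0.16 um/px) is a convention for a
#' high-NA TIRF/confocal setup and should be set explicitly when known.
#'
#' The noise model is the standard fluorescence one: the noiseless image
#' (objects + background) is scaled to expected photon counts by
#' `poisson_scale`, Poisson shot noise is drawn, the result is scaled back
#' and Gaussian read noise of s.d. `read_noise_sigma` is added.
#'
#' @param frame_interval minutes per frame (> 0).
#' @param n_frames number of frames (>= 2).
#' @param pixel_size micrometres per pixel (> 0).
#' @param image_shape integer c(rows, cols) of each frame in pixels.
#' @param psf_sigma Gaussian PSF standard deviation in micrometres (>= 0).
#' @param background_level constant background intensity added to every pixel.
#' @param poisson_scale photons per intensity unit (>= 0; 0 disables shot
#'   noise).
#' @param read_noise_sigma Gaussian read noise s.d. in intensity units
#'   (>= 0; 0 disables read noise).
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(frame_interval = 1, n_frames = 60,
                             pixel_size = 0.16, image_shape = c(256L, 256L),
                             psf_sigma = 0.16, background_level = 10,
                             poisson_scale = 1, read_noise_sigma = 0) {
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0 (minutes/frame)")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (pixel_size <= 0) stop("pixel_size must be > 0 (um/px)")
  if (length(image_shape) != 2 || any(image_shape < 4))
    stop("image_shape must be c(rows, cols), each >= 4 px")
  if (psf_sigma < 0) stop("psf_sigma must be >= 0")
  if (background_level < 0 || poisson_scale < 0 || read_noise_sigma < 0)
    stop("noise parameters must all be >= 0")
  structure(list(
    frame_interval = frame_interval, n_frames = as.integer(n_frames),
    pixel_size = pixel_size, image_shape = as.integer(image_shape),
    psf_sigma = psf_sigma, background_level = background_level,
    poisson_scale = poisson_scale, read_noise_sigma = read_noise_sigma
  ), class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf(
    "acquisition_spec: %d frames @ %g min/frame, %dx%d px @ %g um/px\n",
    x$n_frames, x$frame_interval, x$image_shape[1], x$image_shape[2],
    x$pixel_size))
  cat(sprintf("  psf_sigma %g um, background %g, poisson_scale %g, read noise %g\n",
              x$psf_sigma, x$background_level, x$poisson_scale,
              x$read_noise_sigma))
  invisible(x)
}

# Apply PSF blur (if any) to an object-signal frame, add background, then
# apply the acquisition noise model using its own RNG substream.
render_frame <- function(signal, acq, seed_frame) {
  if (acq$psf_sigma > 0) {
    sigma_px <- acq$psf_sigma / acq$pixel_size
    signal <- EBImage::imageData(EBImage::gblur(EBImage::Image(signal),
                                                sigma = sigma_px))
  }
  img <- signal + acq$background_level
  nr <- nrow(img); nc <- ncol(img)
  if (acq$poisson_scale > 0 || acq$read_noise_sigma > 0) {
    set.seed(seed_frame)
    if (acq$poisson_scale > 0) {
      img <- stats::rpois(length(img), lambda = pmax(img, 0) * acq$poisson_scale) /
        acq$poisson_scale
      img <- matrix(img, nr, nc)
    }
    if (acq$read_noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(length(img), sd = acq$read_noise_sigma),
                          nr, nc)
    }
  }
  img
}
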