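#' Convert a physical length to pixels
#'
#' Lengths in micrometres are converted to whole pixels by rounding half
#' away from zero, so a radius of 0.8 um at 0.1 um/px is 8 px and 1.25 px
#' rounds to 2 px rather than to the even neighbour. The realised pixel
#' value should always be recorded alongside the requested physical value.
#'
#' @param x_um length in micrometres (may be a vector).
#' @param pixel_size pixel size in micrometres per pixel; must be > 0.
#' @return integer vector of pixel lengths.
#' @export
um_to_px <- function(x_um, pixel_size) {
  stopifnot(is.numeric(x_um), is.numeric(pixel_size), pixel_size > 0)
  as.integer(sign(x_um) * floor(abs(x_um) / pixel_size + 0.5))
}

#' Convert pixels to micrometres
#' @param x_px length in pixels.
#' @param pixel_size micrometres per pixel.
#' @return numeric vector of lengths in micrometres.
#' @export
px_to_um <- function(x_px, pixel_size) x_px * pixel_size

# Counter-based substream seed: every simulated object k draws from its own
# seed derived from (seed, k), so adding objects never reshuffles draws of
# existing ones. Arithmetic stays within 2^53 (exact in doubles) and the
# result within [1, 2^31 - 2] (valid for set.seed).
derive_seed <- function(seed, index) {
  stopifnot(seed >= 0, index >= 0)
  h <- (seed %% 2147483647) + 1
  for (k in c(index + 1, 3)) {
    h <- (h * 48271 + k * 16807) %% 2147483647
  }
  as.integer(h + 1)
}

# Pixel-centre coordinates in um for a mask/image matrix indexed [row=y, col=x].
pixel_centers_um <- function(dim_rc, pixel_size) {
  list(
    y = (seq_len(dim_rc[1]) - 0.5) * pixel_size,
    x = (seq_len(dim_rc[2]) - 0.5) * pixel_size
  )
}

# Coordinates (um) of the TRUE pixels of a mask, matrix [y, x].
mask_coords_um <- function(mask, pixel_size) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = (idx[, 2] - 0.5) * pixel_size, y = (idx[, 1] - 0.5) * pixel_size)
}

# Distance (um) from each foreground pixel centre to the mask boundary:
# Euclidean distance transform to the nearest background pixel centre,
# minus half a pixel (the true boundary runs midway between the last
# foreground and first background pixel). Background pixels get 0.
edge_distance_um <- function(mask, pixel_size) {
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  d <- pmax(d - 0.5, 0) * (d > 0)
  matrix(d * pixel_size, nrow(mask), ncol(mask))
}

as_binary_matrix <- function(x, arg = deparse(substitute(x))) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) stop(sprintf("'%s' must be a matrix", arg))
  if (is.logical(x)) return(x)
  x > 0
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical dimensions (got %s vs %s)",
                 what, paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}
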