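#' Rolling-ball style background subtraction (morphological top-hat)
#'
#' Subtracts the morphological opening of the image by a disc, removing
#' smooth background while preserving objects smaller than the disc. The
#' result is non-negative everywhere.
#'
#' @param image numeric matrix.
#' @param ball_radius disc radius; interpreted in micrometres when
#'   `pixel_size` is given, in pixels otherwise.
#' @param pixel_size optional micrometres per pixel.
#' @return background-subtracted matrix with attribute `ball_radius_px`.
#' @export
subtract_background <- function(image, ball_radius, pixel_size = NULL) {
  if (ball_radius <= 0) stop("ball_radius must be > 0")
  radius_px <- if (is.null(pixel_size)) ball_radius
               else um_to_px(ball_radius, pixel_size)
  if (radius_px < 1)
    stop(sprintf("ball_radius converts to %s px; must be >= 1 px", radius_px))
  brush <- EBImage::makeBrush(2 * radius_px + 1, shape = "disc")
  # EBImage greyscale morphology operates on [0, 1]; rescale around it
  rng <- range(image)
  if (diff(rng) == 0) {
    out <- matrix(0, nrow(image), ncol(image))
    attr(out, "ball_radius_px") <- radius_px
    return(out)
  }
  scaled <- (image - rng[1]) / diff(rng)
  op <- EBImage::imageData(EBImage::opening(EBImage::Image(scaled), brush))
  op <- op * diff(rng) + rng[1]
  out <- pmax(image - op, 0)
  out <- matrix(out, nrow(image), ncol(image))
  attr(out, "ball_radius_px") <- radius_px
  out
}

#' Threshold an image to a binary mask
#'
#' Either Otsu's threshold computed on the image histogram or a fixed
#' numeric threshold. The threshold actually applied is recorded in the
#' `threshold` attribute, so a batch can reuse one value across images
#' (the same-threshold-for-all-conditions rule); see [threshold_batch()].
#'
#' @param image numeric matrix.
#' @param method "otsu" or "fixed".
#' @param value numeric threshold, required for method = "fixed".
#' @return logical mask with attributes `threshold` and `method`. Pixels
#'   strictly above the threshold are foreground.
#' @export
threshold_mask <- function(image, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  if (method == "otsu") {
    rng <- range(image)
    if (diff(rng) == 0)
      stop("image is constant; Otsu undefined - use method = 'fixed'")
    thr <- EBImage::otsu(EBImage::Image(image), range = rng, levels = 256)
  } else {
    if (is.null(value)) stop("method = 'fixed' needs 'value'")
    thr <- value
  }
  mask <- image > thr
  attr(mask, "threshold") <- as.numeric(thr)
  attr(mask, "method") <- method
  mask
}

#' Threshold a list of images with one shared threshold
#'
#' Computes the threshold on the first image (Otsu by default) and applies
#' that same fixed value to every image in the batch, honouring the rule
#' that one threshold is used for all conditions within an experiment.
#'
#' @param images list of numeric matrices.
#' @param method "otsu" (computed on the first image) or "fixed".
#' @param value threshold for method = "fixed".
#' @return list of logical masks; the shared threshold is attached to the
#'   list as attribute `threshold` and to each mask.
#' @export
threshold_batch <- function(images, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  first <- threshold_mask(images[[1]],
                          method = if (method == "otsu") "otsu" else "fixed",
                          value = value)
  thr <- attr(first, "threshold")
  out <- lapply(images, threshold_mask, method = "fixed", value = thr)
  attr(out, "threshold") <- thr
  out
}

#' Label connected regions of a binary mask
#'
#' 8-connected component labelling with a minimum-area filter. EBImage's
#' `bwlabel` is 4-connected; diagonal-touching labels are merged afterwards
#' so diagonal adhesion tips stay one object. Surviving labels are
#' relabelled consecutively 1..N.
#'
#' @param mask logical matrix.
#' @param min_area minimum region area; in um^2 when `pixel_size` is given,
#'   in pixels otherwise.
#' @param pixel_size optional micrometres per pixel.
#' @return integer label matrix with attributes `min_area_px` and
#'   `n_labels`.
#' @export
label_regions <- function(mask, min_area = 0, pixel_size = NULL) {
  mask <- as_binary_matrix(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab > 1) {
    # merge labels that touch diagonally (8-connectivity)
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right pairs
    a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left pairs
    e1 <- a1 > 0 & b1 > 0 & a1 != b1
    e2 <- a2 > 0 & b2 > 0 & a2 != b2
    edges <- rbind(cbind(a1[e1], b1[e1]), cbind(a2[e2], b2[e2]))
    if (nrow(edges) > 0) {
      g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                       directed = FALSE)
      g <- igraph::add_vertices(g, length(setdiff(as.character(seq_len(nlab)),
                                                  igraph::V(g)$name)),
                                name = setdiff(as.character(seq_len(nlab)),
                                               igraph::V(g)$name))
      comp <- igraph::components(g)$membership
      remap <- integer(nlab)
      remap[as.integer(igraph::V(g)$name)] <- comp
      lab[lab > 0] <- remap[lab[lab > 0]]
    }
  }
  min_area_px <- if (min_area <= 0) 0
                 else if (is.null(pixel_size)) min_area
                 else min_area / pixel_size^2
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= max(min_area_px, 1))
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  attr(lab, "min_area_px") <- min_area_px
  attr(lab, "n_labels") <- max(lab)
  lab
}

#' Per-region measurements of a label map
#'
#' @param labels integer label matrix from [label_regions()].
#' @param pixel_size micrometres per pixel (default 1 = pixel units).
#' @return data.frame: label, area_px, area_um2, centroid_x/y (um),
#'   centroid_row/col (px).
#' @export
region_table <- function(labels, pixel_size = 1) {
  n <- max(labels)
  if (n == 0)
    return(data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), centroid_x = numeric(),
                      centroid_y = numeric(), centroid_row = numeric(),
                      centroid_col = numeric()))
  idx <- which(labels > 0, arr.ind = TRUE)
  lb <- labels[labels > 0]
  area <- tabulate(lb, nbins = n)
  crow <- tapply(idx[, 1], lb, mean)
  ccol <- tapply(idx[, 2], lb, mean)
  data.frame(label = seq_len(n), area_px = area,
             area_um2 = area * pixel_size^2,
             centroid_x = (as.numeric(ccol) - 0.5) * pixel_size,
             centroid_y = (as.numeric(crow) - 0.5) * pixel_size,
             centroid_row = as.numeric(crow), centroid_col = as.numeric(ccol))
}

#' Segment the cell footprint from an image
#'
#' Thresholds, keeps the largest 8-connected component and optionally
#' fills interior holes, yielding the single-component projected cell
#' area mask.
#'
#' @param image numeric matrix (a frame, or a time-projection).
#' @param method,value as in [threshold_mask()].
#' @param fill_holes fill interior holes (default TRUE).
#' @return logical mask (one component) with the threshold attributes.
#' @export
cell_mask_from_image <- function(image, method = "otsu", value = NULL,
                                 fill_holes = TRUE) {
  m <- threshold_mask(image, method = method, value = value)
  if (!any(m)) stop("no foreground after thresholding; cannot build a cell mask")
  lab <- label_regions(m, min_area = 0)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- lab == which.max(sizes)
  if (fill_holes)
    keep <- EBImage::imageData(EBImage::fillHull(EBImage::Image(keep * 1))) > 0
  keep <- matrix(keep, nrow(image), ncol(image))
  attr(keep, "threshold") <- attr(m, "threshold")
  attr(keep, "method") <- attr(m, "method")
  keep
}
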