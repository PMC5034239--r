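#' Neighbourhood regions around reference adhesions
#'
#' For each labelled reference object (e.g. vinculin-positive adhesions)
#' two region definitions are produced side by side: (i) the object
#' dilated by a disc of radius `dilation_distance` (default 0.8 um; the
#' realised pixel radius is recorded), and (ii) a `crop_size` rectangle
#' (default 5 x 4 um) centred on the object centroid with its long axis
#' along the object's major axis (set `axis_aligned = TRUE` for
#' image-axis-aligned crops). Overlapping neighbourhoods are kept
#' independent: shared pixels are counted in every region that contains
#' them, and flagged.
#'
#' @param ref_labels integer label map of reference objects.
#' @param dilation_distance dilation radius in micrometres.
#' @param crop_size c(long, short) rectangle size in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param axis_aligned logical; FALSE (default) aligns the crop with the
#'   object's major axis.
#' @return object of class `neighborhood_set`: list with `regions` (one
#'   list per object: label, dilated and crop pixel indices, centroid,
#'   clipped and overlap flags), `dilation_radius_px`, and the inputs.
#' @export
build_neighborhoods <- function(ref_labels, dilation_distance = 0.8,
                                crop_size = c(5, 4), pixel_size,
                                axis_aligned = FALSE) {
  n <- max(ref_labels)
  if (n < 1) stop("need at least one reference object")
  radius_px <- um_to_px(dilation_distance, pixel_size)
  if (radius_px < 1) stop("dilation_distance is below one pixel")
  brush <- EBImage::makeBrush(2 * radius_px + 1, shape = "disc")
  dim_rc <- dim(ref_labels)

  regions <- vector("list", n)
  for (k in seq_len(n)) {
    obj <- ref_labels == k
    idx <- which(obj, arr.ind = TRUE)
    dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(obj * 1), brush)) > 0
    crow <- mean(idx[, 1]); ccol <- mean(idx[, 2])

    ang <- if (axis_aligned || nrow(idx) < 2) 0 else {
      cxx <- stats::var(idx[, 2]) ; cyy <- stats::var(idx[, 1])
      cxy <- if (nrow(idx) > 1) stats::cov(idx[, 2], idx[, 1]) else 0
      0.5 * atan2(2 * cxy, cxx - cyy)
    }
    u <- c(cos(ang), sin(ang)); nv <- c(-u[2], u[1])
    half <- crop_size / 2 / pixel_size
    ext <- ceiling(max(half)) + 1L
    r0 <- max(1L, floor(crow - ext)); r1 <- min(dim_rc[1], ceiling(crow + ext))
    c0 <- max(1L, floor(ccol - ext)); c1 <- min(dim_rc[2], ceiling(ccol + ext))
    rr <- r0:r1; cc <- c0:c1
    xg <- matrix(cc, length(rr), length(cc), byrow = TRUE) - ccol
    yg <- matrix(rr, length(rr), length(cc)) - crow
    s <- xg * u[1] + yg * u[2]
    q <- xg * nv[1] + yg * nv[2]
    # half-open interval so an even crop width covers exactly that many px
    inside <- s >= -half[1] & s < half[1] & q >= -half[2] & q < half[2]
    widx <- which(inside, arr.ind = TRUE)
    crop_idx <- (cc[widx[, 2]] - 1L) * dim_rc[1] + rr[widx[, 1]]
    # clipped if the ideal crop would extend beyond the frame
    clipped <- (crow - half[1] < 0.5) || (crow + half[1] > dim_rc[1] + 0.5) ||
      (ccol - half[1] < 0.5) || (ccol + half[1] > dim_rc[2] + 0.5)

    regions[[k]] <- list(label = k, dilated = which(dil),
                         crop = crop_idx,
                         centroid_row = crow, centroid_col = ccol,
                         clipped = clipped, overlaps = FALSE)
  }
  # overlap flags between dilated regions
  if (n > 1) {
    counts <- integer(prod(dim_rc))
    for (k in seq_len(n)) counts[regions[[k]]$dilated] <-
        counts[regions[[k]]$dilated] + 1L
    for (k in seq_len(n))
      regions[[k]]$overlaps <- any(counts[regions[[k]]$dilated] > 1L)
  }
  structure(list(regions = regions, dilation_radius_px = radius_px,
                 dilation_distance = dilation_distance,
                 crop_size = crop_size, pixel_size = pixel_size,
                 axis_aligned = axis_aligned, dim = dim_rc),
            class = "neighborhood_set")
}

#' Exclusive combinations of three binary masks
#'
#' Partitions the union of masks A, B, C into the 7 disjoint exclusive
#' combinations (A-only, B-only, C-only, AB, AC, BC, ABC); AB excludes
#' pixels also in C, and so on.
#'
#' @param A,B,C logical matrices of equal shape.
#' @return named list of 7 disjoint logical masks
#'   (`A`, `B`, `C`, `AB`, `AC`, `BC`, `ABC`).
#' @export
exclusive_combinations <- function(A, B, C) {
  A <- as_binary_matrix(A); B <- as_binary_matrix(B); C <- as_binary_matrix(C)
  check_same_shape(A, B, "masks A and B")
  check_same_shape(A, C, "masks A and C")
  list(A  = A & !B & !C,
       B  = !A & B & !C,
       C  = !A & !B & C,
       AB = A & B & !C,
       AC = A & !B & C,
       BC = !A & B & C,
       ABC = A & B & C)
}

#' Integrated density over a mask
#'
#' @param image numeric matrix.
#' @param mask logical matrix of the same shape.
#' @return sum of image intensities over the mask (intensity x px).
#' @export
integrated_density <- function(image, mask) {
  mask <- as_binary_matrix(mask)
  check_same_shape(image, mask, "image and mask")
  sum(image[mask])
}

#' Differential colocalization report over neighbourhood regions
#'
#' Within each region, the three channel masks are split into their 7
#' exclusive combinations; for every combination the pixel count and the
#' integrated density of each channel image are accumulated. For each
#' channel X the 4 combinations containing X are expressed as fractions of
#' the channel's in-region total (density by default, pixel counts with
#' `mode = "count"`). Regions where a channel has zero total get missing
#' fractions for that channel and are flagged.
#'
#' @param images named list of 3 numeric matrices (channels A, B, C),
#'   background-subtracted upstream when desired.
#' @param masks named list of 3 logical masks for the same channels.
#' @param regions a [build_neighborhoods()] result, or a list of pixel
#'   index vectors, or NULL for one whole-image region.
#' @param region_type "dilated" or "crop" when `regions` is a
#'   neighbourhood set.
#' @param mode "density" (integrated densities) or "count" (pixels).
#' @return object of class `coloc_report`: list with `per_region`
#'   (data.frame: region, combination, px, density per channel, fraction
#'   per channel) and `summary` (mean fraction per channel x combination
#'   over regions with defined totals).
#' @export
coloc_fractions <- function(images, masks, regions = NULL,
                            region_type = c("dilated", "crop"),
                            mode = c("density", "count")) {
  region_type <- match.arg(region_type)
  mode <- match.arg(mode)
  stopifnot(length(images) == 3, length(masks) == 3)
  chn <- c("A", "B", "C")
  names(images) <- chn; names(masks) <- chn
  masks <- lapply(masks, as_binary_matrix)
  for (ch in chn) check_same_shape(images[[ch]], masks[[ch]], "image and mask")

  region_idx <- if (is.null(regions)) {
    list(seq_along(images[[1]]))
  } else if (inherits(regions, "neighborhood_set")) {
    lapply(regions$regions, function(r) r[[region_type]])
  } else regions

  combos <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  contains <- list(A = c("A", "AB", "AC", "ABC"),
                   B = c("B", "AB", "BC", "ABC"),
                   C = c("C", "AC", "BC", "ABC"))
  excl <- exclusive_combinations(masks$A, masks$B, masks$C)

  rows <- list()
  for (i in seq_along(region_idx)) {
    idx <- region_idx[[i]]
    px <- vapply(excl, function(m) sum(m[idx]), numeric(1))
    dens <- sapply(chn, function(ch)
      vapply(excl, function(m) sum(images[[ch]][idx][m[idx]]), numeric(1)))
    qty <- if (mode == "density") dens else
      sapply(chn, function(ch) px)
    totals <- vapply(chn, function(ch) sum(qty[contains[[ch]], ch]), numeric(1))
    fr <- sapply(chn, function(ch) {
      f <- rep(NA_real_, 7); names(f) <- combos
      if (totals[[ch]] > 0)
        f[contains[[ch]]] <- qty[contains[[ch]], ch] / totals[[ch]]
      f
    })
    rows[[i]] <- data.frame(
      region = i, combination = combos, px = as.numeric(px),
      density_A = dens[, "A"], density_B = dens[, "B"], density_C = dens[, "C"],
      fraction_A = fr[, "A"], fraction_B = fr[, "B"], fraction_C = fr[, "C"],
      row.names = NULL)
  }
  per_region <- do.call(rbind, rows)
  summary <- stats::aggregate(
    per_region[, c("fraction_A", "fraction_B", "fraction_C")],
    by = list(combination = per_region$combination),
    FUN = function(v) mean(v, na.rm = TRUE))
  summary <- summary[match(combos, summary$combination), ]
  rownames(summary) <- NULL
  structure(list(per_region = per_region, summary = summary, mode = mode),
            class = "coloc_report")
}

#' @export
print.coloc_report <- function(x, ...) {
  cat(sprintf("coloc_report (%s mode), %d region(s)\n", x$mode,
              max(x$per_region$region)))
  print(x$summary, digits = 3)
  invisible(x)
}
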