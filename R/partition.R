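#' Partition a cell mask into peripheral band and central region
#'
#' The central region is the set of cell pixels whose Euclidean distance
#' to the cell boundary (distance transform to the nearest background
#' pixel centre, corrected by the half pixel between that centre and the
#' mask boundary) is at least `band_width` - a geometric offset curve,
#' isotropic by construction;
#' the peripheral band is the remainder of the cell. Pixels exactly at
#' `band_width` belong to the central region (>= rule). The two masks
#' partition the cell mask exactly.
#'
#' @param cell_mask logical cell mask (single connected component).
#' @param band_width band width in micrometres (default 10).
#' @param pixel_size micrometres per pixel.
#' @return object of class `periphery_partition`: list with `cell`,
#'   `central`, `peripheral` masks, their areas (um^2 and px), the band
#'   width, pixel size, and `central_empty` flag.
#' @export
partition_cell <- function(cell_mask, band_width = 10, pixel_size) {
  cell_mask <- as_binary_matrix(cell_mask)
  if (!any(cell_mask)) stop("cell mask is empty")
  lab <- label_regions(cell_mask)
  if (attr(lab, "n_labels") > 1)
    stop("cell mask must be a single connected component")
  dist_um <- edge_distance_um(cell_mask, pixel_size)
  central <- matrix(dist_um >= band_width & cell_mask,
                    nrow(cell_mask), ncol(cell_mask))
  peripheral <- cell_mask & !central
  structure(list(
    cell = cell_mask, central = central, peripheral = peripheral,
    band_width = band_width, pixel_size = pixel_size,
    cell_area_px = sum(cell_mask), central_area_px = sum(central),
    peripheral_area_px = sum(peripheral),
    cell_area_um2 = sum(cell_mask) * pixel_size^2,
    central_area_um2 = sum(central) * pixel_size^2,
    peripheral_area_um2 = sum(peripheral) * pixel_size^2,
    central_empty = !any(central)
  ), class = "periphery_partition")
}

#' @export
print.periphery_partition <- function(x, ...) {
  cat(sprintf(
    "periphery_partition: band %g um; cell %.1f um^2 = central %.1f + peripheral %.1f%s\n",
    x$band_width, x$cell_area_um2, x$central_area_um2, x$peripheral_area_um2,
    if (x$central_empty) " [central empty]" else ""))
  invisible(x)
}

#' Peripheral/central split of a signal
#'
#' Splits a signal between the central region and the peripheral band:
#' peripheral = total-in-cell - central, normalised to the cell area.
#' `signal` may be a binary mask (pixel counts) or an intensity image
#' (integrated density). Signal outside the cell mask is counted in
#' neither and reported separately.
#'
#' @param signal logical mask or numeric matrix, same shape as the cell.
#' @param partition a [partition_cell()] result.
#' @return list: total, central, peripheral, out_of_cell,
#'   peripheral_normalized (peripheral / cell area in px),
#'   central_normalized.
#' @export
peripheral_signal <- function(signal, partition) {
  stopifnot(inherits(partition, "periphery_partition"))
  check_same_shape(signal, partition$cell, "signal and cell mask")
  s <- if (is.logical(signal)) signal * 1 else signal
  total_everywhere <- sum(s)
  total <- sum(s[partition$cell])
  central <- sum(s[partition$central])
  peripheral <- total - central
  list(total = total, central = central, peripheral = peripheral,
       out_of_cell = total_everywhere - total,
       peripheral_normalized = peripheral / partition$cell_area_px,
       central_normalized = central / partition$cell_area_px)
}

#' Ratio of marker-positive area to projected cell area
#'
#' @param signal_mask logical marker mask (e.g. Rab7-positive pixels).
#' @param cell_mask logical cell mask.
#' @return pixels/pixels ratio of in-cell marker area to cell area.
#' @export
rab_area_ratio <- function(signal_mask, cell_mask) {
  signal_mask <- as_binary_matrix(signal_mask)
  cell_mask <- as_binary_matrix(cell_mask)
  check_same_shape(signal_mask, cell_mask, "masks")
  if (!any(cell_mask)) stop("cell mask is empty")
  sum(signal_mask & cell_mask) / sum(cell_mask)
}

#' Focal adhesion area and count ratios
#'
#' @param labels adhesion label map ([label_regions()]).
#' @param cell_mask logical cell mask.
#' @param pixel_size micrometres per pixel.
#' @return list: area_ratio (FA px within cell / cell px), count_ratio
#'   (FA count per um^2 of cell), n_adhesions, cell_area_um2.
#' @export
fa_ratios <- function(labels, cell_mask, pixel_size) {
  cell_mask <- as_binary_matrix(cell_mask)
  check_same_shape(labels, cell_mask, "label map and cell mask")
  if (!any(cell_mask)) stop("cell mask is empty")
  n <- max(labels)
  cell_area_um2 <- sum(cell_mask) * pixel_size^2
  list(area_ratio = sum(labels > 0 & cell_mask) / sum(cell_mask),
       count_ratio = n / cell_area_um2,
       n_adhesions = n, cell_area_um2 = cell_area_um2)
}

#' Per-adhesion vesicle-marker intensity, grouped peripheral vs central
#'
#' Each reference adhesion is classified peripheral or central by the
#' membership of its centroid pixel in the partition; its vesicle-channel
#' integrated density is summed over its neighbourhood mask (the dilated
#' region of a [build_neighborhoods()] set). Adhesions whose centroid
#' falls outside the cell are excluded and counted.
#'
#' @param vesicle_image numeric matrix (vesicle channel, background
#'   subtracted upstream if desired).
#' @param neighborhoods a [build_neighborhoods()] result.
#' @param partition a [partition_cell()] result.
#' @return list with data.frame `per_adhesion` (label, group, density),
#'   numeric vectors `peripheral` and `central`, and `n_excluded`.
#' @export
per_fa_rab_intensity <- function(vesicle_image, neighborhoods, partition) {
  stopifnot(inherits(partition, "periphery_partition"))
  check_same_shape(vesicle_image, partition$cell, "image and cell mask")
  rows <- lapply(neighborhoods$regions, function(rg) {
    r <- round(rg$centroid_row); cl <- round(rg$centroid_col)
    r <- min(max(r, 1), nrow(partition$cell))
    cl <- min(max(cl, 1), ncol(partition$cell))
    if (!partition$cell[r, cl]) return(NULL)
    group <- if (partition$central[r, cl]) "central" else "peripheral"
    data.frame(label = rg$label, group = group,
               density = sum(vesicle_image[rg$dilated]))
  })
  n_excluded <- sum(vapply(rows, is.null, logical(1)))
  per <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per))
    per <- data.frame(label = integer(), group = character(),
                      density = numeric())
  list(per_adhesion = per,
       peripheral = per$density[per$group == "peripheral"],
       central = per$density[per$group == "central"],
       n_excluded = n_excluded)
}
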