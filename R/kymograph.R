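#' Growth axis of a tracked adhesion
#'
#' The axis is the principal axis of the union of the track's footprints;
#' its positive (distal) direction is chosen to point toward the nearest
#' cell-edge point, matching distal-tip extension toward the cell edge.
#' When the union is nearly isotropic (principal axis undefined) the axis
#' falls back to the net centroid displacement; when that is also
#' degenerate an error is raised. A line of `length_um` is centred on the
#' union centroid, clipped to the frame and flagged when it exits.
#'
#' @param track one track from [track_adhesions()].
#' @param cell_mask logical cell mask (source of the edge).
#' @param pixel_size micrometres per pixel.
#' @param length_um line length in micrometres (default 10).
#' @param anisotropy_min minimal major/minor eigenvalue ratio for the
#'   principal axis to be considered defined.
#' @return list of class `growth_axis`: `center` (x, y um), `angle`
#'   (radians, distal direction), `p0`, `p1` (proximal and distal line
#'   endpoints, um), `length_um`, `clipped`, `fallback`.
#' @export
growth_axis <- function(track, cell_mask, pixel_size, length_um = 10,
                        anisotropy_min = 1.3) {
  if (length(track$frames) < 2) stop("track must span >= 2 frames")
  cell_mask <- as_binary_matrix(cell_mask)
  dim_rc <- dim(cell_mask)
  px <- unique(unlist(track$footprints))
  rr <- ((px - 1) %% dim_rc[1]) + 1
  cc <- ((px - 1) %/% dim_rc[1]) + 1
  x <- (cc - 0.5) * pixel_size
  y <- (rr - 0.5) * pixel_size
  ctr <- c(mean(x), mean(y))

  fallback <- FALSE
  cxx <- sum((x - ctr[1])^2) / length(x) + pixel_size^2 / 12
  cyy <- sum((y - ctr[2])^2) / length(y) + pixel_size^2 / 12
  cxy <- sum((x - ctr[1]) * (y - ctr[2])) / length(x)
  tr_ <- cxx + cyy
  disc <- sqrt(max(tr_^2 / 4 - (cxx * cyy - cxy^2), 0))
  l1 <- tr_ / 2 + disc; l2 <- tr_ / 2 - disc
  if (l1 / max(l2, .Machine$double.eps) >= anisotropy_min) {
    u <- if (abs(cxy) > .Machine$double.eps * tr_) {
      v <- c(l1 - cyy, cxy); v / sqrt(sum(v^2))
    } else if (cxx >= cyy) c(1, 0) else c(0, 1)
  } else {
    disp <- (track$centroids[nrow(track$centroids), ] -
               track$centroids[1, ]) * pixel_size
    disp <- c(disp[2], disp[1])  # centroids are (row, col) -> (x, y)
    if (sqrt(sum(disp^2)) < pixel_size / 2)
      stop("growth axis undefined: isotropic footprint and no net displacement")
    u <- disp / sqrt(sum(disp^2))
    fallback <- TRUE
  }

  # orient the positive direction toward the nearest cell-edge point
  edge <- cell_mask & !(EBImage::imageData(EBImage::erode(
    EBImage::Image(cell_mask * 1), EBImage::makeBrush(3, "box"))) > 0)
  eidx <- which(edge, arr.ind = TRUE)
  if (nrow(eidx) > 0) {
    ex <- (eidx[, 2] - 0.5) * pixel_size
    ey <- (eidx[, 1] - 0.5) * pixel_size
    i <- which.min((ex - ctr[1])^2 + (ey - ctr[2])^2)
    s <- sum(u * c(ex[i] - ctr[1], ey[i] - ctr[2]))
    if (s < 0) u <- -u
  }
  angle <- atan2(u[2], u[1])

  p0 <- ctr - u * length_um / 2   # proximal end
  p1 <- ctr + u * length_um / 2   # distal end
  lim_x <- c(0.5, dim_rc[2] - 0.5) * pixel_size
  lim_y <- c(0.5, dim_rc[1] - 0.5) * pixel_size
  clipped <- any(c(p0[1], p1[1]) < lim_x[1] | c(p0[1], p1[1]) > lim_x[2] |
                 c(p0[2], p1[2]) < lim_y[1] | c(p0[2], p1[2]) > lim_y[2])
  clamp <- function(p) c(min(max(p[1], lim_x[1]), lim_x[2]),
                         min(max(p[2], lim_y[1]), lim_y[2]))
  structure(list(center = ctr, angle = angle, p0 = clamp(p0), p1 = clamp(p1),
                 length_um = length_um, clipped = clipped,
                 fallback = fallback),
            class = "growth_axis")
}

# Bilinear interpolation of matrix M at fractional (row, col) positions.
bilinear_sample <- function(M, row, col) {
  nr <- nrow(M); nc <- ncol(M)
  row <- pmin(pmax(row, 1), nr); col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1); c0 <- pmin(floor(col), nc - 1)
  fr <- row - r0; fc <- col - c0
  M[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    M[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    M[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    M[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Extract a kymograph along a line
#'
#' Samples the stack along the line at 1 px steps by bilinear
#' interpolation, averaging over `width_avg` parallel lines offset
#' perpendicular to it (integer pixel offsets centred on the line). One
#' column per frame; row index increases toward the distal end.
#'
#' @param stack array (frames x rows x cols) or list of matrices.
#' @param line a [growth_axis()] (or any list with `p0`, `p1` in um).
#' @param width_avg number of parallel 1 px lines averaged (odd).
#' @param pixel_size micrometres per pixel.
#' @return object of class `kymograph`: `matrix` (positions x frames),
#'   `positions_um` (0 at the proximal end), `line`, `pixel_size`.
#' @export
extract_kymograph <- function(stack, line, width_avg = 3, pixel_size) {
  frames <- if (is.list(stack)) stack else
    lapply(seq_len(dim(stack)[1]), function(f) stack[f, , ])
  p0 <- line$p0; p1 <- line$p1
  len_um <- sqrt(sum((p1 - p0)^2))
  if (len_um <= 0) stop("zero-length kymograph line")
  n_pos <- floor(len_um / pixel_size) + 1
  tt <- seq(0, 1, length.out = n_pos)
  u <- (p1 - p0) / len_um
  nv <- c(-u[2], u[1])
  offs <- (seq_len(width_avg) - (width_avg + 1) / 2) * pixel_size

  xs <- outer(p0[1] + tt * len_um * u[1], offs * nv[1], "+")
  ys <- outer(p0[2] + tt * len_um * u[2], offs * nv[2], "+")
  rowp <- ys / pixel_size + 0.5
  colp <- xs / pixel_size + 0.5

  K <- vapply(frames, function(M) {
    v <- bilinear_sample(M, as.vector(rowp), as.vector(colp))
    rowMeans(matrix(v, n_pos, width_avg))
  }, numeric(n_pos))
  structure(list(matrix = K, positions_um = tt * len_um, line = line,
                 pixel_size = pixel_size),
            class = "kymograph")
}

#' Locate adhesion tips on a kymograph
#'
#' Per frame (column), the adhesion extent is the contiguous run of
#' positions whose intensity is at least background + 50% of the column's
#' peak above background; the distal tip is the half-maximum crossing on
#' the cell-edge side (high position index), the proximal tip the other
#' end, both refined to sub-sample precision by linear interpolation.
#' Columns with no signal above background are undefined (NA). When a
#' column holds several runs (a neighbouring adhesion crossing the line),
#' the run nearest the previous frame's tips is kept; before any tip is
#' defined, the run with the largest integrated intensity (tie: the most
#' distal) is used.
#'
#' @param kymo a [extract_kymograph()] result.
#' @param background_level background intensity of the acquisition.
#' @param min_extent_um minimum resolvable adhesion extent (um); columns
#'   measuring shorter than this are left undefined.
#' @return data.frame: frame, distal_um, proximal_um.
#' @export
locate_tips <- function(kymo, background_level, min_extent_um = 0.5) {
  K <- kymo$matrix; pos <- kymo$positions_um
  nf <- ncol(K)
  distal <- proximal <- rep(NA_real_, nf)
  prev_mid <- NA_real_
  any_signal <- FALSE
  for (f in seq_len(nf)) {
    v <- K[, f]
    mx <- max(v)
    if (mx <= background_level) next
    thr <- background_level + 0.5 * (mx - background_level)
    above <- v >= thr
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- cbind(starts[r$values], ends[r$values])
    if (nrow(runs) > 1) {
      mids <- pos[runs[, 1]] + (pos[runs[, 2]] - pos[runs[, 1]]) / 2
      if (!is.na(prev_mid)) {
        sel <- which.min(abs(mids - prev_mid))
      } else {
        mass <- vapply(seq_len(nrow(runs)), function(i)
          sum(v[runs[i, 1]:runs[i, 2]]), numeric(1))
        cand <- which(mass == max(mass))
        sel <- cand[length(cand)]      # tie: most distal
      }
      runs <- runs[sel, , drop = FALSE]
    }
    i0 <- runs[1, 1]; i1 <- runs[1, 2]
    # sub-sample crossings
    proximal[f] <- if (i0 == 1) pos[1] else {
      frac <- (thr - v[i0 - 1]) / (v[i0] - v[i0 - 1])
      pos[i0 - 1] + frac * (pos[i0] - pos[i0 - 1])
    }
    distal[f] <- if (i1 == length(v)) pos[i1] else {
      frac <- (v[i1] - thr) / (v[i1] - v[i1 + 1])
      pos[i1] + frac * (pos[i1 + 1] - pos[i1])
    }
    if (distal[f] - proximal[f] < min_extent_um) {
      distal[f] <- proximal[f] <- NA_real_
      next
    }
    prev_mid <- (proximal[f] + distal[f]) / 2
    any_signal <- TRUE
  }
  if (!any_signal) stop("no adhesion on line: all columns at background")
  data.frame(frame = seq_len(nf), distal_um = distal, proximal_um = proximal)
}
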