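#' Ground-truth kinetics of one simulated focal adhesion
#'
#' Describes the life of one adhesion as a ribbon anchored at `anchor`
#' growing along `axis_angle` (the distal direction, pointing toward the
#' nearest cell edge). The distal tip extends from the anchor at
#' `v_assembly` until `t_halt_start`; the proximal tip stays at the anchor
#' until `t_halt_end`, then retracts toward the distal tip at
#' `v_disassembly`; the adhesion is removed at `t_disappear`.
#'
#' @param anchor c(x, y) position in micrometres.
#' @param axis_angle growth-axis angle in radians (distal direction).
#' @param width ribbon width in micrometres (> 0).
#' @param v_assembly distal-tip extension rate, um/min (>= 0).
#' @param v_disassembly proximal-tip retraction rate, um/min (>= 0).
#' @param t_appear,t_halt_start,t_halt_end,t_disappear event times in
#'   minutes, non-decreasing in this order.
#' @param peak_intensity ribbon intensity before PSF blur.
#' @return one-row data.frame of class `adhesion_kinetics`.
#' @export
adhesion_kinetics <- function(anchor, axis_angle, width = 0.6,
                              v_assembly, v_disassembly,
                              t_appear, t_halt_start, t_halt_end, t_disappear,
                              peak_intensity = 100) {
  stopifnot(length(anchor) == 2, width > 0,
            v_assembly >= 0, v_disassembly >= 0)
  if (!(t_appear <= t_halt_start && t_halt_start <= t_halt_end &&
        t_halt_end <= t_disappear))
    stop("need t_appear <= t_halt_start <= t_halt_end <= t_disappear")
  out <- data.frame(
    anchor_x = anchor[1], anchor_y = anchor[2], axis_angle = axis_angle,
    width = width, v_assembly = v_assembly, v_disassembly = v_disassembly,
    t_appear = t_appear, t_halt_start = t_halt_start,
    t_halt_end = t_halt_end, t_disappear = t_disappear,
    peak_intensity = peak_intensity
  )
  class(out) <- c("adhesion_kinetics", "data.frame")
  out
}

#' Sample a radial field of adhesion kinetics inside a cell mask
#'
#' Places `n` adhesions at equally spaced angular positions near the cell
#' border, each growing outward (distal direction toward the nearest edge),
#' with assembly/disassembly rates drawn uniformly from the given ranges
#' and staggered appearance times. Timings are chosen so that, within a
#' 60 min acquisition, each adhesion shows an observable assembly phase, a
#' halt and the start of disassembly. Disassembly runs until the ribbon is
#' consumed; adhesions whose disassembly outlasts the acquisition are
#' end-censored.
#'
#' @param cell_mask logical cell mask.
#' @param n number of adhesions.
#' @param pixel_size micrometres per pixel.
#' @param v_assembly_range,v_disassembly_range uniform sampling ranges
#'   (um/min).
#' @param length_range range of final ribbon lengths (um).
#' @param width ribbon width (um).
#' @param margin clearance between the final distal tip and the cell edge
#'   (um); each anchor is placed `final length + margin` inside the edge so
#'   the full-grown ribbon stays within the cell.
#' @param peak_intensity ribbon intensity.
#' @param seed integer seed; each adhesion draws from its own substream.
#' @return `adhesion_kinetics` data.frame with `n` rows.
#' @export
sample_adhesion_field <- function(cell_mask, n, pixel_size,
                                  v_assembly_range = c(0.1, 1.0),
                                  v_disassembly_range = c(0.05, 0.5),
                                  length_range = c(2.5, 3.8),
                                  width = 0.6, margin = 0.8,
                                  peak_intensity = 100, seed = 1) {
  cell_mask <- as_binary_matrix(cell_mask)
  dist_um <- edge_distance_um(cell_mask, pixel_size)
  ctr <- colMeans(mask_coords_um(cell_mask, pixel_size))

  rows <- vector("list", n)
  targets <- seq(-pi, pi, length.out = n + 1)[seq_len(n)]
  for (k in seq_len(n)) {
    set.seed(derive_seed(seed, k))
    v_a <- stats::runif(1, v_assembly_range[1], v_assembly_range[2])
    v_d <- stats::runif(1, v_disassembly_range[1], v_disassembly_range[2])
    # final length grows with v_assembly so that every assembly phase
    # spans at least ~3.5 frames (a measurable event at min_duration 3)
    lo <- min(max(length_range[1], 3.5 * v_a), length_range[2])
    len <- stats::runif(1, lo, length_range[2])
    # anchor ring deep enough for the grown ribbon to fit inside the cell
    ring <- dist_um >= len + margin & dist_um <= len + margin + 1.2
    if (!any(ring)) stop("no anchor ring deep enough; enlarge the cell")
    rc <- which(ring, arr.ind = TRUE)
    xy <- cbind((rc[, 2] - 0.5) * pixel_size, (rc[, 1] - 0.5) * pixel_size)
    ang <- atan2(xy[, 2] - ctr[2], xy[, 1] - ctr[1])
    i <- which.min(abs(((ang - targets[k] + pi) %% (2 * pi)) - pi))
    anchor <- xy[i, ]
    # distal direction: toward the nearest edge (outward)
    axis_angle <- atan2(anchor[2] - ctr[2], anchor[1] - ctr[1])
    t_appear <- stats::runif(1, 2, 6)
    dur_a <- len / v_a
    halt <- stats::runif(1, 5, 12)
    t_halt_start <- t_appear + dur_a
    t_halt_end <- min(t_halt_start + halt, 52)
    t_disappear <- t_halt_end + len / v_d
    rows[[k]] <- adhesion_kinetics(
      anchor = anchor, axis_angle = axis_angle, width = width,
      v_assembly = v_a, v_disassembly = v_d,
      t_appear = t_appear, t_halt_start = t_halt_start,
      t_halt_end = t_halt_end, t_disappear = t_disappear,
      peak_intensity = peak_intensity)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("adhesion_kinetics", "data.frame")
  out
}

# Tip positions (um along the growth axis, from the anchor) at time t for
# one kinetics row; NA when the adhesion does not exist at t.
tip_positions_at <- function(kin, t) {
  if (t < kin$t_appear || t > kin$t_disappear) return(c(distal = NA_real_, proximal = NA_real_))
  d_dist <- kin$v_assembly * min(t - kin$t_appear, kin$t_halt_start - kin$t_appear)
  d_prox <- if (t > kin$t_halt_end) kin$v_disassembly * (t - kin$t_halt_end) else 0
  c(distal = d_dist, proximal = min(d_prox, d_dist))
}

#' Simulate a single-channel adhesion time-lapse with ground truth
#'
#' Renders every adhesion per frame as a rectangular ribbon from its
#' proximal to its distal tip along the growth axis, sums objects, applies
#' Gaussian PSF blur, adds background and then noise (Poisson shot noise on
#' scaled counts plus Gaussian read noise, both per-frame substreams of
#' `seed`). Pixels of a ribbon falling outside the cell mask are clipped
#' and the frame is flagged in the truth table.
#'
#' @param cell_mask logical cell mask (single component).
#' @param kinetics `adhesion_kinetics` data.frame (zero or more rows).
#' @param acq an [acquisition_spec()].
#' @param seed integer seed for the noise streams.
#' @param visibility_area minimum rendered footprint (um^2) for a frame
#'   to count as `present` in the truth table: structures below the size
#'   of a minimal adhesion are not scored as visible. The per-frame pixel
#'   footprint is also recorded (`area_px`).
#' @return list with `stack` (array frames x rows x cols), `truth` (list:
#'   `kinetics`, per-frame `tips` table with columns track, frame, t,
#'   distal_um, proximal_um, distal_x/y, proximal_x/y, present, clipped),
#'   and `cell_mask`.
#' @export
simulate_adhesion_timelapse <- function(cell_mask, kinetics, acq, seed = 1,
                                        visibility_area = 0.2) {
  cell_mask <- as_binary_matrix(cell_mask)
  if (!all(dim(cell_mask) == acq$image_shape))
    stop("cell_mask shape must equal acq$image_shape")
  ps <- acq$pixel_size
  n_adh <- if (is.null(kinetics)) 0L else nrow(kinetics)

  # precondition: anchors inside the cell mask
  if (n_adh > 0) {
    arow <- pmin(pmax(ceiling(kinetics$anchor_y / ps), 1L), nrow(cell_mask))
    acol <- pmin(pmax(ceiling(kinetics$anchor_x / ps), 1L), ncol(cell_mask))
    inside <- cell_mask[cbind(arow, acol)]
    if (!all(inside))
      stop(sprintf("anchor(s) outside the cell mask: %s",
                   paste(which(!inside), collapse = ", ")))
  }

  nf <- acq$n_frames
  stack <- array(0, dim = c(nf, acq$image_shape[1], acq$image_shape[2]))
  tips <- vector("list", nf)

  for (f in seq_len(nf)) {
    t <- (f - 1) * acq$frame_interval
    signal <- matrix(0, acq$image_shape[1], acq$image_shape[2])
    rows_f <- vector("list", max(n_adh, 1))
    for (k in seq_len(n_adh)) {
      kin <- kinetics[k, ]
      tp <- tip_positions_at(kin, t)
      present <- FALSE; clipped <- FALSE; area_px <- 0L
      if (!is.na(tp["distal"]) && tp["distal"] - tp["proximal"] > 0) {
        fp <- ribbon_footprint(kin, tp, dim(signal), ps)
        if (length(fp$idx) > 0) {
          keep <- cell_mask[fp$idx]
          clipped <- any(!keep & fp$coverage >= 0.5)
          idx <- fp$idx[keep]; cv <- fp$coverage[keep]
          if (length(idx) > 0) {
            area_px <- sum(cv >= 0.5)
            present <- area_px * ps^2 >= visibility_area
            signal[idx] <- signal[idx] + kin$peak_intensity * cv
          }
        }
      }
      u <- c(cos(kin$axis_angle), sin(kin$axis_angle))
      rows_f[[k]] <- data.frame(
        track = k, frame = f, t = t,
        distal_um = unname(tp["distal"]), proximal_um = unname(tp["proximal"]),
        distal_x = kin$anchor_x + u[1] * tp["distal"],
        distal_y = kin$anchor_y + u[2] * tp["distal"],
        proximal_x = kin$anchor_x + u[1] * tp["proximal"],
        proximal_y = kin$anchor_y + u[2] * tp["proximal"],
        present = present, area_px = area_px, clipped = clipped)
    }
    tips[[f]] <- if (n_adh > 0) do.call(rbind, rows_f) else NULL
    stack[f, , ] <- render_frame(signal, acq, derive_seed(seed, f))
  }

  tips <- if (n_adh > 0) do.call(rbind, tips) else data.frame(
    track = integer(), frame = integer(), t = numeric(),
    distal_um = numeric(), proximal_um = numeric(),
    distal_x = numeric(), distal_y = numeric(),
    proximal_x = numeric(), proximal_y = numeric(),
    present = logical(), area_px = integer(), clipped = logical())
  tips <- tips[order(tips$track, tips$frame), , drop = FALSE]
  rownames(tips) <- NULL

  kin_truth <- if (n_adh > 0) {
    kinetics$censored_start <- kinetics$t_appear < 0
    kinetics$censored_end <- kinetics$t_disappear > (nf - 1) * acq$frame_interval
    kinetics
  } else kinetics

  list(stack = stack,
       truth = list(kinetics = kin_truth, tips = tips, seed = seed),
       cell_mask = cell_mask)
}

# Ribbon footprint with sub-pixel coverage for tips tp (um from anchor).
# Pixel intensity is proportional to the fraction of the pixel covered by
# the ribbon rectangle (photon flux integrates over the pixel area), so
# the rendered edge moves continuously as the tips advance instead of
# jumping one pixel at a time. Coverage is estimated on a 4x4 subgrid.
# Returns list(idx = linear indices with coverage > 0, coverage).
ribbon_footprint <- function(kin, tp, dim_rc, pixel_size) {
  u <- c(cos(kin$axis_angle), sin(kin$axis_angle))
  nv <- c(-u[2], u[1])
  p0 <- c(kin$anchor_x, kin$anchor_y) + u * tp["proximal"]
  p1 <- c(kin$anchor_x, kin$anchor_y) + u * tp["distal"]
  hw <- kin$width / 2
  corners_x <- c(p0[1] + nv[1] * hw, p0[1] - nv[1] * hw,
                 p1[1] + nv[1] * hw, p1[1] - nv[1] * hw)
  corners_y <- c(p0[2] + nv[2] * hw, p0[2] - nv[2] * hw,
                 p1[2] + nv[2] * hw, p1[2] - nv[2] * hw)
  c0 <- max(1L, floor(min(corners_x) / pixel_size))
  c1 <- min(dim_rc[2], ceiling(max(corners_x) / pixel_size) + 1L)
  r0 <- max(1L, floor(min(corners_y) / pixel_size))
  r1 <- min(dim_rc[1], ceiling(max(corners_y) / pixel_size) + 1L)
  if (c0 > c1 || r0 > r1) return(list(idx = integer(0), coverage = numeric(0)))
  rr <- r0:r1; cc <- c0:c1
  sub <- (seq_len(4) - 0.5) / 4 - 0.5          # subpixel offsets
  cov <- matrix(0, length(rr), length(cc))
  for (oy in sub) for (ox in sub) {
    xs <- (cc - 0.5 + ox) * pixel_size; ys <- (rr - 0.5 + oy) * pixel_size
    xg <- matrix(xs, length(rr), length(cc), byrow = TRUE) - kin$anchor_x
    yg <- matrix(ys, length(rr), length(cc)) - kin$anchor_y
    s <- xg * u[1] + yg * u[2]
    q <- xg * nv[1] + yg * nv[2]
    cov <- cov + (s >= tp["proximal"] & s <= tp["distal"] & abs(q) <= hw)
  }
  cov <- cov / 16
  idx <- which(cov > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list(idx = integer(0), coverage = numeric(0)))
  list(idx = (cc[idx[, 2]] - 1L) * dim_rc[1] + rr[idx[, 1]],
       coverage = cov[idx])
}
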