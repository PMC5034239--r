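#' Segment tip trajectories into turnover events
#'
#' The distal tip series is split into maximal runs of advancing steps;
#' a run lasting at least `min_duration` frames whose mean rate (total
#' displacement over total time) is at least `min_rate` becomes an
#' assembly event. The proximal series, whose position increases toward
#' the distal end during retraction, yields disassembly events the same
#' way. Steps are classified against `min_rate` using a windowed local
#' slope (robust to tip jitter near the rate threshold); isolated single
#' non-advancing steps inside a run are absorbed and run boundaries are
#' trimmed of non-moving steps. Events never span frames with undefined
#' tips. Time not covered by an event is halt.
#'
#' @param tips data.frame from [locate_tips()] (frame, distal_um,
#'   proximal_um).
#' @param frame_interval minutes per frame.
#' @param min_rate minimum mean rate for an event (um/min, default 0.05).
#' @param min_duration minimum event length in frames (default 3).
#' @param smooth classify steps by windowed local slope (+/- 2 steps)
#'   instead of raw single-step rates.
#' @return data.frame of class `turnover_events`: kind ("assembly" or
#'   "disassembly"), frame_start, frame_end, t_start, t_end (min),
#'   delta_d (um), rate (um/min).
#' @export
segment_events <- function(tips, frame_interval = 1, min_rate = 0.05,
                           min_duration = 3, smooth = TRUE) {
  if (nrow(tips) < min_duration)
    stop("tip series shorter than min_duration")
  ev_a <- monotone_events(tips$distal_um, tips$frame, frame_interval,
                          min_rate, min_duration, smooth)
  ev_d <- monotone_events(tips$proximal_um, tips$frame, frame_interval,
                          min_rate, min_duration, smooth)
  out <- rbind(
    if (nrow(ev_a$events)) cbind(kind = "assembly", ev_a$events),
    if (nrow(ev_d$events)) cbind(kind = "disassembly", ev_d$events))
  if (is.null(out))
    out <- data.frame(kind = character(), frame_start = integer(),
                      frame_end = integer(), t_start = numeric(),
                      t_end = numeric(), delta_d = numeric(),
                      rate = numeric())
  class(out) <- c("turnover_events", "data.frame")
  # full (untrimmed) moving intervals, used for halt-time accounting
  attr(out, "moving_intervals") <- rbind(ev_a$intervals, ev_d$intervals)
  out
}

# Advancing (increasing-position) events of one tip series.
#
# Steps are classified as moving against a local slope estimated over a
# window of +/- 2 steps (robust to tip-localisation jitter when the true
# rate is near min_rate); runs of moving steps are then trimmed of
# boundary steps whose own step rate is below min_rate/2 (the windowed
# slope otherwise bleeds a fast event's boundary into the adjacent halt
# and dilutes its delta-D/delta-T rate). Single-step interruptions inside
# a run are absorbed.
monotone_events <- function(x, frames, dt, min_rate, min_duration, smooth) {
  empty <- data.frame(frame_start = integer(), frame_end = integer(),
                      t_start = numeric(), t_end = numeric(),
                      delta_d = numeric(), rate = numeric())
  empty_iv <- data.frame(t_start = numeric(), t_end = numeric())
  def <- !is.na(x)
  if (!any(def)) return(list(events = empty, intervals = empty_iv))
  out <- list()
  ivs <- list()
  # process each contiguous defined block independently (events cannot
  # span undefined gaps)
  r <- rle(def)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (b in which(r$values)) {
    i0 <- starts[b]; i1 <- ends[b]
    n <- i1 - i0 + 1
    if (n < min_duration) next
    xs <- x[i0:i1]
    ns <- n - 1                       # number of steps
    step <- diff(xs) / dt
    h <- if (smooth) 2L else 0L
    slope <- vapply(seq_len(ns), function(t) {
      a <- max(1L, t - h); z <- min(n, t + 1L + h)
      (xs[z] - xs[a]) / ((z - a) * dt)
    }, numeric(1))
    # a step is moving when either its local windowed slope or its own
    # step rate reaches min_rate; the windowed slope rescues slow ramps
    # whose single steps jitter around the threshold, the raw step keeps
    # the onset of a slow event from being absorbed into the halt
    adv <- slope >= min_rate | step >= min_rate
    # absorb isolated single non-advancing steps flanked by advances
    if (ns >= 3) {
      iso <- which(!adv[-c(1, ns)]) + 1
      iso <- iso[adv[iso - 1] & adv[iso + 1]]
      adv[iso] <- TRUE
    }
    rr <- rle(adv)
    e2 <- cumsum(rr$lengths); s2 <- e2 - rr$lengths + 1
    for (k in which(rr$values)) {
      a <- s2[k]; z <- e2[k]            # step indices of the run
      while (a <= z && step[a] < min_rate / 2) a <- a + 1
      while (z >= a && step[z] < min_rate / 2) z <- z - 1
      a0 <- a; z0 <- z                  # moving extent (halt accounting)
      # a boundary interval in which the tip moved only part of the frame
      # (motion started/stopped mid-interval) dilutes delta-D/delta-T;
      # trim boundary steps clearly slower than the run's typical step
      if (z > a) {
        med <- stats::median(step[a:z])
        while (a < z && step[a] < 0.8 * med) a <- a + 1
        while (z > a && step[z] < 0.8 * med) z <- z - 1
      }
      if (z - a + 2 < min_duration) next   # frames spanned = steps + 1
      f0 <- frames[i0 + a - 1]; f1 <- frames[i0 + z]
      delta <- xs[z + 1] - xs[a]
      t0 <- (f0 - 1) * dt; t1 <- (f1 - 1) * dt
      rate <- delta / (t1 - t0)
      if (rate < min_rate) next
      out[[length(out) + 1]] <- data.frame(
        frame_start = f0, frame_end = f1, t_start = t0, t_end = t1,
        delta_d = delta, rate = rate)
      ivs[[length(ivs) + 1]] <- data.frame(
        t_start = (frames[i0 + a0 - 1] - 1) * dt,
        t_end = (frames[i0 + z0] - 1) * dt)
    }
  }
  list(events = if (length(out) == 0) empty else do.call(rbind, out),
       intervals = if (length(ivs) == 0) empty_iv else do.call(rbind, ivs))
}

#' Per-adhesion turnover metrics
#'
#' Aggregates one track's events into the turnover summary: mean assembly
#' and disassembly rates (NA when a tip shows no event of that kind, never
#' 0), halt time (observed lifespan minus event time minus undefined-tip
#' time), lifespan ((last - first + 1) frames, capped at the acquisition
#' duration), and event counts both raw and normalised per 60 min of
#' observation.
#'
#' @param events [segment_events()] output for this track.
#' @param track one track from [track_adhesions()].
#' @param acq an [acquisition_spec()].
#' @param tips optional tips data.frame, used to count undefined-tip
#'   frames within the track's life (default: none undefined).
#' @return one-row data.frame: track_id, assembly_rate, disassembly_rate,
#'   halt_time, lifespan, n_assembly, n_disassembly, n_halt,
#'   n_assembly_per60, n_disassembly_per60, undefined_time,
#'   censored_start, censored_end.
#' @export
turnover_metrics <- function(events, track, acq, tips = NULL) {
  if ((is.null(events) || nrow(events) == 0) && length(track$frames) == 0)
    stop("empty event list and empty track")
  dt <- acq$frame_interval
  lifespan <- min((track$last_frame - track$first_frame + 1) * dt,
                  acq$n_frames * dt)
  a <- events[events$kind == "assembly", , drop = FALSE]
  d <- events[events$kind == "disassembly", , drop = FALSE]

  # time covered by events, without double counting overlapping intervals;
  # the untrimmed moving intervals (when attached) give the halt boundary,
  # since rate windows are trimmed of partial boundary steps
  iv0 <- attr(events, "moving_intervals")
  if (is.null(iv0) || nrow(iv0) == 0)
    iv0 <- if (nrow(events)) events[, c("t_start", "t_end")] else NULL
  event_time <- 0
  if (!is.null(iv0) && nrow(iv0) > 0) {
    iv <- iv0[order(iv0$t_start), , drop = FALSE]
    cur <- c(iv$t_start[1], iv$t_end[1])
    for (i in seq_len(nrow(iv))[-1]) {
      if (iv$t_start[i] <= cur[2]) cur[2] <- max(cur[2], iv$t_end[i])
      else { event_time <- event_time + cur[2] - cur[1]; cur <- c(iv$t_start[i], iv$t_end[i]) }
    }
    event_time <- event_time + cur[2] - cur[1]
  }
  undefined_time <- if (is.null(tips)) 0 else {
    inlife <- tips$frame >= track$first_frame & tips$frame <= track$last_frame
    sum(is.na(tips$distal_um[inlife]) & is.na(tips$proximal_um[inlife])) * dt
  }
  halt_time <- max(lifespan - event_time - undefined_time, 0)

  data.frame(
    track_id = track$id,
    assembly_rate = if (nrow(a)) mean(a$rate) else NA_real_,
    disassembly_rate = if (nrow(d)) mean(d$rate) else NA_real_,
    halt_time = halt_time, lifespan = lifespan,
    n_assembly = nrow(a), n_disassembly = nrow(d),
    n_halt = as.integer(halt_time > 0),
    n_assembly_per60 = nrow(a) * 60 / lifespan,
    n_disassembly_per60 = nrow(d) * 60 / lifespan,
    undefined_time = undefined_time,
    censored_start = track$censored_start, censored_end = track$censored_end)
}

#' Adhesion count and density on one frame
#'
#' Quantification of focal adhesion density, typically on the first image
#' of a time series.
#'
#' @param labels adhesion label map of the frame.
#' @param cell_mask logical cell mask.
#' @param pixel_size micrometres per pixel.
#' @return list: count, count_per_um2, area_fraction (adhesion px within
#'   the cell / cell px).
#' @export
adhesion_density <- function(labels, cell_mask, pixel_size) {
  cell_mask <- as_binary_matrix(cell_mask)
  if (!any(cell_mask)) stop("cell area is zero")
  cell_area_um2 <- sum(cell_mask) * pixel_size^2
  list(count = max(labels),
       count_per_um2 = max(labels) / cell_area_um2,
       area_fraction = sum(labels > 0 & cell_mask) / sum(cell_mask))
}

#' Adhesion coverage of a peripheral region
#'
#' Places a `region_size` rectangle (default 20 x 10 um) with its long
#' edge tangent to the cell boundary at an anchor point, extending inward,
#' and reports the fraction of its in-cell pixels that are
#' adhesion-positive. The anchor defaults to the boundary point farthest
#' from the cell centroid (the tip of the dominant protrusion).
#'
#' @param adhesion_mask logical adhesion mask.
#' @param cell_mask logical cell mask.
#' @param pixel_size micrometres per pixel.
#' @param region_size c(long, depth) rectangle in micrometres.
#' @param anchor_um optional c(x, y) boundary anchor in micrometres.
#' @return list: fraction, region_mask, anchor_um, n_region_px.
#' @export
peripheral_adhesion_fraction <- function(adhesion_mask, cell_mask, pixel_size,
                                         region_size = c(20, 10),
                                         anchor_um = NULL) {
  adhesion_mask <- as_binary_matrix(adhesion_mask)
  cell_mask <- as_binary_matrix(cell_mask)
  check_same_shape(adhesion_mask, cell_mask, "masks")
  edge <- cell_mask & !(EBImage::imageData(EBImage::erode(
    EBImage::Image(cell_mask * 1), EBImage::makeBrush(3, "box"))) > 0)
  eidx <- which(edge, arr.ind = TRUE)
  ex <- (eidx[, 2] - 0.5) * pixel_size
  ey <- (eidx[, 1] - 0.5) * pixel_size
  ctr <- colMeans(mask_coords_um(cell_mask, pixel_size))
  if (is.null(anchor_um)) {
    i <- which.max((ex - ctr[1])^2 + (ey - ctr[2])^2)
    anchor_um <- c(ex[i], ey[i])
  }
  # local boundary tangent from boundary points within 3 um of the anchor
  near <- (ex - anchor_um[1])^2 + (ey - anchor_um[2])^2 <= 9
  if (sum(near) >= 2) {
    dx <- ex[near] - mean(ex[near]); dy <- ey[near] - mean(ey[near])
    cxx <- mean(dx^2); cyy <- mean(dy^2); cxy <- mean(dx * dy)
    l1 <- (cxx + cyy) / 2 + sqrt(((cxx - cyy) / 2)^2 + cxy^2)
    u <- if (abs(cxy) > 1e-12) c(l1 - cyy, cxy) else
      if (cxx >= cyy) c(1, 0) else c(0, 1)
    u <- u / sqrt(sum(u^2))
  } else u <- c(1, 0)
  inward <- ctr - anchor_um
  nv <- c(-u[2], u[1])
  if (sum(nv * inward) < 0) nv <- -nv

  center <- anchor_um + nv * region_size[2] / 2
  dim_rc <- dim(cell_mask)
  cc0 <- pixel_centers_um(dim_rc, pixel_size)
  xg <- matrix(cc0$x, dim_rc[1], dim_rc[2], byrow = TRUE) - center[1]
  yg <- matrix(cc0$y, dim_rc[1], dim_rc[2]) - center[2]
  s <- xg * u[1] + yg * u[2]
  q <- xg * nv[1] + yg * nv[2]
  region <- abs(s) <= region_size[1] / 2 & abs(q) <= region_size[2] / 2
  in_cell <- region & cell_mask
  if (!any(in_cell)) stop("region lies fully outside the cell")
  list(fraction = sum(adhesion_mask & in_cell) / sum(in_cell),
       region_mask = region, anchor_um = anchor_um,
       n_region_px = sum(in_cell))
}

#' Full adhesion-dynamics quantification of a time-lapse
#'
#' Runs detection (one shared threshold from the first frame), tracking,
#' growth-axis fitting, kymograph extraction, tip localisation, event
#' segmentation and per-track turnover metrics.
#'
#' @param stack array (frames x rows x cols), adhesion channel.
#' @param cell_mask logical cell mask.
#' @param acq an [acquisition_spec()].
#' @param min_area minimum adhesion area (um^2).
#' @param max_gap tracking gap (frames).
#' @param kymo_length kymograph line length (um).
#' @param width_avg kymograph width averaging (px).
#' @param min_rate,min_duration event criteria, see [segment_events()].
#' @param min_track_frames tracks shorter than this are dropped from the
#'   metrics (too short to orient).
#' @return list: `labels` (per frame), `tracks`, `per_track` (list with
#'   axis, kymo, tips, events per usable track), `metrics` (data.frame),
#'   `threshold`.
#' @export
adhesion_dynamics_pipeline <- function(stack, cell_mask, acq,
                                       min_area = 0.2, max_gap = 1,
                                       kymo_length = 10, width_avg = 3,
                                       min_rate = 0.05, min_duration = 3,
                                       min_track_frames = 5) {
  nf <- dim(stack)[1]
  frames <- lapply(seq_len(nf), function(f) stack[f, , ])
  # one shared threshold for the whole series, computed by Otsu on the
  # pixel-wise max projection (robust to frames without adhesions yet)
  proj <- Reduce(pmax, frames)
  thr <- attr(threshold_mask(proj, method = "otsu"), "threshold")
  masks <- threshold_batch(frames, method = "fixed", value = thr)
  labels <- lapply(masks, label_regions, min_area = min_area,
                   pixel_size = acq$pixel_size)
  tracks <- track_adhesions(labels, max_gap = max_gap)

  per_track <- list()
  metrics <- list()
  for (tr in tracks) {
    if (length(tr$frames) < min_track_frames) next
    ax <- tryCatch(growth_axis(tr, cell_mask, acq$pixel_size,
                               length_um = kymo_length),
                   error = function(e) NULL)
    if (is.null(ax)) next
    ky <- extract_kymograph(frames, ax, width_avg = width_avg,
                            pixel_size = acq$pixel_size)
    # tips are unresolvable below ~2 PSF FWHM: such columns stay undefined
    min_extent <- max(3 * acq$pixel_size, 2 * 2.355 * acq$psf_sigma)
    tp <- tryCatch(locate_tips(ky, acq$background_level,
                               min_extent_um = min_extent),
                   error = function(e) NULL)
    if (is.null(tp)) next
    # restrict tips to the track's life: outside it the line may read a
    # different adhesion
    tp$distal_um[tp$frame < tr$first_frame | tp$frame > tr$last_frame] <- NA
    tp$proximal_um[tp$frame < tr$first_frame | tp$frame > tr$last_frame] <- NA
    ev <- segment_events(tp, frame_interval = acq$frame_interval,
                         min_rate = min_rate, min_duration = min_duration)
    per_track[[length(per_track) + 1]] <-
      list(track = tr, axis = ax, kymo = ky, tips = tp, events = ev)
    metrics[[length(metrics) + 1]] <- turnover_metrics(ev, tr, acq, tips = tp)
  }
  metrics <- if (length(metrics)) do.call(rbind, metrics) else NULL
  list(labels = labels, tracks = tracks, per_track = per_track,
       metrics = metrics, threshold = attr(masks, "threshold"))
}
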