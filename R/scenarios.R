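#' Simulate and quantify one adhesion-turnover scenario
#'
#' End-to-end helper used by the analysis scripts and validation: builds
#' an elliptical cell, samples a radial adhesion field with staggered
#' kinetics, simulates the time-lapse, runs the full quantification
#' pipeline and matches each recovered track back to its ground-truth
#' adhesion by position. `v_disassembly_scale` rescales every adhesion's
#' disassembly rate (e.g. 0.5 emulates a scaffold-silencing condition in
#' which disassembly is specifically slowed); all other kinetics are
#' untouched, so paired scenarios differing only in this scale share
#' identical assembly rates and timings.
#'
#' @param n_adhesions number of simulated adhesions.
#' @param seed integer seed.
#' @param v_disassembly_scale multiplier on sampled disassembly rates.
#' @param v_assembly_range,v_disassembly_range sampling ranges (um/min).
#' @param image_shape,pixel_size,n_frames,frame_interval acquisition
#'   geometry.
#' @param background_level,psf_sigma,poisson_scale,read_noise_sigma
#'   rendering/noise settings (defaults: noiseless, 1 px PSF).
#' @param semi_axes cell ellipse semi-axes (um).
#' @param min_rate,min_duration,kymo_length,width_avg,min_adhesion_area,max_gap
#'   pipeline parameters, see [adhesion_dynamics_pipeline()].
#' @return list: `cell_mask`, `kinetics` (with truth summaries),
#'   `sim` (simulator output), `result` (pipeline output), `matched`
#'   (data.frame pairing truth and recovered metrics per adhesion).
#' @export
turnover_scenario <- function(n_adhesions = 30, seed = 1,
                              v_disassembly_scale = 1,
                              v_assembly_range = c(0.1, 1.0),
                              v_disassembly_range = c(0.05, 0.5),
                              image_shape = c(300L, 300L), pixel_size = 0.16,
                              n_frames = 60, frame_interval = 1,
                              background_level = 10, psf_sigma = 0.16,
                              poisson_scale = 0, read_noise_sigma = 0,
                              semi_axes = c(20, 14),
                              min_rate = 0.05, min_duration = 3,
                              kymo_length = 10, width_avg = 3,
                              min_adhesion_area = 0.2, max_gap = 1) {
  acq <- acquisition_spec(
    frame_interval = frame_interval, n_frames = n_frames,
    pixel_size = pixel_size, image_shape = image_shape,
    psf_sigma = psf_sigma, background_level = background_level,
    poisson_scale = poisson_scale, read_noise_sigma = read_noise_sigma)
  cell <- simulate_cell_mask(image_shape, pixel_size, shape = "ellipse",
                             shape_params = list(semi_axes = semi_axes))
  kin <- sample_adhesion_field(cell, n_adhesions, pixel_size,
                               v_assembly_range = v_assembly_range,
                               v_disassembly_range = v_disassembly_range,
                               seed = seed)
  kin$v_disassembly <- kin$v_disassembly * v_disassembly_scale
  kin$t_disappear <- kin$t_halt_end +
    (kin$v_assembly * (kin$t_halt_start - kin$t_appear)) / kin$v_disassembly
  sim <- simulate_adhesion_timelapse(cell, kin, acq, seed = seed)
  res <- adhesion_dynamics_pipeline(
    sim$stack, cell, acq, min_area = min_adhesion_area, max_gap = max_gap,
    kymo_length = kymo_length, width_avg = width_avg,
    min_rate = min_rate, min_duration = min_duration)
  matched <- match_tracks_to_truth(res, sim$truth, acq)
  list(cell_mask = cell, kinetics = sim$truth$kinetics, sim = sim,
       result = res, matched = matched, acq = acq)
}

#' Pair recovered tracks with ground-truth adhesions
#'
#' Each truth adhesion is matched to the recovered track whose footprint
#' centroid lies nearest its time-averaged truth midpoint (within
#' `max_dist` um). Truth summaries (rates, observed lifespan and halt
#' time) are joined with the recovered turnover metrics.
#'
#' @param result [adhesion_dynamics_pipeline()] output.
#' @param truth simulator truth (list with `kinetics` and `tips`).
#' @param acq the [acquisition_spec()] used.
#' @param max_dist maximum truth-to-track centroid distance (um).
#' @return data.frame, one row per matched adhesion: truth_id, track_id,
#'   true/recovered assembly and disassembly rates, lifespans, halt
#'   times, axis angles.
#' @export
match_tracks_to_truth <- function(result, truth, acq, max_dist = 2.5) {
  ps <- acq$pixel_size
  dt <- acq$frame_interval
  t_end <- (acq$n_frames - 1) * dt
  kin <- truth$kinetics
  if (is.null(kin) || nrow(kin) == 0 || is.null(result$metrics))
    return(NULL)

  track_ctr <- t(vapply(result$per_track, function(pt) {
    px <- unique(unlist(pt$track$footprints))
    rr <- ((px - 1) %% pt$track$dim[1]) + 1
    cc <- ((px - 1) %/% pt$track$dim[1]) + 1
    c((mean(cc) - 0.5) * ps, (mean(rr) - 0.5) * ps)
  }, numeric(2)))
  track_ids <- vapply(result$per_track, function(pt) pt$track$id, numeric(1))

  rows <- list()
  for (k in seq_len(nrow(kin))) {
    tk <- truth$tips[truth$tips$track == k & truth$tips$present, , drop = FALSE]
    if (nrow(tk) == 0) next
    mid <- c(mean((tk$distal_x + tk$proximal_x) / 2),
             mean((tk$distal_y + tk$proximal_y) / 2))
    d2 <- (track_ctr[, 1] - mid[1])^2 + (track_ctr[, 2] - mid[2])^2
    i <- which.min(d2)
    if (sqrt(d2[i]) > max_dist) next
    m <- result$metrics[result$metrics$track_id == track_ids[i], , drop = FALSE]
    if (nrow(m) == 0) next
    true_halt <- max(0, min(kin$t_halt_end[k], t_end) -
                          min(kin$t_halt_start[k], t_end))
    axis_rec <- result$per_track[[i]]$axis$angle
    rows[[length(rows) + 1]] <- data.frame(
      truth_id = k, track_id = m$track_id,
      true_assembly = kin$v_assembly[k], rec_assembly = m$assembly_rate,
      true_disassembly = kin$v_disassembly[k],
      rec_disassembly = m$disassembly_rate,
      true_lifespan = nrow(tk) * dt, rec_lifespan = m$lifespan,
      true_halt = true_halt, rec_halt = m$halt_time,
      true_angle = kin$axis_angle[k], rec_angle = axis_rec,
      assembly_rate = m$assembly_rate,
      disassembly_rate = m$disassembly_rate,
      lifespan = m$lifespan, halt_time = m$halt_time,
      censored_end = m$censored_end)
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}
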