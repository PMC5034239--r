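#' Write an image stack to multipage TIFF with a calibration sidecar
#'
#' Frames are stored as 16-bit unsigned integers (`bits = 16`), which is
#' lossless for integer-valued stacks up to 65535 (the simulator's output
#' with integer `poisson_scale` and no read noise is integer-valued), or
#' as 32-bit floats of the intensities divided by a recorded scale
#' (`bits = 32`, quantised to single precision). Calibration and the
#' storage scale are written to a `<path>.yaml` sidecar so the stack
#' round-trips without external knowledge.
#'
#' @param stack array (frames x rows x cols).
#' @param path output TIFF path.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval minutes per frame.
#' @param bits 16 (integer, exact) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, pixel_size, frame_interval, bits = 16) {
  nf <- dim(stack)[1]
  frames <- lapply(seq_len(nf), function(f) stack[f, , ])
  if (bits == 16) {
    mx <- max(stack)
    if (max(abs(stack - round(stack))) > 1e-9 || mx > 65535 || min(stack) < 0)
      stop("16-bit mode needs integer-valued intensities in [0, 65535]; use bits = 32")
    scale <- 65535
    frames <- lapply(frames, function(m) round(m) / 65535)
  } else {
    scale <- max(stack, 1e-12)
    frames <- lapply(frames, function(m) pmin(pmax(m / scale, 0), 1))
  }
  tiff::writeTIFF(frames, path, bits.per.sample = bits, reduce = FALSE)
  yaml::write_yaml(list(pixel_size = pixel_size,
                        frame_interval = frame_interval,
                        scale = scale, bits = bits, n_frames = nf),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a calibrated image stack from multipage TIFF
#'
#' Reads one file per channel (layout "tyx") or one interleaved file
#' (layout "tcyx", frame-major: frame 1 channels 1..C, frame 2 ...).
#' Calibration is taken from the sidecar written by [write_stack()] when
#' present; otherwise `pixel_size` and `frame_interval` must be given
#' explicitly — they are never silently assumed.
#'
#' @param paths character vector of TIFF paths (one per channel for
#'   "tyx"; a single path for "tcyx").
#' @param layout "tyx" or "tcyx".
#' @param n_channels number of channels for layout "tcyx".
#' @param pixel_size,frame_interval calibration overrides (um/px,
#'   min/frame).
#' @param channel_roles optional character vector naming each channel's
#'   role (e.g. c("adhesion", "vesicle")).
#' @return object of class `image_stack`: list with `data` (array
#'   frames x channels x rows x cols), `pixel_size`, `frame_interval`,
#'   `channel_roles`.
#' @export
read_stack <- function(paths, layout = c("tyx", "tcyx"), n_channels = 1,
                       pixel_size = NULL, frame_interval = NULL,
                       channel_roles = NULL) {
  layout <- match.arg(layout)
  for (p in paths) if (!file.exists(p)) stop("file not found: ", p)

  read_one <- function(p) {
    fr <- tiff::readTIFF(p, all = TRUE)
    side <- paste0(p, ".yaml")
    meta <- if (file.exists(side)) yaml::read_yaml(side) else NULL
    sc <- if (is.null(meta)) 1 else meta$scale
    frames <- lapply(fr, function(m) {
      v <- m * sc
      if (!is.null(meta) && meta$bits == 16) v <- round(v)
      v
    })
    list(frames = frames, meta = meta)
  }

  parts <- lapply(paths, read_one)
  metas <- Filter(Negate(is.null), lapply(parts, `[[`, "meta"))
  if (is.null(pixel_size))
    pixel_size <- if (length(metas)) metas[[1]]$pixel_size else
      stop("pixel_size unknown: no sidecar found, pass it explicitly")
  if (is.null(frame_interval))
    frame_interval <- if (length(metas)) metas[[1]]$frame_interval else
      stop("frame_interval unknown: no sidecar found, pass it explicitly")

  if (layout == "tyx") {
    nC <- length(paths)
    nT <- length(parts[[1]]$frames)
    for (p in parts) if (length(p$frames) != nT)
      stop("channel files disagree on frame count")
    dim_rc <- dim(parts[[1]]$frames[[1]])
    data <- array(0, dim = c(nT, nC, dim_rc[1], dim_rc[2]))
    for (ch in seq_len(nC)) for (f in seq_len(nT))
      data[f, ch, , ] <- parts[[ch]]$frames[[f]]
  } else {
    frames <- parts[[1]]$frames
    if (length(frames) %% n_channels != 0)
      stop(sprintf("frame count %d is not a multiple of n_channels = %d",
                   length(frames), n_channels))
    nT <- length(frames) / n_channels
    dim_rc <- dim(frames[[1]])
    data <- array(0, dim = c(nT, n_channels, dim_rc[1], dim_rc[2]))
    for (f in seq_len(nT)) for (ch in seq_len(n_channels))
      data[f, ch, , ] <- frames[[(f - 1) * n_channels + ch]]
  }
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channel_roles = channel_roles),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d frames x %d channels x %dx%d px @ %g um/px, %g min/frame\n",
              d[1], d[2], d[3], d[4], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Pipeline configuration
#'
#' All tunable parameters of the quantification pipeline in one list that
#' round-trips losslessly through YAML. Physical parameters are in
#' micrometres and minutes.
#'
#' @param ... overrides of the defaults (see the returned list).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    pixel_size = 0.16, frame_interval = 1, n_frames = 60,
    image_shape = c(300L, 300L),
    background_level = 10, psf_sigma = 0.16,
    poisson_scale = 0, read_noise_sigma = 0,
    min_adhesion_area = 0.2, max_gap = 1,
    kymo_length = 10, width_avg = 3,
    min_rate = 0.05, min_duration = 3,
    neighborhood_distance = 0.8, crop_size = c(5, 4),
    band_width = 10,
    n_adhesions = 12, v_disassembly_scale = 1,
    semi_axes = c(20, 14),
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  for (f in c("pixel_size", "frame_interval", "band_width", "kymo_length"))
    if (cfg[[f]] <= 0) stop(f, " must be > 0")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the simulation-to-metrics pipeline and write its reports
#'
#' Simulates an adhesion time-lapse under the configured scenario, runs
#' segmentation, tracking, kymograph turnover analysis and the peripheral
#' partition, and writes per-track metrics, per-event tables, partition
#' statistics, a JSON summary and the resolved configuration beside them.
#' Re-running with the same config reproduces the outputs byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `metrics`, `events`, `partition_stats`, `summary`
#'   (also written to `out_dir`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "resolved_config.yaml"))

  scn <- turnover_scenario(
    n_adhesions = config$n_adhesions, seed = config$seed,
    v_disassembly_scale = config$v_disassembly_scale,
    semi_axes = config$semi_axes,
    image_shape = config$image_shape, pixel_size = config$pixel_size,
    n_frames = config$n_frames, frame_interval = config$frame_interval,
    background_level = config$background_level,
    psf_sigma = config$psf_sigma, poisson_scale = config$poisson_scale,
    read_noise_sigma = config$read_noise_sigma,
    min_rate = config$min_rate, min_duration = config$min_duration,
    kymo_length = config$kymo_length, width_avg = config$width_avg,
    min_adhesion_area = config$min_adhesion_area, max_gap = config$max_gap)

  part <- partition_cell(scn$cell_mask, band_width = config$band_width,
                         pixel_size = config$pixel_size)
  adh_mask <- scn$result$labels[[1]] > 0
  psig <- peripheral_signal(adh_mask, part)
  partition_stats <- data.frame(
    cell_area_um2 = part$cell_area_um2,
    central_area_um2 = part$central_area_um2,
    peripheral_area_um2 = part$peripheral_area_um2,
    fa_total_px = psig$total, fa_peripheral_px = psig$peripheral,
    fa_peripheral_normalized = psig$peripheral_normalized)

  events <- do.call(rbind, lapply(seq_along(scn$result$per_track), function(i) {
    ev <- scn$result$per_track[[i]]$events
    if (nrow(ev) == 0) return(NULL)
    cbind(track_id = scn$result$per_track[[i]]$track$id, ev)
  }))
  if (is.null(events))
    events <- data.frame(track_id = integer(), kind = character(),
                         frame_start = integer(), frame_end = integer(),
                         t_start = numeric(), t_end = numeric(),
                         delta_d = numeric(), rate = numeric())

  metrics <- scn$matched
  summary <- list(
    n_tracks = nrow(metrics),
    mean_assembly_rate = mean(metrics$assembly_rate, na.rm = TRUE),
    mean_disassembly_rate = mean(metrics$disassembly_rate, na.rm = TRUE),
    mean_lifespan = mean(metrics$lifespan),
    mean_halt_time = mean(metrics$halt_time),
    adhesions_first_frame = max(scn$result$labels[[1]]),
    seed = config$seed)

  export_report(list(metrics = metrics, events = events,
                     partition_stats = partition_stats), out_dir)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(list(metrics = metrics, events = events,
                 partition_stats = partition_stats, summary = summary))
}

#' Write result tables as CSV files with a stable schema
#'
#' Each element of `results` must be a data.frame; it is written to
#' `<name>.csv` with numeric columns rounded to 6 decimals so reruns are
#' byte-stable and re-parsing returns the written values.
#'
#' @param results named list of data.frames.
#' @param out_dir output directory.
#' @return character vector of file paths, invisibly.
#' @export
export_report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    df <- results[[nm]]
    if (!is.data.frame(df)) stop("'", nm, "' is not a data.frame")
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) round(v, 6))
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
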