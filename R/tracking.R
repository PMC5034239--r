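#' Detect focal adhesions in one frame
#'
#' Thresholds the adhesion channel and labels 8-connected regions at least
#' `min_area` large; a thin wrapper around [threshold_mask()] and
#' [label_regions()] so the detection settings live in one place.
#'
#' @param frame numeric matrix.
#' @param method,value thresholding as in [threshold_mask()].
#' @param min_area minimum adhesion area (um^2 when `pixel_size` given).
#' @param pixel_size micrometres per pixel.
#' @return integer label map.
#' @export
detect_adhesions <- function(frame, method = "otsu", value = NULL,
                             min_area = 0.2, pixel_size = NULL) {
  m <- threshold_mask(frame, method = method, value = value)
  lab <- label_regions(m, min_area = min_area, pixel_size = pixel_size)
  attr(lab, "threshold") <- attr(m, "threshold")
  lab
}

#' Track adhesions across frames by footprint overlap
#'
#' Greedy frame-to-frame linking: candidate pairs between open tracks and
#' the current frame's objects are ranked by overlap fraction
#' (intersection over union of footprints), ties broken by smaller
#' centroid distance and then smaller label; unmatched objects start new
#' tracks; a track missing from up to `max_gap` consecutive frames is
#' bridged, otherwise closed. Tracks touching the first or last frame are
#' flagged censored.
#'
#' @param label_stack list of integer label maps, one per frame (>= 2).
#' @param max_gap maximum number of consecutive missed frames bridged.
#' @return list of tracks, each a list with `id`, `frames`, `labels`,
#'   `footprints` (pixel index vectors), `centroids` (frames x 2 matrix of
#'   row/col), `first_frame`, `last_frame`, `censored_start`,
#'   `censored_end`.
#' @export
track_adhesions <- function(label_stack, max_gap = 1) {
  nf <- length(label_stack)
  if (nf < 2) stop("need >= 2 frames to track")
  dim_rc <- dim(label_stack[[1]])

  objects_of <- function(lab) {
    n <- max(lab)
    if (n == 0) return(list())
    idx <- which(lab > 0)
    lb <- lab[idx]
    lapply(seq_len(n), function(k) {
      px <- idx[lb == k]
      rr <- ((px - 1) %% dim_rc[1]) + 1
      cc <- ((px - 1) %/% dim_rc[1]) + 1
      list(label = k, px = px, centroid = c(mean(rr), mean(cc)))
    })
  }

  tracks <- list()
  open <- list()   # each: track index, last_px, last_centroid, last_frame

  for (f in seq_len(nf)) {
    objs <- objects_of(label_stack[[f]])
    # score all candidate (open track, object) pairs
    pairs <- NULL
    if (length(open) > 0 && length(objs) > 0) {
      pairs <- do.call(rbind, lapply(seq_along(open), function(oi) {
        tr <- open[[oi]]
        do.call(rbind, lapply(seq_along(objs), function(ji) {
          inter <- length(intersect(tr$last_px, objs[[ji]]$px))
          if (inter == 0) return(NULL)
          uni <- length(tr$last_px) + length(objs[[ji]]$px) - inter
          cd <- sqrt(sum((tr$last_centroid - objs[[ji]]$centroid)^2))
          data.frame(oi = oi, ji = ji, ovl = inter / uni, cd = cd,
                     label = objs[[ji]]$label)
        }))
      }))
    }
    assigned_obj <- logical(length(objs))
    matched_open <- logical(length(open))
    if (!is.null(pairs) && nrow(pairs) > 0) {
      pairs <- pairs[order(-pairs$ovl, pairs$cd, pairs$label), , drop = FALSE]
      for (r in seq_len(nrow(pairs))) {
        oi <- pairs$oi[r]; ji <- pairs$ji[r]
        if (matched_open[oi] || assigned_obj[ji]) next
        matched_open[oi] <- TRUE; assigned_obj[ji] <- TRUE
        ti <- open[[oi]]$track
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
        tracks[[ti]]$labels <- c(tracks[[ti]]$labels, objs[[ji]]$label)
        tracks[[ti]]$footprints <- c(tracks[[ti]]$footprints,
                                     list(objs[[ji]]$px))
        tracks[[ti]]$centroids <- rbind(tracks[[ti]]$centroids,
                                        objs[[ji]]$centroid)
        open[[oi]]$last_px <- objs[[ji]]$px
        open[[oi]]$last_centroid <- objs[[ji]]$centroid
        open[[oi]]$last_frame <- f
      }
    }
    # new tracks for unmatched objects
    for (ji in which(!assigned_obj)) {
      ti <- length(tracks) + 1
      tracks[[ti]] <- list(id = ti, frames = f, labels = objs[[ji]]$label,
                           footprints = list(objs[[ji]]$px),
                           centroids = matrix(objs[[ji]]$centroid, 1))
      open[[length(open) + 1]] <- list(track = ti, last_px = objs[[ji]]$px,
                                       last_centroid = objs[[ji]]$centroid,
                                       last_frame = f)
    }
    # close tracks that exceeded the gap
    open <- Filter(function(tr) f - tr$last_frame <= max_gap, open)
  }

  lapply(tracks, function(tr) {
    tr$first_frame <- min(tr$frames)
    tr$last_frame <- max(tr$frames)
    tr$censored_start <- tr$first_frame == 1
    tr$censored_end <- tr$last_frame == nf
    tr$dim <- dim_rc
    tr
  })
}
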