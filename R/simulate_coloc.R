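#' Prescribed exclusive-overlap specification for a three-channel triad
#'
#' Targets for the 7 exclusive combinations of three channels A, B, C
#' (A-only, B-only, C-only, AB, AC, BC, ABC). Targets are either absolute
#' pixel counts (`counts`) or fractions of `total_px` (`fractions`);
#' unnamed combinations default to 0.
#'
#' @param counts named numeric vector with names among
#'   c("A","B","C","AB","AC","BC","ABC"); pixel counts (>= 0).
#' @param fractions alternative to `counts`: fractions in [0, 1] of
#'   `total_px` (need not sum to 1; the remainder is empty background).
#' @param total_px total pixels to distribute when `fractions` is used.
#' @param patch_px side (px) of the square patches used to realise each
#'   combination as contiguous blocks; contiguous, well-separated patches
#'   keep the prescribed overlap recoverable after PSF blur, and a low
#'   perimeter-to-area ratio limits the influence of noisy border pixels
#'   on the recovered fractions.
#' @return object of class `overlap_spec`.
#' @export
overlap_spec <- function(counts = NULL, fractions = NULL, total_px = NULL,
                         patch_px = 10L) {
  combos <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  if (is.null(counts) == is.null(fractions))
    stop("give exactly one of 'counts' or 'fractions'")
  if (!is.null(fractions)) {
    if (any(fractions < 0 | fractions > 1)) stop("fractions must be in [0, 1]")
    if (is.null(total_px)) stop("'total_px' required with 'fractions'")
    counts <- round(fractions * total_px)
  }
  if (any(counts < 0)) stop("combination counts must be >= 0")
  bad <- setdiff(names(counts), combos)
  if (length(bad)) stop("unknown combination name(s): ", paste(bad, collapse = ", "))
  full <- stats::setNames(numeric(7), combos)
  full[names(counts)] <- counts
  structure(list(counts = full, patch_px = as.integer(patch_px)),
            class = "overlap_spec")
}

#' Simulate a three-channel image with prescribed exclusive overlaps
#'
#' Disjoint pixel sets are realised for each of the 7 exclusive
#' combinations by tiling the placement region into `patch_px` square
#' blocks, shuffling them (seeded) and assigning whole (or trimmed) blocks
#' to combinations until each target count is met exactly. Channel A's
#' mask is the union of the 4 combinations containing A (likewise B, C).
#' Channels are rendered at `intensity`, PSF-blurred and noised per the
#' acquisition spec.
#'
#' @param cell_mask logical placement region (typically the cell mask).
#' @param spec an [overlap_spec()].
#' @param acq an [acquisition_spec()].
#' @param seed integer seed.
#' @param intensity per-channel rendering intensity.
#' @return list with `stack` (3 x rows x cols array, channels A, B, C),
#'   `masks` (list of 3 logical truth masks), and `truth` (realised
#'   exclusive counts plus the per-combination pixel index sets).
#' @export
simulate_coloc_triad <- function(cell_mask, spec, acq, seed = 1,
                                 intensity = 100) {
  cell_mask <- as_binary_matrix(cell_mask)
  counts <- spec$counts
  need <- sum(counts)
  k <- spec$patch_px

  # tile the region bounding box into k x k blocks, keep blocks fully inside
  if (!any(cell_mask)) stop("placement region is empty")
  rc <- which(cell_mask, arr.ind = TRUE)
  blocks <- list()
  # stride 2k leaves a one-block gap between patches, so PSF blur from one
  # patch never reaches a neighbouring patch of a different combination
  r_last <- max(rc[, 1]) - k + 1; c_last <- max(rc[, 2]) - k + 1
  r_starts <- if (r_last >= min(rc[, 1])) seq(min(rc[, 1]), r_last, by = 2 * k) else integer(0)
  c_starts <- if (c_last >= min(rc[, 2])) seq(min(rc[, 2]), c_last, by = 2 * k) else integer(0)
  for (r in r_starts) for (cl in c_starts) {
    sub <- cell_mask[r:(r + k - 1), cl:(cl + k - 1)]
    if (all(sub)) {
      idx <- as.vector(outer((r:(r + k - 1)), (cl:(cl + k - 1)) - 1L,
                             function(i, j) j * nrow(cell_mask) + i))
      blocks[[length(blocks) + 1]] <- idx
    }
  }
  avail <- length(blocks) * k * k
  if (need > avail)
    stop(sprintf("infeasible packing: %d px requested, %d px available in the placement region",
                 need, avail))

  set.seed(derive_seed(seed, 0))
  blocks <- blocks[sample.int(length(blocks))]
  combo_px <- stats::setNames(vector("list", 7), names(counts))
  bi <- 1L
  for (cmb in names(counts)) {
    rem <- counts[[cmb]]
    px <- integer(0)
    while (rem > 0) {
      blk <- blocks[[bi]]
      take <- min(length(blk), rem)
      px <- c(px, blk[seq_len(take)])
      if (take < length(blk)) {
        blocks[[bi]] <- blk[-seq_len(take)]
      } else {
        bi <- bi + 1L
      }
      rem <- rem - take
    }
    combo_px[[cmb]] <- px
  }

  dim_rc <- dim(cell_mask)
  mk <- function(cmbs) {
    m <- matrix(FALSE, dim_rc[1], dim_rc[2])
    m[unlist(combo_px[cmbs])] <- TRUE
    m
  }
  masks <- list(A = mk(c("A", "AB", "AC", "ABC")),
                B = mk(c("B", "AB", "BC", "ABC")),
                C = mk(c("C", "AC", "BC", "ABC")))

  stack <- array(0, dim = c(3, dim_rc[1], dim_rc[2]))
  for (ch in 1:3) {
    stack[ch, , ] <- render_frame(masks[[ch]] * intensity, acq,
                                  derive_seed(seed, 200000 + ch))
  }
  realized <- vapply(combo_px, length, integer(1))
  list(stack = stack, masks = masks,
       truth = list(counts = realized, pixels = combo_px, seed = seed))
}
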