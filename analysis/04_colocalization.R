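#!/usr/bin/env Rscript
# Differential triple colocalization: simulate a three-channel field with
# prescribed exclusive overlaps (channel A: 50% alone, 30% shared with B,
# 20% shared with B and C), threshold each channel, split the masks into
# the 7 exclusive combinations, and report each channel's integrated
# density fractions.

suppressMessages(library(fadyn))
out <- "results/04_coloc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 501

ps <- 0.2
acq <- acquisition_spec(n_frames = 2, pixel_size = ps,
                        image_shape = c(220L, 220L), psf_sigma = ps,
                        background_level = 10, poisson_scale = 1)
cell <- simulate_cell_mask(c(220L, 220L), ps, "ellipse",
                           list(semi_axes = c(19, 15)))
spec <- overlap_spec(fractions = c(A = 0.5, AB = 0.3, ABC = 0.2),
                     total_px = 3000)
tri <- simulate_coloc_triad(cell, spec, acq, seed = seed, intensity = 100)

imgs <- lapply(1:3, function(ch) tri$stack[ch, , ])
masks <- lapply(imgs, threshold_mask, method = "otsu")
rep_density <- coloc_fractions(imgs, masks, mode = "density")
rep_count <- coloc_fractions(imgs, masks, mode = "count")
export_report(list(coloc_density = rep_density$per_region,
                   coloc_count = rep_count$per_region), out)

pr <- rep_count$per_region
fA <- stats::setNames(pr$fraction_A, pr$combination)
cat("Prescribed channel-A composition: A-only 0.50, AB 0.30, ABC 0.20\n")
cat(sprintf("Recovered at SNR ~ 10:        A-only %.3f, AB %.3f, ABC %.3f\n",
            fA["A"], fA["AB"], fA["ABC"]))
cat(sprintf("Largest deviation: %.2f percentage points.\n",
            100 * max(abs(fA[c("A", "AB", "ABC")] - c(0.5, 0.3, 0.2)))))
cat("Per-region combination tables written to", out, "\n")
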