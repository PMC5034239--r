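#!/usr/bin/env Rscript
# Peripheral-band statistics: split the cell footprint at the offset curve
# 10 um from the edge, then (i) compare the peripheral normalised vesicle
# signal between fields simulated with peripheral placement bias 0.8 and
# 0.0, (ii) recover a 2x peripheral-vs-central per-adhesion vesicle
# density, and (iii) report the cell's shape descriptors.

suppressMessages(library(fadyn))
out <- "results/05_peripheral"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ps <- 0.2
shape <- c(240L, 240L)
acq <- acquisition_spec(n_frames = 2, pixel_size = ps, image_shape = shape,
                        psf_sigma = ps, background_level = 5,
                        poisson_scale = 1)
cell <- simulate_cell_mask(shape, ps, "ellipse", list(semi_axes = c(21, 16)))
part <- partition_cell(cell, band_width = 10, pixel_size = ps)

rows <- list()
for (seed in 601:605) {
  for (bias in c(0.8, 0)) {
    vf <- simulate_vesicle_field(cell,
                                 vesicle_field_spec(120, peripheral_bias = bias),
                                 acq, seed = seed)
    m <- threshold_mask(vf$stack[1, , ], "otsu")
    sg <- peripheral_signal(m, part)
    rows[[length(rows) + 1]] <- data.frame(
      seed = seed, bias = bias,
      rab_area_ratio = rab_area_ratio(m, cell),
      peripheral_normalized = sg$peripheral_normalized,
      central_normalized = sg$central_normalized)
  }
}
tab <- do.call(rbind, rows)

# 2x peripheral per-adhesion vesicle density scenario
lab <- matrix(0L, shape[1], shape[2])
ctr <- dim(lab) / 2
lab[48:50, 115:119] <- 1L
lab[190:192, 115:119] <- 2L
lab[(ctr[1] - 1):(ctr[1] + 1), (ctr[2] - 2):(ctr[2] + 2)] <- 3L
lab[(ctr[1] + 9):(ctr[1] + 11), (ctr[2] + 8):(ctr[2] + 12)] <- 4L
nb <- build_neighborhoods(lab, dilation_distance = 0.8, pixel_size = ps)
img <- matrix(0, shape[1], shape[2])
for (k in 1:4) img[nb$regions[[k]]$dilated] <- if (k <= 2) 20 else 10
pf <- per_fa_rab_intensity(img, nb, part)

geom <- cell_geometry(cell, ps)
export_report(list(vesicle_enrichment = tab,
                   per_fa_intensity = pf$per_adhesion,
                   cell_geometry = geom), out)

wide <- merge(tab[tab$bias == 0.8, c("seed", "peripheral_normalized")],
              tab[tab$bias == 0, c("seed", "peripheral_normalized")],
              by = "seed", suffixes = c("_biased", "_uniform"))
cat(sprintf("Cell: %.0f um^2, circularity %.2f, aspect ratio %.2f; band splits it %.0f + %.0f um^2.\n",
            geom$area_um2, geom$circularity, geom$aspect_ratio,
            part$peripheral_area_um2, part$central_area_um2))
cat(sprintf("Peripheral normalised vesicle signal higher under bias 0.8 in %d/5 replicates.\n",
            sum(wide$peripheral_normalized_biased >
                wide$peripheral_normalized_uniform)))
cat(sprintf("Per-adhesion vesicle density, peripheral/central mean ratio: %.2f (truth 2.0)\n",
            mean(pf$peripheral) / mean(pf$central)))
cat("Tables written to", out, "\n")
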