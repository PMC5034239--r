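# fadyn — focal adhesion turnover and peripheral trafficking quantification

`fadyn` is an R package for quantifying focal adhesion (FA) dynamics at
the edge of migrating cells from fluorescence time-lapse microscopy, of
the kind used to show that edge scaffold proteins (liprin-α1, ERC1)
promote FA *disassembly*: silencing them slows the disassembly rate,
leaves the assembly rate unchanged, lengthens FA lifespan, and enriches
FAs and Rab7-positive endosomes in the cell periphery. The package
implements the full measurement chain and a seeded synthetic-microscopy
generator with ground truth, so every stage is validated end to end
without external data.

## What it measures

* **Kymograph turnover metrics.** Adhesions are segmented (shared
  threshold per series), tracked by footprint overlap, and a 10 µm line
  is traced along each adhesion's growth axis. Tips are located per frame
  at the half-maximum crossing; the assembly rate is the distal tip's
  extension speed toward the cell edge, ΔD/ΔT (µm/min); the disassembly
  rate is the proximal tip's retraction speed ΔD/ΔT; halt time is the
  period with neither event; lifespan is the time visible within the 1 h
  acquisition. Event counts are reported per 60 min.
* **Differential triple colocalization.** Three channel masks are split
  into the 7 exclusive combinations (A-only, …, AB, …, ABC) in
  neighbourhoods around reference adhesions (0.8 µm dilation and 5 × 4 µm
  crops, both provided); integrated densities of each combination are
  expressed as fractions of each channel's total. Channel-wise additivity
  is bit-exact on integer images.
* **Peripheral band statistics.** The cell footprint is partitioned at
  the offset curve equidistant 10 µm from the edge (Euclidean distance
  transform, exact against a brute-force oracle); peripheral signal =
  total − central, normalised to cell area; plus marker-area/cell-area
  ratios, FA counts and per-FA vesicle intensities grouped peripheral vs
  central.
* **Cell morphometrics.** Projected area A, perimeter p (sub-pixel
  contour; pixel-edge mode for ImageJ parity), circularity 4πA/p² (1.0
  for a perfect circle), aspect ratio = major/minor equivalent-ellipse
  axis.
* **Synthetic time-lapse microscopy.** Ribbon-shaped adhesions that
  extend, halt and retract at prescribed rates; vesicle fields with a
  peripheral placement bias; three-channel fields with prescribed
  exclusive overlaps; Gaussian PSF, Poisson shot noise and read noise;
  bit-reproducible given one seed, with full ground-truth tables.

## Worked example

```r
library(fadyn)

# simulate a cell with 30 adhesions (60 frames @ 1/min, 0.16 um/px,
# noiseless, 1 px PSF), quantify it, and compare with ground truth
scn <- turnover_scenario(n_adhesions = 30, seed = 101)
m <- scn$matched

mean(m$true_assembly);    mean(m$rec_assembly)     # 0.576 vs 0.567 um/min
mean(m$true_disassembly); mean(m$rec_disassembly)  # 0.255 vs 0.255 um/min
max(abs(m$rec_lifespan - m$true_lifespan))         # 1 frame
```

Running the numbered drivers reproduces the whole analysis; each prints a
short narrative and writes CSV tables under `results/`:

```
$ Rscript analysis/02_turnover_quantification.R
Recovered 30/30 adhesions.
Assembly rate:    truth 0.576, recovered 0.567 um/min (max |rel err| 8.6%)
Disassembly rate: truth 0.255, recovered 0.255 um/min (max |rel err| 1.0%)
Lifespan: max |err| 1 frame(s); halt time: max |err| 1.04 min
Distal direction matched for 30/30 adhesions.

$ Rscript analysis/03_silencing_comparison.R
Disassembly rate: control 0.260 vs silenced 0.141 um/min (ratio 0.54)
Assembly rate:    control 0.558 vs silenced 0.558 um/min (0.0% apart)
Lifespan:         control 31.3 vs silenced 41.2 min (+9.9 min)
```

The "silenced" condition halves every adhesion's disassembly rate and
changes nothing else; the pipeline reads out exactly that signature —
slower disassembly, untouched assembly, longer lifespan.

Scripts: `01` simulates the reference stack and writes it with its truth
tables; `02` runs the turnover quantification; `03` the paired condition
comparison; `04` the triple-colocalization recovery (prescribed channel-A
composition 0.50/0.30/0.20 recovered to half a percentage point at
SNR ≈ 10); `05` the peripheral-band enrichment and morphometrics.

## Package layout

```
R/                  implementation (simulators, image prep, kymographs,
                    events, colocalization, partition, morphometrics, I/O)
analysis/           numbered narrative drivers writing results/
scripts/acceptance.R  validation quantities as JSON
tests/testthat/     unit, property and end-to-end validation suites
vignettes/          methods vignette: models, parameters, design choices
```
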