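# gliaquant

Image-quantification toolkit for measuring microglial dynamics in visual
cortex plasticity experiments. Microglia — the brain's resident immune
cells — remodel their process arbors within hours of monocular deprivation,
and quantifying that behaviour requires a chain of small, well-defined image
measurements. This package implements that chain for R users working with
multi-page TIFF stacks and simple CSV tables:

* **Sholl morphometry** — crossings of concentric circles around the soma
  on a binarized arbor, plus soma area/intensity and cell density.
* **Process motility** — pixel classification between consecutive
  registered, thresholded time-lapse projections. Per overlay:
  motility index = (extension + retraction pixels) / stable pixels, with
  extension/retraction indices, stability and instability indices, a
  stability histogram, and a traced-process rate |ΔL|/Δt.
* **Laser-ablation response** — R(t) = (Rx(t) − Rx(0)) / Ry(0), the
  normalized accumulation of process pixels inside an inner disc (X ≈ 40 µm)
  fed from an outer annulus (Y ≈ 80 µm) after a focal injury.
* **Engulfment scoring** — triangle auto-thresholding of two confocal
  channels, multiplication of the binary stacks, counting internalized
  puncta larger than 1 pixel, density per µm² of microglial area.
* **Ocular dominance index** — stimulus-locked FFT amplitude maps of
  intrinsic-signal recordings per eye; ODI = (C − I) / (C + I).
* **EM event statistics** — per-process event densities (events/µm²),
  one-pass Grubbs outlier removal, per-animal then per-group summaries.
* **Synthetic data** — seeded generators with recorded ground truth for
  every stage (arbors with analytic Sholl profiles, movies with planted
  extension/retraction pixel sets, convergence movies, planted puncta,
  exact-bin sinusoidal recordings, Poisson event tables), so the entire
  pipeline is testable without animal data.

The methods vignette (`vignettes/gliaquant-methods.Rmd`) documents each
algorithm, its assumptions and the design decisions.

## Worked example

```r
library(gliaquant)

# a synthetic arbor whose Sholl profile is known analytically
arb <- generate_arbor(n_branches = 6, branch_radii = seq(10, 30, 5), seed = 1)
sholl(binarize(arb$image, "triangle"), arb$soma_center,
      radius_step = 5, max_radius = 30)
#>   radius_um crossings
#> 1         5         6
#> 2        10         6
#> 3        15         5
#> 4        20         5
#> 5        25         5
#> 6        30         4

# a 12-frame movie at 4-min cadence with 10% planted extension/retraction
movie <- generate_timelapse(arb, T = 12, extension_fraction = 0.1,
                            retraction_fraction = 0.1, frame_interval = 4,
                            noise_sd = 12, seed = 2)
res <- motility_pipeline(movie$frames, frame_interval = 4)
res$indices$motility_index        # 0.1702  (planted: 0.1702)
res$indices$extension_index       # 0.1061
res$indices$retraction_index      # 0.0641
res$stability$stability_index     # 0.456

# ocular dominance from four synthetic recording sessions
ios <- generate_ios_session(matrix(2, 8, 8), matrix(1, 8, 8),
                            stim_frequency = 0.125, duration_s = 96,
                            sampling_rate = 4, noise_sd = 0.05, seed = 3)
odi <- odi_pipeline(ios$sessions, sampling_rate = 4, stim_frequency = 0.125,
                    roi = matrix(TRUE, 8, 8))
c(odi$contra_response, odi$ipsi_response, odi$odi)
#> 2.000 1.000 0.3334
```

The Sholl profile counts how many processes cross each circle: 6 rays cross
the innermost circles and progressively fewer reach larger radii. The
motility index says that per 4-minute interval, extension plus retraction
pixels amounted to ~17% of the stable arbor footprint, matching the planted
churn; the stability index says ~46% of newly extended pixels persisted
through the next interval. The ODI of +0.33 reflects the planted 2:1
contralateral bias.

## Analysis workflow

`analysis/` contains numbered drivers that run the whole study on simulated
data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # TIFF/CSV inputs + ground-truth sidecars
Rscript analysis/02_sholl_morphometry.R
Rscript analysis/03_motility.R
Rscript analysis/04_ablation.R
Rscript analysis/05_engulfment.R
Rscript analysis/06_ocular_dominance.R
Rscript analysis/07_em_statistics.R
```

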