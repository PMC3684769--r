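# kymoradon

Red blood cell (RBC) velocimetry from line-scan (kymograph) images, for
two-photon and bright-field blood-flow studies.

Repeatedly scanning one line along a vessel and stacking the scans as rows
gives a space-time image in which each moving RBC traces a diagonal streak.
The streak angle θ, measured from the time (vertical) axis, encodes the
velocity

    v = (Δx / Δt) · tan(θ)        [Δx in µm/pixel, Δt in ms/line, v in mm/s]

`kymoradon` estimates θ as the angle maximizing the variance of the Radon
projection of the image, with two ingredients that make the estimate fast
and robust on real data:

* **Vertical Sobel pre-filtering** — a 3×3 temporal-derivative kernel that
  enhances the plasma–RBC streak edges while suppressing both static
  vertical bands (scan path outside the vessel) and slow time-varying
  horizontal bands (heartbeat/respiration motion), the artifact that defeats
  the classical column-demeaning pre-process.
* **Iterative Radon search** — four projection angles per iteration, step
  size halving each round, centered on the best angle found so far.
  An angle step of δ degrees costs `4·(⌈log2(45/δ)⌉+1)` transforms instead
  of `⌈180/δ⌉`: 28 vs 180 at δ = 1°, 56 vs 18,000 at δ = 0.01°.

Around the estimator the package provides the full measurement calculus
(detectable angle change for a given image geometry, angle step for a target
Δv/v sensitivity, acquisition-speed re-planning toward the 45° optimum), a
windowed pipeline for long recordings with outlier flagging and smoothing, a
ground-truth synthetic streak generator with artifact injection, TIFF and
plain-text I/O, and a command-line interface (`estimate`, `simulate`,
`plan`).

## Worked example

Simulate a vessel whose streaks sit at 59.5° under the acquisition settings
Δx = 0.23 µm/pixel, Δt = 1.37 ms/line, then measure it blind in 100-line
windows:

```r
library(kymoradon)

img <- generate_streak_image(synthetic_spec(
  theta = 59.5, width = 112, height = 400,
  noise_sd = 0.05, seed = 2, dx = 0.23, dt = 1.37))

tr <- estimate_trace(img, window = 100, step = 100, target_delta = 0.1)
tr$samples[, c("segment_index", "angle_deg", "velocity_mm_s",
               "n_transforms", "valid")]
#>   segment_index angle_deg velocity_mm_s n_transforms valid
#> 1             0  59.50195     0.2850314           40  TRUE
#> 2             1  59.50195     0.2850314           40  TRUE
#> 3             2  59.50195     0.2850314           40  TRUE
#> 4             3  59.50195     0.2850314           40  TRUE
```

Each window recovers the 59.5° ground truth to within the achieved step
size (45/2⁹ ≈ 0.088°, i.e. 10 iterations = 40 Radon transforms instead of
the ~2,048 a traditional search at that step would need), and the velocity
column gives the 0.285 mm/s this angle corresponds to at these acquisition
settings.  `flag_outliers()` then marks any near-±90° failures and
`smooth_trace()` averages over cardiac cycles if desired.

The same pipeline runs from a shell:

```sh
Rscript inst/scripts/kymoradon simulate --theta 59.5 --height 400 --dx 0.23 --dt 1.37 --out vessel.tif
Rscript inst/scripts/kymoradon estimate --input vessel.tif --dx 0.23 --dt 1.37 \
    --window 100 --step 100 --delta 0.1 --out trace.csv
Rscript inst/scripts/kymoradon plan --width 300 --height 100 --dx 1.19 --dt 1 --theta 45 --delta 1
```

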