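# maxinfo

Adaptive frame selection and segmentation for live cells in **bright-field
defocused z-stacks** — microscopy without fluorescent labels, stains, or
phototoxicity.

At the focal plane, unstained cells are nearly invisible; below focus they
appear dark and above focus bright. Differences between frames on opposite
sides of focus therefore highlight cell interiors, and the standard
label-free recipe picks four out-of-focus frames (two weakly, two strongly
defocused) to initialize and guide an active-contour segmentation. The
catch is *which* four frames: fixed physical offsets (±10 µm, ±25 µm from
the entropy-minimal in-focus frame) cannot react to cells sitting at
different heights, camera strip banding on individual frames, or noise
that varies between experiments.

`maxinfo` selects the four frames adaptively. Each frame is
Otsu-binarized, linearized column-by-column into a '0'/'1' string, and
bzip2-compressed; the compressed length `C(s)` proxies Kolmogorov
complexity. Pairwise similarity is the normalized compression distance

    NCD(s_i, s_j) = ( C(s_i s_j) − min(C(s_i), C(s_j)) ) / max(C(s_i), C(s_j))

and a four-frame set `S` is scored by its **set complexity**

    Ψ(S) = 1/(n(n−1)) · Σ_i C(s_i) · Σ_{j≠i} NCD(s_i,s_j)·(1 − NCD(s_i,s_j))

which rewards individually complex, mutually half-similar frames and
discounts both redundant (NCD ≈ 0) and mutually random (NCD ≈ 1) pairs —
so frames corrupted by banding or noise are avoided automatically. The
package exhaustively scores every two-below × two-above combination
(compressions are computed once and cached: exactly n + n(n−1)/2
compressor calls per n-frame stack) and segments with the winning quad:
the strong difference |I⁻⁻ − I⁺⁺| seeds regions via Otsu + 8-connected
components + a size filter, and a region-based morphological active
contour expands the seeds under the weak difference |I⁻ − I⁺|, with
colliding fronts frozen so adherent cells keep separate labels.

Also included: the fixed-offset baseline strategy, a synthetic
bright-field z-stack generator with ground truth (contrast inversion,
defocus blur, per-cell focal jitter, camera strip banding, pixel noise),
a precision/recall evaluation harness, TIFF/PNG stack I/O, and a CLI.

## Worked example

```r
library(maxinfo)

# a synthetic 21-frame stack under the noisy reference conditions:
# 15 cells with ±8 µm focal jitter, strip banding on frames 4, 7 and 12
sim   <- generate_zstack(noisy_synthetic_spec(seed = 42))
stack <- sim$stack
stack
#> <zstack 'synthetic-seed42': 21 frames of 256x256, 12-bit, 10 um spacing>

quad <- select_frames_maxinfo(stack)
quad
#> <frame_quad [maxinfo]: I--=2 I-=3 (I0=11) I+=19 I++=20, psi=61.3119>

baseline <- select_frames_fixed(stack)     # ±10 µm, ±25 µm → ±30 µm
baseline
#> <frame_quad [fixed]: I--=8 I-=10 (I0=11) I+=12 I++=14, psi=-9.6111>

mask <- segment_stack(stack, quad)
match_detections(mask, sim$truth$centers)
#> <detection_counts tp=15 fp=0 fn=0 precision=1.000 recall=1.000>
```

Reading the output: both strategies agree the in-focus frame is 11 (the
entropy minimum). The adaptive quad (2, 3, 19, 20) avoids all three
banded frames and scores Ψ = 61.3; the fixed offsets land on frame 12 —
which is banded — and the corrupted pairs push that quad's Ψ to −9.6
(banding makes a frame's encoding mutually random against the others,
NCD > 1, so its terms turn negative). Segmenting with the adaptive quad
recovers all 15 planted cells with no spurious objects.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/maxinfo.R simulate --seed 4 --out-dir stack4 --jitter-um 8 --stripe-frames 5,17
Rscript inst/cli/maxinfo.R select   --stack stack4 --spacing-um 10 --strategy maxinfo --out sel.json --ncd-csv ncd.csv
Rscript inst/cli/maxinfo.R segment  --stack stack4 --spacing-um 10 --out mask.tif
Rscript inst/cli/maxinfo.R evaluate --mask mask.tif --truth stack4/truth.csv
Rscript inst/cli/maxinfo.R compare  --seeds 5 --out comparison.csv
```

`select` emits a JSON record (stack id, in-focus index, quad, Ψ, entropy
profile) plus an optional NCD-matrix CSV; every run writes its resolved
configuration next to its outputs, and a `--config file.json|yaml` can
supply defaults that flags override.

See `vignettes/maxinfo-methods.Rmd` for the model, its assumptions, the
tunable parameters, and what the synthetic conditions do and do not show
about real microscope data.

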