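# tonguecolor

Automated grading of tongue body colour — **light red** / **red** /
**deep red** — from segmented, coating-removed tongue photographs, for
computer-assisted tongue diagnosis in Kampo and traditional Chinese
medicine. Input images are 24-bit sRGB with non-tongue pixels set to exact
black `(0, 0, 0)`; every decision is made in CIELAB under the plain
Euclidean metric.

## The method

The classifier is a two-stage cascade:

**Stage 1 — deep red vs red/light-red, by SVM on clustering identifiers.**
The image is partitioned by k-means (k = 4) in Lab space into background,
deep red, red/light-red and transitional clusters. Two *clustering
identifiers* pick the informative clusters among the non-background ones:

* *maximum colour distance*: the cluster whose centroid `(C₁*, C₂*, C₃*)`
  maximises the Euclidean distance
  `Δ = √((L*−0)² + (a*−0)² + (b*−0)²)` from Lab black — the red/light-red
  cluster, since saturated red tissue lies farthest from black;
* *maximum pixels' coverage area*: the cluster maximising
  `A_np = w′ × h′`, the tight bounding box over its member pixels
  (`w′ ≤ w`, `h′ ≤ h`) — the deep red cluster, spread sparsely across tip,
  bilateral edges and centre.

The mean Lab colours of these two clusters (a 6-vector) feed a soft-margin
SVM (`min ½‖w‖² s.t. yᵢ(wᵀxᵢ − b) ≥ 1`, linear kernel by default).
Because each image collapses to two informative cluster colours instead of
thousands of overlapping pixels, the fitted model needs far fewer support
vectors — and prediction cost scales with the support-vector count.

**Stage 2 — red vs light red, by colour ranges.** Images that stage 1 did
not call deep red are resolved by explicit Lab ranges applied to the mean
colour of the red/light-red identifier cluster:

| class | `L*` | `a*` | `b*` |
|---|---|---|---|
| red | `< 56` | `32–39` | `6–10` |
| light red | `≥ 56` | `23–27` | `15–19` |

A colour outside both boxes falls back to luminance alone: `L* < 56` reads
red, otherwise light red. The rule is total — every Lab point gets exactly
one label. Accuracy is reported as the rate
`ACC = 100 × (n_red/light-red + n_deep-red) / N`.

No clinical corpus is distributed, so the package includes a synthetic
generator (`make_corpus()`) producing labelled elliptical tongues on black
backgrounds with class-conditional Lab structure (body, tip/edge accent,
transitional rim) and ground-truth masks; see the vignette
(`vignettes/tongue-colour-diagnosis.Rmd`) for what it does and does not
emulate.

## Worked example

```r
library(tonguecolor)

params <- generator_params(width = 96, height = 96, centre_jitter = 3,
                           semi_x = c(26, 32), semi_y = c(36, 43))
corpus <- make_corpus(30, params, seed = 1)
ev <- evaluate_corpus(corpus, pipeline_config(), folds = 5, seed = 2)
ev
#> <cascade_eval> stratified 5-fold CV, seed 2
#>   3-class accuracy: 100.0% (N = 30)
#>   stage 1 (deep red vs red/light red): 100.0%
#>   stage 2 (red vs light red, conditional): 100.0% (N = 20)
#>   support vectors per fold: 3, 3, 3, 3, 3
```

The cascade separates all 30 synthetic images (the three class means are
several noise standard deviations apart, so this corpus is easy by
construction), and each fold's linear SVM needs only 3 support vectors.
Classifying a single image shows the cascade's anatomy:

```r
model <- train_stage1(corpus_features(corpus, pipeline_config())$X,
                      corpus$manifest$label)
img <- make_tongue_image("red", params, seed = 99)
rec <- classify_image(img, model, pipeline_config(), image_id = "demo")
rec$final
#> <final_label> red (stage 2, fallback_L)
round(rec$features, 2)
#> dist_L dist_a dist_b  cov_L  cov_a  cov_b
#>  49.92  39.00   8.93  40.04  29.99   6.06
```

Stage 1 passed the image on (`red_or_light_red`); stage 2 judged the
identifier cluster's mean colour `(49.9, 39.0, 8.9)` — here a hair outside
the red box's `a* ≤ 39` bound, so the luminance fallback fired and `L* < 56`
read red. The feature vector is the two identifier clusters' mean colours:
the max-distance cluster (first three entries, the chromatic accent band)
and the max-coverage cluster.

A command-line front end wrapping the same functions ships in
`inst/cli/tonguecolor` (subcommands `simulate`, `cluster`, `train`,
`classify`, `evaluate`, `compare`).

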