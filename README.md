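# cathmtl

Joint **electrode detection and catheter segmentation** for X-ray
fluoroscopy, trained with **multi-level dynamic resource prioritization** —
an R package implementing the full pipeline at CPU scale on a built-in
synthetic fluoroscopy scene generator.

## Who this is for

Researchers in interventional-imaging analysis who want a fully inspectable,
dependency-light implementation of a multi-task center-heatmap
detector/segmenter and of KPI-driven task/sample weighting, with every
formula unit-tested against closed forms and brute-force oracles.

## The model and training strategy

A single encoder–attention–decoder CNN serves three heads from one forward
pass: segmentation logits at input resolution, a stride-4 electrode center
heatmap, and a (w, h) box-size map. Training minimizes

```
L_total = (1/κ̄_d) L_d + (1/κ̄_s) L_s
L_d = L_focal + λ L_size          (penalty-reduced focal + L1 size, λ = 1)
L_s = L_bce + L_iou               (pixel BCE + soft region IoU)
```

where each task KPI `κ_t ∈ (0,1]` (inverse matched MAE for detection, IoU
for segmentation) is tracked by an exponential moving average
`κ̄ ← α κ + (1−α) κ̄`, so **harder tasks get larger weights**. At the sample
level, per-sample difficulties `1/κ̄_{t,i}` feed a top-k hard mask
`δ_{t,i} ∈ {0,1}` whose retained fraction anneals 70% → 30% over the run;
the masked task loss is `L_t = (1/N) Σ_i δ_{t,i} L_t(p_i, y_i)`. Evaluation
reports COCO-style AP over IoU thresholds 0.50–0.95, mean region similarity
𝒥 (mask IoU), matched-MAE in pixels, and the mean KPI `(AP + mean 𝒥)/2`.

There is no deep-learning framework dependency: convolutions, pooling,
bilinear resizing and the reverse-mode tape are implemented in
RcppArmadillo/R and validated against finite differences in the test suite.

## Worked example

```r
library(cathmtl)

spec  <- benchmark_spec("desk", noise_free = TRUE, seed = 11)  # 96x96 scenes
train_scenes <- generate_scenes(spec, 200)
valid_scenes <- generate_scenes(spec, 24, offset = 5000)

fit <- train(preset_desk(seed = 7), train_scenes, verbose = TRUE)
evaluate(fit$model, valid_scenes, score_thresh = 0.25)
```

After ten epochs on one CPU core (about two minutes) this prints:

```
eval_report (n = 24)
  AP        : 0.0454
  mean J    : 0.5771
  mean KPI  : 0.3112
  MAE (px)  : 4.64
```

Read these as: the model segments the target catheter with mean mask IoU
0.58 on held-out scenes while ignoring distractor wires; decoded electrode
centers land within ~5 px of the optimal one-to-one matching of the ground
truth; strict AP over IoU 0.50–0.95 remains low at this scale because
electrode boxes are only 5–9 px wide and a stride-4 heatmap's half-stride
quantization already costs most of the IoU@0.5 overlap (see the vignette).

The command-line surface (`inst/cli/cathmtl.R`) wraps the same functions:

```sh
Rscript inst/cli/cathmtl.R generate --out data/ --n 50 --seed 1
Rscript inst/cli/cathmtl.R train --data data/ --out run/ --epochs 10
Rscript inst/cli/cathmtl.R evaluate --data data/ --checkpoint run/checkpoint.rds
Rscript inst/cli/cathmtl.R ablate --data data/ --valid valdata/ --out ablation.csv
```

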