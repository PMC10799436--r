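# adfuse

Multimodal fusion of structural MRI and FDG-PET for binary neuroimaging
diagnosis (Alzheimer's disease vs. cognitively normal), with built-in
interpretability: attention-rollout feature ranking and deconvolution-based
brain-region salience maps.

## What it implements

Each subject contributes two co-registered `64^3` volumes, min–max
normalized to `[0, 1]`. The model is:

1. **Per-modality 3D CNN encoders** (independent parameters, shared
   structure): five blocks of 3×3×3 convolution → batch norm → ReLU →
   2×2×2 max pooling, plus a final standalone convolution, producing **200
   feature maps of 2×2×2** per modality.
2. **A shared gated Transformer encoder** (2 layers, 4 heads). Tokens are
   the flattened feature maps (200 tokens, d = 8). Q/K/V are 1×1×1
   convolutions over the channel dimension. The attention residual is gated
   by a learnable scalar per block,

   `X' = α·O + X`,  `α ∈ [0, 1]`, `α = 0` at initialization,

   so self-attention is masked early in training and unmasked
   progressively as α grows (no positional embeddings; the convolutional
   projections encode position).
3. **Fusion MLP**: both modalities' tokens are flattened, concatenated
   (3200 values), and classified by a two-layer MLP with dropout 0.1 and a
   softmax, trained end to end with categorical cross-entropy (Adam,
   batch 11, 60 epochs, lr 1e-4 decaying ×0.1 every 20 epochs).

Evaluation follows a stratified tenfold scheme (per loop: one portion
test, the next portion validation, the rest training) with ACC / PRE /
SPE / SEN / F1S / AUC reported as mean ± sd across folds, and a
label-permutation significance test.

For interpretability, per-layer attention is head-averaged, residual-
augmented (`A = 0.5W + 0.5I`) and rolled out across layers
(`Ã_i = A_i Ã_{i-1}`); averaging the final matrix over rows and columns
gives one contribution weight per feature (a 200-vector). The top-weight
feature is decoded back to image space by a mirror deconvolution network
(nearest-neighbour upsampling + convolution, MSE-trained against the
frozen encoder), and the decoded salience volume is thresholded (top 1 %
of voxels, clusters larger than a size threshold, 26-connectivity) into a
cluster report: peak coordinate (voxel and mm), peak intensity, voxel
count.

Because clinical scans are controlled-access, the package ships a
synthetic paired-modality cohort generator (`generate_cohort()`): an
ellipsoidal brain phantom with subject jitter and modality-specific noise,
and a focal intensity reduction planted in the AD class of both
modalities — enough to validate learning, significance testing and lesion
localization end to end on a CPU.

All network forward/backward passes are implemented in the package itself
(C++ kernels for the volumetric operations, verified against brute-force
oracles and finite-difference gradients); no external deep-learning
runtime is required.

## Worked example

A complete reduced-scale run — simulate, cross-validate, test significance:

```r
library(adfuse)

pr  <- desk_profile("micro", seed = 5)      # 16^3 reduced architecture
cc  <- synthetic_config(n_ad = 20, n_cn = 20, grid = 16,
                        effect_size = 0.5, noise_sd = 0.05, seed = 5)
coh <- generate_cohort(cc)

tc  <- train_config(batch_size = 5, epochs = 6, lr = 1e-3, seed = 5)
rep <- cross_validate(coh, pr$enc_cfg, pr$tx_cfg, pr$fus_cfg, tc,
                      n_portions = 5)
print(rep)
#> <metrics_report> 5 folds (mean +/- sd, %):
#>   ACC  100.00 +/-  0.00
#>   PRE  100.00 +/-  0.00
#>   SPE  100.00 +/-  0.00
#>   SEN  100.00 +/-  0.00
#>   F1S  100.00 +/-  0.00
#>   AUC  100.00 +/-  0.00

res <- permutation_test(coh, pr$enc_cfg, pr$tx_cfg, pr$fus_cfg,
                        train_config(batch_size = 5, epochs = 4,
                                     lr = 1e-3, seed = 5),
                        n_perm = 19, n_portions = 4)
print(res)
#> <permutation_result> observed 100.0%, 19 permutations (max 90.0%), p = 0.05
```

With a planted lesion of effect size 0.5 the reduced model separates the
classes perfectly on every fold (the planted signal is strong by design),
and the observed accuracy exceeds all 19 label-permuted retrainings, so
the permutation p-value takes its minimum value `(1+0)/(1+19) = 0.05`:
the classifier demonstrably learns the image–label relationship rather
than memorizing noise.

Interpretability on a trained model:

```r
pred <- forward_fused(model, coh[[1]])            # probs + attention stacks
w    <- feature_weights(attention_rollout(pred$attention$smri))
dec  <- train_deconv(build_deconv(pr$enc_cfg), enc_par,
                     lapply(coh, `[[`, "smri"), deconv_config(epochs = 15))
sal  <- decode_feature(dec$decoder, encode_volume(coh[[1]]$smri, pr$enc_cfg,
                                                  enc_par), w$argmax)
threshold_and_cluster(sal, top_pct = 1, min_size = 20)
```

A command-line interface over the same functions is installed at
`inst/cli/adfuse.R` (`simulate`, `train`, `crossval`, `permtest`,
`visualize`).

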