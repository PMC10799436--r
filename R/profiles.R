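#' Reduced-scale study profiles
#'
#' The full-scale architecture (64^3 inputs, 200 feature maps, 60 epochs) is
#' sized for GPU training on a real cohort. For CPU-scale validation the
#' package defines two fixed reduced profiles used throughout its tests and
#' examples:
#'
#' * `"scaled"` — 32^3 volumes, a 4-block encoder with filters 8/16/32/64
#'   and 64 feature maps of 2x2x2 (64 tokens of dim 8), the standard L = 2 /
#'   H = 4 transformer, and a planted-lesion cohort of 30 AD + 30 CN
#'   subjects (`effect_size = 0.5`, `noise_sd = 0.05`). Training runs 15
#'   epochs of Adam at 1e-3 with batch 4; held-out evaluation uses an
#'   independently generated 50 + 50 cohort.
#' * `"micro"` — 16^3 volumes, a 2-block encoder (filters 4/8, 16 feature
#'   maps of 4x4x4), 15 + 15 subjects, 4 epochs; small enough that the
#'   many retrainings of a permutation test stay tractable.
#'
#' @param kind `"scaled"` or `"micro"`.
#' @param seed integer seed propagated to every stochastic component.
#' @param effect_size lesion effect size for the cohort (`0` gives a null
#'   cohort in which both classes share one distribution).
#' @return List with `enc_cfg`, `tx_cfg`, `fus_cfg`, `train_cfg`,
#'   `cohort_cfg`, and `eval_cohort_cfg`.
#' @export
desk_profile <- function(kind = c("scaled", "micro"), seed = 1L,
                         effect_size = 0.5) {
  kind <- match.arg(kind)
  seed <- as.integer(seed)
  if (kind == "scaled") {
    list(
      enc_cfg = encoder_config(n_blocks = 4L, filters = c(8L, 16L, 32L, 64L),
                               final_filters = 64L),
      tx_cfg = transformer_config(L = 2L, H = 4L, d = 8L, n_tokens = 64L),
      fus_cfg = fusion_config(mlp_hidden = 64L),
      train_cfg = train_config(batch_size = 4L, epochs = 15L, lr = 1e-3,
                               seed = seed),
      cohort_cfg = synthetic_config(n_ad = 30L, n_cn = 30L, grid = 32L,
                                    effect_size = effect_size,
                                    noise_sd = 0.05, seed = seed),
      eval_cohort_cfg = synthetic_config(n_ad = 50L, n_cn = 50L, grid = 32L,
                                         effect_size = effect_size,
                                         noise_sd = 0.05,
                                         seed = derive_seed(seed, 9L))
    )
  } else {
    list(
      enc_cfg = encoder_config(n_blocks = 2L, filters = c(4L, 8L),
                               final_filters = 16L),
      tx_cfg = transformer_config(L = 2L, H = 4L, d = 64L, D = 64L,
                                  n_tokens = 16L),
      fus_cfg = fusion_config(mlp_hidden = 32L),
      train_cfg = train_config(batch_size = 5L, epochs = 4L, lr = 1e-3,
                               seed = seed),
      cohort_cfg = synthetic_config(n_ad = 15L, n_cn = 15L, grid = 16L,
                                    effect_size = effect_size,
                                    noise_sd = 0.05, seed = seed),
      eval_cohort_cfg = synthetic_config(n_ad = 20L, n_cn = 20L, grid = 16L,
                                         effect_size = effect_size,
                                         noise_sd = 0.05,
                                         seed = derive_seed(seed, 9L))
    )
  }
}
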