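#' Run configuration with documented defaults
#'
#' Every tunable of the pipeline in one flat list. Published-default
#' values: hidden dimension 512, 6 transformer layers, 8 attention
#' heads, dropout 0.3, learning rate 1e-4 (AdamW-style Adam with the L2
#' term carried explicitly in the loss), batch size 256, contrastive
#' temperature 0.1, contrastive weight alpha 0.5, L2 weight beta 1e-5;
#' augmentation ratios mask 0.15, perturb 0.10, sample 0.75, hop 0.05;
#' three-phase schedule 50/100/25 epochs; gradient-norm clip 1.0; early
#' stopping patience 15. The ablation switches mirror the standard
#' component-removal variants (\code{use_contrastive}, \code{use_hier_pool},
#' \code{fusion_on}, \code{spatial_bias_on}, \code{use_hard_mining},
#' \code{adaptive_fusion_on}, \code{standard_transformer_mode},
#' \code{gcn_baseline_mode}).
#'
#' @param ... overrides of any default, e.g. \code{runConfig(d_model = 64)}.
#' @param file optional YAML file of flat key: value overrides (command
#'   line > file > defaults).
#' @return a named list with class \code{"runConfig"}.
#' @export
runConfig <- function(..., file = NULL) {
  cfg <- list(
    ## encoder (published defaults)
    d_model = 512L, n_layers = 6L, n_heads = 8L, dropout = 0.3,
    ffn_mult = 4L,
    ## spatial encoding
    d_max = 8L, weight_scheme = "unit", spatial_bias_on = TRUE,
    spatial_bias_inside_scale = TRUE,
    ## hierarchical pooling: K2 = max(2, ceil(n/4)) capped
    use_hier_pool = TRUE, k2_cap = 16L, pool_aux_weight = 0,
    ## augmentation (published ratios)
    mask_ratio = 0.15, perturb_ratio = 0.10, sample_ratio = 0.75,
    hop_probability = 0.05, importance_threshold = 0.5,
    ensemble_weights = c(0.25, 0.25, 0.25, 0.25),
    mask_mode = "token",
    ## contrastive
    temperature = 0.1, use_contrastive = TRUE, use_hard_mining = TRUE,
    hard_negative_k = 8L, denominator_mode = "with_positive",
    projection_dim = 128L,
    ## cross-modal fusion
    fusion_on = TRUE, adaptive_fusion_on = TRUE, d_bert = 128L,
    seq_layers = 2L, seq_heads = 4L, seq_max_len = 128L,
    ## prediction head
    head_dims = c(1024L, 256L), alpha = 0.5, beta = 1e-5,
    symmetrize_inference = TRUE, bce_reduction = "mean",
    ## optimization (published defaults)
    learning_rate = 1e-4, batch_size = 256L, grad_clip = 1.0,
    patience = 15L, phase1_epochs = 50L, phase2_epochs = 100L,
    phase3_epochs = 25L, phase3_lr_factor = 0.1,
    ## splits
    split_mode = "transductive", split_fractions = c(0.6, 0.2, 0.2),
    inductive_drug_fraction = 0.8, threshold = 0.5,
    ## baselines
    standard_transformer_mode = FALSE, gcn_baseline_mode = FALSE,
    seed = 42L
  )
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    for (k in names(y)) cfg[[k]] <- y[[k]]
  }
  dots <- list(...)
  for (k in names(dots)) {
    if (!k %in% names(cfg)) stop("unknown config key: ", k)
    cfg[[k]] <- dots[[k]]
  }
  ## integrity
  stopifnot(cfg$d_model %% cfg$n_heads == 0,
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$temperature > 0,
            abs(sum(cfg$split_fractions) - 1) < 1e-9,
            all(unlist(cfg[c("mask_ratio", "perturb_ratio",
                             "sample_ratio", "hop_probability")]) >= 0),
            all(unlist(cfg[c("mask_ratio", "perturb_ratio",
                             "sample_ratio", "hop_probability")]) <= 1))
  class(cfg) <- c("runConfig", "list")
  cfg
}

#' Number of clusters for the pooling level of a molecule with n atoms
#' @noRd
k2For <- function(n, cfg) {
  if (!cfg$use_hier_pool) return(as.integer(n))
  min(max(2L, as.integer(ceiling(n / 4))), cfg$k2_cap)
}
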