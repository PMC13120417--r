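#' Model configuration
#'
#' Full architectural description of the spatial-spectral transformer:
#' spectral embedding (1x1 conv, batch norm, ReLU), `n_layers` encoder layers
#' with center-focused linear attention (CFLA) or full self-attention,
#' optional low-rank factorized projections (LRP) and a choice of positional
#' encoding, learnable layer aggregation, and a two-layer MLP classifier.
#'
#' The reference dimensions (patch 7, 171 bands, 128-dim embeddings, 8 heads,
#' bottleneck 32, 3 layers, FFN hidden 256, classifier hidden 216, 13
#' classes) give 451,216 trainable parameters for the full-rank baseline and
#' 352,912 for the LRP variant.
#'
#' @param patch_size odd patch side P (default 7; n = P^2 tokens).
#' @param n_bands spectral bands B of the input patch (default 171).
#' @param d_emb token embedding width (default 128), divisible by `n_heads`.
#' @param n_heads attention heads k (default 8); head width is `d_emb/n_heads`.
#' @param d_bottleneck LRP rank r (default 32), at most `d_emb`.
#' @param n_layers encoder layers L (default 3).
#' @param ffn_hidden feed-forward hidden width (default 256).
#' @param classifier_hidden classifier hidden width (default 216).
#' @param n_classes output classes K (default 13).
#' @param dropout classifier dropout rate (default 0.1).
#' @param use_lrp use rank-`d_bottleneck` factorized q/k/v/out projections.
#' @param attention_mode `"cfla"` (center-query linear attention; feed-forward
#'   and residual updates touch the center token only) or `"full"` (standard
#'   self-attention over all tokens, used as the ablation baseline).
#' @param pos_encoding `"rope2d_mixed"` (patch-local mixed-axis 2D rotary
#'   embedding with learnable per-head frequencies), `"ape"` (learnable
#'   absolute table added to token embeddings) or `"none"`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(patch_size = 7L, n_bands = 171L, d_emb = 128L,
                         n_heads = 8L, d_bottleneck = 32L, n_layers = 3L,
                         ffn_hidden = 256L, classifier_hidden = 216L,
                         n_classes = 13L, dropout = 0.1,
                         use_lrp = TRUE,
                         attention_mode = c("cfla", "full"),
                         pos_encoding = c("rope2d_mixed", "ape", "none")) {
  attention_mode <- match.arg(attention_mode)
  pos_encoding <- match.arg(pos_encoding)
  if (patch_size %% 2L == 0L) stop_config("patch_size must be odd")
  if (d_emb %% n_heads != 0L) stop_config("d_emb must be divisible by n_heads")
  if (d_bottleneck > d_emb) stop_config("d_bottleneck must be <= d_emb")
  d_head <- d_emb %/% n_heads
  if (d_head %% 2L != 0L && pos_encoding == "rope2d_mixed")
    stop_config("head dimension must be even for rotary embedding")
  if (dropout < 0 || dropout >= 1) stop_config("dropout must be in [0, 1)")
  structure(list(patch_size = as.integer(patch_size),
                 n_bands = as.integer(n_bands), d_emb = as.integer(d_emb),
                 n_heads = as.integer(n_heads), d_head = as.integer(d_head),
                 d_bottleneck = as.integer(d_bottleneck),
                 n_layers = as.integer(n_layers),
                 ffn_hidden = as.integer(ffn_hidden),
                 classifier_hidden = as.integer(classifier_hidden),
                 n_classes = as.integer(n_classes), dropout = dropout,
                 use_lrp = isTRUE(use_lrp), attention_mode = attention_mode,
                 pos_encoding = pos_encoding,
                 ffn_scope = if (attention_mode == "cfla") "center_only"
                             else "all_tokens",
                 n_tokens = as.integer(patch_size)^2L),
            class = "model_config")
}

#' Reference configurations of the ablation grid
#'
#' `"final"` is the published model (LRP + CFLA + 2D RoPE); `"baseline"` is
#' the full-rank, full-self-attention reference against which MAC/parameter
#' reductions and speedups are computed; `"cfla_only"` and `"lrp_only"`
#' toggle one component each.
#'
#' @param variant one of `"final"`, `"baseline"`, `"cfla_only"`, `"lrp_only"`.
#' @param pos_encoding positional encoding override (default 2D RoPE).
#' @param ... further arguments passed to [model_config()].
#' @return A `model_config`.
#' @export
reference_config <- function(variant = c("final", "baseline", "cfla_only",
                                         "lrp_only"),
                             pos_encoding = "rope2d_mixed", ...) {
  variant <- match.arg(variant)
  opts <- switch(variant,
    final     = list(use_lrp = TRUE,  attention_mode = "cfla"),
    baseline  = list(use_lrp = FALSE, attention_mode = "full"),
    cfla_only = list(use_lrp = FALSE, attention_mode = "cfla"),
    lrp_only  = list(use_lrp = TRUE,  attention_mode = "full"))
  do.call(model_config,
          c(opts, list(pos_encoding = pos_encoding), list(...)))
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0("model_config: P=%d B=%d d_emb=%d heads=%d L=%d | ",
                     "lrp=%s attention=%s pos=%s\n"),
              x$patch_size, x$n_bands, x$d_emb, x$n_heads, x$n_layers,
              x$use_lrp, x$attention_mode, x$pos_encoding))
  invisible(x)
}

# 1-based center token index; the 0-based definition is c = floor(n/2).
center_token <- function(cfg) (cfg$n_tokens %/% 2L) + 1L

# Token grid coordinates, row-major: token t has (x = col, y = row), 0-based.
token_coords <- function(patch_size) {
  n <- patch_size^2L
  t0 <- seq_len(n) - 1L
  cbind(x = t0 %% patch_size, y = t0 %/% patch_size)
}
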