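# Aggregator: combines the LSSI score track and the sparse motif track
# into per-position splice-site probabilities.
#
# Pipeline: concat(LSSI, motifs) -> conv (width 49) -> windowed attention
# (width 401, i.e. each position attends within +/-200 nt) -> elementwise
# multiply of the first M channels with the sparse motif track (making the
# sparsity propagate literally) -> two more convolutions -> BiLSTM ->
# 3-way logits, with the acceptor/donor logits gated by adding the
# corresponding LSSI score (log-space multiplication).  Positions at the
# LSSI floor for both site types are forced to the null class.

#' Aggregator configuration
#'
#' Only the local convolution width (49) and attention window (401) are
#' structural constants of the architecture; the remaining sizes are free
#' and exposed here.
#'
#' @param n_motif_channels M, the motif-track channel count.
#' @param channels internal channel count (must exceed `n_motif_channels`).
#' @param local_conv_width,attention_window architecture widths (odd).
#' @param attention_heads number of attention heads.
#' @param post_cnn_widths widths of the two post-attention convolutions.
#' @param lstm_hidden BiLSTM hidden size per direction.
#' @param lssi_floor the LSSI clamp value (used for the null-forcing mask).
#' @param sparsity_multiply how the attention output is multiplied with
#'   the sparse motif track: `"per_channel"` (default) multiplies the
#'   first M channels elementwise with the motif track and lets the
#'   remaining channels pass through (sparsity propagates in the motif
#'   channels while LSSI-derived information keeps flowing);
#'   `"all_channels"` scales every channel by the summed motif strength,
#'   making everything downstream of the attention stage sparse.
#' @export
aggregator_config <- function(n_motif_channels, channels = 64L,
                              local_conv_width = 49L,
                              attention_window = 401L,
                              attention_heads = 4L,
                              post_cnn_widths = c(15L, 15L),
                              lstm_hidden = 128L, lssi_floor = -10,
                              sparsity_multiply = c("per_channel",
                                                    "all_channels")) {
  stopifnot(local_conv_width %% 2L == 1L, attention_window %% 2L == 1L,
            all(post_cnn_widths %% 2L == 1L),
            channels > n_motif_channels,
            channels %% attention_heads == 0L)
  structure(list(n_motif_channels = n_motif_channels, channels = channels,
                 local_conv_width = local_conv_width,
                 attention_window = attention_window,
                 attention_heads = attention_heads,
                 post_cnn_widths = post_cnn_widths,
                 lstm_hidden = lstm_hidden, lssi_floor = lssi_floor,
                 sparsity_multiply = match.arg(sparsity_multiply)),
            class = "aggregator_config")
}

#' Initialise aggregator parameters
#' @param cfg an [aggregator_config()].
#' @export
aggregator_init <- function(cfg) {
  C <- cfg$channels
  head <- nn_init_dense(2L * cfg$lstm_hidden, 3L)
  # zero-init the output head: before training the logits are exactly the
  # LSSI gating, so the model starts at the LSSI-only baseline and can
  # only add ranking signal it actually learns
  head$W <- head$W * 0
  list(
    conv0 = nn_init_conv(cfg$local_conv_width, 2L + cfg$n_motif_channels, C),
    attn = nn_init_attention(C, cfg$attention_heads,
                             C %/% cfg$attention_heads),
    post1 = nn_init_conv(cfg$post_cnn_widths[1], C, C),
    post2 = nn_init_conv(cfg$post_cnn_widths[2], C, C),
    lstm = list(fw = nn_init_lstm(C, cfg$lstm_hidden),
                bw = nn_init_lstm(C, cfg$lstm_hidden)),
    head = head
  )
}

#' Aggregator forward pass
#'
#' @param params parameters from [aggregator_init()].
#' @param cfg an [aggregator_config()].
#' @param lssi L x 2 clamped LSSI score track.
#' @param motifs L x M sparsified motif track.
#' @param keep_cache retain layer caches for backpropagation.
#' @return list with `probs` (L x 3 rows over null/acceptor/donor summing
#'   to 1), `logits`, `null_mask` (positions forced to null), and `cache`.
#' @export
aggregator_fwd <- function(params, cfg, lssi, motifs, keep_cache = FALSE) {
  if (nrow(lssi) != nrow(motifs)) stop("track length mismatch")
  M <- cfg$n_motif_channels
  stopifnot(ncol(motifs) == M)
  # the concat uses exponentiated LSSI scores (probabilities in [0, 1]) so
  # the two input families share a scale; the floor maps to ~0 and the
  # final gating still uses the raw log scores
  x0 <- cbind(exp(lssi), motifs)
  cv0 <- conv1d_fwd(x0, params$conv0)
  r0 <- relu_fwd(cv0$out)
  at <- attn_fwd(r0$out, params$attn, (cfg$attention_window - 1L) %/% 2L,
                 cfg$attention_heads)
  h2 <- at$out
  if (is.null(cfg$sparsity_multiply) ||
      cfg$sparsity_multiply == "all_channels") {
    h2m <- h2 * rowSums(motifs)
  } else {
    h2m <- h2
    h2m[, seq_len(M)] <- h2[, seq_len(M), drop = FALSE] * motifs
  }
  p1 <- conv1d_fwd(h2m, params$post1)
  r1 <- relu_fwd(p1$out)
  p2 <- conv1d_fwd(r1$out, params$post2)
  r2 <- relu_fwd(p2$out)
  bl <- bilstm_fwd(r2$out, params$lstm)
  hd <- dense_fwd(bl$out, params$head)
  logits <- hd$out
  logits[, 2] <- logits[, 2] + lssi[, 1]
  logits[, 3] <- logits[, 3] + lssi[, 2]
  null_mask <- lssi[, 1] <= cfg$lssi_floor & lssi[, 2] <= cfg$lssi_floor
  probs <- softmax_rows(logits)
  probs[null_mask, ] <- rep(c(1, 0, 0), each = sum(null_mask))
  cache <- if (keep_cache) {
    list(cv0 = cv0$cache, r0 = r0$cache, at = at$cache, h2 = h2,
         motifs = motifs, p1 = p1$cache, r1 = r1$cache, p2 = p2$cache,
         r2 = r2$cache, bl = bl$cache, hd = hd$cache)
  } else NULL
  list(probs = probs, logits = logits, null_mask = null_mask, cache = cache)
}

#' Aggregator backward pass
#'
#' @param params,cfg as in [aggregator_fwd()].
#' @param cache the cache from a forward pass with `keep_cache = TRUE`.
#' @param dlogits gradient of the loss w.r.t. the logits (rows at
#'   null-forced positions should already be zero).
#' @return list with `grads` (parameter gradients) and `dmotifs` (gradient
#'   w.r.t. the motif track, for AM training).
#' @export
aggregator_bwd <- function(params, cfg, cache, dlogits) {
  M <- cfg$n_motif_channels
  hb <- dense_bwd(params$head, cache$hd, dlogits)
  bb <- bilstm_bwd(params$lstm, cache$bl, hb$dx)
  dr2 <- relu_bwd(cache$r2, bb$dx)
  b2 <- conv1d_bwd(params$post2, cache$p2, dr2)
  dr1 <- relu_bwd(cache$r1, b2$dx)
  b1 <- conv1d_bwd(params$post1, cache$p1, dr1)
  dh2m <- b1$dx
  if (is.null(cfg$sparsity_multiply) ||
      cfg$sparsity_multiply == "all_channels") {
    dh2 <- dh2m * rowSums(cache$motifs)
    dsite <- rowSums(dh2m * cache$h2)
    dmotifs_mul <- matrix(dsite, nrow(dh2m), M)  # d strength / d motifs = 1
  } else {
    dh2 <- dh2m
    dh2[, seq_len(M)] <- dh2m[, seq_len(M), drop = FALSE] * cache$motifs
    dmotifs_mul <- dh2m[, seq_len(M), drop = FALSE] *
      cache$h2[, seq_len(M), drop = FALSE]
  }
  ab <- attn_bwd(params$attn, cache$at, dh2)
  dr0 <- relu_bwd(cache$r0, ab$dx)
  b0 <- conv1d_bwd(params$conv0, cache$cv0, dr0)
  dmotifs <- dmotifs_mul + b0$dx[, 3:(2L + M), drop = FALSE]
  list(grads = list(conv0 = b0$grads, attn = ab$grads, post1 = b1$grads,
                    post2 = b2$grads, lstm = bb$grads, head = hb$grads),
       dmotifs = dmotifs)
}

#' Percent-spliced-in of an exon from a splice prediction
#'
#' The model's probabilistic prediction is treated as a psi value: the mean
#' of the acceptor probability at the exon's 3'SS and the donor probability
#' at its 5'SS.
#'
#' @param probs L x 3 prediction matrix from [aggregator_fwd()] (columns
#'   null, acceptor, donor).
#' @param acc_pos,don_pos 0-based positions of the exon's acceptor and
#'   donor sites.
#' @return psi in `[0, 1]`.
#' @export
predict_psi <- function(probs, acc_pos, don_pos) {
  L <- nrow(probs)
  if (acc_pos < 0 || acc_pos >= L || don_pos < 0 || don_pos >= L) {
    stop("site position out of range")
  }
  mean(c(probs[acc_pos + 1L, 2], probs[don_pos + 1L, 3]))
}
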