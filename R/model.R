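# The assembled splicing model: LSSI + motif model (+ sparsity) +
# aggregator, bundled with everything needed to reproduce its forward pass
# (motif type, PSAM set, adjustment network, sparsity states, and whether
# the aggregator was trained on binarized motifs).

#' Assemble a splicing model bundle
#'
#' @param lssi trained [train_lssi()] model (frozen; shared across motif
#'   models).
#' @param sets list of [rbp_motif_set()] defining the motif channels.
#' @param motif_type `"fm"` (PSAMs + sparsity) or `"am"` (PSAMs + adjustment
#'   network with support constraint).
#' @param agg_cfg an [aggregator_config()].
#' @param agg aggregator parameters ([aggregator_init()]).
#' @param state final-density [sparsity_state()].
#' @param adj adjustment-network parameters ([adjnet_init()]; AM only).
#' @param am_cfg an [am_config()] (AM only).
#' @param state_k pre-sparsification state at density `k * delta` (AM only).
#' @param binarized if `TRUE` the motif track is binarized before the
#'   aggregator (module-substitution wiring).
#' @return object of class `sam_model`.
#' @export
sam_model <- function(lssi, sets, motif_type = c("fm", "am"), agg_cfg, agg,
                      state, adj = NULL, am_cfg = NULL, state_k = NULL,
                      binarized = FALSE) {
  motif_type <- match.arg(motif_type)
  if (motif_type == "am" &&
      (is.null(adj) || is.null(am_cfg) || is.null(state_k))) {
    stop("AM bundles need adj, am_cfg and state_k")
  }
  ids <- vapply(sets, `[[`, character(1), "rbp_id")
  stopifnot(length(ids) == agg_cfg$n_motif_channels)
  structure(list(lssi = lssi, sets = sets, channel_ids = ids,
                 motif_type = motif_type, agg_cfg = agg_cfg, agg = agg,
                 state = state, adj = adj, am_cfg = am_cfg,
                 state_k = state_k, binarized = binarized),
            class = "sam_model")
}

#' @export
print.sam_model <- function(x, ...) {
  cat(sprintf(
    "<sam_model: %s motifs%s, M = %d channels, delta = %.4g>\n",
    toupper(x$motif_type), if (x$binarized) " (binarized)" else "",
    length(x$channel_ids), x$state$delta))
  invisible(x)
}

# Compute the sparse motif track a bundle feeds its aggregator.
# Returns the pre-binarization track, the aggregator input, updated states
# and (for AM) the adjustment cache + gradient mask.
sam_motif_track <- function(model, seq_int, training = FALSE,
                            keep_cache = FALSE) {
  fm <- fm_forward(model$sets, seq_int)
  adj_cache <- NULL
  grad_mask <- NULL
  if (model$motif_type == "fm") {
    sp <- sparse_forward(fm, model$state, training = training)
    track <- sp$track
    model$state <- sp$state
  } else {
    af <- adjnet_fwd(model$adj, one_hot(seq_int))
    adj_cache <- if (keep_cache) af$cache
    amr <- am_forward(fm, af$out, model$am_cfg, model$state_k, model$state,
                      training = training)
    track <- amr$track
    model$state_k <- amr$state_k
    model$state <- amr$state_final
    grad_mask <- amr$grad_mask
  }
  track_in <- if (model$binarized) binarize(track) else track
  list(track = track, track_in = track_in, model = model,
       adj_cache = adj_cache, grad_mask = grad_mask, fm = fm)
}

#' Full forward pass of a splicing model bundle
#'
#' @param model a [sam_model()].
#' @param gene a [gene_record()] or sequence string.
#' @param lssi_scores optional precomputed [lssi_score()] track (the LSSI
#'   is frozen, so callers evaluating one gene repeatedly should pass it).
#' @param knockout_channels character vector of rbp ids whose channels are
#'   zeroed after sparsification, before the aggregator (in-silico
#'   knockout).
#' @param knockout_sites optional data frame (`pos0`, `channel`) zeroing
#'   individual motif occurrences (0-based positions; channel = rbp id or
#'   index).
#' @param motif_override optional L x M matrix replacing the motif track
#'   entirely (module substitution / ablations).
#' @param training update sparsity-state thresholds?
#' @param keep_cache retain caches for backpropagation.
#' @return list with `probs`, `psi`-ready prediction matrix, the motif
#'   `track` (pre-knockout aggregator input), `lssi_scores`, the updated
#'   `model`, and backprop material (`agg_out`, `motif_info`) when
#'   `keep_cache`.
#' @export
sam_forward <- function(model, gene, lssi_scores = NULL,
                        knockout_channels = NULL, knockout_sites = NULL,
                        motif_override = NULL, training = FALSE,
                        keep_cache = FALSE) {
  sequence <- if (inherits(gene, "gene_record")) gene$sequence else gene
  s <- seq_to_int(sequence)
  if (is.null(lssi_scores)) lssi_scores <- lssi_score(model$lssi, sequence)
  if (is.null(motif_override)) {
    mt <- sam_motif_track(model, s, training = training,
                          keep_cache = keep_cache)
    track_in <- mt$track_in
    model <- mt$model
  } else {
    stopifnot(nrow(motif_override) == length(s),
              ncol(motif_override) == model$agg_cfg$n_motif_channels)
    mt <- NULL
    track_in <- motif_override
  }
  if (!is.null(knockout_channels)) {
    idx <- match(knockout_channels, model$channel_ids)
    if (anyNA(idx)) {
      stop("unknown rbp id(s): ",
           paste(knockout_channels[is.na(idx)], collapse = ", "))
    }
    track_in[, idx] <- 0
  }
  if (!is.null(knockout_sites) && nrow(knockout_sites) > 0) {
    ch <- knockout_sites$channel
    if (is.character(ch)) ch <- match(ch, model$channel_ids)
    if (anyNA(ch)) stop("unknown channel in knockout_sites")
    track_in[cbind(knockout_sites$pos0 + 1L, ch)] <- 0
  }
  ag <- aggregator_fwd(model$agg, model$agg_cfg, lssi_scores, track_in,
                       keep_cache = keep_cache)
  list(probs = ag$probs, logits = ag$logits, null_mask = ag$null_mask,
       track_in = track_in, lssi_scores = lssi_scores, model = model,
       agg_cache = ag$cache, motif_info = mt)
}
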