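# Adjusted Motif (AM) model.
#
# The AM adjusts FM affinity scores with a small residual CNN while
# constraining its support: the FM track is first sparsified at k*delta
# (k-fold looser than the final density), the adjustment is gated onto that
# support with the oplus operator u (+) v = 1(u != 0)(u + v), and the
# result is re-sparsified at delta.  Every nonzero AM site is therefore
# among the top-k*delta FM sites of its channel, which keeps the adjusted
# motifs anchored to the RBP they started from.

#' The support-gated addition operator
#'
#' `oplus(u, v) = 1(u != 0) * (u + v)`: where `u` is zero the output is
#' zero; elsewhere the two are added.
#'
#' @param u,v numeric arrays of identical shape.
#' @export
oplus <- function(u, v) {
  if (!identical(dim(u), dim(v)) || length(u) != length(v)) {
    stop("oplus: shape mismatch")
  }
  (u != 0) * (u + v)
}

#' Binarize a motif track
#'
#' Sets every nonzero value to 1 (idempotent; preserves support exactly).
#' Used by the module-substitution experiment and RNA maps to strip
#' motif-strength information.
#' @param track numeric array.
#' @export
binarize <- function(track) {
  (track != 0) * 1
}

#' AM configuration
#' @param k overshoot factor: the FM pre-sparsification keeps `k` times as
#'   many sites as the final density allows (default 2).
#' @param delta final maximum density.
#' @param clip_negative clip post-oplus values at 0 so the track stays in
#'   nonnegative affinity-like units (motif scores are displayed in
#'   relative-affinity units, which are nonnegative).
#' @export
am_config <- function(k = 2, delta = 0.0018, clip_negative = TRUE) {
  stopifnot(k >= 1)
  if (k * delta > 1) stop("k * delta exceeds 1")
  structure(list(k = k, delta = delta, clip_negative = clip_negative),
            class = "am_config")
}

## ---- adjustment network (residual CNN, receptive field 21 nt) -------------

#' Initialise the adjustment network
#'
#' A CNN of 5 residual units, each with two width-3 convolutions, giving a
#' total context window of `1 + 5 * 2 * (3 - 1) = 21` nt.  One shared trunk
#' emits all M channels (parameter-efficient; the per-RBP alternative is a
#' straightforward variant).
#'
#' @param n_channels M, the number of motif channels emitted.
#' @param trunk_width internal channel count.
#' @param residual_units,convs_per_unit,conv_width architecture constants.
#' @return parameter list with a `receptive_field` attribute (21).
#' @export
adjnet_init <- function(n_channels, trunk_width = 16L, residual_units = 5L,
                        convs_per_unit = 2L, conv_width = 3L) {
  rf <- 1L + residual_units * convs_per_unit * (conv_width - 1L)
  head <- nn_init_conv(1L, trunk_width, n_channels)
  # zero-init the head: the adjustment starts as the identity (AM output
  # equals the resparsified FM track) and grows only as training demands
  head$W <- lapply(head$W, function(w) w * 0)
  params <- list(
    stem = nn_init_conv(1L, 4L, trunk_width),
    units = lapply(seq_len(residual_units), function(u)
      list(c1 = nn_init_conv(conv_width, trunk_width, trunk_width),
           c2 = nn_init_conv(conv_width, trunk_width, trunk_width))),
    head = head
  )
  attr(params, "receptive_field") <- rf
  params
}

adjnet_fwd <- function(params, X) {
  st <- conv1d_fwd(X, params$stem)
  h <- st$out
  unit_caches <- vector("list", length(params$units))
  for (u in seq_along(params$units)) {
    pu <- params$units[[u]]
    c1 <- conv1d_fwd(h, pu$c1)
    r1 <- relu_fwd(c1$out)
    c2 <- conv1d_fwd(r1$out, pu$c2)
    unit_caches[[u]] <- list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache)
    h <- h + c2$out
  }
  hd <- conv1d_fwd(h, params$head)
  list(out = hd$out,
       cache = list(stem = st$cache, units = unit_caches, head = hd$cache))
}

adjnet_bwd <- function(params, cache, dout) {
  hb <- conv1d_bwd(params$head, cache$head, dout)
  dh <- hb$dx
  unit_grads <- vector("list", length(params$units))
  for (u in rev(seq_along(params$units))) {
    pu <- params$units[[u]]
    cu <- cache$units[[u]]
    b2 <- conv1d_bwd(pu$c2, cu$c2, dh)
    dr1 <- relu_bwd(cu$r1, b2$dx)
    b1 <- conv1d_bwd(pu$c1, cu$c1, dr1)
    unit_grads[[u]] <- list(c1 = b1$grads, c2 = b2$grads)
    dh <- dh + b1$dx                    # residual skip
  }
  sb <- conv1d_bwd(params$stem, cache$stem, dh)
  list(grads = list(stem = sb$grads, units = unit_grads, head = hb$grads),
       dx = sb$dx)
}

## ---- AM forward -----------------------------------------------------------

#' AM forward pass
#'
#' `f' = Sparse(f, k * delta)`, `y = Sparse(clip(f' (+) a), delta)` where
#' `f` is the FM track and `a` the adjustment output.  The support of the
#' result is contained in the top-`k*delta` FM sites per channel.
#'
#' @param fm_track L x M FM affinity track ([fm_forward()]).
#' @param adj_out L x M adjustment track (from [adjnet_fwd()]), or `NULL`
#'   for a pure resparsified FM pass-through.
#' @param cfg an [am_config()].
#' @param state_k [sparsity_state()] at density `k * delta` for the FM
#'   pre-sparsification (kept separate from the final state).
#' @param state_final [sparsity_state()] at density `delta`.
#' @param training update the sparsity states' thresholds?
#' @return list with `track` (the AM output), updated `state_k`,
#'   `state_final`, and `grad_mask` (L x M matrix of d track / d adj_out,
#'   0/1, for backpropagation).
#' @export
am_forward <- function(fm_track, adj_out, cfg, state_k, state_final,
                       training = FALSE) {
  if (cfg$k * cfg$delta > 1) stop("k * delta exceeds 1")
  # During annealing the states carry the current (capped) densities; the
  # looser pre-sparsification must never be tighter than the final one.
  stopifnot(state_k$delta >= state_final$delta - 1e-12)
  sk <- sparse_forward(fm_track, state_k, training = training)
  fprime <- sk$track
  if (is.null(adj_out)) adj_out <- fm_track * 0
  y_pre <- oplus(fprime, adj_out)
  clipped <- matrix(FALSE, nrow(y_pre), ncol(y_pre))
  if (cfg$clip_negative) {
    clipped <- y_pre < 0
    y_pre[clipped] <- 0
  }
  sf <- sparse_forward(y_pre, state_final, training = training)
  grad_mask <- (fprime != 0) * (!clipped) * (sf$track != 0)
  list(track = sf$track, state_k = sk$state, state_final = sf$state,
       grad_mask = grad_mask)
}

## ---- neural motif models trained on RBNS read pools -----------------------

# Per-read score track for a given architecture; reads are short, so each
# is pushed through the CNN individually.
rbns_arch_init <- function(arch, trunk_width) {
  switch(arch,
    am21 = adjnet_init(1L, trunk_width = trunk_width),
    conv11 = list(convs = list(nn_init_conv(3L, 4L, trunk_width),
                               nn_init_conv(3L, trunk_width, trunk_width),
                               nn_init_conv(3L, trunk_width, trunk_width),
                               nn_init_conv(5L, trunk_width, 1L))),
    conv14 = list(convs = list(nn_init_conv(4L, 4L, trunk_width),
                               nn_init_conv(4L, trunk_width, trunk_width),
                               nn_init_conv(4L, trunk_width, trunk_width),
                               nn_init_conv(5L, trunk_width, 1L))),
    stop("unknown architecture: ", arch))
}

rbns_arch_fwd <- function(arch, params, X) {
  if (arch == "am21") return(adjnet_fwd(params, X))
  h <- X
  caches <- vector("list", length(params$convs))
  for (i in seq_along(params$convs)) {
    cv <- conv1d_fwd(h, params$convs[[i]])
    if (i < length(params$convs)) {
      r <- relu_fwd(cv$out)
      caches[[i]] <- list(conv = cv$cache, relu = r$cache)
      h <- r$out
    } else {
      caches[[i]] <- list(conv = cv$cache)
      h <- cv$out
    }
  }
  list(out = h, cache = caches)
}

rbns_arch_bwd <- function(arch, params, cache, dout) {
  if (arch == "am21") return(adjnet_bwd(params, cache, dout))
  dh <- dout
  grads <- vector("list", length(params$convs))
  for (i in rev(seq_along(params$convs))) {
    if (i < length(params$convs)) dh <- relu_bwd(cache[[i]]$relu, dh)
    bk <- conv1d_bwd(params$convs[[i]], cache[[i]]$conv, dh)
    grads[[i]] <- bk$grads
    dh <- bk$dx
  }
  list(grads = list(convs = grads), dx = dh)
}

# Smooth-max pooling of a per-position score vector into a read score:
# log-sum-exp matches "at least one binding site" semantics.
lse_pool <- function(v) {
  m <- max(v)
  m + log(sum(exp(v - m)))
}

#' Train a neural motif model on RBNS-style bound/input read pools
#'
#' Binary classification of reads as coming from the protein-bound pool
#' versus the input pool.  The `am21` architecture is the adjustment-CNN
#' shape trained without sparsity — effectively the sum of a PSAM signal
#' and a learned neural model — and requires `psams`; `conv11`/`conv14`
#' are plain 4-layer CNNs with total receptive fields of 11 and 14 nt.
#' Per-read scores pool the per-position track with log-sum-exp.
#'
#' @param reads_bound,reads_input character vectors of reads.
#' @param arch `"am21"`, `"conv11"` or `"conv14"`.
#' @param psams an [rbp_motif_set()] (required for `am21`): the fixed PSAM
#'   signal added to the neural track, and the PSAM-only baseline.
#' @param epochs,learning_rate,trunk_width training hyperparameters.
#' @param val_frac held-out fraction for accuracy reporting.
#' @param seed RNG seed.
#' @return list with `params`, `arch`, `accuracy` (held-out), and, when a
#'   PSAM baseline is available, `baseline_accuracy` and `delta_accuracy`.
#' @export
train_neural_motif_rbns <- function(reads_bound, reads_input,
                                    arch = c("am21", "conv11", "conv14"),
                                    psams = NULL, epochs = 3L,
                                    learning_rate = 3e-3, trunk_width = 8L,
                                    val_frac = 0.25, seed = 1L) {
  arch <- match.arg(arch)
  if (length(reads_bound) == 0 || length(reads_input) == 0) {
    stop("empty read pool")
  }
  if (arch == "am21" && is.null(psams)) {
    stop("am21 architecture requires psams")
  }
  set.seed(seed)
  reads <- c(reads_bound, reads_input)
  y <- c(rep(1L, length(reads_bound)), rep(0L, length(reads_input)))
  n <- length(reads)
  ord <- sample.int(n)
  n_val <- max(1L, floor(val_frac * n))
  val_idx <- ord[seq_len(n_val)]
  train_idx <- ord[-seq_len(n_val)]
  enc <- lapply(reads, seq_to_int)
  Xs <- lapply(enc, one_hot)
  # PSAM signal on the log-affinity scale, so the smooth-max pooling reads
  # it as "the best site's log affinity" and the neural track adds to it
  psam_scores <- if (!is.null(psams)) {
    lapply(enc, function(s) log(score_rbp(psams, s) + 1e-6))
  } else NULL

  params <- rbns_arch_init(arch, trunk_width)
  bias <- 0
  opt <- adam_init(params)
  read_logit <- function(i, with_cache = FALSE) {
    fw <- rbns_arch_fwd(arch, params, Xs[[i]])
    track <- drop(fw$out)
    if (arch == "am21") track <- track + psam_scores[[i]]
    list(logit = lse_pool(track) + bias, track = track, fw = fw)
  }
  for (ep in seq_len(epochs)) {
    for (i in sample(train_idx)) {
      rl <- read_logit(i)
      p <- sigmoid(rl$logit)
      dlogit <- p - y[i]                 # d logistic loss / d logit
      w <- exp(rl$track - max(rl$track))
      dtrack <- dlogit * w / sum(w)      # lse pooling backward
      bk <- rbns_arch_bwd(arch, params, rl$fw$cache,
                          matrix(dtrack, ncol = 1))
      upd <- adam_step(params, bk$grads, opt, lr = learning_rate)
      params <- upd$params
      opt <- upd$opt
      bias <- bias - learning_rate * dlogit
    }
  }
  logits_val <- vapply(val_idx, function(i) read_logit(i)$logit, numeric(1))
  accuracy <- mean((logits_val > 0) == (y[val_idx] == 1L))
  out <- list(params = params, arch = arch, bias = bias,
              accuracy = accuracy)
  if (!is.null(psam_scores)) {
    # PSAM-only baseline: logistic fit of the pooled PSAM score
    base_tr <- vapply(train_idx, function(i) lse_pool(psam_scores[[i]]),
                      numeric(1))
    base_va <- vapply(val_idx, function(i) lse_pool(psam_scores[[i]]),
                      numeric(1))
    fit <- suppressWarnings(stats::glm(y[train_idx] ~ base_tr,
                                       family = stats::binomial()))
    pred <- stats::predict(fit, newdata = data.frame(base_tr = base_va))
    out$baseline_accuracy <- mean((pred > 0) == (y[val_idx] == 1L))
    out$delta_accuracy <- accuracy - out$baseline_accuracy
  }
  out
}

#' Logistic discriminator between AM-exclusive and FM-exclusive sites
#'
#' Fits a logistic model with four parameters per motif position (one-hot
#' bases) to distinguish sites bound only by the AM from sites bound only
#' by the FM, reporting held-out accuracy.  High accuracy means the
#' difference between the motif models is largely a linear function of the
#' bases present.
#'
#' @param am_only_sites,fm_only_sites character vectors of equal-length
#'   site sequences.
#' @param val_frac held-out fraction.
#' @param seed RNG seed.
#' @return list with `coefficients` (width x 4 matrix, NA for aliased
#'   levels), `accuracy` (held-out), and the fitted `model`.
#' @export
am_fm_discriminator <- function(am_only_sites, fm_only_sites,
                                val_frac = 0.25, seed = 1L) {
  if (length(am_only_sites) == 0 || length(fm_only_sites) == 0) {
    stop("both site classes must be non-empty")
  }
  seqs <- c(am_only_sites, fm_only_sites)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1) stop("site sequences differ in length")
  w <- widths[1]
  y <- c(rep(1L, length(am_only_sites)), rep(0L, length(fm_only_sites)))
  X <- do.call(rbind, lapply(seqs, function(sq) {
    as.vector(t(one_hot(seq_to_int(sq))))
  }))
  colnames(X) <- paste0("p", rep(seq_len(w), each = 4), "_",
                        rep(BASES, w))
  set.seed(seed)
  ord <- sample.int(length(y))
  n_val <- max(1L, floor(val_frac * length(y)))
  val_idx <- ord[seq_len(n_val)]
  tr_idx <- ord[-seq_len(n_val)]
  df <- as.data.frame(X)
  fit <- suppressWarnings(stats::glm(y[tr_idx] ~ ., family = stats::binomial(),
                                     data = df[tr_idx, , drop = FALSE]))
  pred <- suppressWarnings(
    stats::predict(fit, newdata = df[val_idx, , drop = FALSE]))
  accuracy <- mean((pred > 0) == (y[val_idx] == 1L))
  cf <- stats::coef(fit)[-1]
  coef_mat <- matrix(cf[paste0("p", rep(seq_len(w), each = 4), "_",
                               rep(BASES, w))],
                     nrow = w, ncol = 4, byrow = TRUE,
                     dimnames = list(NULL, BASES))
  coef_mat[is.na(coef_mat)] <- 0        # aliased one-hot reference levels
  list(coefficients = coef_mat, accuracy = accuracy, model = fit)
}
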