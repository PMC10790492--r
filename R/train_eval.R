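# End-to-end training and evaluation: top-k accuracy, the density-annealed
# training loop, the module-substitution experiment and the
# sequence-reconstruction probe.

#' Top-k splice-site accuracy
#'
#' Top-k accuracy is the fraction of true sites predicted correctly at a
#' score cutoff that emits exactly as many predictions as there are true
#' sites.  In `per_class` mode each class (acceptor, donor) uses its own
#' k = number of true sites of that class; in `union` mode a single
#' k = total number of true sites is applied to the pooled
#' (position, class) candidates, giving a threshold consistent across
#' exon classes.  Ties at the k-th score break by (score desc, position
#' asc).
#'
#' @param scores L x 3 matrix (columns null, acceptor, donor) or a list of
#'   such matrices (genes are pooled).
#' @param labels label track(s) from [make_label_track()], matching
#'   `scores`.
#' @param mode `"per_class"` or `"union"`.
#' @param exclude optional logical vector/list marking positions excluded
#'   from ranking (e.g. N bases).
#' @return list with per-class `k`, `threshold`, `accuracy`, and the mean
#'   `accuracy` (`per_class`), or the single union accuracy (`union`).
#'   k = 0 yields an NA accuracy with a flag.
#' @export
topk_accuracy <- function(scores, labels, mode = c("per_class", "union"),
                          exclude = NULL) {
  mode <- match.arg(mode)
  if (is.list(scores)) scores <- do.call(rbind, scores)
  if (is.list(labels)) labels <- unlist(labels, use.names = FALSE)
  if (is.list(exclude)) exclude <- unlist(exclude, use.names = FALSE)
  stopifnot(nrow(scores) == length(labels))
  keep <- if (is.null(exclude)) rep(TRUE, length(labels)) else !exclude
  top_of <- function(score, k) {
    ord <- order(score, decreasing = TRUE)   # stable: position asc on ties
    list(idx = ord[seq_len(k)], threshold = score[ord[k]])
  }
  if (mode == "per_class") {
    res <- lapply(c(acceptor = 1L, donor = 2L), function(cls) {
      k <- sum(labels == cls & keep)
      if (k == 0) {
        return(list(k = 0L, threshold = NA_real_, accuracy = NA_real_,
                    undefined = TRUE))
      }
      sc <- scores[, cls + 1L]
      sc[!keep] <- -Inf
      tp <- top_of(sc, k)
      list(k = k, threshold = tp$threshold,
           accuracy = mean(labels[tp$idx] == cls), undefined = FALSE)
    })
    accs <- vapply(res, `[[`, numeric(1), "accuracy")
    c(res, list(accuracy = mean(accs, na.rm = TRUE)))
  } else {
    k <- sum(labels %in% c(1L, 2L) & keep)
    if (k == 0) return(list(k = 0L, accuracy = NA_real_, undefined = TRUE))
    # pooled candidates: (position, acceptor) and (position, donor)
    sc <- c(scores[, 2], scores[, 3])
    sc[c(!keep, !keep)] <- -Inf
    cand_class <- rep(c(1L, 2L), each = length(labels))
    cand_label <- rep(labels, 2)
    tp <- top_of(sc, k)
    list(k = k, threshold = tp$threshold,
         accuracy = sum(cand_label[tp$idx] == cand_class[tp$idx]) / k,
         undefined = FALSE)
  }
}

#' Evaluate a model bundle's top-k accuracy over genes
#' @param model a [sam_model()].
#' @param genes,labels evaluation set.
#' @param mode passed to [topk_accuracy()].
#' @param lssi_cache optional precomputed list of LSSI score tracks.
#' @return the [topk_accuracy()] result.
#' @export
sam_eval_topk <- function(model, genes, labels, mode = "per_class",
                          lssi_cache = NULL) {
  probs <- lapply(seq_along(genes), function(i) {
    sam_forward(model, genes[[i]],
                lssi_scores = lssi_cache[[i]])$probs
  })
  topk_accuracy(probs, labels, mode = mode)
}

#' Top-k accuracy of the LSSI scores alone (baseline)
#'
#' Uses the clamped LSSI log-probabilities directly as site scores, with a
#' flat null column.
#' @param lssi a trained [train_lssi()] model.
#' @param genes,labels evaluation set.
#' @export
lssi_eval_topk <- function(lssi, genes, labels, mode = "per_class") {
  scores <- lapply(genes, function(g) {
    sc <- lssi_score(lssi, g)
    cbind(0, sc[, 1], sc[, 2])
  })
  topk_accuracy(scores, labels, mode = mode)
}

## ---- end-to-end training --------------------------------------------------

# Recalibrate a bundle's sparsity thresholds to the exact top-delta cut
# over a set of genes (deterministic eval pass).
sam_recalibrate <- function(model, genes) {
  seqs <- lapply(genes, function(g) seq_to_int(g$sequence))
  fms <- lapply(seqs, function(s) fm_forward(model$sets, s))
  if (model$motif_type == "fm") {
    model$state <- sparse_recalibrate(fms, model$state)
  } else {
    model$state_k <- sparse_recalibrate(fms, model$state_k)
    pre <- lapply(seq_along(seqs), function(i) {
      fprime <- sparse_forward(fms[[i]], model$state_k)$track
      a <- adjnet_fwd(model$adj, one_hot(seqs[[i]]))$out
      y <- oplus(fprime, a)
      if (model$am_cfg$clip_negative) y[y < 0] <- 0
      y
    })
    model$state <- sparse_recalibrate(pre, model$state)
  }
  model
}

#' Train a splicing model end-to-end with density annealing
#'
#' Trains the aggregator (and, for AM, the adjustment network) by
#' per-position cross-entropy on the splice-site labels, with the motif
#' layer's maximum density delta annealed from `schedule$start_delta`
#' downward: `schedule$checks_per_epoch` times per epoch, validation
#' accuracy V(t) (mean of acceptor and donor top-k) is compared against
#' the target VT(t) and delta is multiplied by `schedule$factor` when the
#' target is met.  The LSSI model is frozen throughout.
#'
#' @param genes,labels training set.
#' @param lssi frozen [train_lssi()] model.
#' @param sets list of [rbp_motif_set()] (the FM channels).
#' @param val_genes,val_labels validation set driving the annealing.
#' @param motif_type `"fm"` or `"am"`.
#' @param mode `"standard"` (constant VT from `schedule$vt`) or `"quick"`
#'   (dynamic VT: starts at 0.85, decays 1% per epoch, bumps to the
#'   accuracy achieved at each delta reduction).
#' @param schedule an [anneal_schedule()].
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param accum_genes genes per optimizer update: gradients are averaged
#'   over this many genes before each Adam step (larger = smoother but
#'   fewer updates).
#' @param clip_norm global gradient-norm clip applied before each update
#'   (BiLSTM backpropagation occasionally produces exploding gradients
#'   that would otherwise wreck the learned ranking).
#' @param weight_decay decoupled weight decay applied at each update;
#'   keeps unused aggregator capacity near zero so the prediction
#'   defaults to the LSSI-gated baseline unless the motif pathway earns
#'   its keep.
#' @param agg_cfg an [aggregator_config()]; defaults to modest sizes for
#'   the channel count.
#' @param am_k AM overshoot factor k.
#' @param trunk_width adjustment-network trunk width (AM).
#' @param seed RNG seed (controls init and gene order).
#' @param init_model optional [sam_model()] to warm-start from.
#' @param binarized train the aggregator on binarized motif tracks (the
#'   motif model itself is then frozen: no adjustment training, no
#'   annealing).
#' @param keep_best snapshot parameters at the end of every epoch (once
#'   the density target is reached) and return the snapshot with the best
#'   validation top-k, protecting the returned model against
#'   late-training degradation.
#' @param recalibrate recalibrate thresholds deterministically at the end.
#' @param verbose print annealing events.
#' @return list with `model` (a [sam_model()]) and `history` (one row per
#'   annealing check: step, epoch, delta, val_accuracy, vt, reduced).
#' @export
train_end_to_end <- function(genes, labels, lssi, sets, val_genes,
                             val_labels, motif_type = c("fm", "am"),
                             mode = c("quick", "standard"),
                             schedule = anneal_schedule(),
                             epochs = 4L, learning_rate = 1e-3,
                             accum_genes = 1L, clip_norm = 1,
                             weight_decay = 0,
                             agg_cfg = NULL, am_k = 2,
                             trunk_width = 16L, seed = 1L,
                             init_model = NULL, binarized = FALSE,
                             keep_best = TRUE,
                             recalibrate = TRUE, verbose = FALSE) {
  motif_type <- match.arg(motif_type)
  mode <- match.arg(mode)
  set.seed(seed)
  M <- length(sets)
  if (is.null(agg_cfg)) {
    agg_cfg <- if (!is.null(init_model)) init_model$agg_cfg else
      aggregator_config(M, channels = 4L * max(2L, ceiling(M / 2L)),
                        attention_heads = 2L, lstm_hidden = 16L)
  }
  target_delta <- schedule$target_delta
  if (!is.null(init_model)) {
    model <- init_model
    model$binarized <- binarized
  } else {
    state <- sparsity_state(M, delta = if (binarized) target_delta else
      schedule$start_delta)
    if (motif_type == "am") {
      am_cfg <- am_config(k = am_k, delta = target_delta)
      model <- sam_model(lssi, sets, "am", agg_cfg, aggregator_init(agg_cfg),
                         state, adj = adjnet_init(M, trunk_width),
                         am_cfg = am_cfg,
                         state_k = sparsity_state(
                           M, delta = min(1, am_k * state$delta)),
                         binarized = binarized)
    } else {
      model <- sam_model(lssi, sets, "fm", agg_cfg, aggregator_init(agg_cfg),
                         state, binarized = binarized)
    }
  }
  anneal_active <- !binarized
  train_adj <- model$motif_type == "am" && !binarized

  params <- list(agg = model$agg)
  if (train_adj) params$adj <- model$adj
  opt <- adam_init(params)

  lssi_tr <- lapply(genes, function(g) lssi_score(lssi, g))
  lssi_va <- lapply(val_genes, function(g) lssi_score(lssi, g))

  n <- length(genes)
  checks <- unique(pmax(1L, round(seq_len(schedule$checks_per_epoch) *
                                    n / schedule$checks_per_epoch)))
  history <- list()
  step <- 0L
  last_red_acc <- NULL
  last_red_epoch <- 0
  validate <- function() {
    mdl <- model
    mdl$agg <- params$agg
    if (train_adj) mdl$adj <- params$adj
    sam_eval_topk(mdl, val_genes, val_labels,
                  lssi_cache = lssi_va)$accuracy
  }
  best <- NULL
  consider_best <- function(tag) {
    if (!keep_best) return(invisible(NULL))
    vacc <- validate()
    if (is.null(best) || vacc > best$vacc) {
      # snapshot parameters only: the sparsity states keep annealing to
      # their final densities regardless of which snapshot wins
      best <<- list(vacc = vacc, params = params, tag = tag)
      if (verbose) message("best so far: ", tag, " (V = ", round(vacc, 3),
                           ")")
    }
    invisible(NULL)
  }

  pending <- NULL
  n_pending <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (j in seq_len(n)) {
      i <- ord[j]
      model$agg <- params$agg
      if (train_adj) model$adj <- params$adj
      fw <- sam_forward(model, genes[[i]], lssi_scores = lssi_tr[[i]],
                        training = anneal_active, keep_cache = TRUE)
      model <- fw$model                  # EMA threshold updates
      lab <- labels[[i]] + 1L
      ce <- softmax_xent(fw$logits, lab, include = !fw$null_mask)
      bk <- aggregator_bwd(params$agg, model$agg_cfg, fw$agg_cache,
                           ce$dlogits)
      grads <- list(agg = bk$grads)
      if (train_adj) {
        dadj <- bk$dmotifs * fw$motif_info$grad_mask
        grads$adj <- adjnet_bwd(params$adj, fw$motif_info$adj_cache,
                                dadj)$grads
      }
      pending <- grad_add(pending, grads)
      n_pending <- n_pending + 1L
      if (n_pending >= accum_genes || j == n) {
        scale_rec <- function(g) {
          if (is.list(g)) lapply(g, scale_rec) else g / n_pending
        }
        upd <- adam_step(params, grad_clip(scale_rec(pending), clip_norm),
                         opt, lr = learning_rate,
                         weight_decay = weight_decay)
        params <- upd$params
        opt <- upd$opt
        pending <- NULL
        n_pending <- 0L
      }
      if (anneal_active && model$state$delta > target_delta &&
          j %in% checks) {
        step <- step + 1L
        epoch_frac <- ep - 1 + j / n
        vacc <- validate()
        vt <- if (mode == "quick") {
          quick_vt(epoch_frac, last_red_acc, last_red_epoch)
        } else if (is.function(schedule$vt)) schedule$vt(step) else
          schedule$vt
        sched_now <- schedule
        sched_now$vt <- vt
        ans <- anneal_step(sched_now, model$state, vacc, step)
        reduced <- ans$reduced
        if (reduced) {
          model$state <- ans$state
          if (model$motif_type == "am") {
            model$state_k$delta <- min(1, model$am_cfg$k * model$state$delta)
          }
          last_red_acc <- vacc
          last_red_epoch <- epoch_frac
          if (verbose) {
            message(sprintf("step %d: delta -> %.4g (V=%.3f >= VT=%.3f)",
                            step, model$state$delta, vacc, vt))
          }
        }
        history[[step]] <- data.frame(step = step, epoch = epoch_frac,
                                      delta = model$state$delta,
                                      val_accuracy = vacc, vt = vt,
                                      reduced = reduced)
      }
    }
    if (model$state$delta <= target_delta || binarized) {
      consider_best(paste0("epoch", ep))
    }
  }
  if (keep_best && !is.null(best)) {
    params <- best$params
  }
  model$agg <- params$agg
  if (train_adj) model$adj <- params$adj
  if (recalibrate && !binarized) model <- sam_recalibrate(model, genes)
  list(model = model,
       history = if (length(history)) do.call(rbind, history) else
         data.frame(step = integer(0), epoch = numeric(0),
                    delta = numeric(0), val_accuracy = numeric(0),
                    vt = numeric(0), reduced = logical(0)))
}

#' Module-substitution experiment
#'
#' Binarizes the motif outputs of both bundles, retrains each aggregator
#' on its own binarized motifs, then evaluates the full grid of
#' {FM, AM} binary motifs x {FM-retrained, AM-retrained} aggregators on a
#' test set.  If the motif interface carries stable meaning, the AM motifs
#' should help even through the FM-trained aggregator.
#'
#' @param fm_bundle,am_bundle trained [sam_model()] bundles sharing channel
#'   ids and LSSI.
#' @param genes,labels retraining set.
#' @param test_genes,test_labels evaluation set.
#' @param epochs,learning_rate retraining hyperparameters.
#' @param seed RNG seed.
#' @return list with `grid` (2 x 2 accuracy matrix, rows = motif source,
#'   cols = aggregator) and the retrained bundles.
#' @export
module_substitution <- function(fm_bundle, am_bundle, genes, labels,
                                test_genes, test_labels, epochs = 2L,
                                learning_rate = 1e-3, seed = 1L) {
  if (!identical(fm_bundle$channel_ids, am_bundle$channel_ids)) {
    stop("bundles have incompatible channel sets")
  }
  retrain <- function(bundle, salt) {
    train_end_to_end(genes, labels, bundle$lssi, bundle$sets,
                     val_genes = genes[1], val_labels = labels[1],
                     motif_type = bundle$motif_type, epochs = epochs,
                     learning_rate = learning_rate,
                     seed = derive_seed(seed, salt),
                     init_model = bundle, binarized = TRUE)$model
  }
  fm_bin <- retrain(fm_bundle, 1L)
  am_bin <- retrain(am_bundle, 2L)
  binary_tracks <- function(bundle) {
    lapply(test_genes, function(g) {
      binarize(sam_motif_track(bundle, seq_to_int(g$sequence))$track)
    })
  }
  tracks <- list(fm = binary_tracks(fm_bundle), am = binary_tracks(am_bundle))
  aggs <- list(fm = fm_bin, am = am_bin)
  grid <- matrix(NA_real_, 2, 2,
                 dimnames = list(motifs = c("fm", "am"),
                                 aggregator = c("fm", "am")))
  for (mo in c("fm", "am")) {
    for (ag in c("fm", "am")) {
      probs <- lapply(seq_along(test_genes), function(i) {
        sam_forward(aggs[[ag]], test_genes[[i]],
                    motif_override = tracks[[mo]][[i]])$probs
      })
      grid[mo, ag] <- topk_accuracy(probs, test_labels)$accuracy
    }
  }
  list(grid = grid, fm_binary = fm_bin, am_binary = am_bin)
}

## ---- reconstruction probe -------------------------------------------------

#' Probe how much sequence the sparse motif layer lets through
#'
#' Trains a small decoder from windows of the sparse motif track to the
#' base identity at the window center and reports held-out per-base
#' accuracy plus an information estimate: `2 - H(base | prediction)` in
#' bits/nt, with the conditional entropy read off the held-out confusion
#' matrix.  Comparing the estimate against [entropy_bound()] at the
#' track's measured (density, eta) checks the bound's soundness.
#'
#' @param tracks list of sparse L x M motif tracks.
#' @param sequences matching list of sequences (strings or integer codes).
#' @param half_window decoder input half-width (window = 2*half+1
#'   positions x M channels).
#' @param hidden decoder hidden width.
#' @param epochs,learning_rate,batch_size decoder training
#'   hyperparameters.
#' @param max_positions cap on sampled training+test positions.
#' @param val_frac held-out fraction.
#' @param seed RNG seed.
#' @return list with `accuracy`, `info_bits`, `confusion`, `base_rate`
#'   (majority-class accuracy floor).
#' @export
reconstruction_probe <- function(tracks, sequences, half_window = 5L,
                                 hidden = 32L, epochs = 6L,
                                 learning_rate = 3e-3, batch_size = 100L,
                                 max_positions = 20000L, val_frac = 0.25,
                                 seed = 1L) {
  set.seed(seed)
  seqs <- lapply(sequences, function(s)
    if (is.character(s)) seq_to_int(s) else s)
  M <- ncol(tracks[[1]])
  W <- 2L * half_window + 1L
  feats <- list(); targs <- list()
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    L <- nrow(tr)
    pos <- (half_window + 1L):(L - half_window)
    X <- matrix(0, length(pos), W * M)
    for (w in seq_len(W)) {
      X[, ((w - 1L) * M + 1L):(w * M)] <-
        tr[pos + (w - half_window - 1L), , drop = FALSE]
    }
    feats[[i]] <- X
    targs[[i]] <- seqs[[i]][pos]
  }
  X <- do.call(rbind, feats)
  y <- unlist(targs)
  keep <- y > 0L
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (nrow(X) > max_positions) {
    idx <- sample.int(nrow(X), max_positions)
    X <- X[idx, , drop = FALSE]; y <- y[idx]
  }
  n <- nrow(X)
  ord <- sample.int(n)
  n_val <- max(1L, floor(val_frac * n))
  val <- ord[seq_len(n_val)]
  tr_idx <- ord[-seq_len(n_val)]
  params <- list(h = nn_init_dense(ncol(X), hidden),
                 o = nn_init_dense(hidden, 4L))
  opt <- adam_init(params)
  for (ep in seq_len(epochs)) {
    shuffled <- sample(tr_idx)
    for (st in seq(1L, length(shuffled), by = batch_size)) {
      idx <- shuffled[st:min(st + batch_size - 1L, length(shuffled))]
      d1 <- dense_fwd(X[idx, , drop = FALSE], params$h)
      r1 <- relu_fwd(d1$out)
      d2 <- dense_fwd(r1$out, params$o)
      ce <- softmax_xent(d2$out, y[idx])
      b2 <- dense_bwd(params$o, d2$cache, ce$dlogits)
      b1 <- dense_bwd(params$h, d1$cache, relu_bwd(r1$cache, b2$dx))
      upd <- adam_step(params, list(h = b1$grads, o = b2$grads), opt,
                       lr = learning_rate)
      params <- upd$params
      opt <- upd$opt
    }
  }
  d1 <- dense_fwd(X[val, , drop = FALSE], params$h)
  d2 <- dense_fwd(relu_fwd(d1$out)$out, params$o)
  pred <- max.col(d2$out, ties.method = "first")
  confusion <- table(factor(y[val], levels = 1:4),
                     factor(pred, levels = 1:4))
  accuracy <- mean(pred == y[val])
  # conditional entropy H(base | prediction) from the confusion matrix
  h_cond <- 0
  n_tot <- sum(confusion)
  for (p in 1:4) {
    np <- sum(confusion[, p])
    if (np == 0) next
    q <- confusion[, p] / np
    q <- q[q > 0]
    h_cond <- h_cond + (np / n_tot) * (-sum(q * log2(q)))
  }
  list(accuracy = accuracy, info_bits = 2 - h_cond, confusion = confusion,
       base_rate = max(tabulate(y[val], 4)) / length(val))
}
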