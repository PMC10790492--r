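# A tiny aggregator configuration keeps these contract tests fast; the
# architectural widths (49/401) are exercised in the training-level tests.
tiny_agg <- function(M = 3L, seed = 101) {
  set.seed(seed)
  cfg <- aggregator_config(M, channels = 8L, local_conv_width = 5L,
                           attention_window = 9L, attention_heads = 2L,
                           post_cnn_widths = c(3L, 3L), lstm_hidden = 4L)
  list(cfg = cfg, params = aggregator_init(cfg))
}

test_that("prediction rows are a proper distribution and floor positions are null", {
  ta <- tiny_agg()
  L <- 60L
  set.seed(102)
  lssi <- matrix(stats::runif(L * 2, -9, -1), L, 2)
  lssi[c(5, 20), ] <- -10               # both columns at the floor
  lssi[30, 1] <- -10                    # only one column: still a candidate
  motifs <- matrix(0, L, 3)
  motifs[sample.int(L * 3, 20)] <- stats::runif(20, 0.5, 2)
  out <- aggregator_fwd(ta$params, ta$cfg, lssi, motifs)
  expect_equal(rowSums(out$probs), rep(1, L), tolerance = 1e-6)
  expect_true(all(out$probs >= 0))
  expect_equal(out$probs[5, ], c(1, 0, 0))
  expect_equal(out$probs[20, ], c(1, 0, 0))
  expect_false(all(out$probs[30, 2:3] == 0))
  expect_error(aggregator_fwd(ta$params, ta$cfg, lssi[1:10, ], motifs),
               "mismatch")
})

test_that("windowed attention is exactly local; the BiLSTM is not", {
  ta <- tiny_agg()
  set.seed(103)
  L <- 80L
  x <- matrix(stats::rnorm(L * 8), L, 8)
  base <- attn_fwd(x, ta$params$attn, 4L, 2L)$out
  x2 <- x
  x2[60, ] <- stats::rnorm(8)           # 30 positions away from row 30
  pert <- attn_fwd(x2, ta$params$attn, 4L, 2L)$out
  expect_equal(pert[30, ], base[30, ])  # outside the +/-4 window: exactly 0
  expect_false(isTRUE(all.equal(pert[58, ], base[58, ])))
  # BiLSTM carries information across the whole sequence
  pl <- list(fw = nn_init_lstm(8L, 4L), bw = nn_init_lstm(8L, 4L))
  bbase <- bilstm_fwd(x, pl)$out
  bpert <- bilstm_fwd(x2, pl)$out
  expect_false(isTRUE(all.equal(bpert[30, ], bbase[30, ])))
})

test_that("sparsity propagates: all-zero motifs reduce to an LSSI-only path", {
  # with an all-zero motif track, predictions depend only on the LSSI
  # input: changing the motif multiply stage's scale cannot matter
  ta <- tiny_agg()
  # a zero-initialised head is insensitive to everything; randomize it so
  # the motif pathway is visible in the output
  ta$params$head$W <- matrix(stats::rnorm(length(ta$params$head$W),
                                          sd = 0.5),
                             nrow(ta$params$head$W))
  L <- 50L
  set.seed(104)
  lssi <- matrix(stats::runif(L * 2, -8, -1), L, 2)
  zero <- matrix(0, L, 3)
  out1 <- aggregator_fwd(ta$params, ta$cfg, lssi, zero)$probs
  # doubling any motif values is a no-op when there are none
  out2 <- aggregator_fwd(ta$params, ta$cfg, lssi, 2 * zero)$probs
  expect_equal(out1, out2)
  # but a nonzero motif track does change the prediction
  nz <- zero; nz[25, 2] <- 1.5
  out3 <- aggregator_fwd(ta$params, ta$cfg, lssi, nz)$probs
  expect_false(isTRUE(all.equal(out1, out3)))
})

test_that("aggregator gradients agree with finite differences", {
  L <- 24L
  for (mode in c("per_channel", "all_channels")) {
    set.seed(105)
    cfg <- aggregator_config(3L, channels = 8L, local_conv_width = 5L,
                             attention_window = 9L, attention_heads = 2L,
                             post_cnn_widths = c(3L, 3L), lstm_hidden = 4L,
                             sparsity_multiply = mode)
    params <- aggregator_init(cfg)
    # randomize the zero-initialised head (and biases) so gradients flow
    # everywhere and no relu input sits exactly at its kink
    params$head$W <- matrix(stats::rnorm(length(params$head$W), sd = 0.5),
                            nrow(params$head$W))
    params$post1$b <- stats::runif(8, 0.05, 0.2)
    params$post2$b <- stats::runif(8, 0.05, 0.2)
    set.seed(106)
    lssi <- matrix(stats::runif(L * 2, -9, -1), L, 2)
    motifs <- matrix(stats::rbinom(L * 3, 1, 0.2) * stats::runif(L * 3),
                     L, 3)
    labels <- sample(1:3, L, replace = TRUE)
    lossfn <- function(p) {
      fw <- aggregator_fwd(p, cfg, lssi, motifs)
      samsplice:::softmax_xent(fw$logits, labels,
                               include = !fw$null_mask)$loss
    }
    fw <- aggregator_fwd(params, cfg, lssi, motifs, keep_cache = TRUE)
    ce <- samsplice:::softmax_xent(fw$logits, labels,
                                   include = !fw$null_mask)
    bk <- aggregator_bwd(params, cfg, fw$cache, ce$dlogits)
    ng <- samsplice:::numeric_grad(lossfn, params, eps = 1e-6)
    expect_lt(max(abs(unlist(bk$grads) - unlist(ng))), 1e-4)
    # gradient w.r.t. the motif track (the AM training path)
    lm <- function(mm) {
      fw2 <- aggregator_fwd(params, cfg, lssi, mm$m)
      samsplice:::softmax_xent(fw2$logits, labels,
                               include = !fw2$null_mask)$loss
    }
    ngm <- samsplice:::numeric_grad(lm, list(m = motifs), eps = 1e-6)$m
    expect_lt(max(abs(bk$dmotifs - ngm)), 1e-4)
  }
})

test_that("psi is the mean of the two site probabilities", {
  probs <- matrix(c(1, 0, 0), 10, 3, byrow = TRUE)
  probs[3, ] <- c(0, 1, 0)
  probs[7, ] <- c(0, 0, 1)
  expect_equal(predict_psi(probs, 2, 6), 1)
  expect_equal(predict_psi(probs, 4, 5), 0)
  probs[4, ] <- c(0.4, 0.6, 0)
  probs[8, ] <- c(0.2, 0, 0.8)
  expect_equal(predict_psi(probs, 3, 7), 0.7)
  expect_error(predict_psi(probs, -1, 7), "range")
  expect_error(predict_psi(probs, 3, 10), "range")
})
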