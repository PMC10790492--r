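test_that("oplus gates additions to the support of its first argument", {
  expect_equal(oplus(0.5, -0.2), 0.3)
  expect_equal(oplus(0, 7), 0)
  # elementwise oracle over random arrays
  set.seed(81)
  u <- matrix(stats::rbinom(60, 1, 0.4) * stats::runif(60), 10, 6)
  v <- matrix(stats::rnorm(60), 10, 6)
  oracle <- matrix(0, 10, 6)
  for (i in 1:10) for (j in 1:6) {
    oracle[i, j] <- if (u[i, j] != 0) u[i, j] + v[i, j] else 0
  }
  expect_equal(oplus(u, v), oracle)
  expect_error(oplus(matrix(1, 2, 2), matrix(1, 3, 2)), "shape")
})

test_that("binarize is an idempotent support indicator", {
  expect_equal(binarize(c(0, 0.5, 2.0)), c(0, 1, 1))
  set.seed(82)
  x <- matrix(stats::rnorm(50) * stats::rbinom(50, 1, 0.5), 10, 5)
  b <- binarize(x)
  expect_equal(binarize(b), b)
  expect_equal(b != 0, x != 0)
  expect_true(all(b %in% c(0, 1)))
})

test_that("AM forward output support is contained in the top-k*delta FM sites", {
  set.seed(83)
  L <- 400L; M <- 3L
  fm <- matrix(stats::rexp(L * M), L, M)
  adj <- matrix(stats::rnorm(L * M, sd = 0.5), L, M)
  cfg <- am_config(k = 2, delta = 0.02)
  st_k <- sparse_recalibrate(fm, sparsity_state(M, delta = 0.04))
  # final state calibrated on the gated pre-track, as in training
  pre <- oplus(sparse_forward(fm, st_k)$track, adj)
  pre[pre < 0] <- 0
  st_f <- sparse_recalibrate(pre, sparsity_state(M, delta = 0.02))
  res <- am_forward(fm, adj, cfg, st_k, st_f)
  fk <- sparse_forward(fm, st_k)$track
  # set-containment oracle: every nonzero output position is among the
  # top-k*delta FM positions of its channel
  for (m in 1:M) {
    out_sites <- which(res$track[, m] != 0)
    top_sites <- which(fk[, m] != 0)
    expect_true(all(out_sites %in% top_sites))
    expect_lte(length(out_sites), length(top_sites))
  }
  # adj == 0 reduces to a resparsified FM pass-through
  st_f0 <- sparse_recalibrate(sparse_forward(fm, st_k)$track,
                              sparsity_state(M, delta = 0.02))
  res0 <- am_forward(fm, NULL, cfg, st_k, st_f0)
  surv <- res0$track != 0
  expect_true(all(res0$track[surv] == fm[surv]))
  # fm == 0 gates everything to zero
  res_z <- am_forward(fm * 0, adj, cfg, sparsity_state(M, 0.04),
                      sparsity_state(M, 0.02))
  expect_true(all(res_z$track == 0))
  expect_error(am_config(k = 3, delta = 0.5), "exceeds 1")
})

test_that("adjustment network has the stated 21-nt receptive field", {
  set.seed(84)
  ap <- adjnet_init(2L, trunk_width = 4L)
  expect_equal(attr(ap, "receptive_field"), 21L)
  # zero-init head: the initial adjustment is exactly zero
  X <- one_hot(samsplice:::seq_to_int(random_seq(60, seed = 85)))
  expect_true(all(adjnet_fwd(ap, X)$out == 0))
  # after perturbing the head, locality holds: a mutation > 10 nt away
  # never changes the output at a position
  ap$head$W[[1]] <- matrix(stats::rnorm(length(ap$head$W[[1]])),
                           nrow(ap$head$W[[1]]))
  base <- adjnet_fwd(ap, X)$out
  X2 <- X; X2[40, ] <- c(0, 0, 1, 0)         # 11 positions from row 29
  mut <- adjnet_fwd(ap, X2)$out
  expect_equal(mut[29, ], base[29, ])
  expect_equal(mut[1:29, ], base[1:29, ])
  # and a mutation inside the field does propagate
  X3 <- X; X3[35, ] <- 1 - X3[35, ]
  expect_false(isTRUE(all.equal(adjnet_fwd(ap, X3)$out[29, ], base[29, ])))
})

test_that("RBNS neural motifs separate enriched pools but not identical ones", {
  pools <- gen_rbns("TGCATG", n_reads = 240L, read_len = 30L,
                    enrichment = 400, seed = 91)
  ps <- gen_psams(synth_motif_table()[2, ], seed = 1)[[1]]
  fit <- train_neural_motif_rbns(pools$bound, pools$input, arch = "am21",
                                 psams = ps, epochs = 2L, seed = 1)
  expect_gt(fit$accuracy, 0.5)
  # shuffled-label control: same reads, labels scrambled
  set.seed(92)
  mixed <- sample(c(pools$bound, pools$input))
  half <- length(mixed) / 2
  ctrl <- train_neural_motif_rbns(mixed[1:half], mixed[-(1:half)],
                                  arch = "am21", psams = ps, epochs = 2L,
                                  seed = 1)
  expect_gt(fit$accuracy, ctrl$accuracy)
  # identical pools: no signal, accuracy near chance
  same <- gen_rbns("TGCATG", n_reads = 200L, read_len = 30L,
                   enrichment = 1, seed = 93)
  expect_equal(same$plant_prob, 0)
  null_fit <- train_neural_motif_rbns(same$bound, same$input, arch = "conv11",
                                      epochs = 1L, seed = 1)
  expect_lt(abs(null_fit$accuracy - 0.5), 0.2)
  expect_error(train_neural_motif_rbns(character(0), pools$input), "empty")
})

test_that("am21 with a zeroed neural part reproduces the PSAM-only ordering", {
  pools <- gen_rbns("TGCATG", n_reads = 60L, read_len = 25L,
                    enrichment = 300, seed = 94)
  ps <- gen_psams(synth_motif_table()[2, ], seed = 1)[[1]]
  # untrained (zero-head) am21 scores = pooled PSAM scores + constant bias
  params <- samsplice:::rbns_arch_init("am21", 4L)
  reads <- c(pools$bound, pools$input)
  model_scores <- vapply(reads, function(r) {
    s <- samsplice:::seq_to_int(r)
    tr <- drop(samsplice:::adjnet_fwd(params, one_hot(s))$out) +
      log(score_rbp(ps, s) + 1e-6)
    samsplice:::lse_pool(tr)
  }, numeric(1))
  baseline <- vapply(reads, function(r)
    samsplice:::lse_pool(log(score_rbp(ps, samsplice:::seq_to_int(r)) + 1e-6)),
    numeric(1))
  expect_equal(order(model_scores), order(baseline))
})

test_that("the AM/FM site discriminator recovers planted linear preferences", {
  # classes differing deterministically at one position separate perfectly
  set.seed(95)
  base <- replicate(120, paste(sample(c("A", "C", "G", "T"), 7,
                                      replace = TRUE), collapse = ""))
  am_sites <- base
  substr(am_sites, 4, 4) <- "G"
  fm_sites <- base
  substr(fm_sites, 4, 4) <- "T"
  fit <- am_fm_discriminator(am_sites, fm_sites, seed = 1)
  expect_gt(fit$accuracy, 0.95)
  # recovered coefficients prefer G over T at the planted position
  expect_gt(fit$coefficients[4, "G"], fit$coefficients[4, "T"])
  # identical class distributions: chance-level accuracy
  null_fit <- am_fm_discriminator(base[1:60], base[61:120], seed = 1)
  expect_lt(abs(null_fit$accuracy - 0.5), 0.25)
  expect_error(am_fm_discriminator(c("ACGT"), c("ACGTA")), "length")
  expect_error(am_fm_discriminator(character(0), "ACGT"), "non-empty")
})
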