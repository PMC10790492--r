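test_that("eval-mode sparse layer keeps exactly the top-delta values", {
  set.seed(51)
  x <- matrix(stats::runif(1000), ncol = 1)   # distinct values
  st <- sparsity_state(1L, delta = 0.01)
  st <- sparse_recalibrate(x, st)
  out <- sparse_forward(x, st)$track
  # sort-based oracle: the 10 largest values survive, untouched
  expect_equal(sum(out != 0), 10L)
  expect_setequal(out[out != 0], sort(x, decreasing = TRUE)[1:10])
  # mask semantics: survivors pass through unchanged
  expect_true(all(out[out != 0] == x[out != 0]))
  # idempotent in eval mode
  expect_equal(sparse_forward(out, st)$track, out)
})

test_that("all-zero channels stay zero and NaN input errors", {
  st <- sparsity_state(2L, delta = 0.1)
  x <- cbind(rep(0, 50), stats::runif(50))
  res <- sparse_forward(x, st, training = TRUE)
  expect_true(all(res$track[, 1] == 0))
  expect_equal(res$state$thresholds[1], 0)
  xn <- x; xn[3, 1] <- NaN
  expect_error(sparse_forward(xn, st), "finite")
})

test_that("training mode moves thresholds toward the batch quantile by EMA", {
  set.seed(52)
  x <- matrix(stats::runif(2000), ncol = 2)
  st <- sparsity_state(2L, delta = 0.05, momentum = 0.9)
  q <- apply(x, 2, function(col)
    samsplice:::top_delta_threshold(col, 0.05))
  res <- sparse_forward(x, st, training = TRUE)
  expect_equal(res$state$thresholds, 0.9 * 0 + 0.1 * q)
  # repeated exposure converges to the quantile
  for (i in 1:200) res <- sparse_forward(x, res$state, training = TRUE)
  expect_equal(res$state$thresholds, q, tolerance = 1e-6)
  # realized density after convergence is within tolerance of delta
  dens <- colMeans(sparse_forward(x, res$state)$track != 0)
  expect_true(all(dens <= 1.2 * 0.05))
})

test_that("annealing multiplies delta by the factor only when V meets VT", {
  sched <- anneal_schedule(vt = 0.85)
  st <- sparsity_state(1L, delta = 0.75)
  up <- anneal_step(sched, st, validation_accuracy = 0.90)
  expect_equal(up$state$delta, 0.5625)      # 0.75 * 0.75
  expect_true(up$reduced)
  same <- anneal_step(sched, st, validation_accuracy = 0.80)
  expect_equal(same$state$delta, 0.75)
  expect_false(same$reduced)
  # geometric decay: 21 successful reductions reach the 0.18% floor
  st2 <- sparsity_state(1L, delta = 0.75)
  deltas <- numeric(21)
  for (i in 1:21) {
    st2 <- anneal_step(sched, st2, 0.99)$state
    deltas[i] <- st2$delta
  }
  expect_true(all(diff(deltas) <= 0))        # monotone non-increasing
  expect_equal(st2$delta, 0.0018)            # 0.75^22 ~ 0.00178, floored
})

test_that("quick-training VT decays per epoch and bumps on reductions", {
  expect_equal(quick_vt(0), 0.85)
  expect_equal(quick_vt(3), 0.82)
  # a reduction at V = 0.88 lifts VT to 0.88, then it decays again
  expect_equal(quick_vt(5, last_reduction_accuracy = 0.88,
                        last_reduction_epoch = 5), 0.88)
  expect_equal(quick_vt(7, last_reduction_accuracy = 0.88,
                        last_reduction_epoch = 5), 0.86)
  # simulate the schedule over a scripted V(t) trace
  vt_trace <- numeric(10)
  last_acc <- NULL; last_ep <- 0
  v_trace <- c(0.80, 0.84, 0.86, 0.82, 0.83, 0.85, 0.88, 0.84, 0.86, 0.90)
  for (ep in 1:10) {
    vt_trace[ep] <- quick_vt(ep - 1, last_acc, last_ep)
    if (v_trace[ep] >= vt_trace[ep]) {
      last_acc <- v_trace[ep]; last_ep <- ep - 1
    }
  }
  expect_equal(vt_trace[3], 0.83)            # decayed from 0.85
  expect_equal(vt_trace[4], 0.85)            # bumped to 0.86, one epoch decay
  expect_true(all(vt_trace <= 0.92))
})

test_that("entropy bound matches the closed form and its edge cases", {
  h2 <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  expect_equal(entropy_bound(79, 0.0018, 2.8),
               79 * (h2(0.0018) + 0.0018 * 2.8))
  expect_equal(entropy_bound(10, 0, 5), 0)
  expect_equal(entropy_bound(1, 1, 0), 0)    # H2(1) = 0 by continuity
  expect_error(entropy_bound(1, 1.5, 0), "delta")
  # closed-form eta inversion is consistent with the bound
  eta <- solve_eta(1.91, 79, 0.0018)
  expect_equal(entropy_bound(79, 0.0018, eta), 1.91)
})

test_that("empirical channel entropy recovers analytic values", {
  # point mass: all equal nonzeros carry no activation entropy
  x <- matrix(0, 100, 1); x[1:20, 1] <- 3.3
  res <- empirical_channel_entropy(x)
  expect_equal(res$eta_hat, 0)
  expect_equal(res$density, 0.2)
  # uniform over 4 equal bins: exactly 2 bits
  v <- rep(c(0.5, 1.5, 2.5, 3.5), each = 25)
  res4 <- empirical_channel_entropy(matrix(v, ncol = 1), bins = 4L)
  expect_equal(res4$eta_hat, 2)
  # known discrete distribution matches closed-form entropy
  p <- c(0.5, 0.25, 0.125, 0.125)
  v2 <- rep(c(1, 2, 3, 4), round(800 * p))
  res_d <- empirical_channel_entropy(matrix(v2, ncol = 1), bins = 4L)
  expect_equal(res_d$eta_hat, -sum(p * log2(p)), tolerance = 1e-6)
  # degenerate channel: < 2 nonzeros flagged with zero entropy
  xd <- matrix(0, 50, 1); xd[7] <- 1
  resd <- empirical_channel_entropy(xd)
  expect_true(resd$degenerate)
  expect_equal(resd$eta_hat, 0)
})

test_that("bound soundness: empirical entropy never exceeds the bound", {
  # for synthetic sparse tracks the per-base empirical entropy estimate
  # M * delta_hat * eta_hat (+ support entropy) stays below the bound at
  # the measured (delta, eta)
  set.seed(53)
  for (rep in 1:5) {
    L <- 2000L; M <- 4L
    track <- matrix(0, L, M)
    for (m in 1:M) {
      k <- sample(5:40, 1)
      track[sample.int(L, k), m] <- stats::rexp(k) + 0.1
    }
    emp <- empirical_channel_entropy(track, bins = 8L)
    delta_bar <- mean(emp$density)
    eta_max <- max(emp$eta_hat)
    bound <- entropy_bound(M, delta_bar, eta_max)
    h2 <- function(p) if (p <= 0 || p >= 1) 0 else
      -p * log2(p) - (1 - p) * log2(1 - p)
    per_channel <- vapply(seq_len(M), function(m)
      h2(emp$density[m]) + emp$density[m] * emp$eta_hat[m], numeric(1))
    expect_lte(sum(per_channel), bound + 1e-9)
  }
})
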