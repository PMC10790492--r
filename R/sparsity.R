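# Sparsity bottleneck over the motif layer.
#
# A per-channel threshold zeroes all but the highest-affinity sites
# (hard-mask semantics: surviving values pass through unchanged, preserving
# affinity units).  During training the thresholds chase the (1 - delta)
# batch quantile via an exponential moving average; the maximum density
# delta itself is annealed from 0.75 downward by factors of 0.75 whenever
# validation accuracy reaches its target.  The analytic entropy bound
# M[H(B(delta)) + delta*eta] caps the information (bits per base) the layer
# can transmit.

#' Create a sparsity-layer state
#'
#' @param n_channels number of motif channels M.
#' @param delta maximum density (fraction of positions allowed nonzero per
#'   channel).
#' @param momentum EMA coefficient for threshold updates during training.
#' @return object of class `sparsity_state` with per-channel `thresholds`.
#' @export
sparsity_state <- function(n_channels, delta = 0.0018, momentum = 0.9) {
  stopifnot(delta > 0, delta <= 1, momentum >= 0, momentum < 1)
  structure(list(thresholds = rep(0, n_channels), momentum = momentum,
                 delta = delta), class = "sparsity_state")
}

# Threshold such that strictly greater values are exactly the top
# floor(delta * n) of x (ties broken against survival).
top_delta_threshold <- function(x, delta) {
  n <- length(x)
  k <- floor(delta * n)
  if (k >= n) return(-Inf)
  if (k <= 0) return(max(x))
  -sort(-x, partial = k + 1L)[k + 1L]     # (k+1)-th largest value
}

#' Sparse layer forward pass
#'
#' Values at or below the channel threshold are zeroed; surviving values
#' pass unchanged.  In training mode the thresholds move by EMA toward the
#' current track's `(1 - delta)` quantile (computed over all values of the
#' channel); in eval mode thresholds are frozen.
#'
#' @param track L x M nonnegative affinity matrix.
#' @param state a [sparsity_state()].
#' @param training logical; update thresholds?
#' @return list with `track` (sparsified L x M matrix) and `state` (updated
#'   when `training`).
#' @export
sparse_forward <- function(track, state, training = FALSE) {
  if (anyNA(track) || any(!is.finite(track))) {
    stop("non-finite values in affinity track")
  }
  M <- ncol(track)
  stopifnot(length(state$thresholds) == M)
  if (training) {
    batch_thr <- vapply(seq_len(M), function(m)
      top_delta_threshold(track[, m], state$delta), numeric(1))
    batch_thr[!is.finite(batch_thr)] <- 0
    state$thresholds <- state$momentum * state$thresholds +
      (1 - state$momentum) * batch_thr
  }
  out <- track
  for (m in seq_len(M)) {
    out[track[, m] <= state$thresholds[m], m] <- 0
  }
  list(track = out, state = state)
}

#' Deterministically recalibrate thresholds to the exact top-delta cut
#'
#' The eval-time alternative to EMA thresholds: sets each channel's
#' threshold so that exactly `floor(delta * L)` values survive on the given
#' track(s).
#'
#' @param tracks an L x M matrix or list of such matrices (rows pooled).
#' @param state a [sparsity_state()]; its `delta` is used.
#' @return the state with recalibrated `thresholds`.
#' @export
sparse_recalibrate <- function(tracks, state) {
  if (is.matrix(tracks)) tracks <- list(tracks)
  pooled <- do.call(rbind, tracks)
  state$thresholds <- vapply(seq_len(ncol(pooled)), function(m)
    top_delta_threshold(pooled[, m], state$delta), numeric(1))
  state$thresholds[!is.finite(state$thresholds)] <- 0
  state
}

## ---- density annealing ----------------------------------------------------

#' Annealing schedule for the maximum density delta
#'
#' @param start_delta initial maximum density (default 0.75).
#' @param factor multiplicative reduction applied at each successful check
#'   (default 0.75).
#' @param target_delta floor for delta (default 0.0018, i.e. 0.18%).
#' @param checks_per_epoch how many times per epoch validation accuracy is
#'   checked against its target (default 20).
#' @param vt the accuracy target: either a constant (standard training,
#'   tuned externally) or a function of the check step (quick training; see
#'   [quick_vt()]).
#' @export
anneal_schedule <- function(start_delta = 0.75, factor = 0.75,
                            target_delta = 0.0018, checks_per_epoch = 20L,
                            vt = 0.85) {
  stopifnot(factor > 0, factor < 1, target_delta < start_delta)
  structure(list(start_delta = start_delta, factor = factor,
                 target_delta = target_delta,
                 checks_per_epoch = checks_per_epoch, vt = vt),
            class = "anneal_schedule")
}

#' One annealing check: reduce delta if validation accuracy met its target
#'
#' If `validation_accuracy >= VT(step)`, delta becomes
#' `factor * delta` (floored at `target_delta`); otherwise it is unchanged.
#'
#' @param schedule an [anneal_schedule()].
#' @param state a [sparsity_state()].
#' @param validation_accuracy current validation accuracy V(t) in `[0, 1]`.
#' @param step check index (passed to `vt` when it is a function).
#' @return list with updated `state` and logical `reduced`.
#' @export
anneal_step <- function(schedule, state, validation_accuracy, step = 0L) {
  vt <- if (is.function(schedule$vt)) schedule$vt(step) else schedule$vt
  reduced <- FALSE
  if (validation_accuracy >= vt && state$delta > schedule$target_delta) {
    state$delta <- max(schedule$target_delta,
                       schedule$factor * state$delta)
    reduced <- TRUE
  }
  list(state = state, reduced = reduced)
}

#' Quick-training accuracy target VT(t)
#'
#' Starts at `base` (85%), decays by `decay_per_epoch` (1%) per epoch, and
#' jumps to whatever validation accuracy was achieved at the most recent
#' delta reduction, decaying again from there.
#'
#' @param epoch current epoch (fractional epochs allowed).
#' @param last_reduction_accuracy validation accuracy at the last delta
#'   reduction, or `NULL` if none has happened yet.
#' @param last_reduction_epoch epoch of that reduction.
#' @param base,decay_per_epoch schedule constants.
#' @return the target accuracy VT.
#' @export
quick_vt <- function(epoch, last_reduction_accuracy = NULL,
                     last_reduction_epoch = 0, base = 0.85,
                     decay_per_epoch = 0.01) {
  from_base <- base - decay_per_epoch * epoch
  if (is.null(last_reduction_accuracy)) return(from_base)
  bumped <- last_reduction_accuracy -
    decay_per_epoch * (epoch - last_reduction_epoch)
  max(from_base, bumped)
}

## ---- entropy bound --------------------------------------------------------

# Binary entropy in bits, continuous at 0 and 1.
binary_entropy <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p == 0 || p == 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' Entropy bound of the motif layer, in bits per base
#'
#' `H/L <= M * [H(B(delta)) + delta * eta]` where `H(B(x))` is the binary
#' entropy (bits) of a Bernoulli with probability `x`, `delta` the mean
#' channel density and `eta` an upper bound (across channels) on the
#' entropy of the distribution of nonzero activations.
#'
#' @param M number of motif channels.
#' @param delta mean density in `[0, 1]`.
#' @param eta bits per nonzero activation (upper bound).
#' @return the bound in bits per base.
#' @export
entropy_bound <- function(M, delta, eta) {
  stopifnot(M >= 1, eta >= 0)
  if (delta < 0 || delta > 1) stop("delta must lie in [0, 1]")
  M * (binary_entropy(delta) + delta * eta)
}

#' Largest per-activation entropy eta compatible with a bound
#'
#' Solves `M * [H(B(delta)) + delta * eta] = bound` for `eta` in closed
#' form.
#'
#' @param bound the required bits-per-base cap (e.g. 1.91).
#' @inheritParams entropy_bound
#' @return eta in bits.
#' @export
solve_eta <- function(bound, M, delta) {
  stopifnot(delta > 0, delta < 1)
  (bound / M - binary_entropy(delta)) / delta
}

#' Empirical per-channel density and activation entropy
#'
#' For each channel of an already-sparsified track: the nonzero fraction
#' (density) and a histogram estimate (bits) of the entropy of the nonzero
#' values, using `bins` equal-width bins over the channel's nonzero range.
#' Channels with fewer than 2 nonzero values get `eta_hat = 0` and are
#' flagged.
#'
#' @param track sparsified L x M matrix.
#' @param bins number of histogram bins.
#' @return data frame with columns `channel`, `density`, `eta_hat`,
#'   `degenerate`.
#' @export
empirical_channel_entropy <- function(track, bins = 16L) {
  res <- lapply(seq_len(ncol(track)), function(m) {
    x <- track[, m]
    nz <- x[x != 0]
    density <- length(nz) / length(x)
    if (length(nz) < 2 || diff(range(nz)) == 0) {
      return(data.frame(channel = m, density = density, eta_hat = 0,
                        degenerate = TRUE))
    }
    breaks <- seq(min(nz), max(nz), length.out = bins + 1L)
    counts <- tabulate(findInterval(nz, breaks, rightmost.closed = TRUE,
                                    all.inside = TRUE), nbins = bins)
    p <- counts / sum(counts)
    p <- p[p > 0]
    data.frame(channel = m, density = density,
               eta_hat = -sum(p * log2(p)), degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(colnames(track))) out$channel <- colnames(track)
  out
}
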