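# Minimal neural-network core: layers with hand-written gradients.
#
# Everything operates on plain R matrices (positions in rows) so that the
# heavy lifting is BLAS matrix multiplication.  Parameters live in nested
# named lists of numeric arrays; gradients mirror that structure exactly,
# which lets a single recursive Adam walker update any model here.

#' Shift the rows of a matrix, zero-padding at the edges
#'
#' Row `l` of the result is row `l + d` of `x` (or zeros where that falls
#' outside the matrix). Used to express convolutions and windowed attention
#' as sums over offsets of BLAS-sized operations.
#'
#' @param x numeric matrix.
#' @param d integer shift (positive pulls rows from further down).
#' @return matrix of the same shape as `x`.
#' @keywords internal
shift_rows <- function(x, d) {
  L <- nrow(x)
  if (d == 0L) return(x)
  out <- matrix(0, L, ncol(x))
  if (abs(d) >= L) return(out)
  if (d > 0L) {
    out[1:(L - d), ] <- x[(1 + d):L, , drop = FALSE]
  } else {
    out[(1 - d):L, ] <- x[1:(L + d), , drop = FALSE]
  }
  out
}

## ---- initialisation -------------------------------------------------------

nn_init_dense <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

# W is a list of `width` (Cin x Cout) matrices, one per tap.
nn_init_conv <- function(width, c_in, c_out) {
  list(W = lapply(seq_len(width), function(j)
         matrix(stats::rnorm(c_in * c_out, sd = sqrt(2 / (width * c_in))),
                c_in, c_out)),
       b = rep(0, c_out))
}

nn_init_attention <- function(c_in, heads, d_head, c_out = c_in) {
  hd <- heads * d_head
  sc <- sqrt(1 / c_in)
  list(Wq = matrix(stats::rnorm(c_in * hd, sd = sc), c_in, hd),
       Wk = matrix(stats::rnorm(c_in * hd, sd = sc), c_in, hd),
       Wv = matrix(stats::rnorm(c_in * hd, sd = sc), c_in, hd),
       Wo = matrix(stats::rnorm(hd * c_out, sd = sqrt(1 / hd)), hd, c_out),
       bo = rep(0, c_out))
}

nn_init_lstm <- function(c_in, hidden) {
  sc <- sqrt(1 / hidden)
  list(Wx = matrix(stats::rnorm(c_in * 4 * hidden, sd = sqrt(1 / c_in)),
                   c_in, 4 * hidden),
       Wh = matrix(stats::rnorm(hidden * 4 * hidden, sd = sc),
                   hidden, 4 * hidden),
       b = rep(0, 4 * hidden))
}

## ---- dense / relu ---------------------------------------------------------

dense_fwd <- function(x, p) {
  list(out = sweep(x %*% p$W, 2, p$b, `+`), cache = list(x = x))
}

dense_bwd <- function(p, cache, dout) {
  list(grads = list(W = crossprod(cache$x, dout), b = colSums(dout)),
       dx = dout %*% t(p$W))
}

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dout) dout * cache

## ---- 1-D convolution (same padding, odd width) ----------------------------

conv1d_fwd <- function(x, p) {
  w <- length(p$W)
  ctr <- (w + 1L) %/% 2L
  out <- matrix(rep(p$b, each = nrow(x)), nrow(x), length(p$b))
  for (j in seq_len(w)) {
    out <- out + shift_rows(x, j - ctr) %*% p$W[[j]]
  }
  list(out = out, cache = list(x = x))
}

conv1d_bwd <- function(p, cache, dout) {
  w <- length(p$W)
  ctr <- (w + 1L) %/% 2L
  x <- cache$x
  dW <- vector("list", w)
  dx <- matrix(0, nrow(x), ncol(x))
  for (j in seq_len(w)) {
    xs <- shift_rows(x, j - ctr)
    dW[[j]] <- crossprod(xs, dout)
    dx <- dx + shift_rows(dout %*% t(p$W[[j]]), ctr - j)
  }
  list(grads = list(W = dW, b = colSums(dout)), dx = dx)
}

## ---- windowed multi-head self-attention -----------------------------------

# Each position attends to positions within +/- half-window only.  For
# gene-scale inputs (L up to a few thousand) the banded scores are
# materialised as a masked dense L x L matrix so every step is a BLAS
# matrix product; attention weights outside the band are exactly zero, so
# the windowed semantics are preserved.

attn_band_mask <- function(L, half_window) {
  idx <- seq_len(L)
  abs(outer(idx, idx, `-`)) > half_window
}

attn_fwd <- function(x, p, half_window, heads) {
  L <- nrow(x)
  hd <- ncol(p$Wq)
  d_head <- hd %/% heads
  Q <- x %*% p$Wq
  K <- x %*% p$Wk
  V <- x %*% p$Wv
  outside <- attn_band_mask(L, half_window)
  A_list <- vector("list", heads)
  O <- matrix(0, L, hd)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * d_head + 1L):(h * d_head)
    Qh <- Q[, idx, drop = FALSE]
    Kh <- K[, idx, drop = FALSE]
    Vh <- V[, idx, drop = FALSE]
    S <- tcrossprod(Qh, Kh) / sqrt(d_head)
    S[outside] <- -Inf
    S <- S - apply(S, 1, max)
    A <- exp(S)
    A <- A / rowSums(A)
    A_list[[h]] <- A
    O[, idx] <- A %*% Vh
  }
  out <- sweep(O %*% p$Wo, 2, p$bo, `+`)
  list(out = out,
       cache = list(x = x, Q = Q, K = K, V = V, A = A_list, O = O,
                    half_window = half_window, heads = heads,
                    d_head = d_head))
}

attn_bwd <- function(p, cache, dout) {
  x <- cache$x
  L <- nrow(x)
  d_head <- cache$d_head
  dO <- dout %*% t(p$Wo)
  dQ <- matrix(0, L, ncol(cache$Q))
  dK <- dQ
  dV <- dQ
  for (h in seq_len(cache$heads)) {
    idx <- ((h - 1L) * d_head + 1L):(h * d_head)
    Qh <- cache$Q[, idx, drop = FALSE]
    Kh <- cache$K[, idx, drop = FALSE]
    Vh <- cache$V[, idx, drop = FALSE]
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, idx] <- crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))   # zero outside the band (A = 0)
    dQ[, idx] <- dS %*% Kh / sqrt(d_head)
    dK[, idx] <- crossprod(dS, Qh) / sqrt(d_head)
  }
  dx <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  grads <- list(Wq = crossprod(x, dQ), Wk = crossprod(x, dK),
                Wv = crossprod(x, dV), Wo = crossprod(cache$O, dout),
                bo = colSums(dout))
  list(grads = grads, dx = dx)
}

## ---- LSTM -----------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# Gate layout within the 4H columns: input, forget, cell (tanh), output.
lstm_fwd <- function(x, p, reverse = FALSE) {
  L <- nrow(x)
  H <- nrow(p$Wh)
  ord <- if (reverse) rev(seq_len(L)) else seq_len(L)
  Zx <- sweep(x %*% p$Wx, 2, p$b, `+`)
  Gi <- Gf <- Gg <- Go <- Cs <- Hs <- Tc <- matrix(0, L, H)
  h_prev <- rep(0, H)
  c_prev <- rep(0, H)
  i_idx <- 1:H; f_idx <- (H + 1):(2 * H)
  g_idx <- (2 * H + 1):(3 * H); o_idx <- (3 * H + 1):(4 * H)
  for (t in ord) {
    z <- Zx[t, ] + drop(h_prev %*% p$Wh)
    gi <- sigmoid(z[i_idx]); gf <- sigmoid(z[f_idx])
    gg <- tanh(z[g_idx]);    go <- sigmoid(z[o_idx])
    c_t <- gf * c_prev + gi * gg
    tc <- tanh(c_t)
    h_t <- go * tc
    Gi[t, ] <- gi; Gf[t, ] <- gf; Gg[t, ] <- gg; Go[t, ] <- go
    Cs[t, ] <- c_t; Tc[t, ] <- tc; Hs[t, ] <- h_t
    h_prev <- h_t; c_prev <- c_t
  }
  list(out = Hs,
       cache = list(x = x, Gi = Gi, Gf = Gf, Gg = Gg, Go = Go, Cs = Cs,
                    Tc = Tc, Hs = Hs, ord = ord, H = H))
}

lstm_bwd <- function(p, cache, dout) {
  x <- cache$x
  L <- nrow(x)
  H <- cache$H
  ord <- cache$ord
  dZ <- matrix(0, L, 4 * H)
  dWh <- matrix(0, H, 4 * H)
  dh_next <- rep(0, H)
  dc_next <- rep(0, H)
  i_idx <- 1:H; f_idx <- (H + 1):(2 * H)
  g_idx <- (2 * H + 1):(3 * H); o_idx <- (3 * H + 1):(4 * H)
  rord <- rev(ord)
  for (k in seq_along(rord)) {
    t <- rord[k]
    prev_t <- if (k < L) rord[k + 1L] else 0L
    gi <- cache$Gi[t, ]; gf <- cache$Gf[t, ]; gg <- cache$Gg[t, ]
    go <- cache$Go[t, ]; tc <- cache$Tc[t, ]
    c_prev <- if (prev_t > 0L) cache$Cs[prev_t, ] else rep(0, H)
    h_prev <- if (prev_t > 0L) cache$Hs[prev_t, ] else rep(0, H)
    dh <- dout[t, ] + dh_next
    dc <- dc_next + dh * go * (1 - tc^2)
    dgo <- dh * tc * go * (1 - go)
    dgi <- dc * gg * gi * (1 - gi)
    dgf <- dc * c_prev * gf * (1 - gf)
    dgg <- dc * gi * (1 - gg^2)
    dz <- c(dgi, dgf, dgg, dgo)
    dZ[t, ] <- dz
    dWh <- dWh + outer(h_prev, dz)
    dh_next <- drop(p$Wh %*% dz)
    dc_next <- dc * gf
  }
  list(grads = list(Wx = crossprod(x, dZ), Wh = dWh, b = colSums(dZ)),
       dx = dZ %*% t(p$Wx))
}

bilstm_fwd <- function(x, p) {
  fw <- lstm_fwd(x, p$fw, reverse = FALSE)
  bw <- lstm_fwd(x, p$bw, reverse = TRUE)
  list(out = cbind(fw$out, bw$out), cache = list(fw = fw$cache, bw = bw$cache))
}

bilstm_bwd <- function(p, cache, dout) {
  H <- cache$fw$H
  g_fw <- lstm_bwd(p$fw, cache$fw, dout[, 1:H, drop = FALSE])
  g_bw <- lstm_bwd(p$bw, cache$bw, dout[, (H + 1):(2 * H), drop = FALSE])
  list(grads = list(fw = g_fw$grads, bw = g_bw$grads),
       dx = g_fw$dx + g_bw$dx)
}

## ---- softmax / losses -----------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy over rows where include is TRUE; labels are 1-based
# class indices. Returns the loss and d(loss)/d(logits).
softmax_xent <- function(logits, labels, include = NULL, weights = NULL) {
  n <- nrow(logits)
  if (is.null(include)) include <- rep(TRUE, n)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights * include
  wsum <- sum(w)
  P <- softmax_rows(logits)
  picked <- P[cbind(seq_len(n), labels)]
  loss <- sum(w * -log(pmax(picked, 1e-12))) / wsum
  dlogits <- P
  dlogits[cbind(seq_len(n), labels)] <-
    dlogits[cbind(seq_len(n), labels)] - 1
  dlogits <- dlogits * (w / wsum)
  list(loss = loss, dlogits = dlogits)
}

## ---- Adam optimiser over nested parameter lists ---------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

#' One Adam update step
#'
#' @param params,grads nested lists of numeric arrays with identical shape.
#' @param opt optimiser state from [adam_init()].
#' @param lr learning rate.
#' @return list(params, opt) after the update.
#' @keywords internal
adam_step <- function(params, grads, opt, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      res <- Map(walk, p, g, m, v)
      list(p = lapply(res, `[[`, "p"),
           m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps) -
        lr * weight_decay * p          # decoupled (AdamW-style) decay
      list(p = p, m = m, v = v)
    }
  }
  res <- walk(params, grads, opt$m, opt$v)
  list(params = res$p, opt = list(m = res$m, v = res$v, t = opt$t))
}

# Elementwise sum of two gradient structures (for accumulation).
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) Map(grad_add, a, b) else a + b
}

# Global-norm gradient clipping over a nested gradient structure.
grad_clip <- function(grads, max_norm) {
  total <- sqrt(sum(unlist(grads)^2))
  if (!is.finite(total) || total <= max_norm) return(grads)
  scale <- max_norm / total
  rec <- function(g) if (is.list(g)) lapply(g, rec) else g * scale
  rec(grads)
}

## ---- numeric gradient check (used by the test-suite) ----------------------

#' Central-difference numeric gradient of a scalar function of nested params
#' @keywords internal
numeric_grad <- function(fn, params, eps = 1e-5) {
  rec <- function(prefix) {
    node <- params
    for (k in prefix) node <- node[[k]]
    if (is.list(node)) {
      out <- lapply(seq_along(node), function(i) rec(c(prefix, i)))
      names(out) <- names(node)
      return(out)
    }
    g <- node * 0
    for (i in seq_along(node)) {
      ph <- node; ph[i] <- ph[i] + eps
      pl <- node; pl[i] <- pl[i] - eps
      g[i] <- (fn(assign_nested(params, prefix, ph)) -
               fn(assign_nested(params, prefix, pl))) / (2 * eps)
    }
    g
  }
  rec(integer(0))
}

assign_nested <- function(lst, path, value) {
  if (length(path) == 0) return(value)
  lst[[path[1]]] <- assign_nested(lst[[path[1]]], path[-1], value)
  lst
}
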