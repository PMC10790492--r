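# Local Splice Site Identifier (LSSI): small feedforward networks scoring
# every position as a potential acceptor (3'SS) or donor (5'SS).
#
# Windows follow the MaxEnt conventions: the 3'SS window is 23 nt (last 20
# intron bases + first 3 exon bases) and the 5'SS window is 9 nt (last 3
# exon bases + first 6 intron bases), anchored on the labeled exonic base
# (acceptor = first exonic base, donor = last exonic base).  Scores are
# natural-log probabilities from a log-softmax head, clamped at a floor of
# -10; positions whose window runs off the sequence get the floor.  The
# model deliberately favours recall over precision: it acts downstream as a
# mask, so positions at the floor for both site types are never considered
# splice sites.

#' LSSI configuration
#' @param hidden_width,hidden_layers network size (100-wide, 5 hidden ReLU
#'   layers after the input mapping).
#' @param epochs,batch_size,learning_rate training hyperparameters.
#' @param floor score clamp in natural-log units.
#' @export
lssi_config <- function(hidden_width = 100L, hidden_layers = 5L,
                        epochs = 10L, batch_size = 150L,
                        learning_rate = 1e-3, floor = -10) {
  stopifnot(floor < 0, hidden_width > 0, hidden_layers > 0, epochs > 0,
            batch_size > 0, learning_rate > 0)
  structure(list(hidden_width = hidden_width, hidden_layers = hidden_layers,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, floor = floor),
            class = "lssi_config")
}

# 0-based window geometry per site type: offsets of the window start
# relative to the labeled site position, and window width.
lssi_geometry <- function(type = c("acceptor", "donor")) {
  type <- match.arg(type)
  if (type == "acceptor") list(offset = -20L, width = 23L)
  else list(offset = -2L, width = 9L)
}

#' Extract the 23-nt acceptor window around a candidate 3'SS
#'
#' @param gene a [gene_record()].
#' @param pos 0-based candidate acceptor position (first exonic base).
#' @return the 23-mer `sequence[pos - 20, pos + 3)`, or `NA` when the
#'   window does not fit (the position is then excluded from scoring).
#' @export
acceptor_window <- function(gene, pos) {
  L <- nchar(gene$sequence)
  if (pos < 20L || pos + 3L > L) return(NA_character_)
  substr(gene$sequence, pos - 20L + 1L, pos + 3L)
}

#' Extract the 9-nt donor window around a candidate 5'SS
#'
#' @param gene a [gene_record()].
#' @param pos 0-based candidate donor position (last exonic base).
#' @return the 9-mer `sequence[pos - 2, pos + 7)`, or `NA` when the window
#'   does not fit.
#' @export
donor_window <- function(gene, pos) {
  L <- nchar(gene$sequence)
  if (pos < 2L || pos + 7L > L) return(NA_character_)
  substr(gene$sequence, pos - 2L + 1L, pos + 7L)
}

# One-hot window matrix for all valid site positions of a type.
# Returns list(pos0 = 0-based positions, X = n x (4*width) matrix).
lssi_window_matrix <- function(seq_int, type) {
  geo <- lssi_geometry(type)
  L <- length(seq_int)
  first <- -geo$offset                    # smallest valid 0-based pos
  last <- L - (geo$width + geo$offset)    # largest valid 0-based pos
  if (last < first) return(list(pos0 = integer(0),
                                X = matrix(0, 0, 4L * geo$width)))
  pos0 <- first:last
  n <- length(pos0)
  X <- matrix(0, n, 4L * geo$width)
  for (j in seq_len(geo$width)) {
    b <- seq_int[pos0 + geo$offset + j]   # 1-based index into sequence
    cols <- (j - 1L) * 4L
    known <- b > 0L
    X[cbind(which(known), cols + b[known])] <- 1
    if (any(!known)) X[!known, cols + (1:4)] <- 0.25
  }
  list(pos0 = pos0, X = X)
}

lssi_mlp_init <- function(d_in, cfg) {
  layers <- list(nn_init_dense(d_in, cfg$hidden_width))
  for (i in seq_len(cfg$hidden_layers)) {
    layers[[i + 1L]] <- nn_init_dense(cfg$hidden_width, cfg$hidden_width)
  }
  layers[[cfg$hidden_layers + 2L]] <- nn_init_dense(cfg$hidden_width, 2L)
  layers
}

lssi_mlp_fwd <- function(params, X) {
  caches <- vector("list", length(params))
  h <- X
  for (i in seq_along(params)) {
    d <- dense_fwd(h, params[[i]])
    if (i < length(params)) {
      r <- relu_fwd(d$out)
      caches[[i]] <- list(dense = d$cache, relu = r$cache)
      h <- r$out
    } else {
      caches[[i]] <- list(dense = d$cache)
      h <- d$out
    }
  }
  list(logits = h, caches = caches)
}

lssi_mlp_bwd <- function(params, caches, dlogits) {
  grads <- vector("list", length(params))
  dh <- dlogits
  for (i in rev(seq_along(params))) {
    if (i < length(params)) dh <- relu_bwd(caches[[i]]$relu, dh)
    bk <- dense_bwd(params[[i]], caches[[i]]$dense, dh)
    grads[[i]] <- bk$grads
    dh <- bk$dx
  }
  grads
}

#' Train the acceptor and donor LSSI networks
#'
#' Positive examples are the labeled sites of each type; negatives are all
#' other positions whose window fits, class-weighted to balance (so the
#' recall-over-precision goal needs no negative-sampling hyperparameter).
#' The two networks are independent and trained separately from the main
#' model.
#'
#' @param genes list of [gene_record()].
#' @param labels list of label tracks from [make_label_track()], parallel
#'   to `genes`.
#' @param config an [lssi_config()].
#' @param seed RNG seed; the same seed reproduces identical weights.
#' @return object of class `lssi_model` with `acceptor`/`donor` parameter
#'   lists and the config.
#' @export
train_lssi <- function(genes, labels, config = lssi_config(), seed = 1L) {
  set.seed(seed)
  models <- list()
  for (type in c("acceptor", "donor")) {
    lab_code <- if (type == "acceptor") 1L else 2L
    Xs <- list(); ys <- list()
    for (i in seq_along(genes)) {
      s <- seq_to_int(genes[[i]]$sequence)
      wm <- lssi_window_matrix(s, type)
      Xs[[i]] <- wm$X
      ys[[i]] <- as.integer(labels[[i]][wm$pos0 + 1L] == lab_code)
    }
    X <- do.call(rbind, Xs)
    y <- unlist(ys)
    if (sum(y) == 0) stop("no positive ", type, " examples")
    w <- ifelse(y == 1L, sum(y == 0L) / sum(y == 1L), 1)
    params <- lssi_mlp_init(ncol(X), config)
    opt <- adam_init(params)
    n <- nrow(X)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      for (st in starts) {
        idx <- ord[st:min(st + config$batch_size - 1L, n)]
        fw <- lssi_mlp_fwd(params, X[idx, , drop = FALSE])
        ce <- softmax_xent(fw$logits, y[idx] + 1L, weights = w[idx])
        grads <- lssi_mlp_bwd(params, fw$caches, ce$dlogits)
        upd <- adam_step(params, grads, opt, lr = config$learning_rate)
        params <- upd$params
        opt <- upd$opt
      }
    }
    models[[type]] <- params
  }
  structure(list(acceptor = models$acceptor, donor = models$donor,
                 config = config), class = "lssi_model")
}

#' Score every position of a gene with the trained LSSI networks
#'
#' @param model an `lssi_model` from [train_lssi()].
#' @param gene a [gene_record()] (or a bare sequence string).
#' @return L x 2 matrix (columns `acceptor`, `donor`) of natural-log
#'   probabilities clamped at the floor; unavailable windows get the floor.
#' @export
lssi_score <- function(model, gene) {
  sequence <- if (inherits(gene, "gene_record")) gene$sequence else gene
  s <- seq_to_int(sequence)
  L <- length(s)
  floor_v <- model$config$floor
  out <- matrix(floor_v, L, 2, dimnames = list(NULL, c("acceptor", "donor")))
  for (type in c("acceptor", "donor")) {
    wm <- lssi_window_matrix(s, type)
    if (length(wm$pos0) == 0) next
    logits <- lssi_mlp_fwd(model[[type]], wm$X)$logits
    # natural-log softmax of the site class
    m <- pmax(logits[, 1], logits[, 2])
    logp <- logits[, 2] - (m + log(exp(logits[, 1] - m) +
                                   exp(logits[, 2] - m)))
    col <- if (type == "acceptor") 1L else 2L
    out[wm$pos0 + 1L, col] <- pmax(logp, floor_v)
  }
  out
}

#' Fraction of positions scoring above the floor
#'
#' The "meaningful-score density" of an LSSI score track: positions whose
#' clamped log-probability exceeds the floor.
#' @param scores L x 2 matrix from [lssi_score()].
#' @param floor the clamp value.
#' @return named vector with per-column densities and their mean.
#' @export
lssi_density <- function(scores, floor = -10) {
  d <- colMeans(scores > floor)
  c(d, mean = mean(d))
}
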