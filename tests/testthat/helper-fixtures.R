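# Shared small fixtures, built in code.

# A deterministic sequence with given length from a seeded alphabet draw.
random_seq <- function(L, seed = 1L) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Brute-force PSAM scorer: independent sliding-window product oracle.
oracle_score_psam <- function(ps, sequence) {
  s <- samsplice:::seq_to_int(sequence)
  L <- length(s)
  w <- ps$width
  out <- numeric(L)
  if (L < w) return(out)
  for (start in 1:(L - w + 1)) {
    v <- ps$abs_affinity
    for (j in 1:w) {
      b <- s[start + j - 1]
      v <- v * if (b > 0) ps$rel_affinity[j, b] else
        mean(ps$rel_affinity[j, ])
    }
    out[start + w %/% 2] <- v
  }
  out
}

# A tiny two-gene fixture with hand-placed exons.
tiny_genes <- function() {
  list(
    g1 = gene_record("g1", random_seq(200, seed = 11),
                     rbind(c(10, 50), c(100, 140), c(170, 195))),
    g2 = gene_record("g2", random_seq(150, seed = 12),
                     rbind(c(5, 40), c(90, 130)))
  )
}

# A small random PSAM with rows normalised to max 1.
random_psam <- function(width = 5L, seed = 1L, abs_affinity = 2) {
  set.seed(seed)
  rel <- matrix(stats::runif(width * 4, 0.05, 1), width, 4)
  psam(rel, abs_affinity = abs_affinity)
}

# An untrained bundle is enough for the exactness contracts here (zero-
# channel knockouts, composition, landscapes); trained-model behaviour is
# covered by the acceptance suite.
make_untrained_bundle <- function(gn, delta = 0.01, seed = 131) {
  set.seed(seed)
  sets <- gen_psams(gn$truth$motifs, seed = seed)
  n_tr <- min(4L, length(gn$genes))
  lssi <- train_lssi(gn$genes[seq_len(n_tr)], gn$labels[seq_len(n_tr)],
                     lssi_config(epochs = 1L), seed = seed)
  M <- length(sets)
  cfg <- aggregator_config(M, channels = 8L, local_conv_width = 5L,
                           attention_window = 9L, attention_heads = 2L,
                           post_cnn_widths = c(3L, 3L), lstm_hidden = 4L)
  st <- sparse_recalibrate(
    lapply(gn$genes, function(g) fm_forward(sets, g$sequence)),
    sparsity_state(M, delta = delta))
  sam_model(lssi, sets, "fm", cfg, aggregator_init(cfg), st)
}

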