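test_that("knockout of an absent channel changes nothing, exactly", {
  gn <- gen_genome(synth_config(n_genes = 5L), seed = 121)
  mdl <- make_untrained_bundle(gn)
  # force one channel to carry no activation anywhere: knocking it out is
  # then an exact no-op
  mdl$state$thresholds[1] <- Inf
  g <- gn$genes[[2]]
  trk <- sam_motif_track(mdl, samsplice:::seq_to_int(g$sequence))$track
  expect_true(all(trk[, 1] == 0))
  ex <- g$exons
  kd <- in_silico_knockdown(mdl, g, c(ex[2, 1], ex[2, 2] - 1L),
                            mdl$channel_ids[1])
  expect_identical(kd$delta_psi, 0)
  expect_identical(kd$psi_baseline, kd$psi_knockout)
  expect_error(in_silico_knockdown(mdl, gn$genes[[1]], c(1, 2), "NOPE"),
               "unknown rbp")
})

test_that("zeroing all channels equals evaluating an all-zero motif track", {
  gn <- gen_genome(synth_config(n_genes = 3L), seed = 122)
  mdl <- make_untrained_bundle(gn)
  g <- gn$genes[[1]]
  all_ko <- sam_forward(mdl, g, knockout_channels = mdl$channel_ids)
  zero_tr <- matrix(0, nchar(g$sequence), length(mdl$channel_ids))
  override <- sam_forward(mdl, g, motif_override = zero_tr)
  expect_equal(all_ko$probs, override$probs)
})

test_that("peak extension moves starts 50 nt 5' with clipping", {
  peaks <- data.frame(gene_id = "g", start = c(100L, 30L), end = c(120L, 40L),
                      rbp_id = "X", is_control = FALSE)
  ext <- extend_peaks(peaks)
  expect_equal(ext$start, c(50L, 0L))
  expect_equal(ext$end, c(120L, 40L))
  # a minus-strand source peak is extended on its 5' side after strand
  # resolution: resolving the strand reflects coordinates, so extending
  # the resolved start equals reflecting an end-side extension
  L <- 200L
  minus_peak <- c(start = 60L, end = 80L)      # original minus-strand coords
  resolved <- c(start = L - unname(minus_peak["end"]),
                end = L - unname(minus_peak["start"]))
  ext_resolved <- extend_peaks(data.frame(gene_id = "g",
                                          start = resolved[["start"]],
                                          end = resolved[["end"]],
                                          rbp_id = "X", is_control = FALSE))
  # oracle: extend the 5' end on the minus strand (the *end* coordinate),
  # then reflect
  oracle_start <- L - (minus_peak["end"] + 50L)
  expect_equal(ext_resolved$start, unname(oracle_start))
})

test_that("control peaks preserve widths and are seed-deterministic", {
  gn <- gen_genome(synth_config(n_genes = 6L), seed = 123)
  pk <- gen_eclip(gn, "ENH1", seed = 124)
  ctrl <- make_control_peaks(pk, gn$genes, seed = 9)
  expect_equal(ctrl$end - ctrl$start, pk$end - pk$start)
  expect_true(all(ctrl$is_control))
  expect_identical(ctrl, make_control_peaks(pk, gn$genes, seed = 9))
  expect_false(identical(ctrl$start,
                         make_control_peaks(pk, gn$genes, seed = 10)$start))
  # placement is uniform: overlap of controls with planted sites is near
  # the density expectation
  occ <- gn$truth$occurrences
  occ <- occ[occ$rbp == "ENH1", ]
  hit <- vapply(seq_len(nrow(ctrl)), function(i) {
    any(occ$gene == ctrl$gene_id[i] & occ$center0 >= ctrl$start[i] &
          occ$center0 < ctrl$end[i])
  }, logical(1))
  width_frac <- mean((ctrl$end - ctrl$start) /
                       vapply(ctrl$gene_id, function(id)
                         nchar(gn$genes[[id]]$sequence), numeric(1)))
  occ_per_gene <- nrow(occ) / length(gn$genes)
  expect_lt(abs(mean(hit) - min(1, width_frac * occ_per_gene)), 0.35)
})

test_that("eCLIP enrichment counts match a hand-built two-peak toy", {
  # one gene, 30 nt, exon [0,15), intron [15,30); one RBP channel
  g <- gene_record("g", random_seq(30, seed = 125), rbind(c(0, 15), c(20, 30)))
  am <- matrix(0, 30, 1, dimnames = list(NULL, "X"))
  am[c(3, 8, 17), 1] <- 1               # sites at 2, 7 (exon) and 16 (intron)
  fm <- matrix(stats::runif(30, 0, 0.1), 30, 1, dimnames = list(NULL, "X"))
  fm[c(3, 8, 17), 1] <- c(0.9, 0.8, 0.7) # FM top sites coincide here
  real <- data.frame(gene_id = "g", start = c(0L, 16L), end = c(5L, 19L),
                     rbp_id = "X", is_control = FALSE)
  ctrl <- data.frame(gene_id = "g", start = c(6L, 25L), end = c(9L, 28L),
                     rbp_id = "X", is_control = TRUE)
  res <- suppressMessages(
    eclip_enrichment(list(g = am), list(g = fm), real, ctrl, list(g = g)))
  ex_row <- res$per_rbp[res$per_rbp$region_class == "exon", ]
  # hand count (exon sites 2 and 7): real peak [0,5) covers 2; control
  # [6,9) covers 7 -> enrichment 1/1 for both models, increase 0
  expect_equal(ex_row$enrichment_am, 1)
  expect_equal(ex_row$enrichment_fm, 1)
  expect_equal(ex_row$relative_increase_percent, 0)
  # intron site 16 is in the real peak [16,19) but no control: excluded
  expect_false("intron" %in% res$per_rbp$region_class)
})

test_that("sparsity-matched AM == FM sites give exactly 0% relative increase", {
  gn <- gen_genome(synth_config(n_genes = 4L), seed = 126)
  mdl <- make_untrained_bundle(gn)
  am_tracks <- sam_motif_tracks(mdl, gn$genes)
  fm_tracks <- lapply(gn$genes, function(g) {
    tr <- fm_forward(mdl$sets, g$sequence)
    colnames(tr) <- mdl$channel_ids
    tr
  })
  pk <- extend_peaks(gen_eclip(gn, "ENH1", seed = 127), 20L)
  ctrl <- make_control_peaks(pk, gn$genes, seed = 128)
  res <- suppressMessages(
    eclip_enrichment(am_tracks, fm_tracks, pk, ctrl, gn$genes))
  # the sparse AM track *is* the FM top-delta set, so the matched FM sites
  # coincide and every reported relative increase is exactly zero
  expect_false(is.null(res$per_rbp))
  expect_true(all(abs(res$per_rbp$relative_increase_percent) < 1e-9))
})

test_that("relative intron inclusion follows the stated count differences", {
  segs <- data.frame(segment = "ACGT", dataset = "donor", sd1 = 10L,
                     sd2 = 4L)
  expect_equal(mpra_rii(segs), 6)
  segs2 <- data.frame(segment = "ACGT", dataset = "acceptor", sa1 = 3L,
                      sa2 = 3L)
  expect_equal(mpra_rii(segs2), 0)
  # spreadsheet oracle over a toy table
  tab <- data.frame(segment = "A", dataset = c("donor", "donor", "acceptor"),
                    sd1 = c(5L, 2L, NA), sd2 = c(1L, 9L, NA),
                    sa1 = c(NA, NA, 4L), sa2 = c(NA, NA, 10L))
  expect_equal(mpra_rii(tab), c(4, -7, 6))
  expect_equal(mpra_rii(tab, flip = TRUE), c(-4, 7, -6))
  expect_error(mpra_rii(data.frame(segment = "A", dataset = "donor")),
               "sd1")
})

test_that("knockdown evaluation: perfect signs, random nulls, noise monotonicity", {
  set.seed(129)
  n <- 300L
  truth <- stats::rnorm(n, 0, 0.2)
  base <- data.frame(exon_id = paste0("e", 1:n), rbp_id = "X",
                     delta_psi = truth)
  experimental <- data.frame(exon_id = paste0("e", 1:n), rbp_id = "X",
                             delta_psi = truth, fdr = 0.01,
                             n_control = 60L, n_kd = 60L)
  perfect <- knockdown_eval(base, experimental, seed = 1)
  expect_equal(perfect$sign_accuracy, 1.0)
  expect_equal(perfect$magnitude_accuracy, 1.0)
  # random in-silico values: accuracy near 0.5, inside its bootstrap CI
  rand <- base
  rand$delta_psi <- stats::rnorm(n, 0, 0.2)
  null_res <- knockdown_eval(rand, experimental, seed = 1)
  expect_lt(abs(null_res$sign_accuracy - 0.5), 0.12)
  expect_true(null_res$sign_ci[1] <= 0.5 + 0.1 &&
                null_res$sign_ci[2] >= 0.5 - 0.1)
  # accuracy decreases monotonically with observation noise
  accs <- vapply(c(0.05, 0.3, 1.5), function(sd_noise) {
    noisy <- experimental
    set.seed(42)
    noisy$delta_psi <- truth + stats::rnorm(n, 0, sd_noise)
    knockdown_eval(base, noisy, seed = 1)$sign_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
  # filters: high FDR rows flagged out
  experimental$fdr <- 0.5
  flagged <- knockdown_eval(base, experimental, seed = 1)
  expect_true(flagged$sign_flagged)
})

test_that("regulatory landscapes report sites, motifs and knockout arrows", {
  gn <- gen_genome(synth_config(n_genes = 4L), seed = 141)
  mdl <- make_untrained_bundle(gn, seed = 142)
  # randomize the zero-initialised head so knockouts can move predictions
  set.seed(143)
  mdl$agg$head$W <- matrix(stats::rnorm(length(mdl$agg$head$W), sd = 0.5),
                           nrow(mdl$agg$head$W))
  g <- gn$genes[[1]]
  thresholds <- list(
    fm = c(acceptor = 0.1, donor = 0.1),
    lssi = c(acceptor = log(0.2), donor = log(0.2))
  )
  ls_ <- regulatory_landscape(list(fm = mdl), g, thresholds = thresholds)
  expect_named(ls_, c("fm", "lssi"))
  # normalization: a site at exactly the top-k threshold maps to -1
  if (!is.null(ls_$fm$sites)) {
    expect_true(all(ls_$fm$sites$norm_score > -5))
    implied <- log(ls_$fm$sites$prob) -
      log(thresholds$fm[ifelse(ls_$fm$sites$class == "acceptor",
                               "acceptor", "donor")]) - 1
    expect_equal(ls_$fm$sites$norm_score, unname(implied))
  }
  # arrows carry the documented fold-change styling
  if (!is.null(ls_$fm$arrows) && nrow(ls_$fm$arrows) > 0) {
    ar <- ls_$fm$arrows
    expect_equal(ar$style,
                 ifelse(ar$fold >= 1.5, "green",
                        ifelse(ar$fold <= 2 / 3, "red", "dashed")))
  }
  # a region with no motif sites yields no arrows
  empty_region <- c(0L, 5L)
  ls0 <- regulatory_landscape(list(fm = mdl), g, region = empty_region,
                              thresholds = thresholds,
                              include_lssi = FALSE)
  expect_equal(nrow(ls0$fm$motifs), 0L)
  expect_true(is.null(ls0$fm$arrows))
})

test_that("eCLIP-trained motifs factorize peak probabilities and find real peaks", {
  gn <- gen_genome(synth_config(n_genes = 8L), seed = 151)
  peaks <- gen_eclip(gn, "ENH1", noise = 0.1, seed = 152)
  ctrl <- make_control_peaks(peaks, gn$genes, seed = 153)
  fit <- train_am_e(peaks, ctrl, gn$genes, epochs = 2L, seed = 1L)
  # peak no-match probability equals the per-position product oracle
  g <- gn$genes[[peaks$gene_id[1]]]
  s <- samsplice:::seq_to_int(g$sequence)
  o <- fit$score(s)
  expect_true(all(o >= 0))
  span <- (peaks$start[1] + 1L):peaks$end[1]
  expect_equal(exp(-sum(o[span])), prod(exp(-o[span])))
  # the trained track scores real peaks above shifted controls on average
  mean_in <- function(pk) {
    mean(vapply(seq_len(nrow(pk)), function(i) {
      gg <- gn$genes[[pk$gene_id[i]]]
      oo <- fit$score(samsplice:::seq_to_int(gg$sequence))
      mean(oo[(pk$start[i] + 1L):pk$end[i]])
    }, numeric(1)))
  }
  expect_gt(mean_in(peaks), mean_in(ctrl))
})
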