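# Downstream interpretability and external-assay analyses: in-silico
# knockdowns, RNA maps, regulatory landscapes, eCLIP peak enrichment and
# eCLIP-trained motifs, MPRA activity statistics, and knockdown
# sign/magnitude evaluation.

#' Compute a bundle's sparse motif track for each gene
#' @param model a [sam_model()].
#' @param genes list of [gene_record()].
#' @param binar binarize the tracks.
#' @return named list of L x M matrices (colnames = rbp ids).
#' @export
sam_motif_tracks <- function(model, genes, binar = FALSE) {
  out <- lapply(genes, function(g) {
    tr <- sam_motif_track(model, seq_to_int(g$sequence))$track
    colnames(tr) <- model$channel_ids
    if (binar) binarize(tr) else tr
  })
  names(out) <- vapply(genes, `[[`, character(1), "gene_id")
  out
}

#' In-silico knockdown of one RBP for one exon
#'
#' The channel is zeroed after sparsification, before the aggregator
#' (occurrences treated as absent), and the exon's psi recomputed.
#'
#' @param model a [sam_model()].
#' @param gene a [gene_record()].
#' @param exon numeric `(acc_pos, don_pos)`, 0-based site positions.
#' @param rbp_id channel to knock out.
#' @param lssi_scores optional precomputed LSSI track.
#' @return list with `psi_baseline`, `psi_knockout` and
#'   `delta_psi = knockout - baseline` (negative for an enhancer).
#' @export
in_silico_knockdown <- function(model, gene, exon, rbp_id,
                                lssi_scores = NULL) {
  if (!rbp_id %in% model$channel_ids) stop("unknown rbp: ", rbp_id)
  if (is.null(lssi_scores)) lssi_scores <- lssi_score(model$lssi, gene)
  base <- sam_forward(model, gene, lssi_scores = lssi_scores)
  # exact no-op shortcut: a channel with no activations cannot move psi
  ch <- match(rbp_id, model$channel_ids)
  psi_b <- predict_psi(base$probs, exon[1], exon[2])
  if (all(base$track_in[, ch] == 0)) {
    return(list(exon = exon, rbp_id = rbp_id, psi_baseline = psi_b,
                psi_knockout = psi_b, delta_psi = 0))
  }
  ko <- sam_forward(model, gene, lssi_scores = lssi_scores,
                    knockout_channels = rbp_id)
  psi_k <- predict_psi(ko$probs, exon[1], exon[2])
  list(exon = exon, rbp_id = rbp_id, psi_baseline = psi_b,
       psi_knockout = psi_k, delta_psi = psi_k - psi_b)
}

#' RNA map: positional splicing effect of an RBP around the meta-exon
#'
#' For every analysed exon, each motif occurrence (nonzero, typically
#' binarized track position) of the RBP within the meta-window is removed
#' individually and the resulting psi change recorded at its position
#' relative to the exon's 3'SS (A axis) and 5'SS (D axis).  Effects are
#' means over occurrences at each meta-position (0 where no occurrence was
#' seen), normalized so an absolute value of 1 corresponds to the 99th
#' percentile of |effect| across positions, then clipped to `[-1, 1]`.
#' Positive values mean removal *decreases* psi, i.e. the factor enhances
#' inclusion at that position.
#'
#' @param model a [sam_model()] (normally binarized: effects then reflect
#'   site presence, not strength).
#' @param genes named list of [gene_record()].
#' @param exons data frame with columns `gene`, `acc_pos`, `don_pos`
#'   (0-based).
#' @param rbp_id channel to map.
#' @param flank_intron,flank_exon meta-window extents (nt into the intron /
#'   into the exon on each side).
#' @return list with `A` and `D` data frames (`offset`, `effect`,
#'   `n_occurrences`), the normalization quantile `q99`, and `flat`
#'   (TRUE when the RBP had no occurrence anywhere in the windows).
#' @export
rna_map <- function(model, genes, exons, rbp_id, flank_intron = 150L,
                    flank_exon = 75L) {
  ch <- match(rbp_id, model$channel_ids)
  if (is.na(ch)) stop("unknown rbp: ", rbp_id)
  a_off <- (-flank_intron):(flank_exon)     # relative to 3'SS
  d_off <- (-flank_exon):(flank_intron)     # relative to 5'SS
  a_sum <- a_cnt <- numeric(length(a_off))
  d_sum <- d_cnt <- numeric(length(d_off))
  for (gid in unique(exons$gene)) {
    gene <- genes[[gid]]
    lsc <- lssi_score(model$lssi, gene)
    base <- sam_forward(model, gene, lssi_scores = lsc)
    occ_pos <- which(base$track_in[, ch] != 0) - 1L     # 0-based
    if (length(occ_pos) == 0) next
    ex_g <- exons[exons$gene == gid, , drop = FALSE]
    for (e in seq_len(nrow(ex_g))) {
      acc <- ex_g$acc_pos[e]; don <- ex_g$don_pos[e]
      psi_b <- predict_psi(base$probs, acc, don)
      rel_a <- occ_pos - acc
      rel_d <- occ_pos - don
      in_a <- rel_a >= -flank_intron & rel_a <= flank_exon
      in_d <- rel_d >= -flank_exon & rel_d <= flank_intron
      for (oi in which(in_a | in_d)) {
        ko <- sam_forward(model, gene, lssi_scores = lsc,
                          knockout_sites = data.frame(pos0 = occ_pos[oi],
                                                      channel = ch))
        eff <- psi_b - predict_psi(ko$probs, acc, don)
        if (in_a[oi]) {
          j <- rel_a[oi] + flank_intron + 1L
          a_sum[j] <- a_sum[j] + eff; a_cnt[j] <- a_cnt[j] + 1
        }
        if (in_d[oi]) {
          j <- rel_d[oi] + flank_exon + 1L
          d_sum[j] <- d_sum[j] + eff; d_cnt[j] <- d_cnt[j] + 1
        }
      }
    }
  }
  a_eff <- ifelse(a_cnt > 0, a_sum / pmax(a_cnt, 1), 0)
  d_eff <- ifelse(d_cnt > 0, d_sum / pmax(d_cnt, 1), 0)
  flat <- all(a_cnt == 0) && all(d_cnt == 0)
  q99 <- stats::quantile(abs(c(a_eff, d_eff)), 0.99, names = FALSE)
  if (q99 > 0) {
    a_eff <- pmax(pmin(a_eff / q99, 1), -1)
    d_eff <- pmax(pmin(d_eff / q99, 1), -1)
  }
  list(rbp_id = rbp_id,
       A = data.frame(offset = a_off, effect = a_eff, n_occurrences = a_cnt),
       D = data.frame(offset = d_off, effect = d_eff, n_occurrences = d_cnt),
       q99 = q99, flat = flat)
}

#' Per-class top-k probability thresholds of a model over a gene set
#'
#' The probability cutoffs that emit exactly as many acceptor/donor
#' predictions as there are labeled sites — the reference point ("-1") of
#' regulatory-landscape score normalization.
#' @param model a [sam_model()].
#' @param genes,labels reference set.
#' @export
sam_topk_thresholds <- function(model, genes, labels) {
  probs <- lapply(genes, function(g) sam_forward(model, g)$probs)
  tk <- topk_accuracy(probs, labels)
  c(acceptor = tk$acceptor$threshold, donor = tk$donor$threshold)
}

#' Putative regulatory landscape of a genomic region
#'
#' For each model bundle: splice-site lollipops with scores normalized so
#' the model's top-k threshold maps to -1 (`log(p) - log(p_threshold) - 1`,
#' natural log) and only sites above -5 are shown; motif lollipops in
#' relative-affinity units; and motif-to-site arrows wherever knocking out
#' a single motif occurrence changes a shown site's probability by a
#' factor of at least 1.5 (green) or at most 2/3 (red).  The top 5 effects
#' per site are always listed, dashed when below the cutoff.
#'
#' @param models named list of [sam_model()] bundles (e.g. fm, am) sharing
#'   the LSSI.
#' @param gene a [gene_record()].
#' @param region optional `(start, end)` 0-based half-open window to
#'   report on (default: whole gene).
#' @param thresholds named list (per model) of per-class top-k probability
#'   thresholds from [sam_topk_thresholds()].
#' @param show_floor normalized-score display cutoff.
#' @param include_lssi also report the LSSI-only site landscape.
#' @return list per model with `sites`, `motifs` and `arrows` data frames;
#'   plus an `lssi` entry when requested.
#' @export
regulatory_landscape <- function(models, gene, region = NULL, thresholds,
                                 show_floor = -5, include_lssi = TRUE) {
  L <- nchar(gene$sequence)
  if (is.null(region)) region <- c(0L, L)
  in_region <- function(p0) p0 >= region[1] & p0 < region[2]
  lsc <- lssi_score(models[[1]]$lssi, gene)
  out <- list()
  for (nm in names(models)) {
    model <- models[[nm]]
    thr <- thresholds[[nm]]
    fw <- sam_forward(model, gene, lssi_scores = lsc)
    sites <- do.call(rbind, lapply(c(acceptor = 1L, donor = 2L),
                                   function(cls) {
      p <- fw$probs[, cls + 1L]
      norm <- log(pmax(p, 1e-300)) - log(thr[cls]) - 1
      keep <- which(norm > show_floor & in_region(seq_along(p) - 1L))
      if (length(keep) == 0) return(NULL)
      data.frame(pos0 = keep - 1L, class = c("acceptor", "donor")[cls],
                 prob = p[keep], norm_score = norm[keep],
                 stringsAsFactors = FALSE)
    }))
    occ <- which(fw$track_in != 0, arr.ind = TRUE)
    occ <- occ[in_region(occ[, 1] - 1L), , drop = FALSE]
    motifs <- data.frame(pos0 = occ[, 1] - 1L,
                         rbp_id = model$channel_ids[occ[, 2]],
                         value = fw$track_in[occ],
                         stringsAsFactors = FALSE)
    arrows <- NULL
    if (!is.null(sites) && nrow(sites) > 0 && nrow(motifs) > 0) {
      rows <- list()
      for (k in seq_len(nrow(motifs))) {
        ko <- sam_forward(model, gene, lssi_scores = lsc,
                          knockout_sites = data.frame(
                            pos0 = motifs$pos0[k],
                            channel = motifs$rbp_id[k]))
        for (si in seq_len(nrow(sites))) {
          cls <- if (sites$class[si] == "acceptor") 2L else 3L
          p_new <- ko$probs[sites$pos0[si] + 1L, cls]
          fold <- p_new / max(sites$prob[si], 1e-300)
          rows[[length(rows) + 1L]] <- data.frame(
            motif_pos0 = motifs$pos0[k], rbp_id = motifs$rbp_id[k],
            site_pos0 = sites$pos0[si], site_class = sites$class[si],
            fold = fold, stringsAsFactors = FALSE)
        }
      }
      arrows <- do.call(rbind, rows)
      arrows$style <- ifelse(arrows$fold >= 1.5, "green",
                             ifelse(arrows$fold <= 2 / 3, "red", "dashed"))
      # always keep at least the top-5 effects per site
      arrows <- do.call(rbind, lapply(split(arrows, list(arrows$site_pos0,
                                                         arrows$site_class),
                                            drop = TRUE), function(df) {
        df <- df[order(-abs(log(df$fold))), , drop = FALSE]
        df[df$style != "dashed" | seq_len(nrow(df)) <= 5L, , drop = FALSE]
      }))
      rownames(arrows) <- NULL
    }
    out[[nm]] <- list(sites = sites, motifs = motifs, arrows = arrows)
  }
  if (include_lssi) {
    thr_l <- thresholds$lssi
    sites <- do.call(rbind, lapply(c(acceptor = 1L, donor = 2L),
                                   function(cls) {
      sc <- lsc[, cls]
      norm <- sc - thr_l[cls] - 1        # scores are already log-probs
      keep <- which(norm > show_floor & in_region(seq_along(sc) - 1L))
      if (length(keep) == 0) return(NULL)
      data.frame(pos0 = keep - 1L, class = c("acceptor", "donor")[cls],
                 prob = exp(sc[keep]), norm_score = norm[keep],
                 stringsAsFactors = FALSE)
    }))
    out$lssi <- list(sites = sites, motifs = NULL, arrows = NULL)
  }
  out
}

## ---- eCLIP ----------------------------------------------------------------

#' Extend peaks toward the 5' end
#'
#' Peak coordinates are sense-strand (strand was resolved at load time), so
#' the 5' extension always moves the start, clipped at 0; this enriches
#' the region for the binding motif upstream of the crosslink site.
#' @param peaks peak data frame ([read_peaks_bed()] layout).
#' @param amount nt to extend (default 50).
#' @export
extend_peaks <- function(peaks, amount = 50L) {
  peaks$start <- pmax(0L, peaks$start - as.integer(amount))
  peaks
}

#' Shifted-control peaks: same widths, random positions, same transcript
#'
#' @param peaks real peaks.
#' @param genes named list of [gene_record()] (for transcript lengths).
#' @param seed RNG seed (same seed, same controls).
#' @return control peak data frame (`is_control = TRUE`); peaks wider than
#'   their transcript are dropped with a message.
#' @export
make_control_peaks <- function(peaks, genes, seed = 1L) {
  set.seed(seed)
  rows <- list()
  dropped <- 0L
  for (i in seq_len(nrow(peaks))) {
    gid <- peaks$gene_id[i]
    L <- nchar(genes[[gid]]$sequence)
    w <- peaks$end[i] - peaks$start[i]
    if (w > L) { dropped <- dropped + 1L; next }
    start <- rint(0L, L - w)
    rows[[length(rows) + 1L]] <-
      data.frame(gene_id = gid, start = start, end = start + w,
                 rbp_id = peaks$rbp_id[i], is_control = TRUE,
                 stringsAsFactors = FALSE)
  }
  if (dropped > 0) message(dropped, " peak(s) wider than transcript dropped")
  do.call(rbind, rows)
}

# Classify 0-based positions of a gene as exon/intron/flank.
position_region_class <- function(gene, pos0) {
  ex <- gene$exons
  cls <- rep("flank", length(pos0))
  body <- pos0 >= ex[1, 1] & pos0 < ex[nrow(ex), 2]
  cls[body] <- "intron"
  for (i in seq_len(nrow(ex))) {
    cls[pos0 >= ex[i, 1] & pos0 < ex[i, 2]] <- "exon"
  }
  cls
}

#' eCLIP enrichment of a motif model versus the FM model
#'
#' For each RBP and region class (exon/intron): the model's sites are the
#' nonzero positions of its sparse track; the FM comparator is thresholded
#' to *exactly as many* sites in that region class ("equivalent
#' sparsity").  Enrichment = (sites inside real, extended peaks) / (sites
#' inside shifted-control peaks); the headline number is the relative
#' increase `100 * (enr_am / enr_fm - 1)`, averaged across RBPs.
#'
#' @param am_tracks named (per gene) list of sparse L x M tracks for the
#'   evaluated model (colnames = rbp ids).
#' @param fm_tracks matching list of *dense* FM affinity tracks (used for
#'   the sparsity-matched threshold).
#' @param peaks_real,peaks_ctrl peak data frames (real peaks already
#'   extended with [extend_peaks()]).
#' @param genes named list of [gene_record()] for region classification.
#' @return list with `per_rbp` (rbp x region rows with both enrichments
#'   and the % increase) and `means` (mean % increase per region class).
#'   RBPs with zero control overlap are excluded with a message.
#' @export
eclip_enrichment <- function(am_tracks, fm_tracks, peaks_real, peaks_ctrl,
                             genes) {
  rbps <- colnames(am_tracks[[1]])
  gids <- names(am_tracks)
  region_of <- lapply(gids, function(gid) {
    position_region_class(genes[[gid]],
                          seq_len(nrow(am_tracks[[gid]])) - 1L)
  })
  names(region_of) <- gids
  in_peaks <- function(gid, pos0, rbp, peaks) {
    pk <- peaks[peaks$gene_id == gid & peaks$rbp_id == rbp, , drop = FALSE]
    if (nrow(pk) == 0) return(rep(FALSE, length(pos0)))
    hit <- rep(FALSE, length(pos0))
    for (i in seq_len(nrow(pk))) {
      hit <- hit | (pos0 >= pk$start[i] & pos0 < pk$end[i])
    }
    hit
  }
  rows <- list()
  for (rbp in rbps) {
    for (rc in c("exon", "intron")) {
      am_pos <- list(); fm_val <- list(); fm_pos <- list()
      for (gid in gids) {
        sel <- region_of[[gid]] == rc
        pos0 <- which(sel) - 1L
        am_here <- which(am_tracks[[gid]][sel, rbp] != 0)
        am_pos[[gid]] <- pos0[am_here]
        fm_val[[gid]] <- fm_tracks[[gid]][sel, rbp]
        fm_pos[[gid]] <- pos0
      }
      n_am <- sum(lengths(am_pos))
      if (n_am == 0) next
      # sparsity-matched FM sites: exactly the top n_am values pooled
      # across genes (stable order breaks ties)
      allv <- unlist(fm_val)
      gene_of <- rep(gids, times = lengths(fm_val))
      top_idx <- order(allv, decreasing = TRUE)[seq_len(n_am)]
      fm_sel <- split(unlist(fm_pos)[top_idx], gene_of[top_idx])
      counts <- c(am_real = 0, am_ctrl = 0, fm_real = 0, fm_ctrl = 0)
      for (gid in gids) {
        fm_sites <- fm_sel[[gid]]
        if (length(fm_sites) > 0) {
          counts["fm_real"] <- counts["fm_real"] +
            sum(in_peaks(gid, fm_sites, rbp, peaks_real))
          counts["fm_ctrl"] <- counts["fm_ctrl"] +
            sum(in_peaks(gid, fm_sites, rbp, peaks_ctrl))
        }
        if (length(am_pos[[gid]]) > 0) {
          counts["am_real"] <- counts["am_real"] +
            sum(in_peaks(gid, am_pos[[gid]], rbp, peaks_real))
          counts["am_ctrl"] <- counts["am_ctrl"] +
            sum(in_peaks(gid, am_pos[[gid]], rbp, peaks_ctrl))
        }
      }
      if (counts["am_ctrl"] == 0 || counts["fm_ctrl"] == 0) {
        message("zero control overlap for ", rbp, " (", rc,
                "); excluded")
        next
      }
      enr_am <- counts["am_real"] / counts["am_ctrl"]
      enr_fm <- counts["fm_real"] / counts["fm_ctrl"]
      if (enr_am == 0 || enr_fm == 0) {
        message("zero real-peak enrichment for ", rbp, " (", rc,
                "); excluded")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        rbp_id = rbp, region_class = rc, n_sites = n_am,
        enrichment_am = unname(enr_am), enrichment_fm = unname(enr_fm),
        relative_increase_percent = unname(100 * (enr_am / enr_fm - 1)),
        stringsAsFactors = FALSE)
    }
  }
  per_rbp <- do.call(rbind, rows)
  means <- if (!is.null(per_rbp)) {
    tapply(per_rbp$relative_increase_percent, per_rbp$region_class, mean)
  } else NULL
  list(per_rbp = per_rbp, means = means)
}

#' Train an AM-architecture motif model on eCLIP peaks (AM-E)
#'
#' The network's nonnegative per-position output is interpreted as the
#' negative log probability that the position is *not* a motif match;
#' multiplying across a peak gives `P(no match in peak) = exp(-sum)`, and
#' the logistic loss pushes real peaks toward containing a match and
#' shifted-control peaks toward containing none.  The training set is
#' balanced 50% intron / 50% exon peaks.
#'
#' @param peaks_real,peaks_ctrl peak data frames for one RBP.
#' @param genes named list of [gene_record()].
#' @param epochs,learning_rate,trunk_width training hyperparameters.
#' @param seed RNG seed.
#' @return list with `params` and `score(seq_int)` returning the
#'   nonnegative per-position match track.
#' @export
train_am_e <- function(peaks_real, peaks_ctrl, genes, epochs = 3L,
                       learning_rate = 3e-3, trunk_width = 8L, seed = 1L) {
  set.seed(seed)
  all_peaks <- rbind(peaks_real, peaks_ctrl)
  all_peaks <- all_peaks[all_peaks$end - all_peaks$start >= 5, , drop = FALSE]
  if (nrow(all_peaks) == 0) stop("no usable peaks")
  # balance exon/intron by peak-center class
  centers <- (all_peaks$start + all_peaks$end) %/% 2L
  rc <- vapply(seq_len(nrow(all_peaks)), function(i)
    position_region_class(genes[[all_peaks$gene_id[i]]], centers[i]),
    character(1))
  all_peaks <- all_peaks[rc %in% c("exon", "intron"), , drop = FALSE]
  rc <- rc[rc %in% c("exon", "intron")]
  n_min <- min(table(factor(rc, levels = c("exon", "intron"))))
  keep <- c(sample(which(rc == "exon"), min(n_min, sum(rc == "exon"))),
            sample(which(rc == "intron"), min(n_min, sum(rc == "intron"))))
  all_peaks <- all_peaks[keep, , drop = FALSE]
  if (nrow(all_peaks) == 0) stop("no peaks left after balancing")

  params <- adjnet_init(1L, trunk_width = trunk_width)
  opt <- adam_init(params)
  ctx <- 10L                              # receptive-field context
  forward_peak <- function(i) {
    pk <- all_peaks[i, ]
    g <- genes[[pk$gene_id]]
    L <- nchar(g$sequence)
    lo <- max(0L, pk$start - ctx)
    hi <- min(L, pk$end + ctx)
    s <- seq_to_int(substr(g$sequence, lo + 1L, hi))
    fw <- adjnet_fwd(params, one_hot(s))
    inside <- (pk$start - lo + 1L):(pk$end - lo)
    list(fw = fw, inside = inside, raw = drop(fw$out))
  }
  for (ep in seq_len(epochs)) {
    for (i in sample(seq_len(nrow(all_peaks)))) {
      y <- as.numeric(!all_peaks$is_control[i])
      fp <- forward_peak(i)
      o <- log1p(exp(fp$raw))             # softplus: nonnegative -log P
      S <- sum(o[fp$inside])
      dS <- if (y == 1) {
        -exp(-S) / max(1 - exp(-S), 1e-8)
      } else 1
      do_ <- numeric(length(o))
      do_[fp$inside] <- dS
      draw <- do_ * sigmoid(fp$raw)       # softplus'
      bk <- adjnet_bwd(params, fp$fw$cache, matrix(draw, ncol = 1))
      upd <- adam_step(params, bk$grads, opt, lr = learning_rate)
      params <- upd$params
      opt <- upd$opt
    }
  }
  score <- function(seq_int) {
    log1p(exp(drop(adjnet_fwd(params, one_hot(seq_int))$out)))
  }
  list(params = params, score = score)
}

## ---- MPRA -----------------------------------------------------------------

#' Relative intron inclusion (RII) of reporter segments
#'
#' Donor datasets: `RII = count(SD1) - count(SD2)` (SD1 = distal donor,
#' placing the segment in the intron); acceptor datasets:
#' `RII = count(SA2) - count(SA1)`.  Positive RII means the segment
#' favours recognition as intron.
#'
#' @param segments data frame with a `dataset` column (`donor` /
#'   `acceptor`) and the matching count columns (`sd1`,`sd2` or
#'   `sa1`,`sa2`).
#' @param flip reverse the subtraction direction (exposed because captions
#'   and text can disagree on orientation; the default follows SD1-SD2 /
#'   SA2-SA1).
#' @return numeric RII per segment.
#' @export
mpra_rii <- function(segments, flip = FALSE) {
  rii <- numeric(nrow(segments))
  don <- segments$dataset == "donor"
  if (any(don)) {
    if (is.null(segments$sd1) || is.null(segments$sd2)) {
      stop("donor segments need sd1 and sd2 counts")
    }
    rii[don] <- segments$sd1[don] - segments$sd2[don]
  }
  if (any(!don)) {
    if (is.null(segments$sa1) || is.null(segments$sa2)) {
      stop("acceptor segments need sa1 and sa2 counts")
    }
    rii[!don] <- segments$sa2[!don] - segments$sa1[!don]
  }
  if (flip) rii <- -rii
  rii
}

# Bound/unbound calls for each segment under a motif bundle: at least one
# nonzero sparse site in the (possibly trimmed) segment.
segment_bound <- function(model, segments, trim_left = 3L) {
  res <- matrix(FALSE, nrow(segments), length(model$channel_ids),
                dimnames = list(NULL, model$channel_ids))
  for (i in seq_len(nrow(segments))) {
    s <- seq_to_int(segments$segment[i])
    tr <- sam_motif_track(model, s)$track
    if (segments$dataset[i] == "donor" && trim_left > 0) {
      tr <- tr[-seq_len(min(trim_left, nrow(tr))), , drop = FALSE]
    }
    res[i, ] <- colSums(tr != 0) > 0
  }
  res
}

#' Baseline motif activity (BMA) and AM-FM difference (AFD) per RBP
#'
#' BMA = mean RII of FM-bound segments minus mean RII of FM-unbound
#' segments (the FM model's implied activity sign for the RBP).
#' AFD = mean RII of segments bound *only* by the AM minus mean RII of
#' segments bound only by the FM — positive products BMA*AFD mean the AM's
#' binding calls better reflect the factor's activity.  The leftmost 3
#' positions of donor-dataset segments are excluded for both models (the
#' AM context window does not fit there).  Sign agreement across RBPs is
#' tested with a permutation test.
#'
#' @param segments data frame from [gen_mpra()] (or same layout).
#' @param fm_model,am_model [sam_model()] bundles sharing channels.
#' @param trim_left positions trimmed from donor segments.
#' @param n_perm permutations for the sign-agreement p-value.
#' @param seed RNG seed.
#' @return list with `per_rbp` (BMA, AFD, stratum sizes, flags),
#'   `sign_agreement`, `correlation` and `p_value`.
#' @export
bma_afd <- function(segments, fm_model, am_model, trim_left = 3L,
                    n_perm = 10000L, seed = 1L) {
  rii <- mpra_rii(segments)
  fm_b <- segment_bound(fm_model, segments, trim_left)
  am_b <- segment_bound(am_model, segments, trim_left)
  rows <- lapply(colnames(fm_b), function(rbp) {
    fb <- fm_b[, rbp]; ab <- am_b[, rbp]
    n_bound <- sum(fb); n_unbound <- sum(!fb)
    bma <- if (n_bound > 0 && n_unbound > 0) {
      mean(rii[fb]) - mean(rii[!fb])
    } else NA_real_
    am_only <- ab & !fb
    fm_only <- fb & !ab
    afd <- if (sum(am_only) > 0 && sum(fm_only) > 0) {
      mean(rii[am_only]) - mean(rii[fm_only])
    } else NA_real_
    data.frame(rbp_id = rbp, BMA = bma, AFD = afd, n_bound = n_bound,
               n_unbound = n_unbound, n_am_only = sum(am_only),
               n_fm_only = sum(fm_only),
               flagged = is.na(bma) || is.na(afd),
               stringsAsFactors = FALSE)
  })
  per_rbp <- do.call(rbind, rows)
  ok <- !per_rbp$flagged
  sign_agree <- NA_real_; corr <- NA_real_; pval <- NA_real_
  if (sum(ok) >= 2) {
    b <- per_rbp$BMA[ok]; a <- per_rbp$AFD[ok]
    sign_agree <- mean(sign(b) == sign(a))
    corr <- stats::cor(b, a)
    set.seed(seed)
    perm <- replicate(n_perm, mean(sign(b) == sign(sample(a))))
    pval <- (sum(perm >= sign_agree) + 1) / (n_perm + 1)
  }
  list(per_rbp = per_rbp, sign_agreement = sign_agree,
       correlation = corr, p_value = pval)
}

## ---- knockdown evaluation -------------------------------------------------

#' Evaluate in-silico knockdowns against experimental delta-psi tables
#'
#' Joined on (exon_id, rbp_id), cell lines pooled by the caller.  The sign
#' task (does the model predict the direction of the psi change?) is
#' evaluated on exons with `fdr < 0.05`; the magnitude task (is |delta
#' psi| above or below the median?) on experiments with at least
#' `min_samples` control and knockdown samples.  95% bootstrap confidence
#' intervals resample exons.
#'
#' @param in_silico data frame with `exon_id`, `rbp_id`, `delta_psi`
#'   (model predictions).
#' @param experimental data frame with `exon_id`, `rbp_id`, `delta_psi`,
#'   `fdr`, `n_control`, `n_kd`.
#' @param fdr_cutoff,min_samples the two reliability filters.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @return list with `sign_accuracy`, `magnitude_accuracy`, their CIs and
#'   subset sizes (NA + flag when a subset is empty).
#' @export
knockdown_eval <- function(in_silico, experimental, fdr_cutoff = 0.05,
                           min_samples = 50L, n_boot = 1000L, seed = 1L) {
  joined <- merge(in_silico, experimental, by = c("exon_id", "rbp_id"),
                  suffixes = c("_pred", "_obs"))
  if (nrow(joined) == 0) stop("no (exon, rbp) pairs in common")
  set.seed(seed)
  boot_ci <- function(x, stat) {
    reps <- replicate(n_boot, stat(x[sample.int(length(x), replace = TRUE)]))
    stats::quantile(reps, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  }
  out <- list(n_joined = nrow(joined))
  sig <- joined[joined$fdr < fdr_cutoff, , drop = FALSE]
  if (nrow(sig) == 0) {
    out$sign_accuracy <- NA_real_
    out$sign_flagged <- TRUE
  } else {
    agree <- sign(sig$delta_psi_pred) == sign(sig$delta_psi_obs)
    out$sign_accuracy <- mean(agree)
    out$sign_ci <- boot_ci(agree, mean)
    out$n_sign <- nrow(sig)
    out$sign_flagged <- FALSE
  }
  hc <- joined[joined$n_control >= min_samples & joined$n_kd >= min_samples,
               , drop = FALSE]
  if (nrow(hc) == 0) {
    out$magnitude_accuracy <- NA_real_
    out$magnitude_flagged <- TRUE
  } else {
    pred_above <- abs(hc$delta_psi_pred) > stats::median(abs(hc$delta_psi_pred))
    obs_above <- abs(hc$delta_psi_obs) > stats::median(abs(hc$delta_psi_obs))
    agree <- pred_above == obs_above
    out$magnitude_accuracy <- mean(agree)
    out$magnitude_ci <- boot_ci(agree, mean)
    out$n_magnitude <- nrow(hc)
    out$magnitude_flagged <- FALSE
  }
  out
}
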