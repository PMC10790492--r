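# Ground-truthed synthetic data generators.
#
# The generators emulate the statistical structure the splicing analyses
# assume — genes with consensus splice sites and decoy exons, planted
# enhancer/silencer motifs with signed activities, RBNS-like read pools,
# peaks centered on planted occurrences, and reporter segments whose
# relative intron inclusion follows planted activities — so that every
# pipeline stage can be trained and validated against known ground truth
# without external data.  Every generator is a pure function of
# (config, seed).
#
# Exon inclusion follows a logistic link: candidate internal exons (real
# and decoy, all carrying consensus splice sites of equal strength) are
# included with probability
#   plogis(gain * (core + sum of signed activities of motif occurrences
#                  within the effect window) + bias),
# which makes the planted regulatory logic recoverable: splice-site
# sequence alone cannot separate real from decoy exons, motif context can.

#' Default planted-motif table
#'
#' Five splicing regulatory factors: two exonic enhancers, one exonic
#' silencer, one intronic enhancer and one intronic silencer, with signed
#' activities on the logistic scale of the inclusion link.
#' @export
synth_motif_table <- function() {
  data.frame(
    rbp = c("ENH1", "ENH2", "SIL1", "IENH", "ISIL"),
    consensus = c("GAAGAA", "TGCATG", "CCGCCA", "ACGCGA", "CAACCA"),
    abs_affinity = 1,
    activity = c(2.5, 2.0, -2.5, 2.0, -2.0),
    region = c("exon", "exon", "exon", "intron", "intron"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic-genome configuration
#'
#' @param n_genes number of genes.
#' @param n_exons_range range of real exon counts per gene (at least 3 so
#'   every gene has an internal, skippable exon).
#' @param exon_len_range,intron_len_range,flank_len_range length ranges
#'   (nt); introns are comfortably above the 24-nt window minimum.
#' @param consensus_strength probability that each consensus base of a
#'   splice-site window is planted (the GT/AG cores use a higher floor).
#' @param motifs planted-motif table ([synth_motif_table()] layout).
#' @param enhancer_plant_prob probability an enhancer is planted near each
#'   real internal exon (silencers use it for decoys).
#' @param cross_plant_prob probability of planting against type (enhancer
#'   near decoy, silencer near real exon) — regulatory noise.
#' @param background_occ_rate per-nt rate of neutral background occurrences
#'   of each motif.
#' @param decoys_per_gene_range decoy exons planted per gene.
#' @param effect_window nt around an exon's boundaries within which a motif
#'   occurrence contributes its activity to the inclusion link.
#' @param link_gain,link_bias logistic-link parameters.
#' @param core_sd standard deviation of the latent core-strength term.
#' @param perturb_positions how many consensus positions per motif are
#'   mis-specified when deriving "in vitro" PSAMs with [gen_psams()]
#'   (models the in-vivo-vs-in-vitro gap; 0 = faithful PSAMs).
#' @export
synth_config <- function(n_genes = 200L, n_exons_range = c(3L, 4L),
                         exon_len_range = c(30L, 60L),
                         intron_len_range = c(90L, 160L),
                         flank_len_range = c(40L, 80L),
                         consensus_strength = 0.9,
                         motifs = synth_motif_table(),
                         enhancer_plant_prob = 0.8,
                         cross_plant_prob = 0.1,
                         background_occ_rate = 5e-4,
                         decoys_per_gene_range = c(1L, 2L),
                         effect_window = 50L,
                         link_gain = 1, link_bias = -2,
                         core_sd = 0.5,
                         perturb_positions = 0L) {
  stopifnot(n_genes >= 1, intron_len_range[1] >= 24,
            consensus_strength > 0, consensus_strength <= 1,
            effect_window > 0)
  structure(as.list(environment()), class = "synth_config")
}

# Uniform integer draw(s) on [lo, hi], safe when lo == hi (R's sample()
# treats a scalar first argument as 1:n).
rint <- function(lo, hi, n = 1L) {
  if (lo >= hi) rep(as.integer(lo), n)
  else sample(lo:hi, n, replace = TRUE)
}

# Plant a string into an integer-coded sequence at 0-based position pos0,
# each base independently with probability prob.
plant_string <- function(s, pos0, string, prob = 1) {
  chars <- seq_to_int(string)
  for (j in seq_along(chars)) {
    if (stats::runif(1) <= prob) s[pos0 + j] <- chars[j]
  }
  s
}

# Acceptor consensus: 18-nt polypyrimidine tract then AG, ending at the
# last intron base; `pos0` is the (0-based) first exonic base.
plant_acceptor <- function(s, pos0, strength) {
  ppt_start <- pos0 - 20L
  for (j in 0:17) {
    if (stats::runif(1) <= strength) {
      s[ppt_start + j + 1L] <- sample(c(2L, 4L), 1)   # C or T
    }
  }
  core <- min(1, strength + 0.08)
  if (stats::runif(1) <= core) s[pos0 - 1L] <- 1L     # A
  if (stats::runif(1) <= core) s[pos0] <- 3L          # G
  s
}

# Donor consensus: exon ends ...AG | GTAAGT; `pos0` is the last exonic base.
plant_donor <- function(s, pos0, strength) {
  core <- min(1, strength + 0.08)
  if (stats::runif(1) <= strength) s[pos0] <- 1L      # A (pos0-1 0-based)
  if (stats::runif(1) <= strength) s[pos0 + 1L] <- 3L # G last exon base
  if (stats::runif(1) <= core) s[pos0 + 2L] <- 3L     # G
  if (stats::runif(1) <= core) s[pos0 + 3L] <- 4L     # T
  s <- plant_string(s, pos0 + 3L, "AAGT", strength)
  s
}

#' Generate a synthetic genome with planted splicing regulation
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed; the generator is a pure function of
#'   `(cfg, seed)`.
#' @return list with `genes` (named list of [gene_record()], exons = the
#'   *included* exons), `labels` (label tracks), and `truth`: `exons`
#'   (every candidate exon with its type, summed local activity, inclusion
#'   probability and outcome), `occurrences` (planted motif instances with
#'   positions and signed activities) and the `motifs` table.
#' @export
gen_genome <- function(cfg = synth_config(), seed = 1L) {
  set.seed(seed)
  genes <- list()
  labels <- list()
  exon_rows <- list()
  occ_rows <- list()
  mot <- cfg$motifs
  mot_w <- nchar(mot$consensus)
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("gene%03d", g)
    n_ex <- rint(cfg$n_exons_range[1], cfg$n_exons_range[2])
    ex_len <- rint(cfg$exon_len_range[1], cfg$exon_len_range[2], n_ex)
    in_len <- rint(cfg$intron_len_range[1], cfg$intron_len_range[2],
                   n_ex - 1L)
    fl <- rint(cfg$flank_len_range[1], cfg$flank_len_range[2], 2L)
    # real exon coordinates (0-based half-open)
    starts <- integer(n_ex); ends <- integer(n_ex)
    cur <- fl[1]
    for (i in seq_len(n_ex)) {
      starts[i] <- cur; ends[i] <- cur + ex_len[i]
      cur <- ends[i] + if (i < n_ex) in_len[i] else fl[2]
    }
    L <- cur
    s <- sample.int(4L, L, replace = TRUE)
    # splice-site consensus at real boundaries
    for (i in seq_len(n_ex)) {
      if (i > 1) s <- plant_acceptor(s, starts[i], cfg$consensus_strength)
      if (i < n_ex) s <- plant_donor(s, ends[i] - 1L, cfg$consensus_strength)
    }
    # decoy exons inside introns, same consensus strength
    n_dec <- rint(cfg$decoys_per_gene_range[1], cfg$decoys_per_gene_range[2])
    decoys <- list()
    for (d in seq_len(n_dec)) {
      iv <- rint(1L, n_ex - 1L)                  # host intron
      i_start <- ends[iv]; i_end <- starts[iv + 1L]
      dl <- rint(cfg$exon_len_range[1], cfg$exon_len_range[2])
      lo <- i_start + 45L
      hi <- i_end - 45L - dl
      if (hi <= lo) next
      dstart <- NA_integer_
      for (attempt in 1:10) {          # avoid overlapping a prior decoy
        cand_start <- rint(lo, hi)
        clash <- any(vapply(decoys, function(d)
          cand_start < d[2] + 45L && cand_start + dl + 45L > d[1],
          logical(1)))
        if (!clash) { dstart <- cand_start; break }
      }
      if (is.na(dstart)) next
      s <- plant_acceptor(s, dstart, cfg$consensus_strength)
      s <- plant_donor(s, dstart + dl - 1L, cfg$consensus_strength)
      decoys[[length(decoys) + 1L]] <- c(dstart, dstart + dl)
    }
    # candidate internal exons: real internals + decoys
    cand <- list()
    for (i in seq_len(n_ex)) {
      if (i > 1 && i < n_ex) {
        cand[[length(cand) + 1L]] <-
          list(start = starts[i], end = ends[i], type = "real", idx = i)
      }
    }
    for (d in decoys) {
      cand[[length(cand) + 1L]] <-
        list(start = d[1], end = d[2], type = "decoy", idx = NA_integer_)
    }
    # forbidden zones for motif planting: splice-site windows
    site_pos <- c(starts[-1], vapply(decoys, `[`, integer(1), 1L))
    don_pos <- c(ends[-n_ex] - 1L,
                 vapply(decoys, function(d) d[2] - 1L, integer(1)))
    forbidden <- rep(FALSE, L)
    for (p in site_pos) forbidden[pmax(1, p - 20L + 1L):(p + 3L)] <- TRUE
    for (p in don_pos) forbidden[(p - 2L + 1L):pmin(L, p + 7L)] <- TRUE
    occupied <- rep(FALSE, L)
    try_plant <- function(lo, hi, w) {
      # 0-based candidate start in [lo, hi]; NA if no clear slot found
      lo <- max(0L, lo)
      if (hi < lo) return(NA_integer_)
      for (attempt in 1:20) {
        p <- rint(lo, hi)
        span <- (p + 1L):(p + w)
        if (p + w <= L && !any(forbidden[span]) && !any(occupied[span])) {
          return(p)
        }
      }
      NA_integer_
    }
    gene_occs <- list()
    add_occ <- function(p, m) {
      s <<- plant_string(s, p, mot$consensus[m], prob = 1)
      occupied[(p + 1L):(p + mot_w[m])] <<- TRUE
      gene_occs[[length(gene_occs) + 1L]] <<-
        data.frame(gene = gid, rbp = mot$rbp[m], pos0 = p,
                   center0 = p + mot_w[m] %/% 2L,
                   activity = mot$activity[m], stringsAsFactors = FALSE)
    }
    for (ci in seq_along(cand)) {
      cc <- cand[[ci]]
      for (m in seq_len(nrow(mot))) {
        matched <- (mot$activity[m] > 0) == (cc$type == "real")
        p_plant <- if (matched) cfg$enhancer_plant_prob else
          cfg$cross_plant_prob
        if (stats::runif(1) > p_plant) next
        w <- mot_w[m]
        if (mot$region[m] == "exon") {
          p <- try_plant(cc$start + 2L, cc$end - w - 2L, w)
        } else {
          side <- sample(c("up", "down"), 1)
          dist <- rint(12L, max(13L, cfg$effect_window - w - 5L))
          p <- if (side == "up") try_plant(cc$start - dist - w,
                                           cc$start - dist, w)
               else try_plant(cc$end + dist, cc$end + dist + w, w)
        }
        if (!is.na(p)) add_occ(p, m)
      }
    }
    # neutral background occurrences
    for (m in seq_len(nrow(mot))) {
      n_bg <- stats::rpois(1, cfg$background_occ_rate * L)
      for (b in seq_len(n_bg)) {
        p <- try_plant(0L, L - mot_w[m], mot_w[m])
        if (!is.na(p)) add_occ(p, m)
      }
    }
    occ <- if (length(gene_occs) > 0) do.call(rbind, gene_occs) else
      data.frame(gene = character(0), rbp = character(0),
                 pos0 = integer(0), center0 = integer(0),
                 activity = numeric(0))
    # inclusion via the logistic link
    included <- logical(length(cand))
    for (ci in seq_along(cand)) {
      cc <- cand[[ci]]
      near <- nrow(occ) > 0 &
        (occ$center0 >= cc$start - cfg$effect_window) &
        (occ$center0 <= cc$end + cfg$effect_window)
      act <- sum(occ$activity[near])
      core <- stats::rnorm(1, 0, cfg$core_sd)
      p_inc <- stats::plogis(cfg$link_gain * (core + act) + cfg$link_bias)
      included[ci] <- stats::runif(1) <= p_inc
      exon_rows[[length(exon_rows) + 1L]] <-
        data.frame(gene = gid, acc_pos = cc$start, don_pos = cc$end - 1L,
                   type = cc$type, local_activity = act, core = core,
                   p_inclusion = p_inc, included = included[ci],
                   stringsAsFactors = FALSE)
    }
    # final exon structure: terminal exons always, included candidates
    ex_final <- rbind(c(starts[1], ends[1]),
                      do.call(rbind, lapply(which(included), function(ci)
                        c(cand[[ci]]$start, cand[[ci]]$end))),
                      c(starts[n_ex], ends[n_ex]))
    ex_final <- ex_final[order(ex_final[, 1]), , drop = FALSE]
    gene <- gene_record(gid, int_to_seq(s), ex_final)
    genes[[gid]] <- gene
    labels[[gid]] <- make_label_track(gene)
    occ_rows[[g]] <- occ
  }
  truth <- list(exons = do.call(rbind, exon_rows),
                occurrences = do.call(rbind, occ_rows),
                motifs = mot)
  list(genes = genes, labels = labels, truth = truth, cfg = cfg)
}

#' Derive PSAMs for the planted motifs (optionally mis-specified)
#'
#' Builds one PSAM per planted motif: relative affinity 1 at the consensus
#' base and `base_rel` elsewhere.  With `n_perturb > 0`, that many
#' positions per motif have their preferred base switched to a random
#' other base — emulating in vitro motif models that differ slightly from
#' the in vivo motif driving the (synthetic) splicing code.
#'
#' @param motifs motif table ([synth_motif_table()] layout).
#' @param base_rel off-consensus relative affinity (kept positive so
#'   support is never lost entirely).
#' @param n_perturb consensus positions to mis-specify per motif.
#' @param seed RNG seed for the perturbation choice.
#' @return list of [rbp_motif_set()], one per motif row.
#' @export
gen_psams <- function(motifs = synth_motif_table(), base_rel = 0.2,
                      n_perturb = 0L, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(nrow(motifs)), function(m) {
    chars <- seq_to_int(motifs$consensus[m])
    w <- length(chars)
    if (n_perturb > 0) {
      pos <- sample.int(w, min(n_perturb, w))
      for (j in pos) chars[j] <- sample(setdiff(1:4, chars[j]), 1)
    }
    rel <- matrix(base_rel, w, 4)
    rel[cbind(seq_len(w), chars)] <- 1
    rbp_motif_set(motifs$rbp[m],
                  list(psam(rel, abs_affinity = motifs$abs_affinity[m])))
  })
}

#' Generate RBNS-like bound and input read pools
#'
#' The input pool is uniform random sequence; the bound pool plants the
#' motif consensus at a random position with probability chosen so that
#' the motif k-mer frequency ratio between pools approximates `enrichment`.
#'
#' @param motif consensus string of the bound motif.
#' @param n_reads reads per pool.
#' @param read_len read length (nt).
#' @param enrichment target bound/input k-mer frequency ratio (>= 1).
#' @param seed RNG seed.
#' @return list with `bound` and `input` character vectors and the
#'   realised `plant_prob`.
#' @export
gen_rbns <- function(motif, n_reads = 1000L, read_len = 40L,
                     enrichment = 20, seed = 1L) {
  stopifnot(enrichment >= 1, read_len > nchar(motif))
  set.seed(seed)
  w <- nchar(motif)
  f0 <- (read_len - w + 1) / 4^w         # background occurrence rate/read
  p_plant <- min(1, (enrichment - 1) * f0)
  rand_read <- function() {
    paste(BASES[sample.int(4L, read_len, replace = TRUE)], collapse = "")
  }
  input <- vapply(seq_len(n_reads), function(i) rand_read(), character(1))
  bound <- vapply(seq_len(n_reads), function(i) {
    r <- rand_read()
    if (stats::runif(1) <= p_plant) {
      at <- sample.int(read_len - w + 1L, 1)
      substr(r, at, at + w - 1L) <- motif
    }
    r
  }, character(1))
  list(bound = bound, input = input, plant_prob = p_plant)
}

#' Generate eCLIP-like peaks around planted motif occurrences
#'
#' Signal peaks are centered on a sampled subset of the true occurrences
#' of the RBP (with small positional jitter); a `noise` fraction of peaks
#' is placed uniformly at random in the same genes.
#'
#' @param genome output of [gen_genome()].
#' @param rbp rbp id from the planted motif table.
#' @param noise fraction of peaks that are uniform noise (1 = all noise).
#' @param detect_frac fraction of true occurrences that yield a peak.
#' @param width_range peak width range (nt).
#' @param seed RNG seed.
#' @return peaks data frame (gene_id, start, end, rbp_id, is_control).
#' @export
gen_eclip <- function(genome, rbp, noise = 0.2, detect_frac = 0.8,
                      width_range = c(20L, 50L), seed = 1L) {
  set.seed(seed)
  occ <- genome$truth$occurrences
  occ <- occ[occ$rbp == rbp, , drop = FALSE]
  if (nrow(occ) == 0) stop("rbp has no planted occurrences: ", rbp)
  rows <- list()
  for (i in seq_len(nrow(occ))) {
    if (stats::runif(1) > detect_frac) next
    L <- nchar(genome$genes[[occ$gene[i]]]$sequence)
    w <- rint(width_range[1], width_range[2])
    center <- occ$center0[i] + sample(-3:3, 1)
    start <- max(0L, center - w %/% 2L)
    end <- min(L, start + w)
    if (end - start < 5L) next
    rows[[length(rows) + 1L]] <-
      data.frame(gene_id = occ$gene[i], start = start, end = end,
                 rbp_id = rbp, is_control = FALSE,
                 stringsAsFactors = FALSE)
  }
  n_signal <- length(rows)
  n_noise <- round(noise / max(1e-9, 1 - noise) * n_signal)
  if (noise >= 1) { rows <- list(); n_noise <- max(10L, n_signal) }
  gids <- names(genome$genes)
  for (i in seq_len(n_noise)) {
    gid <- sample(gids, 1)
    L <- nchar(genome$genes[[gid]]$sequence)
    w <- rint(width_range[1], width_range[2])
    start <- rint(0L, L - w)
    rows[[length(rows) + 1L]] <-
      data.frame(gene_id = gid, start = start, end = start + w,
                 rbp_id = rbp, is_control = FALSE,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate MPRA-like reporter segments with planted activities
#'
#' Each segment is random sequence in which each motif is planted with
#' probability `plant_prob`; its expected relative intron inclusion (RII)
#' is the sum of the planted motifs' `mpra_activity`, realised through
#' binomially distributed read counts for the two competing splice sites.
#'
#' @param motifs motif table; column `mpra_activity` gives each motif's
#'   effect on intron recognition (defaults to `-activity`: an
#'   exon-inclusion enhancer disfavours intron recognition).
#' @param n_segments,seg_len,count_depth experiment dimensions.
#' @param dataset `"donor"` (counts SD1/SD2) or `"acceptor"` (SA1/SA2).
#' @param plant_prob per-motif planting probability per segment.
#' @param activity_scale logistic scale from summed activity to the
#'   distal-site read probability.
#' @param seed RNG seed.
#' @return data frame with the segment sequence, the two read counts, and
#'   ground-truth columns (`true_activity`, per-motif presence flags).
#' @export
gen_mpra <- function(motifs = synth_motif_table(), n_segments = 400L,
                     seg_len = 40L, count_depth = 100L,
                     dataset = c("donor", "acceptor"), plant_prob = 0.35,
                     activity_scale = 0.5, seed = 1L) {
  dataset <- match.arg(dataset)
  set.seed(seed)
  if (is.null(motifs$mpra_activity)) motifs$mpra_activity <- -motifs$activity
  w <- nchar(motifs$consensus)
  segs <- list()
  for (i in seq_len(n_segments)) {
    s <- sample.int(4L, seg_len, replace = TRUE)
    present <- stats::runif(nrow(motifs)) <= plant_prob
    for (m in which(present)) {
      at <- rint(0L, seg_len - w[m])
      s <- plant_string(s, at, motifs$consensus[m])
    }
    act <- sum(motifs$mpra_activity[present])
    p_distal <- stats::plogis(activity_scale * act)
    c_distal <- stats::rbinom(1, count_depth, p_distal)
    row <- data.frame(segment = int_to_seq(s), dataset = dataset,
                      true_activity = act, stringsAsFactors = FALSE)
    if (dataset == "donor") {          # distal = SD1 (region in intron)
      row$sd1 <- c_distal; row$sd2 <- count_depth - c_distal
    } else {                           # distal = SA2
      row$sa2 <- c_distal; row$sa1 <- count_depth - c_distal
    }
    for (m in seq_len(nrow(motifs))) {
      row[[paste0("has_", motifs$rbp[m])]] <- present[m]
    }
    segs[[i]] <- row
  }
  do.call(rbind, segs)
}
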