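# Fixed Motif (FM) model: position-specific affinity matrices (PSAMs) and
# the per-position RBP affinity tracks they induce.
#
# A PSAM gives a relative affinity in [0,1] for each (position, base); the
# affinity of a window is the product over positions of the matching
# entries, times the PSAM's absolute affinity.  An RBP is represented by
# 1-5 PSAMs whose tracks are summed.  Window scores are assigned to the
# window's *center* position (offset floor(width/2)), which keeps AM/FM
# site comparisons symmetric; this convention is recorded in file headers.

#' Construct a PSAM
#'
#' @param rel_affinity width x 4 numeric matrix (columns A,C,G,T/U) with
#'   entries in `[0, 1]`; each row's maximum should be exactly 1 (the
#'   consensus base at that position).
#' @param abs_affinity positive scalar multiplying the relative affinity.
#' @param normalize if `TRUE` (default), rows are rescaled so their maximum
#'   is exactly 1; set `FALSE` to accept matrices that violate the row-max
#'   convention as-is.
#' @return object of class `psam` with fields `width`, `rel_affinity`,
#'   `abs_affinity`.
#' @export
psam <- function(rel_affinity, abs_affinity = 1, normalize = TRUE) {
  rel_affinity <- as.matrix(rel_affinity)
  stopifnot(ncol(rel_affinity) == 4, nrow(rel_affinity) >= 1,
            abs_affinity > 0)
  colnames(rel_affinity) <- BASES
  if (any(rel_affinity < 0) || any(!is.finite(rel_affinity))) {
    stop("PSAM entries must be finite and nonnegative")
  }
  mx <- apply(rel_affinity, 1, max)
  if (normalize) {
    if (any(mx <= 0)) stop("PSAM row with no positive entry")
    rel_affinity <- rel_affinity / mx
  } else if (any(rel_affinity > 1)) {
    stop("PSAM entries must lie in [0, 1] (use normalize = TRUE)")
  }
  structure(list(width = nrow(rel_affinity),
                 rel_affinity = rel_affinity,
                 abs_affinity = abs_affinity),
            class = "psam")
}

#' Construct a motif set for one RBP (1-5 PSAMs)
#' @param rbp_id character scalar.
#' @param psams list of [psam()] objects, length 1-5.
#' @export
rbp_motif_set <- function(rbp_id, psams) {
  if (inherits(psams, "psam")) psams <- list(psams)
  stopifnot(length(psams) >= 1, length(psams) <= 5,
            all(vapply(psams, inherits, logical(1), "psam")))
  structure(list(rbp_id = rbp_id, psams = psams), class = "rbp_motif_set")
}

#' Score a sequence with a single PSAM
#'
#' The value at position `i` (1-based) is
#' `abs_affinity * prod_j rel_affinity[j, base(i - c + j)]` where
#' `c = floor(width/2)` — i.e. the product over the window centered at `i` —
#' and 0 wherever the window would leave the sequence.
#'
#' @param ps a [psam()].
#' @param sequence DNA string, or an integer-coded sequence from
#'   [seq_to_int()].
#' @return nonnegative numeric vector of length `L`.
#' @export
score_psam <- function(ps, sequence) {
  s <- if (is.character(sequence)) seq_to_int(sequence) else sequence
  L <- length(s)
  w <- ps$width
  if (L < w) {
    warning("sequence shorter than PSAM width; returning all-zero track")
    return(numeric(L))
  }
  ctr <- w %/% 2L                       # 0-based center offset
  # product over the window starting at position t (1-based): acc[t]
  acc <- rep(ps$abs_affinity, L - w + 1L)
  for (j in seq_len(w)) {
    base_idx <- s[(j):(L - w + j)]
    # N (code 0): uniform 0.25 row dotted with the PSAM row, i.e. its mean
    rel <- ifelse(base_idx > 0L, ps$rel_affinity[j, pmax(base_idx, 1L)],
                  mean(ps$rel_affinity[j, ]))
    acc <- acc * rel
  }
  out <- numeric(L)
  out[(1L + ctr):(L - w + 1L + ctr)] <- acc
  out
}

#' Score a sequence with all PSAMs of an RBP (elementwise sum)
#' @param motifs an [rbp_motif_set()].
#' @inheritParams score_psam
#' @export
score_rbp <- function(motifs, sequence) {
  s <- if (is.character(sequence)) seq_to_int(sequence) else sequence
  Reduce(`+`, lapply(motifs$psams, score_psam, sequence = s))
}

#' Fixed-motif forward pass: the L x M affinity track
#'
#' @param sets list of [rbp_motif_set()] with distinct rbp ids; the channel
#'   order is the list order and is recorded in the column names.
#' @inheritParams score_psam
#' @return L x M nonnegative matrix with `colnames` = rbp ids (the
#'   "affinity track" flowing into the sparsity layer and aggregator).
#' @export
fm_forward <- function(sets, sequence) {
  ids <- vapply(sets, `[[`, character(1), "rbp_id")
  if (anyDuplicated(ids)) stop("duplicate rbp_id in motif sets")
  s <- if (is.character(sequence)) seq_to_int(sequence) else sequence
  track <- vapply(sets, score_rbp, numeric(length(s)), sequence = s)
  track <- matrix(track, nrow = length(s), ncol = length(sets),
                  dimnames = list(NULL, ids))
  track
}

## ---- PSAM disk format -----------------------------------------------------

#' Read/write PSAM sets as TSV
#'
#' Flat layout: one row per (rbp, psam, position) with columns
#' `rbp`, `psam_index`, `abs_affinity`, `pos` (1-based within the motif) and
#' `A`, `C`, `G`, `U` (or `T`; U and T are interchangeable on input — the
#' internal alphabet is DNA). A `# window scores assigned to center` header
#' comment records the window-to-position convention.
#'
#' @param path TSV path.
#' @param normalize passed to [psam()] (row-max normalisation).
#' @return list of [rbp_motif_set()].
#' @export
read_psam_tsv <- function(path, normalize = TRUE) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  base_cols <- if ("U" %in% names(tb)) c("A", "C", "G", "U") else
    c("A", "C", "G", "T")
  if (!all(base_cols %in% names(tb))) stop("PSAM TSV lacks base columns")
  sets <- lapply(split(tb, tb$rbp), function(rb) {
    psams <- lapply(split(rb, rb$psam_index), function(pb) {
      pb <- pb[order(pb$pos), , drop = FALSE]
      rel <- as.matrix(pb[, base_cols])
      dimnames(rel) <- NULL
      psam(rel, abs_affinity = pb$abs_affinity[1], normalize = normalize)
    })
    rbp_motif_set(rb$rbp[1], unname(psams))
  })
  unname(sets[unique(tb$rbp)])
}

#' @rdname read_psam_tsv
#' @param sets list of [rbp_motif_set()] to write.
#' @export
write_psam_tsv <- function(sets, path) {
  rows <- do.call(rbind, lapply(sets, function(st) {
    do.call(rbind, lapply(seq_along(st$psams), function(i) {
      ps <- st$psams[[i]]
      data.frame(rbp = st$rbp_id, psam_index = i,
                 abs_affinity = ps$abs_affinity,
                 pos = seq_len(ps$width), ps$rel_affinity,
                 stringsAsFactors = FALSE)
    }))
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# PSAM table; window scores assigned to center position", con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
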