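# Reading/writing external formats, strand resolution, label tracks and
# dataset splits.
#
# Coordinate convention: 0-based half-open everywhere internally (BED-style
# on disk).  After load_genes(), every gene is sense-strand: minus-strand
# genes are reverse-complemented and their exon coordinates reflected, so no
# downstream code ever sees strand.

#' Construct a gene record
#'
#' @param gene_id character scalar.
#' @param sequence sense-strand sequence over A/C/G/T (N allowed; lowercase
#'   and U are normalised).
#' @param exons integer matrix with two columns (start, end), 0-based
#'   half-open, in sense-strand coordinates; rows sorted and
#'   non-overlapping.
#' @param source_strand `"+"` or `"-"`: the strand the gene was annotated on
#'   before strand resolution (metadata only).
#' @return an object of class `gene_record` with fields `gene_id`,
#'   `sequence`, `exons`, `source_strand`.
#' @export
gene_record <- function(gene_id, sequence, exons, source_strand = "+") {
  sequence <- toupper(chartr("Uu", "Tt", sequence))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  L <- nchar(sequence)
  if (nrow(exons) > 0) {
    if (any(exons[, 1] >= exons[, 2])) {
      stop("malformed exon interval (start >= end) in gene ", gene_id)
    }
    if (any(exons[, 1] < 0) || any(exons[, 2] > L)) {
      stop("exon outside [0, ", L, ") in gene ", gene_id)
    }
    ord <- order(exons[, 1])
    exons <- exons[ord, , drop = FALSE]
    if (nrow(exons) > 1 &&
        any(exons[-1, 1] < exons[-nrow(exons), 2])) {
      stop("overlapping exons in gene ", gene_id)
    }
  }
  structure(list(gene_id = gene_id, sequence = sequence, exons = exons,
                 source_strand = match.arg(source_strand, c("+", "-"))),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record %s: %d nt, %d exon(s), source strand %s>\n",
              x$gene_id, nchar(x$sequence), nrow(x$exons), x$source_strand))
  invisible(x)
}

#' Load genes from FASTA + annotation, resolving strand
#'
#' Reads sequences with [Biostrings::readDNAStringSet()] and a 5-column
#' annotation TSV (`gene`, `strand`, `exon_start`, `exon_end`, `class`; one
#' row per exon, BED-style 0-based half-open coordinates on the plus
#' strand).  Minus-strand genes are reverse-complemented and exon
#' coordinates reflected (`(start, end) -> (L - end, L - start)`), so every
#' returned record is sense-strand.
#'
#' @param fasta_path path to a FASTA file.
#' @param annotation_path path to the annotation TSV (or a data frame in
#'   that layout).
#' @return named list of [gene_record()] objects.
#' @export
load_genes <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- if (is.data.frame(annotation_path)) annotation_path
         else read_annotation_tsv(annotation_path)
  missing <- setdiff(unique(ann$gene), names(seqs))
  if (length(missing) > 0) {
    stop("annotation refers to id(s) absent from FASTA: ",
         paste(missing, collapse = ", "))
  }
  genes <- lapply(unique(ann$gene), function(id) {
    rows <- ann[ann$gene == id, , drop = FALSE]
    strand <- rows$strand[1]
    sq <- as.character(seqs[[id]])
    L <- nchar(sq)
    ex <- cbind(rows$exon_start, rows$exon_end)
    if (strand == "-") {
      sq <- revcomp(sq)
      ex <- cbind(L - ex[, 2], L - ex[, 1])
    }
    gene_record(id, sq, ex, source_strand = strand)
  })
  names(genes) <- unique(ann$gene)
  genes
}

#' Read the native 5-column annotation TSV
#' @param path TSV with columns gene, strand, exon_start, exon_end, class.
#' @return data frame with one row per exon.
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene", "strand", "exon_start", "exon_end")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(ann$exon_start >= ann$exon_end)
  if (length(bad) > 0) {
    stop("malformed interval (start >= end) at annotation line ",
         bad[1] + 1L)  # +1 for the header line
  }
  if (!"class" %in% names(ann)) ann$class <- "exon"
  ann
}

#' Import exon features from a GTF file into the native annotation layout
#'
#' Only `exon` features are read; GTF 1-based closed coordinates are
#' converted to 0-based half-open. The gene id is taken from the `gene_id`
#' attribute.
#'
#' @param path path to a GTF file.
#' @return data frame in [read_annotation_tsv()] layout.
#' @export
read_annotation_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "exon",
                 logical(1))
  fields <- fields[keep]
  if (length(fields) == 0) stop("no exon features in GTF: ", path)
  gene_ids <- vapply(fields, function(f) {
    m <- regmatches(f[9], regexec('gene_id[ =]+"?([^";]+)"?', f[9]))[[1]]
    if (length(m) < 2) stop("GTF exon feature without gene_id attribute")
    m[2]
  }, character(1))
  data.frame(
    gene = gene_ids,
    strand = vapply(fields, `[`, character(1), 7),
    exon_start = vapply(fields, function(f) as.integer(f[4]) - 1L, integer(1)),
    exon_end = vapply(fields, function(f) as.integer(f[5]), integer(1)),
    class = "exon",
    stringsAsFactors = FALSE
  )
}

#' Write genes back to FASTA + annotation TSV
#'
#' Records are written as stored (sense strand, `+`), so a write/read
#' round-trip reproduces them exactly.
#' @param genes list of [gene_record()].
#' @param fasta_path,annotation_path output paths.
#' @export
write_genes <- function(genes, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(vapply(genes, `[[`, character(1),
                                          "sequence"))
  names(seqs) <- vapply(genes, `[[`, character(1), "gene_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  rows <- do.call(rbind, lapply(genes, function(g) {
    if (nrow(g$exons) == 0) return(NULL)
    data.frame(gene = g$gene_id, strand = "+",
               exon_start = g$exons[, 1], exon_end = g$exons[, 2],
               class = "exon", stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Build the per-position splice-site label track for a gene
#'
#' Label convention (documented prominently because window extraction
#' depends on it): the acceptor label sits on the *first exonic base* of
#' every exon preceded by an intron, and the donor label on the *last
#' exonic base* of every exon followed by an intron. Single-exon genes have
#' no introns and therefore an all-null track.
#'
#' @param gene a [gene_record()].
#' @return integer vector of length `nchar(gene$sequence)` over
#'   0 = null, 1 = acceptor, 2 = donor. Sites whose scoring window would
#'   run off the sequence edge are still labeled but recorded in the
#'   `edge_sites` attribute.
#' @export
make_label_track <- function(gene) {
  L <- nchar(gene$sequence)
  labels <- integer(L)
  ex <- gene$exons
  n <- nrow(ex)
  if (n == 0) stop("gene ", gene$gene_id, " has no exons")
  edge <- integer(0)
  if (n > 1) {
    for (i in seq_len(n)) {
      if (i > 1) {                      # exon preceded by an intron
        acc <- ex[i, 1]
        labels[acc + 1L] <- 1L
        if (acc < 20L || acc + 3L > L) edge <- c(edge, acc)
      }
      if (i < n) {                      # exon followed by an intron
        don <- ex[i, 2] - 1L
        labels[don + 1L] <- 2L
        if (don < 2L || don + 7L > L) edge <- c(edge, don)
      }
    }
  }
  attr(labels, "edge_sites") <- edge
  labels
}

#' Partition held-out genes into validation / gap / test by sequence length
#'
#' Genes are shuffled by `seed`, then walked in order accumulating sequence
#' length: genes entirely within the first `fractions[1]` of total length
#' form the validation set, genes entirely within the last `fractions[2]`
#' form the test set, and genes straddling the `fractions[3]` gap between
#' them are excluded (preventing near-boundary leakage).
#'
#' @param genes named list of [gene_record()].
#' @param held_out_ids gene ids to partition (the remainder are training).
#' @param fractions `(val, test, gap)` length fractions, summing to 1.
#' @param seed integer; the shuffle seed ("different random orders of genes").
#' @return list with `train_genes`, `val_genes`, `test_genes`, `gap_genes`
#'   (character vectors of gene ids, pairwise disjoint).
#' @export
make_split <- function(genes, held_out_ids, fractions = c(0.50, 0.45, 0.05),
                       seed = 1L) {
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  if (length(held_out_ids) == 0) stop("held-out pool is empty")
  if (!all(held_out_ids %in% ids)) {
    stop("held_out_ids not among gene ids: ",
         paste(setdiff(held_out_ids, ids), collapse = ", "))
  }
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  lens <- vapply(genes, function(g) nchar(g$sequence), numeric(1))
  names(lens) <- ids
  set.seed(seed)
  held <- sample(held_out_ids)
  cum_end <- cumsum(lens[held])
  total <- cum_end[length(cum_end)]
  cum_start <- cum_end - lens[held]
  b1 <- fractions[1] * total
  b2 <- (fractions[1] + fractions[3]) * total
  val <- held[cum_end <= b1 + 1e-9]
  test <- held[cum_start >= b2 - 1e-9]
  gap <- setdiff(held, c(val, test))
  if (length(val) == 0) {
    warning("validation set empty after length walk; assigning first gene")
    val <- held[1]
    test <- setdiff(test, val)
    gap <- setdiff(held, c(val, test))
  }
  if (length(test) == 0) warning("test set is empty")
  list(train_genes = setdiff(ids, held_out_ids),
       val_genes = unname(val), test_genes = unname(test),
       gap_genes = unname(gap))
}

#' Read/write a dataset split as YAML
#' @param split a list as returned by [make_split()].
#' @param path file path.
#' @export
write_split_yaml <- function(split, path) {
  yaml::write_yaml(lapply(split, as.character), path)
  invisible(NULL)
}

#' @rdname write_split_yaml
#' @export
read_split_yaml <- function(path) {
  sp <- yaml::read_yaml(path)
  lapply(sp, as.character)
}

#' Read peaks from a BED6 / narrowPeak file
#'
#' Columns: chrom (interpreted as gene id), start, end, name (rbp id),
#' score, strand; narrowPeak columns beyond the sixth are ignored.
#' Coordinates are kept 0-based half-open and validated against no gene
#' (peaks are validated at use time against the gene they reference).
#'
#' @param path BED file path.
#' @param is_control flag stored on every returned record.
#' @return data frame with columns gene_id, start, end, rbp_id, is_control.
#' @export
read_peaks_bed <- function(path, is_control = FALSE) {
  tb <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tb) < 4) stop("peak BED needs at least 4 columns")
  peaks <- data.frame(gene_id = as.character(tb[[1]]),
                      start = as.integer(tb[[2]]),
                      end = as.integer(tb[[3]]),
                      rbp_id = as.character(tb[[4]]),
                      is_control = is_control,
                      stringsAsFactors = FALSE)
  if (any(peaks$start >= peaks$end) || any(peaks$start < 0)) {
    stop("malformed peak interval in ", path)
  }
  peaks
}

#' @rdname read_peaks_bed
#' @param peaks data frame of peaks to write.
#' @export
write_peaks_bed <- function(peaks, path) {
  bed <- data.frame(peaks$gene_id, peaks$start, peaks$end, peaks$rbp_id,
                    0L, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}
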