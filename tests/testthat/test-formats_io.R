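test_that("strand resolution reflects minus-strand exons onto the sense strand", {
  plus_seq <- random_seq(100, seed = 3)
  fa <- tempfile(fileext = ".fa")
  ann <- tempfile(fileext = ".tsv")
  writeLines(c(">gplus", plus_seq, ">gminus", plus_seq), fa)
  write.table(data.frame(gene = c("gplus", "gminus"), strand = c("+", "-"),
                         exon_start = 10L, exon_end = 20L, class = "exon"),
              ann, sep = "\t", quote = FALSE, row.names = FALSE)
  genes <- load_genes(fa, ann)
  expect_equal(genes$gplus$sequence, plus_seq)
  expect_equal(unname(genes$gplus$exons[1, ]), c(10, 20))
  # brute-force coordinate reflection: (start, end) -> (L - end, L - start)
  expect_equal(unname(genes$gminus$exons[1, ]), c(80, 90))
  expect_equal(genes$gminus$sequence, samsplice:::revcomp(plus_seq))
  # the exon sequence itself matches the reverse complement of the original
  orig_exon <- substr(plus_seq, 11, 20)
  mapped <- substr(genes$gminus$sequence, 81, 90)
  expect_equal(mapped, samsplice:::revcomp(orig_exon))
})

test_that("FASTA lowercase is uppercased and ids are validated", {
  fa <- tempfile(fileext = ".fa")
  ann <- tempfile(fileext = ".tsv")
  writeLines(c(">g1", "acgtacgtacgtacgtacgt"), fa)
  write.table(data.frame(gene = "g1", strand = "+", exon_start = 2L,
                         exon_end = 8L, class = "exon"),
              ann, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- load_genes(fa, ann)$g1
  expect_equal(g$sequence, "ACGTACGTACGTACGTACGT")
  write.table(data.frame(gene = "missing", strand = "+", exon_start = 2L,
                         exon_end = 8L, class = "exon"),
              ann, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_genes(fa, ann), "missing")
})

test_that("malformed intervals are rejected with their line number", {
  ann <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene = c("g1", "g1"), strand = "+",
                         exon_start = c(2L, 30L), exon_end = c(8L, 20L),
                         class = "exon"),
              ann, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_annotation_tsv(ann), "line 3")
  expect_error(gene_record("g", "ACGTACGT", rbind(c(5, 3))), "start >= end")
})

test_that("write/read round-trip reproduces gene records exactly", {
  genes <- tiny_genes()
  fa <- tempfile(fileext = ".fa")
  ann <- tempfile(fileext = ".tsv")
  write_genes(genes, fa, ann)
  back <- load_genes(fa, ann)
  for (id in names(genes)) {
    expect_equal(back[[id]]$sequence, genes[[id]]$sequence)
    expect_equal(back[[id]]$exons, genes[[id]]$exons)
  }
})

test_that("GTF importer reads exon features with 1-based to 0-based shift", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    "# comment",
    paste("g1", "src", "exon", "11", "20", ".", "+", ".",
          'gene_id "g1"; transcript_id "t1";', sep = "\t"),
    paste("g1", "src", "CDS", "11", "18", ".", "+", ".",
          'gene_id "g1";', sep = "\t"),
    paste("g2", "src", "exon", "1", "5", ".", "-", ".",
          'gene_id "g2";', sep = "\t")), gtf)
  ann <- read_annotation_gtf(gtf)
  expect_equal(nrow(ann), 2L)           # CDS feature ignored
  expect_equal(ann$exon_start, c(10L, 0L))
  expect_equal(ann$exon_end, c(20L, 5L))
  expect_equal(ann$strand, c("+", "-"))
})

test_that("label track marks first/last exonic bases of intron-flanked exons", {
  # single exon: no introns, all null
  g1 <- gene_record("s", random_seq(60, seed = 5), rbind(c(10, 40)))
  expect_true(all(make_label_track(g1) == 0))
  # two exons: donor at 49, acceptor at 100 (0-based)
  g2 <- gene_record("d", random_seq(160, seed = 6),
                    rbind(c(0, 50), c(100, 150)))
  lab <- make_label_track(g2)
  expect_equal(which(lab == 2L) - 1L, 49)
  expect_equal(which(lab == 1L) - 1L, 100)
  # three exons: 2 donors, 2 acceptors; counts match annotated sites
  g3 <- tiny_genes()$g1
  lab3 <- make_label_track(g3)
  expect_equal(sum(lab3 == 1L), 2L)
  expect_equal(sum(lab3 == 2L), 2L)
})

test_that("length-weighted split walks the 50/45/5 boundaries", {
  genes <- lapply(1:10, function(i)
    gene_record(paste0("g", i), random_seq(100, seed = i), rbind(c(10, 90))))
  names(genes) <- paste0("g", 1:10)
  sp <- make_split(genes, names(genes), seed = 7)
  expect_length(sp$val_genes, 5L)
  expect_length(sp$test_genes, 4L)
  expect_length(sp$gap_genes, 1L)
  expect_length(sp$train_genes, 0L)
  # same seed twice: identical split
  sp2 <- make_split(genes, names(genes), seed = 7)
  expect_identical(sp, sp2)
  # disjointness across seeds
  for (seed in 1:5) {
    s <- suppressWarnings(make_split(genes, names(genes)[1:6], seed = seed))
    all_ids <- c(s$train_genes, s$val_genes, s$test_genes, s$gap_genes)
    expect_equal(anyDuplicated(all_ids), 0L)
    expect_setequal(c(s$val_genes, s$test_genes, s$gap_genes),
                    names(genes)[1:6])
  }
  # degenerate single-gene pool: val gets it, test empty, warnings raised
  warns <- testthat::capture_warnings(sp1 <- make_split(genes, "g1",
                                                        seed = 1))
  expect_true(any(grepl("empty", warns)))
  expect_equal(sp1$val_genes, "g1")
  expect_length(sp1$test_genes, 0L)
  expect_error(make_split(genes, character(0)), "empty")
})

test_that("split YAML round-trips", {
  genes <- tiny_genes()
  sp <- suppressWarnings(make_split(genes, names(genes), seed = 2))
  path <- tempfile(fileext = ".yaml")
  write_split_yaml(sp, path)
  expect_equal(read_split_yaml(path)[c("val_genes", "test_genes")],
               sp[c("val_genes", "test_genes")])
})

test_that("peak BED round-trips and validates intervals", {
  peaks <- data.frame(gene_id = c("g1", "g2"), start = c(5L, 0L),
                      end = c(25L, 40L), rbp_id = c("RBPA", "RBPB"),
                      is_control = FALSE, stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_peaks_bed(peaks, path)
  back <- read_peaks_bed(path)
  expect_equal(back, peaks)
  writeLines("g1\t30\t10\tX\t0\t+", path)
  expect_error(read_peaks_bed(path), "malformed")
})
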