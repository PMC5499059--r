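# Library profiling, strand-specificity, detection, expression correlation

make_reads <- function(path, pos1, rname = "chrA", flag = 0L, cigar = "50M",
                       len = 50L, qname = NULL) {
  n <- length(pos1)
  if (is.null(qname)) qname <- sprintf("r%03d", seq_len(n))
  make_sam(path, qname = qname, flag = flag, rname = rname, pos1 = pos1,
           cigar = cigar, seq = vapply(rep(len, n), function(k)
             strrep("A", k), character(1)))
}

test_that("profile_library counts categories and assigns genes", {
  idx <- fixture_index()
  f <- tempfile(fileext = ".sam")
  # 10 reads fully inside exon 1 of geneA, none duplicate
  make_reads(f, pos1 = rep(1011L, 10))
  out <- profile_library(read_alignments(f), idx)
  expect_equal(out$report$pct_exonic, 1.0)
  expect_equal(sum(out$expression$read_count), 10L)
  expect_equal(out$expression[gene_id == "geneA"]$read_count, 10L)
  expect_equal(genes_detected(out$expression, 1L), 1L)

  # 20 reads: 10 exonic, 6 intronic, 4 intergenic -> (0.5, 0.3, 0.2)
  make_reads(f, pos1 = c(rep(1011L, 10), rep(1111L, 6), rep(30001L, 4)))
  out2 <- profile_library(read_alignments(f), idx)
  expect_equal(out2$report$pct_exonic, 0.5)
  expect_equal(out2$report$pct_intronic, 0.3)
  expect_equal(out2$report$pct_intergenic, 0.2)
  expect_equal(out2$report$pct_exonic + out2$report$pct_intronic +
                 out2$report$pct_intergenic, 1, tolerance = 1e-9)

  # 8 of 40 mapped reads on chrM -> pct_mitochondrial 0.20
  make_reads(f, pos1 = c(rep(1011L, 32), rep(201L, 8)),
             rname = c(rep("chrA", 32), rep("chrM", 8)))
  out3 <- profile_library(read_alignments(f), idx)
  expect_equal(out3$report$pct_mitochondrial, 0.20)
  # chrM reads sit in the mt gene's exon -> rRNA untouched
  expect_equal(out3$report$pct_rRNA, 0)

  # reads in the rRNA gene count toward pct_rRNA
  make_reads(f, pos1 = c(rep(8011L, 5), rep(1011L, 15)))
  out4 <- profile_library(read_alignments(f), idx)
  expect_equal(out4$report$pct_rRNA, 0.25)
})

test_that("duplicate-flagged reads are excluded from all metrics except duplicate rate", {
  idx <- fixture_index()
  f <- tempfile(fileext = ".sam")
  make_reads(f, pos1 = c(rep(1011L, 5), rep(1111L, 5)),
             flag = c(rep(0L, 5), rep(1024L, 5)))
  out <- profile_library(read_alignments(f), idx)
  expect_equal(out$report$pct_exonic, 1.0)     # the 5 intronic reads are dups
  expect_equal(out$report$duplicate_rate, 0.5)
  expect_equal(sum(out$expression$read_count), 5L)
})

test_that("rpkm follows the definition and zero iff count zero", {
  idx <- fixture_index()
  f <- tempfile(fileext = ".sam")
  make_reads(f, pos1 = rep(1011L, 10))
  expr <- profile_library(read_alignments(f), idx)$expression
  a <- expr[gene_id == "geneA"]
  # geneA exonic length 200; 10 assigned reads total
  expect_equal(a$exonic_length, 200L)
  expect_equal(a$rpkm, 10 / (200 / 1e3) / (10 / 1e6))
  expect_true(all((expr$rpkm == 0) == (expr$read_count == 0L)))
})

test_that("strand_specificity counts junctions with zero antisense reads", {
  # 100 junctions, one sense spanning read each; 3 junctions also get an
  # antisense read -> 97/100
  n <- 100L
  ex <- data.frame(
    contig = "chrA", strand = "+",
    start = as.integer(rbind(seq(0, by = 1000L, length.out = n) + 100L,
                             seq(0, by = 1000L, length.out = n) + 400L)),
    end = as.integer(rbind(seq(0, by = 1000L, length.out = n) + 200L,
                           seq(0, by = 1000L, length.out = n) + 500L)),
    gene_id = rep(sprintf("g%03d", 1:n), each = 2),
    transcript_id = rep(sprintf("t%03d", 1:n), each = 2))
  g <- tempfile(fileext = ".gtf")
  make_gtf(g, ex)
  idx <- parse_gtf(g)
  expect_equal(nrow(idx$junctions), n)

  starts <- seq(0, by = 1000L, length.out = n) + 171L  # 30M200N45M spans
  f <- tempfile(fileext = ".sam")
  make_sam(f,
    qname = c(sprintf("s%03d", 1:n), sprintf("a%03d", 1:3)),
    flag = c(rep(131L, n), rep(67L, 3)),   # read2 fwd = sense; read1 fwd = anti
    rname = "chrA",
    pos1 = c(starts, starts[1:3]),
    cigar = "30M200N45M",
    seq = strrep("A", 75),
    contigs = c(chrA = 200000L, chrM = 20000L))
  ss <- strand_specificity(read_alignments(f), idx)
  expect_equal(ss$value, 0.97)
  expect_equal(ss$junctions_observed, 100L)

  # literal denominator divides by all annotated junctions
  f2 <- tempfile(fileext = ".sam")
  make_sam(f2, qname = "s1", flag = 131L, rname = "chrA", pos1 = starts[1],
           cigar = "30M200N45M", seq = strrep("A", 75),
           contigs = c(chrA = 200000L, chrM = 20000L))
  lit <- strand_specificity(read_alignments(f2), idx,
                            literal_denominator = TRUE)
  expect_equal(lit$value, 1.0)  # no junction has an antisense read
  expect_equal(lit$junctions_observed, 1L)

  # no spanning reads -> NA with warning
  f3 <- tempfile(fileext = ".sam")
  make_sam(f3, qname = "x", flag = 0L, rname = "chrA", pos1 = 10L,
           cigar = "75M", seq = strrep("A", 75),
           contigs = c(chrA = 200000L, chrM = 20000L))
  expect_warning(ss0 <- strand_specificity(read_alignments(f3), idx),
                 "no junction")
  expect_true(is.na(ss0$value))
})

test_that("intron/exon ratio matches construction", {
  idx <- fixture_index()
  f <- tempfile(fileext = ".sam")
  make_reads(f, pos1 = c(rep(1011L, 10), rep(1111L, 6)))
  expect_equal(intron_exon_ratio(read_alignments(f), idx), 0.6)
  make_reads(f, pos1 = rep(1011L, 10))
  expect_equal(intron_exon_ratio(read_alignments(f), idx), 0)
  make_reads(f, pos1 = rep(1111L, 3))
  expect_warning(r <- intron_exon_ratio(read_alignments(f), idx),
                 "no exonic")
  expect_true(is.na(r))
})

test_that("genes_detected is a simple monotone threshold count", {
  expr <- data.table::data.table(gene_id = c("a", "b", "c"),
                                 read_count = c(5L, 1L, 0L),
                                 exonic_length = 1000L, rpkm = 0)
  expect_equal(genes_detected(expr, 1L), 2L)
  expect_equal(genes_detected(expr, 5L), 1L)
  counts <- vapply(1:6, function(k) genes_detected(expr, k), integer(1))
  expect_true(all(diff(counts) <= 0L))
})

test_that("expression correlation: self, scale shift, and oracle agreement", {
  x <- sim_small()
  md <- mark_duplicates(x$sim$alignments)
  expr <- profile_library(md$alignments, x$idx)$expression
  expect_equal(expression_correlation(expr, expr), 1.0)

  doubled <- data.table::copy(expr)[, rpkm := rpkm * 2]
  expect_gt(expression_correlation(expr, doubled), 0.999)

  # naive two-pass Pearson agrees with the package path to 1e-12
  set.seed(42)
  for (k in 1:100) {
    n <- sample(5:50, 1)
    a <- data.table::data.table(gene_id = sprintf("g%02d", 1:n),
                                read_count = 1L, exonic_length = 1000L,
                                rpkm = runif(n, 0, 100))
    bb <- data.table::copy(a)[, rpkm := runif(n, 0, 100)]
    got <- expression_correlation(a, bb, pseudocount = 0.1)
    want <- oracle_pearson(log2(a$rpkm + 0.1), log2(bb$rpkm + 0.1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("replicate libraries from identical expression weights correlate highly", {
  # deep coverage: every expressed gene is well-sampled, so the fixed 0.1
  # pseudocount is negligible against detected RPKMs
  cfg1 <- simulation_config(seed = 31, n_fragments = 20000, n_genes = 60,
                            expression_dispersion = 0.5)
  ref <- generate_reference_and_annotation(cfg1)
  idx <- parse_gtf(ref$gtf_path)
  sim1 <- simulate_library(cfg1, ref)
  # two disjoint-seed half-depth resamples of one library share the same
  # expression truth but different fragment draws
  a1 <- downsample(sim1$alignments, 8000, seed = 1)
  a2 <- downsample(sim1$alignments, 8000, seed = 2)
  x1 <- profile_library(mark_duplicates(a1)$alignments, idx)$expression
  x2 <- profile_library(mark_duplicates(a2)$alignments, idx)$expression
  expect_gt(expression_correlation(x1, x2), 0.98)
})
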