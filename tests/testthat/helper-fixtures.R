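# Hand-built fixtures shared across test files. Everything is generated in
# code at test time; nothing binary is stored.

# Write a SAM text file from record vectors (1-based SAM convention input).
# Fields not supplied default to sensible single-end mapped values.
make_sam <- function(path, qname, flag, rname, pos1, cigar, seq,
                     rnext = "*", pnext1 = 0L, tlen = 0L, mapq = 60L,
                     qual = NULL,
                     contigs = c(chrA = 100000L, chrB = 50000L,
                                 chrM = 20000L)) {
  n <- length(qname)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  qname, rep_len(flag, n), rep_len(rname, n),
                  rep_len(pos1, n), rep_len(mapq, n), rep_len(cigar, n),
                  rep_len(rnext, n), rep_len(pnext1, n), rep_len(tlen, n),
                  seq, rep_len(qual, n))
  writeLines(c(hdr, body), path)
  path
}

# Write a small GTF from an exon table (0-based half-open start/end).
make_gtf <- function(path, exons) {
  at <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                exons$gene_id, exons$transcript_id,
                if (is.null(exons$biotype)) "protein_coding" else exons$biotype)
  lines <- sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
                   exons$contig, exons$start + 1L, exons$end, exons$strand,
                   at)
  writeLines(lines, path)
  path
}

# A two-gene annotation used throughout: geneA (+, two exons with a
# junction), geneB (-, two exons), one rRNA gene and one chrM gene.
fixture_index <- function() {
  exons <- data.frame(
    contig = c("chrA", "chrA", "chrA", "chrA", "chrA", "chrM"),
    start = c(1000L, 1200L, 5000L, 5500L, 8000L, 100L),
    end = c(1100L, 1300L, 5200L, 5700L, 9500L, 15000L),
    strand = c("+", "+", "-", "-", "+", "+"),
    gene_id = c("geneA", "geneA", "geneB", "geneB", "rrna1", "mt1"),
    transcript_id = c("txA", "txA", "txB", "txB", "rtx1", "mtx1"),
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "protein_coding", "rRNA", "protein_coding"))
  gtf <- tempfile(fileext = ".gtf")
  make_gtf(gtf, exons)
  parse_gtf(gtf, mito_contig = "chrM")
}

# random read sequence of length n
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# a small simulated library for reuse (memoised per test run)
sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = 101, n_fragments = 2000)
      ref <- generate_reference_and_annotation(cfg)
      idx <- parse_gtf(ref$gtf_path)
      sim <- simulate_library(cfg, ref)
      cache <<- list(cfg = cfg, ref = ref, idx = idx, sim = sim)
    }
    cache
  }
})
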