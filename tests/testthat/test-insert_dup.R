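# Insert size, pair-preserving downsampling, duplicate marking

pair_sam <- function(path, qname, pos1_1, pos1_2, tlen, rname = "chrM",
                     cigar1 = "50M", cigar2 = "50M",
                     flag1 = 99L, flag2 = 147L, qual = NULL) {
  n <- length(qname)
  make_sam(path,
    qname = rep(qname, each = 2),
    flag = as.integer(rbind(rep_len(flag1, n), rep_len(flag2, n))),
    rname = rname,
    pos1 = as.integer(rbind(pos1_1, pos1_2)),
    cigar = as.character(rbind(rep_len(cigar1, n), rep_len(cigar2, n))),
    seq = strrep("A", 50),
    rnext = "=",
    pnext1 = as.integer(rbind(pos1_2, pos1_1)),
    tlen = as.integer(rbind(tlen, -tlen)),
    qual = qual)
}

test_that("insert size comes from the leftmost mate's template length", {
  f <- tempfile(fileext = ".sam")
  pair_sam(f, "p1", 101L, 331L, 280L)
  d <- insert_size_distribution(read_alignments(f), "chrM")
  expect_equal(d$histogram$insert, 280L)
  expect_equal(d$histogram$n, 1L)
  expect_equal(d$mean, 280)
  expect_equal(d$pairs_used, 1L)

  # pairs on other contigs, spliced pairs and oversized inserts are excluded
  pair_sam(f, c("p1", "p2", "p3"), c(101L, 101L, 101L),
           c(331L, 331L, 5001L), c(280L, 280L, 4950L),
           rname = c("chrA", "chrA", "chrM", "chrM", "chrM", "chrM"),
           cigar1 = c("50M", "20M100N30M", "50M"))
  expect_warning(d2 <- insert_size_distribution(read_alignments(f), "chrM"),
                 "no qualifying pairs")
  expect_true(is.na(d2$mean))
  expect_equal(d2$pairs_used, 0L)

  expect_error(insert_size_distribution(read_alignments(f), "chrQ"),
               "absent from alignment header")
})

test_that("simulated mitochondrial pairs recover the fragment distribution", {
  cfg <- simulation_config(seed = 40, n_fragments = 5000, mito_fraction = 1,
                           rrna_fraction = 0, intronic_fraction = 0,
                           intergenic_fraction = 0, spikein_fraction = 0,
                           duplication_mean_extra = 0)
  ref <- generate_reference_and_annotation(cfg)
  sim <- simulate_library(cfg, ref)
  d <- insert_size_distribution(sim$alignments, "chrM")
  expect_equal(d$pairs_used, 5000L)
  expect_lt(abs(d$mean - 300), 2 * 30 / sqrt(5000))
  expect_gt(d$sd, 27); expect_lt(d$sd, 33)
  expect_equal(sum(d$histogram$n), d$pairs_used)
  expect_gte(d$median, min(d$histogram$insert))
  expect_lte(d$median, max(d$histogram$insert))
})

test_that("downsample keeps exact fragment counts, both mates, and is seeded", {
  f <- tempfile(fileext = ".sam")
  pair_sam(f, sprintf("p%02d", 1:10), seq(101L, by = 500L, length.out = 10),
           seq(331L, by = 500L, length.out = 10), 280L)
  aln <- read_alignments(f)
  expect_equal(nrow(downsample(aln, 10, seed = 1)), nrow(aln))

  d1 <- downsample(aln, 4, seed = 7)
  d2 <- downsample(aln, 4, seed = 7)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_equal(length(unique(d1$qname)), 4L)
  # brute-force: every kept name appears with both mates
  for (qn in unique(d1$qname))
    expect_equal(sum(d1$qname == qn), sum(aln$qname == qn))
  expect_error(downsample(aln, 11, seed = 1), "exceeds distinct fragment")
  # a different seed gives a different (valid) subset eventually
  picks <- vapply(1:10, function(s)
    paste(sort(unique(downsample(aln, 4, seed = s)$qname)), collapse = ","),
    character(1))
  expect_gt(length(unique(picks)), 1L)
})

test_that("mark_duplicates flags coordinate-sharing fragments, keeps the best", {
  f <- tempfile(fileext = ".sam")
  # two pairs at identical coordinates, a third distinct
  pair_sam(f, c("a", "b", "c"), c(101L, 101L, 901L), c(331L, 331L, 1131L),
           280L)
  md <- mark_duplicates(read_alignments(f))
  expect_equal(md$summary$fragments_total, 3L)
  expect_equal(md$summary$duplicate_fragments, 1L)
  expect_equal(md$summary$duplicate_rate, 1 / 3)
  flagged <- unique(md$alignments$qname[bitwAnd(md$alignments$flag,
                                                1024L) > 0L])
  expect_equal(flagged, "b")  # equal qualities -> lexicographically first kept
  # both mates of the duplicate are flagged
  expect_equal(sum(bitwAnd(md$alignments$flag, 1024L) > 0L), 2L)

  # higher summed base quality wins over name order
  pair_sam(f, c("a", "b"), c(101L, 101L), c(331L, 331L), 280L,
           qual = c(strrep("#", 50), strrep("#", 50),
                    strrep("I", 50), strrep("I", 50)))
  md2 <- mark_duplicates(read_alignments(f))
  expect_equal(unique(md2$alignments$qname[bitwAnd(md2$alignments$flag,
                                                   1024L) > 0L]), "a")

  # distinct coordinates -> nothing flagged
  pair_sam(f, c("a", "b"), c(101L, 701L), c(331L, 931L), 280L)
  expect_equal(mark_duplicates(read_alignments(f))$summary$duplicate_rate, 0)
})

test_that("soft clips are backed out of the duplicate key", {
  f <- tempfile(fileext = ".sam")
  # pair b's read1 is soft-clipped by 5 at the start but shares the
  # unclipped 5' position with pair a
  pair_sam(f, c("a", "b"), c(101L, 106L), c(331L, 331L), 280L,
           cigar1 = c("50M", "5S45M"))
  md <- mark_duplicates(read_alignments(f))
  expect_equal(md$summary$duplicate_fragments, 1L)
})

test_that("duplicate rate is invariant under record shuffling", {
  x <- sim_small()
  aln <- x$sim$alignments
  md1 <- mark_duplicates(aln)
  set.seed(1)
  shuf <- aln[sample(nrow(aln))]
  data.table::setattr(shuf, "contigs", attr(aln, "contigs"))
  md2 <- mark_duplicates(shuf)
  expect_equal(md2$summary$duplicate_rate, md1$summary$duplicate_rate)
  expect_setequal(
    unique(md1$alignments$qname[bitwAnd(md1$alignments$flag, 1024L) > 0L]),
    unique(md2$alignments$qname[bitwAnd(md2$alignments$flag, 1024L) > 0L]))
})

test_that("duplicate-rate ordering tracks the duplication multiplier", {
  for (s in 1:3) {
    lo <- simulation_config(seed = 60 + s, n_fragments = 3000,
                            duplication_mean_extra = 0.1,
                            spikein_fraction = 0)
    hi <- simulation_config(seed = 60 + s, n_fragments = 3000,
                            duplication_mean_extra = 0.1 * 1.8,
                            spikein_fraction = 0)
    ref <- generate_reference_and_annotation(lo)
    r_lo <- mark_duplicates(simulate_library(lo, ref)$alignments)$summary
    r_hi <- mark_duplicates(simulate_library(hi, ref)$alignments)$summary
    expect_gt(r_hi$duplicate_rate, r_lo$duplicate_rate)
  }
})
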