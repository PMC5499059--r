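# Mismatch counting, spike-in pool extraction, realignment, dose-response

test_that("base_error_rate counts substitutions over M bases only", {
  ref <- c(chrA = paste(rep("ACGT", 50), collapse = ""))
  f <- tempfile(fileext = ".sam")
  perfect <- substr(ref[["chrA"]], 11, 85)
  make_sam(f, qname = "p", flag = 0L, rname = "chrA", pos1 = 11L,
           cigar = "75M", seq = perfect, contigs = c(chrA = 200L))
  tal <- base_error_rate(read_alignments(f), ref)
  expect_equal(tal$mismatches, 0L)
  expect_equal(tal$aligned_bases, 75L)

  mut <- perfect
  for (p in c(3, 30, 60)) substr(mut, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(mut, p, p))[1]
  make_sam(f, qname = "m", flag = 0L, rname = "chrA", pos1 = 11L,
           cigar = "75M", seq = mut, contigs = c(chrA = 200L))
  tal2 <- base_error_rate(read_alignments(f), ref)
  expect_equal(tal2$mismatches, 3L)
  expect_equal(tal2$rate, 3 / 75)
  expect_equal(tal2$rate_per_kb, 40)

  # soft-clipped and inserted bases are excluded from both sides
  make_sam(f, qname = "s", flag = 0L, rname = "chrA", pos1 = 11L,
           cigar = "5S30M2I38M", seq = paste0("TTTTT", substr(perfect, 1, 30),
                                              "GG", substr(perfect, 31, 68)),
           contigs = c(chrA = 200L))
  tal3 <- base_error_rate(read_alignments(f), ref)
  expect_equal(tal3$aligned_bases, 68L)
  expect_equal(tal3$mismatches, 0L)

  # masking every mismatch position zeroes the tally
  mask <- data.frame(contig = "chrA", pos = c(12L, 39L, 69L))  # 0-based
  tal4 <- base_error_rate(read_alignments(
    make_sam(f, qname = "m", flag = 0L, rname = "chrA", pos1 = 11L,
             cigar = "75M", seq = mut, contigs = c(chrA = 200L))), ref,
    mask = mask)
  expect_equal(tal4$mismatches, 0L)
  expect_equal(tal4$masked_bases, 3L)
  expect_equal(tal4$aligned_bases, 72L)

  expect_error(base_error_rate(read_alignments(f), c(chrZ = "ACGT")),
               "absent from reference")
})

test_that("substitution-rate recovery is unbiased across rates and seeds", {
  for (r in c(0.001, 0.003, 0.01)) for (s in 1:3) {
    cfg <- simulation_config(seed = 100 + s, n_fragments = 1500,
                             substitution_rate = r,
                             duplication_mean_extra = 0,
                             spikein_fraction = 0)
    ref <- generate_reference_and_annotation(cfg)
    sim <- simulate_library(cfg, ref)
    tal <- base_error_rate(sim$alignments, ref$reference)
    se <- sqrt(r * (1 - r) / tal$aligned_bases)
    expect_lt(abs(tal$rate - r), 2.576 * se + 2 * se)  # 99% CI + slack
  }
})

test_that("extract_spikein_pool selects pairs with any unmapped mate", {
  f <- tempfile(fileext = ".sam")
  # 5 fully mapped pairs, 2 pairs with one unmapped mate, 1 both unmapped
  qn <- rep(sprintf("p%d", 1:8), each = 2)
  flags <- c(rep(c(99L, 147L), 5),               # mapped pairs
             73L, 133L, 73L, 133L,               # one mate unmapped
             77L, 141L)                          # both unmapped
  rn <- ifelse(bitwAnd(flags, 4L) > 0L, "*", "chrA")
  p1 <- ifelse(rn == "*", 0L, 101L)
  make_sam(f, qname = qn, flag = flags, rname = rn, pos1 = p1,
           cigar = ifelse(rn == "*", "*", "10M"), seq = strrep("A", 10))
  pool <- extract_spikein_pool(read_alignments(f))
  expect_setequal(unique(pool$qname), c("p6", "p7", "p8"))
  expect_equal(nrow(pool), 6L)

  # all mapped -> empty pool; brute-force flag scan agrees
  make_sam(f, qname = rep(c("a", "b"), each = 2), flag = rep(c(99L, 147L), 2),
           rname = "chrA", pos1 = 101L, cigar = "10M", seq = strrep("A", 10))
  expect_equal(nrow(extract_spikein_pool(read_alignments(f))), 0L)

  x <- sim_small()
  pool2 <- extract_spikein_pool(x$sim$alignments)
  want <- unique(x$sim$alignments$qname[
    bitwAnd(x$sim$alignments$flag, 4L) > 0L |
      bitwAnd(x$sim$alignments$flag, 8L) > 0L])
  expect_setequal(unique(pool2$qname), want)
})

test_that("align_to_panel: verbatim, degraded and truth-labelled reads", {
  x <- sim_small()
  panel <- x$ref$panel
  f <- tempfile(fileext = ".sam")
  # read copied verbatim from panel member 7
  v <- substr(panel$sequence[7], 41, 115)
  make_sam(f, qname = "v", flag = 77L, rname = "*", pos1 = 0L, cigar = "*",
           seq = v)
  r1 <- align_to_panel(read_alignments(f), panel)
  expect_equal(r1$assignments$id, panel$id[7])
  expect_equal(r1$assignments$identity, 1.0)

  # 10% scattered substitutions -> below min_identity 0.95 -> unassigned
  deg <- v
  idxs <- seq(5, 75, by = 10)
  for (p in idxs) substr(deg, p, p) <-
      setdiff(c("A", "C", "G", "T"), substr(deg, p, p))[1]
  make_sam(f, qname = "d", flag = 77L, rname = "*", pos1 = 0L, cigar = "*",
           seq = deg)
  r2 <- align_to_panel(read_alignments(f), panel)
  expect_equal(r2$assigned_total, 0L)
  expect_equal(r2$pool_size, 1L)

  # simulated pool at error 0.005: nearly all reads assigned to true source
  cfg <- simulation_config(seed = 77, n_fragments = 600,
                           spikein_fraction = 1, substitution_rate = 0.005,
                           spike_decoy_fraction = 0, rrna_fraction = 0,
                           mito_fraction = 0, intronic_fraction = 0,
                           intergenic_fraction = 0)
  ref <- generate_reference_and_annotation(cfg)
  sim <- simulate_library(cfg, ref)
  pool <- extract_spikein_pool(sim$alignments)
  res <- align_to_panel(pool, ref$panel)
  truth <- sim$truth$fragments[, .(qname, source)]
  m <- merge(res$assignments, truth, by = "qname")
  expect_gte(nrow(m) / res$pool_size, 0.99)
  expect_true(all(m$id == m$source))
  # deterministic under read order shuffling
  shuf <- pool[rev(seq_len(nrow(pool)))]
  res2 <- align_to_panel(shuf, ref$panel)
  expect_equal(data.table::setorder(data.table::copy(res2$assignments),
                                    qname, mate),
               data.table::setorder(data.table::copy(res$assignments),
                                    qname, mate))
})

test_that("spike-in error rate is per 1000 nt and recovers the truth", {
  cfg <- simulation_config(seed = 78, n_fragments = 800, spikein_fraction = 1,
                           substitution_rate = 0, spike_decoy_fraction = 0,
                           rrna_fraction = 0, mito_fraction = 0,
                           intronic_fraction = 0, intergenic_fraction = 0)
  ref <- generate_reference_and_annotation(cfg)
  sim <- simulate_library(cfg, ref)
  res <- align_to_panel(extract_spikein_pool(sim$alignments), ref$panel)
  expect_equal(spikein_error_rate(res), 0)

  cfg2 <- simulation_config(seed = 79, n_fragments = 1500,
                            spikein_fraction = 1, substitution_rate = 0.002,
                            spike_decoy_fraction = 0, rrna_fraction = 0,
                            mito_fraction = 0, intronic_fraction = 0,
                            intergenic_fraction = 0)
  sim2 <- simulate_library(cfg2, generate_reference_and_annotation(cfg2))
  ref2 <- generate_reference_and_annotation(cfg2)
  res2 <- align_to_panel(extract_spikein_pool(sim2$alignments), ref2$panel)
  per_base <- spikein_error_rate(res2) / 1000
  n <- sum(res2$assignments$aligned)
  se <- sqrt(0.002 * 0.998 / n)
  expect_lt(abs(per_base - 0.002), 2.576 * se + 2 * se)
  expect_gt(n, 100000)
})

test_that("dose-response is exactly 1 for proportional counts and high for Poisson", {
  x <- sim_small()
  panel <- x$ref$panel
  w <- panel$concentration * panel$length / 1000
  prop <- list(per_spikein = data.table::data.table(
    id = panel$id, assigned_reads = pmax(1L, as.integer(round(w * 50))),
    observed_abundance = (w * 50) / (panel$length / 1000)))
  expect_equal(spikein_dose_response(prop, panel), 1.0, tolerance = 1e-12)

  expect_warning(
    r <- spikein_dose_response(list(per_spikein = data.table::data.table(
      id = panel$id, assigned_reads = 0L, observed_abundance = 0)), panel),
    "fewer than 3")
  expect_true(is.na(r))
})
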