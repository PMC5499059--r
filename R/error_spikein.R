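# Base error rate by mismatch counting against the reference, and the
# spike-in analysis: pool extraction (pairs with an unmapped mate), a
# gapless seed-and-extend realigner against the panel, dose-response
# correlation on the known concentration axis, and the spike-in error rate
# per 1000 nt.

# Accept DNAStringSet, named character vector, or FASTA path as a reference.
.as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && is.null(names(reference)))
    reference <- Biostrings::readDNAStringSet(reference)
  if (methods::is(reference, "DNAStringSet"))
    reference <- stats::setNames(as.character(reference), names(reference))
  if (!is.character(reference) || is.null(names(reference)))
    stop("reference must be a named character vector, DNAStringSet or FASTA path")
  names(reference) <- sub("\\s.*$", "", names(reference))
  reference
}

#' Base error rate by mismatch counting
#'
#' Counts substitutions only, over M-operation bases with base quality at
#' least `min_baseq`, using mapped records that are not duplicate-flagged.
#' Soft-clipped, inserted, deleted and N-skipped bases enter neither
#' numerator nor denominator. Known variant positions can be
#' excluded from both through `mask`. Because real variants are counted as
#' errors, the absolute value overstates the true error rate by the variant
#' frequency; the statistic is intended for relative comparisons between
#' libraries.
#'
#' @param aln A `qc_alignments` table (mapped records are used).
#' @param reference Named character vector / `DNAStringSet` / FASTA path
#'   containing every contig appearing in `aln`.
#' @param mask Optional data.frame of (`contig`, `pos`) 0-based positions to
#'   exclude.
#' @param min_baseq Minimum base quality (Phred, default 0 = keep all).
#' @return A `mismatch_tally` list: `aligned_bases`, `mismatches`,
#'   `masked_bases`, `per_contig` breakdown, `rate`, `rate_per_kb`.
#' @export
base_error_rate <- function(aln, reference, mask = NULL, min_baseq = 0L) {
  reference <- .as_reference(reference)
  sub <- aln[.usable(aln)]  # mapped, not duplicate-flagged
  out0 <- structure(list(aligned_bases = 0L, mismatches = 0L,
                         masked_bases = 0L,
                         per_contig = data.table::data.table(
                           contig = character(), aligned_bases = integer(),
                           mismatches = integer()),
                         rate = NA_real_, rate_per_kb = NA_real_),
                    class = "mismatch_tally")
  if (nrow(sub) == 0L) return(out0)
  miss <- setdiff(unique(sub$rname), names(reference))
  if (length(miss)) stop("contig(s) absent from reference: ",
                         paste(miss, collapse = ", "))
  blocks <- .m_blocks(sub$cigar, sub$pos)
  blocks[, rname := sub$rname[idx]]
  blen <- blocks$gend - blocks$gstart
  read_part <- substring(sub$seq[blocks$idx], blocks$qstart + 1L,
                         blocks$qstart + blen)
  ref_part <- substring(reference[blocks$rname], blocks$gstart + 1L,
                        blocks$gend)
  qual_part <- substring(sub$qual[blocks$idx], blocks$qstart + 1L,
                         blocks$qstart + blen)
  a <- charToRaw(paste(read_part, collapse = ""))
  b <- charToRaw(paste(ref_part, collapse = ""))
  q <- as.integer(charToRaw(paste(qual_part, collapse = ""))) - 33L
  block_id <- rep(seq_len(nrow(blocks)), blen)
  keep <- q >= min_baseq
  masked_n <- 0L
  if (!is.null(mask) && nrow(mask) > 0L) {
    gpos <- rep(blocks$gstart, blen) + (sequence(blen) - 1L)
    key <- paste(blocks$rname[block_id], gpos)
    mkey <- paste(mask$contig, mask$pos)
    in_mask <- key %in% mkey
    masked_n <- sum(in_mask & keep)
    keep <- keep & !in_mask
  }
  mm <- (a != b) & keep
  per_block_mm <- tabulate(block_id[mm], nbins = nrow(blocks))
  per_block_al <- tabulate(block_id[keep], nbins = nrow(blocks))
  pc <- data.table::data.table(contig = blocks$rname,
                               mismatches = per_block_mm,
                               aligned_bases = per_block_al)[,
    .(aligned_bases = sum(aligned_bases), mismatches = sum(mismatches)),
    by = contig]
  aligned <- sum(keep)
  nmm <- sum(mm)
  structure(list(aligned_bases = aligned, mismatches = nmm,
                 masked_bases = masked_n, per_contig = pc[],
                 rate = if (aligned > 0) nmm / aligned else NA_real_,
                 rate_per_kb = if (aligned > 0) nmm / aligned * 1000 else
                   NA_real_),
            class = "mismatch_tally")
}

#' @export
print.mismatch_tally <- function(x, ...) {
  cat(sprintf("mismatch_tally: %d mismatches / %d aligned bases (%.4g per kb; %d masked)\n",
              x$mismatches, x$aligned_bases,
              ifelse(is.na(x$rate_per_kb), NA, x$rate_per_kb), x$masked_bases))
  invisible(x)
}

#' Extract the spike-in candidate pool
#'
#' Returns every record belonging to a pair in which at least one mate has
#' the read-unmapped flag (both mates of a selected pair are returned).
#' Mirrors the rule of re-aligning any read that is unaligned itself or has
#' an unaligned mate.
#'
#' @param aln A `qc_alignments` table.
#' @return A `qc_alignments` subset. Pairs missing a mate raise a warning
#'   and the singleton is kept.
#' @export
extract_spikein_pool <- function(aln) {
  unmapped <- .has_flag(aln$flag, FLAG_UNMAP) | .has_flag(aln$flag, FLAG_MUNMAP)
  names_sel <- unique(aln$qname[unmapped])
  sel <- aln[aln$qname %in% names_sel]
  if (length(names_sel)) {
    cnt <- table(sel$qname)
    singles <- names(cnt)[cnt < 2L]
    if (length(singles))
      warning(length(singles), " selected pair(s) missing a mate; singleton kept")
  }
  .as_qc_alignments(sel, attr(aln, "contigs"))
}

# k-mer seed index over panel sequences (forward orientation only; reads are
# queried in both orientations).
.panel_seed_index <- function(panel, seed_length) {
  idx <- lapply(seq_len(nrow(panel)), function(i) {
    s <- panel$sequence[i]
    L <- nchar(s)
    if (L < seed_length) return(NULL)
    starts <- seq_len(L - seed_length + 1L)
    data.table::data.table(kmer = substring(s, starts,
                                            starts + seed_length - 1L),
                           pid = panel$id[i], ppos = starts - 1L)
  })
  out <- data.table::rbindlist(idx)
  data.table::setkey(out, kmer)
  out
}

#' Assign pool reads to spike-in panel members
#'
#' Gapless seed-and-extend: a read is aligned to a panel member when it
#' shares an exact `seed_length`-mer (either orientation); the hit is
#' extended without gaps across the full read and identity is computed over
#' the aligned span. The read is assigned to the member with the highest
#' identity provided identity >= `min_identity` and the span covers at least
#' `min_cov` of the read; ties break by longest span, then lexicographic id.
#' Deterministic and independent of read order.
#'
#' @param pool A `qc_alignments` table from [extract_spikein_pool()].
#' @param panel A `spikein_panel`.
#' @param seed_length Exact seed length (default 20).
#' @param min_identity Minimum identity over the aligned span.
#' @param min_cov Minimum aligned-span fraction of the read length.
#' @return A `spikein_result` list: `assignments` (per assigned read:
#'   `qname`, `mate`, `id`, `identity`, `span`, `mismatches`),
#'   `per_spikein` (per panel member: `assigned_reads`,
#'   `observed_abundance` = reads per kilobase of spike-in), `pool_size`
#'   (reads in the pool), `assigned_total`.
#' @export
align_to_panel <- function(pool, panel, seed_length = 20L,
                           min_identity = 0.95, min_cov = 0.9) {
  if (nrow(panel) == 0L) stop("empty spike-in panel")
  pool_size <- nrow(pool)
  empty_assign <- data.table::data.table(qname = character(),
    mate = integer(), id = character(), identity = numeric(),
    span = integer(), mismatches = integer(), aligned = integer())
  per0 <- data.table::data.table(id = panel$id, assigned_reads = 0L,
                                 observed_abundance = 0)
  result0 <- structure(list(assignments = empty_assign, per_spikein = per0,
                            pool_size = pool_size, assigned_total = 0L),
                       class = "spikein_result")
  if (pool_size == 0L) return(result0)

  sidx <- .panel_seed_index(panel, seed_length)
  reads <- data.table::data.table(
    rid = seq_len(pool_size), qname = pool$qname,
    mate = ifelse(.has_flag(pool$flag, FLAG_READ2), 2L, 1L),
    fwd = pool$seq)
  reads[, rc := .revcomp(fwd)]
  read_len <- nchar(reads$fwd)

  kmers_of <- function(seqs, orient) {
    L <- nchar(seqs)
    n_k <- pmax(0L, L - seed_length + 1L)
    rid <- rep(reads$rid, n_k)
    rpos <- sequence(n_k) - 1L
    data.table::data.table(kmer = substring(seqs[rid], rpos + 1L,
                                            rpos + seed_length),
                           rid = rid, rpos = rpos, orient = orient)
  }
  q <- rbind(kmers_of(reads$fwd, "+"), kmers_of(reads$rc, "-"))
  hits <- sidx[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(result0)
  hits[, offset := ppos - rpos]
  cand <- unique(hits[, .(rid, pid, orient, offset)])

  # gapless extension over the full read
  cand[, rl := read_len[rid]]
  cand[, plen := panel$length[match(pid, panel$id)]]
  cand[, rstart := pmax(0L, -offset)]
  cand[, rend := pmin(rl, plen - offset)]
  cand <- cand[rend > rstart]
  cand[, span := rend - rstart]
  rseq <- ifelse(cand$orient == "+", reads$fwd[cand$rid], reads$rc[cand$rid])
  read_part <- substring(rseq, cand$rstart + 1L, cand$rend)
  pseq <- panel$sequence[match(cand$pid, panel$id)]
  panel_part <- substring(pseq, cand$rstart + cand$offset + 1L,
                          cand$rend + cand$offset)
  a <- charToRaw(paste(read_part, collapse = ""))
  b <- charToRaw(paste(panel_part, collapse = ""))
  cid <- rep(seq_len(nrow(cand)), cand$span)
  mm <- tabulate(cid[a != b], nbins = nrow(cand))
  cand[, mismatches := mm]
  cand[, identity := (span - mismatches) / span]
  cand <- cand[identity >= min_identity & span >= min_cov * rl]
  if (nrow(cand) == 0L) return(result0)
  data.table::setorder(cand, rid, -identity, -span, pid)
  best <- cand[, .SD[1L], by = rid]

  assignments <- best[, .(qname = reads$qname[rid], mate = reads$mate[rid],
                          id = pid, identity, span, mismatches,
                          aligned = span)]
  per <- merge(per0[, .(id)],
               assignments[, .(assigned_reads = .N), by = id],
               by = "id", all.x = TRUE)
  per[, assigned_reads := ifelse(is.na(assigned_reads), 0L, assigned_reads)]
  per[, observed_abundance :=
        assigned_reads / (panel$length[match(id, panel$id)] / 1000)]
  structure(list(assignments = assignments[], per_spikein = per[],
                 pool_size = pool_size,
                 assigned_total = nrow(assignments)),
            class = "spikein_result")
}

#' Spike-in dose-response correlation
#'
#' Pearson correlation of `log2(observed_abundance + pseudocount)` against
#' `log2(expected_concentration)` over panel members with at least one
#' assigned read. Because undetected members are excluded, abundances are
#' strictly positive and the default pseudocount is 0, which keeps the
#' statistic exactly 1 for perfectly proportional counts.
#'
#' @param result A `spikein_result` from [align_to_panel()].
#' @param panel The `spikein_panel` (the ground-truth dose axis).
#' @param pseudocount Added to observed abundance before log2 (default 0).
#' @return Pearson r, or NA with a warning when fewer than 3 members are
#'   detected.
#' @export
spikein_dose_response <- function(result, panel, pseudocount = 0) {
  per <- merge(result$per_spikein, panel[, .(id, concentration)], by = "id")
  per <- per[assigned_reads >= 1L]
  if (nrow(per) < 3L) {
    warning("fewer than 3 spike-in members detected; correlation undefined")
    return(NA_real_)
  }
  stats::cor(log2(per$observed_abundance + pseudocount),
             log2(per$concentration), method = "pearson")
}

#' Spike-in error rate per 1000 nt
#'
#' Mismatches over the gapless aligned spans of assigned reads, divided by
#' aligned bases, times 1000 — the observed-versus-expected sequence
#' divergence of the synthetic spike-ins.
#'
#' @param result A `spikein_result`.
#' @return Rate per 1000 nt, or NA when no bases were assigned.
#' @export
spikein_error_rate <- function(result) {
  total <- sum(result$assignments$aligned)
  if (total == 0L) return(NA_real_)
  sum(result$assignments$mismatches) / total * 1000
}
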