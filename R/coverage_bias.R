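# Meta-transcript coverage profile and the 5'-to-3' coverage-bias ratio.
# Coverage is counted over exonic bases only, concatenated in transcript
# order and reversed for minus-strand transcripts so index 1 is the 5' end.

# coverage of a set of transcripts; returns list of numeric vectors keyed by
# transcript_id. aln must already be restricted to usable reads.
.tx_coverage <- function(aln, index, tx_ids) {
  txs <- index$transcripts[transcript_id %in% tx_ids]
  exd <- index$exons[transcript_id %in% tx_ids,
                     .(transcript_id, contig, start, end)]
  data.table::setorder(exd, transcript_id, start)
  exd[, toff := cumsum(data.table::shift(end - start, fill = 0L)),
      by = transcript_id]
  covs <- stats::setNames(
    lapply(txs$transcript_id, function(t)
      numeric(txs$exonic_length[txs$transcript_id == t])),
    txs$transcript_id)
  if (nrow(aln) == 0L) return(covs)
  blocks <- .m_blocks(aln$cigar, aln$pos)
  if (nrow(blocks) == 0L) return(covs)
  blocks[, rname := aln$rname[idx]]
  # interval join blocks x exons
  bl <- blocks[, .(idx, contig = rname, gstart, gend)]
  exk <- exd[, .(transcript_id, contig, start, end, toff,
                 jstart = start, jend = end)]
  data.table::setkey(exk, contig, jstart, jend)
  hits <- data.table::foverlaps(
    bl[, .(idx, contig, jstart = gstart, jend = gend, gstart, gend)],
    exk, type = "any", nomatch = NULL)
  hits <- hits[gstart < end & start < gend]  # half-open, drop touching
  if (nrow(hits) == 0L) return(covs)
  hits[, `:=`(os = pmax(gstart, start), oe = pmin(gend, end))]
  hits[, `:=`(ts = toff + (os - start), te = toff + (oe - start))]
  # accumulate with a difference array per transcript
  for (t in unique(hits$transcript_id)) {
    h <- hits[transcript_id == t]
    L <- length(covs[[t]])
    d <- numeric(L + 1L)
    add <- tabulate(h$ts + 1L, nbins = L + 1L)
    subt <- tabulate(h$te + 1L, nbins = L + 1L)
    d <- add - subt
    covs[[t]] <- cumsum(d)[seq_len(L)]
  }
  # reverse minus-strand transcripts: 5' end first
  minus <- txs$transcript_id[txs$strand == "-"]
  for (t in minus) covs[[t]] <- rev(covs[[t]])
  covs
}

#' Per-base coverage of one transcript (5' to 3')
#'
#' A read contributes +1 to every exonic transcript base its M blocks
#' overlap. The returned vector is in transcript coordinates, reversed for
#' minus-strand transcripts so that element 1 is the 5' end.
#'
#' @param aln A `qc_alignments` table (deduplicated, mapped records).
#' @param index An `annotation_index`.
#' @param transcript_id Transcript to profile.
#' @return Numeric vector of length equal to the transcript's exonic length.
#' @export
transcript_coverage <- function(aln, index, transcript_id) {
  if (!transcript_id %in% index$transcripts$transcript_id)
    stop("unknown transcript: ", transcript_id)
  tid <- transcript_id
  tx <- index$transcripts[transcript_id == tid]
  contigs <- attr(aln, "contigs")
  if (!is.null(contigs) && !tx$contig %in% names(contigs))
    stop("transcript contig '", tx$contig, "' absent from alignment header")
  sub <- aln[.usable(aln)]
  .tx_coverage(sub, index, transcript_id)[[transcript_id]]
}

#' Mean-normalised meta-transcript profile
#'
#' Each coverage vector is normalised by its own mean, rebinned to `n_bins`
#' equal-width bins (bin means), and averaged across transcripts. The mean of
#' the returned bins is 1 whenever at least one transcript enters.
#'
#' @param coverages list of per-transcript coverage vectors (5' to 3').
#' @param n_bins Number of bins of the meta profile.
#' @return list: `n_bins`, `mean_normalized_coverage` (length `n_bins`),
#'   `transcripts_used`.
#' @export
meta_transcript_profile <- function(coverages, n_bins = 100L) {
  coverages <- coverages[vapply(coverages, function(v)
    length(v) >= n_bins && mean(v) > 0, logical(1))]
  if (length(coverages) == 0L)
    return(list(n_bins = n_bins,
                mean_normalized_coverage = rep(NA_real_, n_bins),
                transcripts_used = 0L))
  binned <- vapply(coverages, function(v) {
    v <- v / mean(v)
    bin <- floor((seq_along(v) - 1L) * n_bins / length(v))
    as.numeric(tapply(v, bin, mean))
  }, numeric(n_bins))
  prof <- rowMeans(binned)
  prof <- prof / mean(prof)  # bin widths differ by <=1 base; re-centre
  list(n_bins = n_bins, mean_normalized_coverage = prof,
       transcripts_used = length(coverages))
}

#' 5'/3' ratio of a meta-transcript profile
#'
#' @param profile Output of [meta_transcript_profile()].
#' @param window_frac Fraction of bins in each terminal window (default 0.2:
#'   bins 1-20 vs 81-100 of a 100-bin profile).
#' @return mean(5' window) / mean(3' window), or NA for an empty profile.
#' @export
profile_ratio <- function(profile, window_frac = 0.2) {
  if (profile$transcripts_used == 0L) return(NA_real_)
  nb <- profile$n_bins
  w <- max(1L, round(nb * window_frac))
  p <- profile$mean_normalized_coverage
  mean(p[seq_len(w)]) / mean(p[(nb - w + 1L):nb])
}

#' 5'-to-3' transcript coverage-bias ratio
#'
#' Eligible transcripts (one per gene: its longest) must have exonic length
#' >= `min_length` and mean coverage >= `min_mean_cov`. Each eligible
#' transcript's coverage is mean-normalised, rebinned to `n_bins`, and
#' averaged; the ratio is mean of the first 20% of bins over mean of the
#' last 20%. A value near 1 indicates an unbiased library; values below 1
#' indicate 3'-end bias, the usual failure mode of poly(A)-capture
#' protocols.
#'
#' @param aln A `qc_alignments` table.
#' @param index An `annotation_index`.
#' @param min_mean_cov Minimum mean per-base coverage for eligibility.
#' @param min_length Minimum transcript exonic length (>= `n_bins`).
#' @param n_bins Number of meta-profile bins.
#' @param window_frac Terminal window fraction.
#' @return list(ratio = numeric or NA when no transcript is eligible,
#'   profile = meta-transcript profile).
#' @export
five_prime_three_prime_ratio <- function(aln, index, min_mean_cov = 5,
                                         min_length = 500L, n_bins = 100L,
                                         window_frac = 0.2) {
  stopifnot(min_mean_cov > 0, min_length >= n_bins)
  sub <- aln[.usable(aln)]
  # longest transcript per gene, length-eligible
  txs <- index$transcripts[order(-exonic_length),
                           .SD[1L], by = gene_id][exonic_length >= min_length]
  if (nrow(txs) == 0L)
    return(list(ratio = NA_real_,
                profile = meta_transcript_profile(list(), n_bins)))
  covs <- .tx_coverage(sub, index, txs$transcript_id)
  covs <- covs[vapply(covs, mean, numeric(1)) >= min_mean_cov]
  prof <- meta_transcript_profile(covs, n_bins)
  list(ratio = profile_ratio(prof, window_frac), profile = prof)
}
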