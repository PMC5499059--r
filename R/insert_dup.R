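# Insert-size estimation from (mitochondrial) alignments, seeded
# pair-preserving down-sampling, and coordinate-based duplicate marking.

#' Insert-size distribution from one contig
#'
#' Uses pairs in which both mates map to `contig` with the proper-pair flag
#' set and neither cigar contains an N operation; the mitochondrial contig
#' gives deep, splice-free coverage, so the outer pair distance there is an
#' unconfounded estimate of the cDNA fragment length. The insert is the
#' positive template length, taken once per pair from the leftmost mate;
#' inserts of 0 or above `max_insert` are excluded.
#'
#' @param aln A `qc_alignments` table.
#' @param contig Contig to restrict to (typically the mitochondrial contig).
#' @param max_insert Maximum plausible insert (default 2000).
#' @return An `insert_size_distribution` list: `histogram` (data.table
#'   `insert`, `n`), `mean`, `median`, `sd`, `pairs_used`, `source_contig`;
#'   or the same structure with NA summaries and a warning when no pair
#'   qualifies.
#' @export
insert_size_distribution <- function(aln, contig, max_insert = 2000L) {
  stopifnot(max_insert > 0L)
  contigs <- attr(aln, "contigs")
  if (!is.null(contigs) && !contig %in% names(contigs))
    stop("contig '", contig, "' absent from alignment header")
  on_c <- !is.na(aln$rname) & aln$rname == contig &
    !.has_flag(aln$flag, FLAG_UNMAP) & !.has_flag(aln$flag, FLAG_MUNMAP) &
    .has_flag(aln$flag, FLAG_PROPER) &
    (is.na(aln$rnext) | aln$rnext %in% c("=", contig))
  sub <- aln[on_c]
  # drop pairs with a spliced mate
  spliced <- unique(sub$qname[grepl("N", sub$cigar, fixed = TRUE)])
  sub <- sub[!sub$qname %in% spliced]
  # both mates present on the contig
  cnt <- table(sub$qname)
  sub <- sub[sub$qname %in% names(cnt)[cnt == 2L]]
  left <- sub[sub$tlen > 0L]
  left <- left[!duplicated(left$qname)]
  ins <- left$tlen
  ins <- ins[ins > 0L & ins <= max_insert]
  if (length(ins) == 0L) {
    warning("no qualifying pairs on contig '", contig,
            "'; insert-size distribution undefined")
    return(structure(list(histogram = data.table::data.table(
      insert = integer(), n = integer()),
      mean = NA_real_, median = NA_real_, sd = NA_real_,
      pairs_used = 0L, source_contig = contig),
      class = "insert_size_distribution"))
  }
  hist <- data.table::data.table(insert = ins)[, .(n = .N), by = insert]
  data.table::setorder(hist, insert)
  structure(list(histogram = hist[], mean = mean(ins),
                 median = stats::median(ins), sd = stats::sd(ins),
                 pairs_used = length(ins), source_contig = contig),
            class = "insert_size_distribution")
}

#' @export
print.insert_size_distribution <- function(x, ...) {
  cat(sprintf("insert_size_distribution (%s): %d pairs, mean %.1f, median %s, sd %.1f\n",
              x$source_contig, x$pairs_used, x$mean,
              format(x$median), x$sd))
  invisible(x)
}

#' Seeded pair-preserving down-sampling
#'
#' Selects exactly `n_fragments` distinct fragment names uniformly without
#' replacement; every record sharing a selected name is kept, so mate pairs
#' never split. Exact-count selection (rather than per-read Bernoulli)
#' removes one source of noise when libraries are compared at matched depth.
#' The caller's RNG state is untouched.
#'
#' @param aln A `qc_alignments` table.
#' @param n_fragments Number of fragments to keep (<= distinct names).
#' @param seed Integer seed; the same seed and input give the identical
#'   subset.
#' @return A `qc_alignments` table in the original record order.
#' @export
downsample <- function(aln, n_fragments, seed) {
  nm <- unique(aln$qname)
  if (n_fragments > length(nm))
    stop("n_fragments (", n_fragments, ") exceeds distinct fragment count (",
         length(nm), ")")
  keep <- .with_seed(seed, sample(nm, n_fragments))
  out <- aln[aln$qname %in% keep]
  .as_qc_alignments(out, attr(aln, "contigs"))
}

# unclipped 5' coordinate of each record: leading/trailing soft clips are
# backed out so PCR copies of one fragment share a key even if clipped
# differently. Forward reads: pos - leading S; reverse reads: reference end
# + trailing S (0-based exclusive).
.unclipped5 <- function(aln) {
  ops <- .cigar_table(aln$cigar)
  lead <- rep(0L, nrow(aln)); trail <- rep(0L, nrow(aln))
  ref_len <- rep(0L, nrow(aln))
  if (nrow(ops)) {
    first <- ops[, .SD[1L], by = idx]
    last <- ops[, .SD[.N], by = idx]
    lead[first$idx] <- ifelse(first$op == "S", first$len, 0L)
    trail[last$idx] <- ifelse(last$op == "S", last$len, 0L)
    rl <- ops[op %in% c("M", "D", "N"), .(n = sum(len)), by = idx]
    ref_len[rl$idx] <- rl$n
  }
  rev <- .has_flag(aln$flag, FLAG_REVERSE)
  ifelse(rev, aln$pos + ref_len + trail, aln$pos - lead)
}

#' Mark PCR duplicates
#'
#' Fragments are grouped by the key (read1 contig, read1 unclipped 5'
#' position, read1 strand, read2 contig, read2 unclipped 5' position, read2
#' strand). Within each group the fragment with the highest summed base
#' quality is kept (ties broken by first query name lexicographically) and
#' every other fragment is flagged on both mates. Fragments with an
#' unmapped mate are never flagged. Optical-duplicate detection is not
#' attempted.
#'
#' @param aln A `qc_alignments` table (paired, coordinate-sorted).
#' @return list: `alignments` (same rows, duplicate flags rewritten) and
#'   `summary` (a `duplicate_summary`: `fragments_total`,
#'   `duplicate_fragments`, `duplicate_rate`).
#' @export
mark_duplicates <- function(aln) {
  aln <- data.table::copy(aln)
  if (nrow(aln) == 0L)
    return(list(alignments = aln,
                summary = structure(list(fragments_total = 0L,
                                         duplicate_fragments = 0L,
                                         duplicate_rate = NA_real_,
                                         downsample_n = NULL, seed = NULL),
                                    class = "duplicate_summary")))
  aln[, flag := bitwAnd(flag, bitwNot(FLAG_DUP))]
  mapped <- !.has_flag(aln$flag, FLAG_UNMAP)
  paired <- .has_flag(aln$flag, FLAG_PAIRED)
  if (any(!paired & mapped))
    warning(sum(!paired & mapped), " unpaired mapped record(s); ",
            "treated as single-end fragments")
  u5 <- rep(NA_integer_, nrow(aln))
  u5[mapped] <- .unclipped5(aln[mapped])
  strand <- ifelse(.has_flag(aln$flag, FLAG_REVERSE), "-", "+")
  # summed base qualities, vectorised over the concatenated quality strings
  qn <- nchar(aln$qual)
  qbytes <- as.integer(charToRaw(paste(aln$qual, collapse = "")))
  qsum <- as.vector(rowsum(qbytes, rep(seq_len(nrow(aln)), qn))) - 33L * qn

  info <- data.table::data.table(
    row = seq_len(nrow(aln)), qname = aln$qname, rname = aln$rname,
    u5 = u5, strand = strand, qsum = qsum, mapped = mapped,
    mate = data.table::fifelse(.has_flag(aln$flag, FLAG_READ2), 2L, 1L),
    paired = paired)
  per_frag <- info[, .(n = .N, n_mapped = sum(mapped), qsum = sum(qsum)),
                   by = qname]
  m1 <- info[mapped & mate == 1L,
             .(qname, k1 = paste(rname, u5, strand, sep = "|"))]
  m2 <- info[mapped & mate == 2L,
             .(qname, k2 = paste(rname, u5, strand, sep = "|"))]
  m1 <- m1[!duplicated(qname)]; m2 <- m2[!duplicated(qname)]
  frag <- merge(per_frag, m1, by = "qname", all.x = TRUE)
  frag <- merge(frag, m2, by = "qname", all.x = TRUE)
  frag[, key := data.table::fifelse(
    !is.na(k1) & !is.na(k2), paste(k1, k2, sep = "|"),
    data.table::fifelse(n_mapped == 1L & n == 1L,
                        paste("SE", data.table::fifelse(is.na(k1), k2, k1),
                              sep = "|"),
                        NA_character_))]
  eligible <- frag[!is.na(key)]
  dup_names <- character(0)
  if (nrow(eligible)) {
    data.table::setorder(eligible, key, -qsum, qname)
    eligible[, keeper := seq_len(.N) == 1L, by = key]
    dup_names <- eligible$qname[!eligible$keeper]
  }
  if (length(dup_names)) {
    is_dup <- aln$qname %in% dup_names
    aln[is_dup, flag := bitwOr(flag, FLAG_DUP)]
  }
  summary <- structure(list(
    fragments_total = nrow(eligible),
    duplicate_fragments = length(dup_names),
    duplicate_rate = if (nrow(eligible) > 0)
      length(dup_names) / nrow(eligible) else NA_real_,
    downsample_n = NULL, seed = NULL), class = "duplicate_summary")
  list(alignments = .as_qc_alignments(aln, attr(aln, "contigs")),
       summary = summary)
}

#' @export
print.duplicate_summary <- function(x, ...) {
  cat(sprintf("duplicate_summary: %d/%d fragments flagged (rate %.4f)\n",
              x$duplicate_fragments, x$fragments_total,
              ifelse(is.na(x$duplicate_rate), NA, x$duplicate_rate)))
  invisible(x)
}
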