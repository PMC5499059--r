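# Per-library profiling metrics: category percentages, rRNA/mitochondrial
# fractions, gene-level expression (RPKM), gene detection,
# intron/exon ratio, junction-based strand-specificity and cross-library
# expression correlation.

# mapped, primary, non-duplicate record selector
.usable <- function(aln) {
  !.has_flag(aln$flag, FLAG_UNMAP) & !.has_flag(aln$flag, FLAG_DUP)
}

#' Profile a library: read categories and gene-level expression
#'
#' Counts primary mapped records only. Duplicate-flagged reads are excluded
#' from every tally except the duplicate rate. A read is assigned to a gene
#' when it is classified exonic and all of its exon-overlapping bases fall
#' within that single gene; reads touching exons of more than one gene are
#' tallied as ambiguous and excluded from expression (but still classified).
#'
#' @param aln A `qc_alignments` table (coordinate-sorted, duplicates marked).
#' @param index An `annotation_index`.
#' @return list with `report` (partial metric list) and `expression`
#'   (data.table `gene_id`, `read_count`, `exonic_length`, `rpkm` over all
#'   annotated genes).
#' @export
profile_library <- function(aln, index) {
  total <- nrow(aln)
  mapped_all <- !.has_flag(aln$flag, FLAG_UNMAP)
  use <- .usable(aln)
  expr0 <- data.table::data.table(gene_id = index$genes$gene_id,
                                  read_count = 0L,
                                  exonic_length = index$genes$exonic_length)
  if (total == 0L || !any(use)) {
    expr0[, rpkm := 0]
    rep <- list(total_reads = total, aligned_fraction = NA_real_,
                pct_exonic = NA_real_, pct_intronic = NA_real_,
                pct_intergenic = NA_real_, pct_mitochondrial = NA_real_,
                pct_rRNA = NA_real_, duplicate_rate = NA_real_,
                ambiguous_reads = 0L)
    return(list(report = rep, expression = expr0[]))
  }
  sub <- aln[use]
  blocks <- .m_blocks(sub$cigar, sub$pos)
  blocks[, rname := sub$rname[idx]]
  cls <- .classify_blocks(blocks[, .(idx, rname, gstart, gend)], nrow(sub),
                          index)
  n_class <- nrow(sub)
  tab <- table(cls$category)
  counts <- data.table::data.table(gene_id = cls$gene)[!is.na(gene_id),
                                                       .N, by = gene_id]
  expr <- merge(expr0, counts, by = "gene_id", all.x = TRUE)
  expr[, read_count := ifelse(is.na(N), 0L, N)][, N := NULL]
  assigned_total <- sum(expr$read_count)
  expr[, rpkm := if (assigned_total > 0)
    read_count / (exonic_length / 1e3) / (assigned_total / 1e6) else 0]

  rrna_reads <- sum(expr$read_count[expr$gene_id %in% index$rrna_genes])
  mito_reads <- sum(sub$rname == index$mito_contig, na.rm = TRUE)
  dup_mapped <- sum(mapped_all & .has_flag(aln$flag, FLAG_DUP))

  rep <- list(
    total_reads = total,
    aligned_fraction = sum(mapped_all) / total,
    pct_exonic = as.numeric(tab[["exonic"]]) / n_class,
    pct_intronic = as.numeric(tab[["intronic"]]) / n_class,
    pct_intergenic = as.numeric(tab[["intergenic"]]) / n_class,
    pct_mitochondrial = mito_reads / nrow(sub),
    pct_rRNA = rrna_reads / nrow(sub),
    duplicate_rate = dup_mapped / sum(mapped_all),
    ambiguous_reads = sum(cls$ambiguous)
  )
  data.table::setorder(expr, gene_id)
  list(report = rep, expression = expr[])
}

#' Junction-based strand-specificity
#'
#' For each annotated exon-exon junction, spanning reads (exact N-skip
#' match, sufficient overhang) are accumulated as sense or antisense under
#' the configured library orientation. The statistic is the fraction of
#' junctions with zero antisense spanning reads. By default the denominator
#' is restricted to junctions observed by at least one spanning read, which
#' makes the statistic robust to sequencing depth; `literal_denominator =
#' TRUE` divides by all annotated junctions instead.
#'
#' @param aln A `qc_alignments` table; duplicate-flagged reads are excluded.
#' @param index An `annotation_index`.
#' @param orientation Library orientation.
#' @param min_overhang Minimum reference bases flanking the skip.
#' @param literal_denominator Use all annotated junctions as denominator.
#' @return list(value = proportion (NA when no junction observed),
#'   junctions_observed = integer)
#' @export
strand_specificity <- function(aln, index, orientation = "reverse-stranded",
                               min_overhang = 3L,
                               literal_denominator = FALSE) {
  sub <- aln[.usable(aln)]
  sp <- junctions_spanned(sub, index, min_overhang = min_overhang,
                          orientation = orientation)
  per_j <- sp[, .(sense_n = sum(sense), anti_n = sum(!sense)),
              by = .(contig, donor_end, acceptor_start, strand)]
  observed <- nrow(per_j)
  if (literal_denominator) {
    denom <- nrow(index$junctions)
    clean <- denom - sum(per_j$anti_n > 0L)
  } else {
    denom <- observed
    clean <- sum(per_j$anti_n == 0L)
  }
  if (denom == 0L) {
    warning("no junction-spanning reads; strand-specificity undefined")
    return(list(value = NA_real_, junctions_observed = 0L))
  }
  list(value = clean / denom, junctions_observed = observed)
}

#' Library-wide intron/exon read ratio
#'
#' @param aln A `qc_alignments` table.
#' @param index An `annotation_index`.
#' @return Ratio of reads classified intronic to reads classified exonic
#'   (NA with a warning when no exonic reads).
#' @export
intron_exon_ratio <- function(aln, index) {
  sub <- aln[.usable(aln)]
  if (nrow(sub) == 0L) {
    warning("no usable reads; intron/exon ratio undefined")
    return(NA_real_)
  }
  blocks <- .m_blocks(sub$cigar, sub$pos)
  blocks[, rname := sub$rname[idx]]
  cls <- .classify_blocks(blocks[, .(idx, rname, gstart, gend)], nrow(sub),
                          index)
  n_ex <- sum(cls$category == "exonic")
  n_in <- sum(cls$category == "intronic")
  if (n_ex == 0L) {
    warning("no exonic reads; intron/exon ratio undefined")
    return(NA_real_)
  }
  n_in / n_ex
}

#' Number of genes detected
#'
#' @param expr Expression table from [profile_library()].
#' @param min_count Minimum assigned read count (>= 1) to call a gene
#'   detected.
#' @return Integer count; monotone non-increasing in `min_count`.
#' @export
genes_detected <- function(expr, min_count = 1L) {
  stopifnot(min_count >= 1L)
  sum(expr$read_count >= min_count)
}

#' Pairwise expression correlation between two libraries
#'
#' Pearson correlation of `log2(rpkm + pseudocount)` over the union of genes
#' detected (read_count >= 1) in at least one of the two libraries.
#'
#' @param a,b Expression tables from [profile_library()] over the same gene
#'   universe.
#' @param pseudocount Added to RPKM before log2 (default 0.1).
#' @return Pearson r, or NA with a warning when fewer than 3 genes enter.
#' @export
expression_correlation <- function(a, b, pseudocount = 0.1) {
  if (!identical(sort(a$gene_id), sort(b$gene_id)))
    stop("expression vectors cover different gene universes")
  m <- merge(a[, .(gene_id, ca = read_count, ra = rpkm)],
             b[, .(gene_id, cb = read_count, rb = rpkm)], by = "gene_id")
  m <- m[ca >= 1L | cb >= 1L]
  if (nrow(m) < 3L) {
    warning("fewer than 3 genes detected in either library")
    return(NA_real_)
  }
  stats::cor(log2(m$ra + pseudocount), log2(m$rb + pseudocount),
             method = "pearson")
}
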