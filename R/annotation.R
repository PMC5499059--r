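# Gene-model index: interval-indexed transcripts/exons/gene spans, the
# deduplicated set of annotated exon-exon junctions, and the read-level
# classification and junction-spanning operations built on top of them.

#' Build an annotation index from a GTF file
#'
#' Transcripts are assembled from `exon` rows (grouped by `transcript_id`),
#' kept in genomic coordinate order regardless of strand. The junction set is
#' the union over transcripts of adjacent-exon pairs, deduplicated by
#' (contig, donor end, acceptor start, strand). Genes whose `gene_biotype`
#' matches `rrna_biotypes` are flagged ribosomal.
#'
#' @param path GTF file with `gene_id`, `transcript_id` and `gene_biotype`
#'   attributes on exon rows.
#' @param mito_contig Name of the mitochondrial contig (default `"chrM"`).
#' @param rrna_biotypes Biotypes treated as ribosomal RNA.
#' @return An `annotation_index` list: `transcripts`, `exons`, `junctions`
#'   data.tables, `GRanges` interval indexes, the rRNA gene set and the
#'   mitochondrial contig name.
#' @export
parse_gtf <- function(path, mito_contig = "chrM",
                      rrna_biotypes = c("rRNA", "Mt_rRNA")) {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  ex <- gr[mc$type == "exon"]
  if (length(ex) == 0L) stop("GTF contains no exon rows")
  exd <- data.table::data.table(
    contig = as.character(GenomicRanges::seqnames(ex)),
    # store 0-based half-open
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = S4Vectors::mcols(ex)$gene_id,
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    biotype = if ("gene_biotype" %in% names(S4Vectors::mcols(ex)))
      S4Vectors::mcols(ex)$gene_biotype else NA_character_
  )
  if (any(is.na(exd$gene_id)) || any(is.na(exd$transcript_id)))
    stop("exon rows must carry gene_id and transcript_id attributes")
  if (any(exd$end <= exd$start))
    stop("exon with end <= start in GTF")
  if (any(exd[, data.table::uniqueN(contig), by = transcript_id]$V1 > 1L))
    stop("transcript spanning more than one contig")
  data.table::setorder(exd, transcript_id, start)
  exd[, exon_rank := seq_len(.N), by = transcript_id]
  overl <- exd[, any(start < data.table::shift(end, fill = -1L)),
               by = transcript_id]
  if (any(overl$V1)) stop("overlapping exons within a transcript")

  tx <- exd[, .(gene_id = gene_id[1L], contig = contig[1L],
                strand = strand[1L],
                biotype = biotype[1L],
                tx_start = min(start), tx_end = max(end),
                exonic_length = sum(end - start), n_exons = .N),
            by = transcript_id]

  # adjacent-exon pairs -> junction set, deduplicated
  jn <- exd[, if (.N > 1L) .(contig = contig[-.N],
                             donor_end = end[-.N],
                             acceptor_start = start[-1L],
                             strand = strand[-.N]),
            by = transcript_id]
  junctions <- if (nrow(jn)) unique(jn[, .(contig, donor_end, acceptor_start,
                                           strand)])
  else data.table::data.table(contig = character(), donor_end = integer(),
                              acceptor_start = integer(), strand = character())
  data.table::setkey(junctions, contig, donor_end, acceptor_start)

  genes <- tx[, .(contig = contig[1L], strand = strand[1L],
                  biotype = biotype[1L],
                  gstart = min(tx_start), gend = max(tx_end)),
              by = gene_id]

  exon_gr <- GenomicRanges::GRanges(exd$contig,
    IRanges::IRanges(exd$start + 1L, exd$end), gene_id = exd$gene_id)
  exon_union <- GenomicRanges::reduce(exon_gr, ignore.strand = TRUE)
  # per-gene reduced exon union (for gene assignment and RPKM lengths)
  spl <- GenomicRanges::split(exon_gr, exd$gene_id)
  red <- GenomicRanges::reduce(spl, ignore.strand = TRUE)
  gene_exon_gr <- unlist(red, use.names = FALSE)
  S4Vectors::mcols(gene_exon_gr)$gene_id <-
    rep(names(red), S4Vectors::elementNROWS(red))
  gene_exonic_len <- vapply(IRanges::width(red), sum, numeric(1))
  genes[, exonic_length := as.integer(gene_exonic_len[gene_id])]

  gene_gr <- GenomicRanges::GRanges(genes$contig,
    IRanges::IRanges(genes$gstart + 1L, genes$gend), gene_id = genes$gene_id)

  structure(list(
    transcripts = tx[],
    exons = exd[],
    genes = genes[],
    junctions = junctions[],
    exon_union = exon_union,
    gene_exon_gr = gene_exon_gr,
    gene_gr = gene_gr,
    rrna_genes = unique(genes$gene_id[!is.na(genes$biotype) &
                                        genes$biotype %in% rrna_biotypes]),
    mito_contig = mito_contig
  ), class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("annotation_index:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts,",
      nrow(x$junctions), "junctions;",
      length(x$rrna_genes), "rRNA gene(s); mito contig:", x$mito_contig, "\n")
  invisible(x)
}

# Vectorised classification of mapped records.
# blocks: data.table(idx, rname, gstart, gend) of M blocks; n = number of reads.
# Returns list(category = factor per read, gene = assigned gene or NA,
#              ambiguous = logical)
.classify_blocks <- function(blocks, n, index) {
  known <- unique(c(as.character(GenomicRanges::seqnames(index$gene_gr)),
                    index$mito_contig))
  # unknown contigs are legal at the alignment level; classification only
  # needs them absent from the annotation to call reads intergenic.
  aligned <- rep(0L, n)
  ab <- blocks[, .(b = sum(gend - gstart)), by = idx]
  aligned[ab$idx] <- ab$b

  bgr <- GenomicRanges::GRanges(blocks$rname,
    IRanges::IRanges(blocks$gstart + 1L, blocks$gend))

  ov_bases <- function(subject) {
    h <- GenomicRanges::findOverlaps(bgr, subject, ignore.strand = TRUE)
    if (length(h) == 0L) return(rep(0L, n))
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(bgr)[S4Vectors::queryHits(h)],
      IRanges::ranges(subject)[S4Vectors::subjectHits(h)]))
    out <- rep(0L, n)
    agg <- data.table::data.table(idx = blocks$idx[S4Vectors::queryHits(h)],
                                  w = w)[, .(w = sum(w)), by = idx]
    out[agg$idx] <- agg$w
    out
  }
  exon_bases <- ov_bases(index$exon_union)
  gene_bases <- ov_bases(GenomicRanges::reduce(index$gene_gr,
                                               ignore.strand = TRUE))
  category <- rep("intergenic", n)
  category[gene_bases * 2L >= aligned & aligned > 0L] <- "intronic"
  category[exon_bases * 2L >= aligned & aligned > 0L] <- "exonic"

  # gene assignment: exonic reads whose exon-overlapping bases touch exactly
  # one gene
  h <- GenomicRanges::findOverlaps(bgr, index$gene_exon_gr,
                                   ignore.strand = TRUE)
  gene <- rep(NA_character_, n)
  ambiguous <- rep(FALSE, n)
  if (length(h)) {
    gh <- data.table::data.table(
      idx = blocks$idx[S4Vectors::queryHits(h)],
      gene_id = S4Vectors::mcols(index$gene_exon_gr)$gene_id[
        S4Vectors::subjectHits(h)])
    gh <- unique(gh)
    ng <- gh[, .(k = .N, g = gene_id[1L]), by = idx]
    one <- ng[k == 1L]
    gene[one$idx] <- one$g
    ambiguous[ng[k > 1L]$idx] <- TRUE
  }
  gene[category != "exonic"] <- NA_character_
  ambiguous[category != "exonic"] <- FALSE
  list(category = factor(category,
                         levels = c("exonic", "intronic", "intergenic")),
       gene = gene, ambiguous = ambiguous, aligned_bases = aligned)
}

#' Classify one read's aligned blocks
#'
#' Category is decided by majority of aligned reference bases with precedence
#' exonic > intronic > intergenic: exonic when at least half the aligned
#' bases fall in annotated exons, else intronic when at least half fall
#' within a gene span, else intergenic.
#'
#' @param blocks data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open M blocks of one read).
#' @param index An `annotation_index`.
#' @return One of `"exonic"`, `"intronic"`, `"intergenic"`.
#' @export
classify_interval_set <- function(blocks, index) {
  blocks <- data.table::as.data.table(blocks)
  if (!all(c("contig", "start", "end") %in% names(blocks)))
    stop("blocks must have columns contig, start, end")
  known <- unique(c(names(attr(index, "contigs")),
                    as.character(GenomicRanges::seqnames(index$gene_gr)),
                    index$mito_contig))
  if (any(!blocks$contig %in% known))
    stop("unknown contig: ", setdiff(blocks$contig, known)[1L])
  b <- data.table::data.table(idx = 1L, rname = blocks$contig,
                              gstart = blocks$start, gend = blocks$end)
  as.character(.classify_blocks(b, 1L, index)$category[1L])
}

#' Annotated junctions spanned by reads
#'
#' A record spans a junction only when one of its N-skip intervals matches
#' the annotated intron exactly (both coordinates) and both flanking M
#' operations cover at least `min_overhang` reference bases. `sense` is
#' whether the fragment strand inferred under `orientation` equals the
#' junction's annotated strand.
#'
#' @param aln A `qc_alignments` table (one or more mapped records).
#' @param index An `annotation_index`.
#' @param min_overhang Minimum reference bases on each side of the skip.
#' @param orientation Library orientation; default `"reverse-stranded"`
#'   matches dUTP second-strand-destruction chemistry.
#' @return data.table with one row per (record, junction) span: `idx` (row
#'   in `aln`), `contig`, `donor_end`, `acceptor_start`, `strand`, `sense`.
#' @export
junctions_spanned <- function(aln, index, min_overhang = 3L,
                              orientation = "reverse-stranded") {
  stopifnot(min_overhang >= 1L)
  empty <- data.table::data.table(idx = integer(), contig = character(),
    donor_end = integer(), acceptor_start = integer(), strand = character(),
    sense = logical())
  mapped <- !.has_flag(aln$flag, FLAG_UNMAP)
  if (!any(mapped)) return(empty)
  ns <- .n_skips(aln$cigar, aln$pos)
  if (nrow(ns) == 0L) return(empty)
  ns <- ns[left_m >= min_overhang & right_m >= min_overhang]
  if (nrow(ns) == 0L) return(empty)
  ns[, contig := aln$rname[idx]]
  hits <- merge(ns,
                index$junctions,
                by.x = c("contig", "nstart", "nend"),
                by.y = c("contig", "donor_end", "acceptor_start"))
  if (nrow(hits) == 0L) return(empty)
  hits[, frag_strand := .fragment_strand(aln$flag[idx], orientation)]
  hits[, sense := frag_strand == strand]
  out <- hits[, .(idx, contig, donor_end = nstart, acceptor_start = nend,
                  strand, sense)]
  data.table::setorder(out, idx)
  out[]
}
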