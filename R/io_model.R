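# Alignment, panel and report I/O.
#
# Alignment records live in a data.table (class "qc_alignments") with one row
# per SAM record and an attribute "contigs" (named integer vector of contig
# lengths from the @SQ header). Internal coordinates are 0-based half-open:
# `pos` is the 0-based leftmost mapped base, NA for unmapped records.

.aln_cols <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
               "rnext", "pnext", "tlen", "seq", "qual")

.as_qc_alignments <- function(dt, contigs) {
  data.table::setDT(dt)
  data.table::setattr(dt, "contigs", contigs)
  data.table::setattr(dt, "class", c("qc_alignments", class(dt)))
  dt
}

#' Read a SAM-dialect alignment file
#'
#' Parses a plain-text SAM file (header `@SQ` lines required) into a
#' `qc_alignments` table, one row per record, preserving file order.
#' Coordinates are converted to 0-based half-open; unmapped records keep
#' their sequence and base qualities so downstream spike-in extraction does
#' not need a second input file.
#'
#' @param path Path to a SAM text file.
#' @param region Optional contig name; when given, only mapped records whose
#'   reference equals `region` are returned (unmapped records are dropped).
#' @return A `qc_alignments` data.table with columns `qname`, `flag`,
#'   `rname`, `pos` (0-based), `mapq`, `cigar`, `rnext`, `pnext`, `tlen`,
#'   `seq`, `qual` and attribute `contigs`.
#' @export
read_alignments <- function(path, region = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  hdr <- lines[is_hdr]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) == 0L) stop("SAM header has no @SQ lines: ", path)
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([^\t]+).*", "\\1", sq))
  if (anyDuplicated(sn)) stop("duplicate contig names in @SQ header")
  contigs <- stats::setNames(ln, sn)

  rec_lines <- which(!is_hdr & nzchar(lines))
  if (!is.null(region) && !region %in% sn)
    stop("region '", region, "' is not a contig named in the header")

  if (length(rec_lines) == 0L) {
    dt <- data.table::data.table(qname = character(), flag = integer(),
      rname = character(), pos = integer(), mapq = integer(),
      cigar = character(), rnext = character(), pnext = integer(),
      tlen = integer(), seq = character(), qual = character())
    return(.as_qc_alignments(dt, contigs))
  }

  fields <- strsplit(lines[rec_lines], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("malformed SAM record at line ", rec_lines[which(nf < 11L)[1L]],
         ": fewer than 11 fields")
  take <- function(k) vapply(fields, `[[`, character(1), k)
  dt <- data.table::data.table(
    qname = take(1L),
    flag  = suppressWarnings(as.integer(take(2L))),
    rname = take(3L),
    pos   = suppressWarnings(as.integer(take(4L))),
    mapq  = suppressWarnings(as.integer(take(5L))),
    cigar = take(6L),
    rnext = take(7L),
    pnext = suppressWarnings(as.integer(take(8L))),
    tlen  = suppressWarnings(as.integer(take(9L))),
    seq   = take(10L),
    qual  = take(11L)
  )
  bad <- which(is.na(dt$flag) | is.na(dt$pos) | is.na(dt$tlen))
  if (length(bad))
    stop("malformed SAM record at line ", rec_lines[bad[1L]],
         ": non-numeric flag/pos/tlen")

  unmapped <- .has_flag(dt$flag, FLAG_UNMAP)
  dt[, rname := ifelse(rname == "*", NA_character_, rname)]
  dt[, pos := ifelse(unmapped | pos == 0L, NA_integer_, pos - 1L)]
  dt[, cigar := ifelse(cigar == "*", NA_character_, cigar)]
  dt[, rnext := ifelse(rnext == "*", NA_character_, rnext)]
  dt[, pnext := ifelse(pnext == 0L, NA_integer_, pnext - 1L)]

  unknown <- !is.na(dt$rname) & !dt$rname %in% sn
  if (any(unknown))
    stop("malformed SAM record at line ", rec_lines[which(unknown)[1L]],
         ": contig '", dt$rname[which(unknown)[1L]], "' absent from header")
  if (any(!unmapped & is.na(dt$pos)))
    stop("malformed SAM record at line ",
         rec_lines[which(!unmapped & is.na(dt$pos))[1L]],
         ": mapped record without position")
  if (any(unmapped & !is.na(dt$cigar)))
    stop("malformed SAM record at line ",
         rec_lines[which(unmapped & !is.na(dt$cigar))[1L]],
         ": unmapped record carries a cigar")

  # cigar/sequence length consistency
  has_cig <- !is.na(dt$cigar)
  if (any(has_cig)) {
    qlen <- .cigar_query_len(dt$cigar[has_cig])
    slen <- nchar(dt$seq[has_cig])
    mism <- qlen != slen & dt$seq[has_cig] != "*"
    if (any(mism))
      stop("malformed SAM record at line ", rec_lines[has_cig][which(mism)[1L]],
           ": cigar implies ", qlen[which(mism)[1L]],
           " query bases but sequence has ", slen[which(mism)[1L]])
  }
  paired <- .has_flag(dt$flag, FLAG_PAIRED)
  r1 <- .has_flag(dt$flag, FLAG_READ1)
  r2 <- .has_flag(dt$flag, FLAG_READ2)
  if (any(paired & (r1 == r2)))
    stop("malformed SAM record at line ",
         rec_lines[which(paired & (r1 == r2))[1L]],
         ": paired record must set exactly one of first/second-in-pair")

  if (!is.null(region)) dt <- dt[!is.na(rname) & rname == region]
  .as_qc_alignments(dt, contigs)
}

#' Write alignment records as SAM text
#'
#' Inverse of [read_alignments()]: emits an `@HD`/`@SQ` header from the
#' `contigs` attribute and one 11-field record line per row, converting the
#' internal 0-based coordinates back to SAM's 1-based convention.
#'
#' @param aln A `qc_alignments` table.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_alignments <- function(aln, path) {
  contigs <- attr(aln, "contigs")
  if (is.null(contigs)) stop("alignments carry no 'contigs' attribute")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
    aln$qname, aln$flag,
    ifelse(is.na(aln$rname), "*", aln$rname),
    ifelse(is.na(aln$pos), 0L, aln$pos + 1L),
    aln$mapq,
    ifelse(is.na(aln$cigar), "*", aln$cigar),
    ifelse(is.na(aln$rnext), "*", aln$rnext),
    ifelse(is.na(aln$pnext), 0L, aln$pnext + 1L),
    aln$tlen, aln$seq, aln$qual)
  con <- file(path, open = "wb")  # fixed \n endings so output is byte-stable
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Read a spike-in panel (sequences plus expected concentrations)
#'
#' @param sequences FASTA file of spike-in reference sequences.
#' @param concentrations Tab-delimited table with header columns
#'   `id`, `concentration` (attomoles/microlitre, strictly positive) and
#'   `length` (nucleotides; cross-checked against the sequence).
#' @return A `spikein_panel` data.table with columns `id`, `sequence`,
#'   `concentration`, `length`.
#' @export
read_spikein_panel <- function(sequences, concentrations) {
  seqs <- Biostrings::readDNAStringSet(sequences)
  tab <- data.table::fread(concentrations, sep = "\t", header = TRUE,
                           colClasses = list(character = "id"))
  need <- c("id", "concentration", "length")
  if (!all(need %in% names(tab)))
    stop("concentration table must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(tab$id, names(seqs))
  if (length(missing))
    stop("spike-in id(s) in table absent from sequence file: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (any(!is.finite(tab$concentration) | tab$concentration <= 0))
    stop("spike-in concentrations must be strictly positive")
  seq_chr <- as.character(seqs[tab$id])
  if (any(nchar(seq_chr) != tab$length))
    stop("spike-in length mismatch between table and sequences for: ",
         paste(tab$id[nchar(seq_chr) != tab$length][1L], collapse = ", "))
  panel <- data.table::data.table(id = tab$id, sequence = unname(seq_chr),
                                  concentration = as.numeric(tab$concentration),
                                  length = as.integer(tab$length))
  data.table::setattr(panel, "class", c("spikein_panel", class(panel)))
  panel
}

#' Write a spike-in panel to FASTA + concentration table
#'
#' @param panel A `spikein_panel`.
#' @param fasta,table Output paths for the sequence FASTA and the
#'   tab-delimited concentration table.
#' @return Invisibly, a list with both paths.
#' @export
write_spikein_panel <- function(panel, fasta, table) {
  ss <- Biostrings::DNAStringSet(stats::setNames(panel$sequence, panel$id))
  Biostrings::writeXStringSet(ss, fasta)
  # %.17g so concentrations round-trip to the exact stored double
  out <- data.table::data.table(id = panel$id,
                                concentration = sprintf("%.17g",
                                                        panel$concentration),
                                length = panel$length)
  data.table::fwrite(out, table, sep = "\t")
  invisible(list(fasta = fasta, table = table))
}

# units for the flat scalar metrics (used by the tsv serialisation)
.metric_units <- c(
  total_reads = "count", aligned_fraction = "proportion",
  pct_exonic = "proportion", pct_intronic = "proportion",
  pct_intergenic = "proportion", pct_mitochondrial = "proportion",
  pct_rRNA = "proportion", duplicate_rate = "proportion",
  strand_specificity = "proportion", junctions_observed = "count",
  intron_exon_ratio = "ratio", genes_detected = "count",
  five_three_ratio = "ratio", base_error_rate_per_kb = "per_kb",
  spikein_error_rate_per_kb = "per_kb", spikein_correlation = "pearson_r",
  insert_size.mean = "nt", insert_size.median = "nt", insert_size.sd = "nt")

#' Construct a per-library metrics report
#'
#' Bundles the full QC vector for one library. Fields that cannot be
#' computed (for example the insert-size block when no mitochondrial pairs
#' exist) are explicitly `NA`, and serialise as JSON `null` rather than
#' being dropped.
#'
#' @param ... Named metric values; unnamed fields default to `NA`.
#' @return An object of class `library_metrics_report`.
#' @export
library_metrics_report <- function(...) {
  given <- list(...)
  fields <- c("total_reads", "aligned_fraction", "pct_exonic", "pct_intronic",
              "pct_intergenic", "pct_mitochondrial", "pct_rRNA",
              "duplicate_rate", "strand_specificity", "junctions_observed",
              "intron_exon_ratio", "genes_detected", "five_three_ratio",
              "base_error_rate_per_kb", "spikein_error_rate_per_kb",
              "spikein_correlation", "insert_size_summary")
  out <- stats::setNames(rep(list(NA_real_), length(fields)), fields)
  out$insert_size_summary <- NULL
  out$insert_size_summary <- list(mean = NA_real_, median = NA_real_,
                                  sd = NA_real_)
  unknown <- setdiff(names(given), fields)
  if (length(unknown)) stop("unknown report field(s): ",
                            paste(unknown, collapse = ", "))
  for (nm in names(given)) out[[nm]] <- given[[nm]]
  structure(out, class = "library_metrics_report")
}

#' @export
print.library_metrics_report <- function(x, ...) {
  cat("Library QC metrics\n")
  flat <- .flatten_report(x)
  for (i in seq_len(nrow(flat)))
    cat(sprintf("  %-26s %s\n", flat$metric[i],
                ifelse(is.na(flat$value[i]), "NA",
                       format(flat$value[i], digits = 6))))
  invisible(x)
}

.flatten_report <- function(report) {
  x <- unclass(report)
  iss <- x$insert_size_summary
  x$insert_size_summary <- NULL
  flat <- data.table::data.table(metric = names(x),
                                 value = vapply(x, function(v)
                                   as.numeric(v %||% NA_real_)[1L], numeric(1)))
  if (!is.null(iss))
    flat <- rbind(flat, data.table::data.table(
      metric = paste0("insert_size.", names(iss)),
      value = vapply(iss, function(v) as.numeric(v %||% NA_real_)[1L],
                     numeric(1))))
  flat[, units := .metric_units[metric]]
  flat
}

#' Serialise a metrics report
#'
#' JSON keeps the nested structure (missing metrics become `null`, never
#' absent keys); TSV emits one metric per row with columns
#' `metric`, `value`, `units`, flattening the insert-size block.
#'
#' @param report A `library_metrics_report`.
#' @param path Output file path.
#' @param format `"json"` or `"tsv"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    # digits = I(17): round-trip every double to full stored precision
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = I(17), na = "null", null = "null")
  } else {
    data.table::fwrite(.flatten_report(report), path, sep = "\t", na = "NA")
  }
  invisible(path)
}

#' Read back a JSON metrics report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A `library_metrics_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- lapply(x, function(v) if (is.null(v)) NA_real_ else v)
  if (is.list(x$insert_size_summary))
    x$insert_size_summary <- lapply(x$insert_size_summary,
                                    function(v) if (is.null(v)) NA_real_ else v)
  do.call(library_metrics_report, x)
}
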