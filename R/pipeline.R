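# End-to-end assembly: configuration, stage ordering, logging, the full
# per-library report and the multi-library comparison table.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the QC stages. Down-sampling (when
#' `downsample_n` is set) precedes duplicate marking by default, matching
#' the usual order of depth normalisation before diversity estimation; set
#' `downsample_after_dedup = TRUE` to reverse the two stages.
#'
#' @param orientation Library chemistry for strand inference.
#' @param min_overhang Minimum reference bases flanking a junction skip.
#' @param min_count Read-count threshold for gene detection.
#' @param pseudocount Pseudocount for log-RPKM expression correlation.
#' @param literal_denominator Strand-specificity over all annotated
#'   junctions instead of observed ones.
#' @param mito_contig Mitochondrial contig name.
#' @param max_insert Insert-size cap.
#' @param min_baseq Minimum base quality for mismatch counting.
#' @param min_mean_cov,min_length,n_bins,window_frac Coverage-bias
#'   parameters.
#' @param seed_length,min_identity,min_cov Spike-in realigner parameters.
#' @param downsample_n,downsample_seed,downsample_repeats Optional exact
#'   fragment down-sampling; with `downsample_repeats > 1` the pipeline is
#'   repeated with seeds `downsample_seed + 0:(repeats-1)` and per-metric
#'   mean/min/max are attached to the report, a direct check that results
#'   are stable under random read sampling.
#' @param downsample_after_dedup Reverse the downsample/dedup stage order.
#' @param verbose Emit per-stage record counts via `message()`.
#' @return A `qc_config` list.
#' @export
qc_config <- function(orientation = "reverse-stranded", min_overhang = 3L,
                      min_count = 1L, pseudocount = 0.1,
                      literal_denominator = FALSE, mito_contig = "chrM",
                      max_insert = 2000L, min_baseq = 0L,
                      min_mean_cov = 5, min_length = 500L, n_bins = 100L,
                      window_frac = 0.2, seed_length = 20L,
                      min_identity = 0.95, min_cov = 0.9,
                      downsample_n = NULL, downsample_seed = 1L,
                      downsample_repeats = 1L,
                      downsample_after_dedup = FALSE, verbose = FALSE) {
  cfg <- as.list(environment())
  cfg$orientation <- match.arg(orientation,
    c("reverse-stranded", "forward-stranded", "unstranded"))
  stopifnot(cfg$min_overhang >= 1L, cfg$min_count >= 1L,
            cfg$max_insert > 0L, cfg$min_mean_cov > 0,
            cfg$min_length >= cfg$n_bins, cfg$downsample_repeats >= 1L)
  structure(cfg, class = "qc_config")
}

.log_stage <- function(verbose, ...) if (verbose) message("[strandqc] ", ...)

.resolve_alignments <- function(x) {
  if (inherits(x, "qc_alignments")) x else read_alignments(x)
}
.resolve_index <- function(x, mito_contig) {
  if (inherits(x, "annotation_index")) x
  else parse_gtf(x, mito_contig = mito_contig)
}
.resolve_panel <- function(x) {
  if (is.null(x) || inherits(x, "spikein_panel")) x
  else read_spikein_panel(x$sequences %||% x[[1L]],
                          x$concentrations %||% x[[2L]])
}

#' Run the full QC pipeline on one library
#'
#' Stage order: read, optional exact down-sampling, duplicate marking, then
#' profiling, strand-specificity, coverage bias, base error rate, insert
#' size, and the spike-in analysis (pool extraction, realignment,
#' dose-response, spike-in error rate). Identical inputs and configuration
#' give an identical report.
#'
#' @param alignments A `qc_alignments` table or SAM path.
#' @param annotation An `annotation_index` or GTF path.
#' @param reference Optional genome reference (named character vector,
#'   `DNAStringSet` or FASTA path); required for the base error rate.
#' @param panel Optional `spikein_panel` or
#'   `list(sequences =, concentrations =)` paths; required for the spike-in
#'   block.
#' @param config A [qc_config()].
#' @param mask Optional variant mask for mismatch counting (data.frame of
#'   `contig`, `pos`).
#' @return A `library_metrics_report` with the gene expression table in
#'   attribute `"expression"` and, when `downsample_repeats > 1`, the
#'   per-metric stability table in attribute `"repeats"`.
#' @export
run_qc <- function(alignments, annotation, reference = NULL, panel = NULL,
                   config = qc_config(), mask = NULL) {
  stopifnot(inherits(config, "qc_config"))
  aln0 <- .resolve_alignments(alignments)
  index <- .resolve_index(annotation, config$mito_contig)
  panel <- .resolve_panel(panel)
  .log_stage(config$verbose, "input: ", nrow(aln0), " records, ",
             length(unique(aln0$qname)), " fragments")

  run_once <- function(ds_seed) {
    aln <- aln0
    if (!is.null(config$downsample_n) && !config$downsample_after_dedup) {
      aln <- downsample(aln, config$downsample_n, ds_seed)
      .log_stage(config$verbose, "downsample(seed=", ds_seed, "): ",
                 nrow(aln), " records")
    }
    md <- mark_duplicates(aln)
    aln <- md$alignments
    .log_stage(config$verbose, "mark_duplicates: ",
               md$summary$duplicate_fragments, "/",
               md$summary$fragments_total, " fragments flagged")
    if (!is.null(config$downsample_n) && config$downsample_after_dedup) {
      aln <- downsample(aln, config$downsample_n, ds_seed)
      .log_stage(config$verbose, "downsample(seed=", ds_seed, "): ",
                 nrow(aln), " records")
    }

    prof <- profile_library(aln, index)
    ss <- tryCatch(strand_specificity(aln, index,
                                      orientation = config$orientation,
                                      min_overhang = config$min_overhang,
                                      literal_denominator =
                                        config$literal_denominator),
                   warning = function(w) list(value = NA_real_,
                                              junctions_observed = 0L))
    # same classification as the profile stage; avoid a second pass
    ier <- if (!is.na(prof$report$pct_exonic) && prof$report$pct_exonic > 0)
      prof$report$pct_intronic / prof$report$pct_exonic else NA_real_
    cb <- five_prime_three_prime_ratio(aln, index,
                                       min_mean_cov = config$min_mean_cov,
                                       min_length = config$min_length,
                                       n_bins = config$n_bins,
                                       window_frac = config$window_frac)
    err_kb <- NA_real_
    if (!is.null(reference)) {
      tal <- base_error_rate(aln, reference, mask = mask,
                             min_baseq = config$min_baseq)
      err_kb <- tal$rate_per_kb
    }
    ins <- suppressWarnings(
      insert_size_distribution(aln, config$mito_contig,
                               max_insert = config$max_insert))
    sp_err <- NA_real_; sp_cor <- NA_real_
    if (!is.null(panel)) {
      pool <- suppressWarnings(extract_spikein_pool(aln))
      .log_stage(config$verbose, "spike-in pool: ", nrow(pool), " reads")
      spr <- align_to_panel(pool, panel, seed_length = config$seed_length,
                            min_identity = config$min_identity,
                            min_cov = config$min_cov)
      sp_err <- spikein_error_rate(spr)
      sp_cor <- suppressWarnings(spikein_dose_response(spr, panel))
    }

    report <- library_metrics_report(
      total_reads = prof$report$total_reads,
      aligned_fraction = prof$report$aligned_fraction,
      pct_exonic = prof$report$pct_exonic,
      pct_intronic = prof$report$pct_intronic,
      pct_intergenic = prof$report$pct_intergenic,
      pct_mitochondrial = prof$report$pct_mitochondrial,
      pct_rRNA = prof$report$pct_rRNA,
      duplicate_rate = md$summary$duplicate_rate,
      strand_specificity = ss$value,
      junctions_observed = ss$junctions_observed,
      intron_exon_ratio = ier,
      genes_detected = genes_detected(prof$expression, config$min_count),
      five_three_ratio = cb$ratio,
      base_error_rate_per_kb = err_kb,
      spikein_error_rate_per_kb = sp_err,
      spikein_correlation = sp_cor,
      insert_size_summary = list(mean = ins$mean, median = ins$median,
                                 sd = ins$sd))
    attr(report, "expression") <- prof$expression
    attr(report, "profile") <- cb$profile
    report
  }

  report <- run_once(config$downsample_seed)
  if (!is.null(config$downsample_n) && config$downsample_repeats > 1L) {
    flats <- lapply(seq_len(config$downsample_repeats) - 1L, function(k)
      .flatten_report(run_once(config$downsample_seed + k))[, .(metric, value)])
    all <- data.table::rbindlist(flats)
    stab <- all[, .(mean = mean(value), min = min(value), max = max(value)),
                by = metric]
    attr(report, "repeats") <- stab[]
  }
  report
}

#' Compare libraries: metric table and pairwise expression correlation
#'
#' @param reports List of `library_metrics_report`s (one per library) whose
#'   expression attributes share one gene universe.
#' @param expressions Optional list of expression tables (defaults to the
#'   reports' `"expression"` attributes).
#' @param names Library names.
#' @param pseudocount Pseudocount for the log-RPKM correlation.
#' @return list: `table` (one row of scalar metrics per library) and
#'   `correlation` (symmetric pairwise Pearson matrix with unit diagonal).
#' @export
compare_libraries <- function(reports, expressions = NULL, names = NULL,
                              pseudocount = 0.1) {
  if (length(reports) < 1L) stop("need at least one report")
  if (is.null(expressions))
    expressions <- lapply(reports, attr, "expression")
  if (any(vapply(expressions, is.null, logical(1))))
    stop("missing expression table(s)")
  k <- length(reports)
  if (is.null(names)) names <- paste0("library", seq_len(k))
  universe <- lapply(expressions, function(e) sort(e$gene_id))
  if (!all(vapply(universe, identical, logical(1), universe[[1L]])))
    stop("libraries were profiled against different annotations")
  tab <- data.table::rbindlist(lapply(reports, function(r)
    data.table::as.data.table(as.list(stats::setNames(
      .flatten_report(r)$value, .flatten_report(r)$metric)))))
  tab <- cbind(data.table::data.table(library = names), tab)
  cm <- diag(1, k)
  dimnames(cm) <- list(names, names)
  if (k > 1L)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      r <- suppressWarnings(expression_correlation(
        expressions[[i]], expressions[[j]], pseudocount = pseudocount))
      cm[i, j] <- cm[j, i] <- r
    }
  list(table = tab[], correlation = cm)
}
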