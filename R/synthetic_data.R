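# Synthetic-data generator: toy genome + spliced annotation + spike-in
# panel, and paired strand-tagged alignment records with fully known ground
# truth. Everything is deterministic under the config seed; the generator's
# bookkeeping (SimulationTruth) is the master oracle for every downstream
# metric.

#' Simulation configuration
#'
#' Defaults describe a small but realistic strand-specific (dUTP) paired-end
#' library: PE75 reads, ~300 +/- 30 nt cDNA fragments, a 0.003 per-base
#' substitution rate (the middle of the 0.002-0.004 range typical of such
#' libraries), a low duplication level, about 1% rRNA, 5% mitochondrial,
#' 15% intronic, 3% intergenic and 2% spike-in fragments, with the
#' remainder exonic.
#'
#' @param seed Integer master seed; reference generation and library
#'   simulation draw from streams derived from it.
#' @param n_genes Number of spliced protein-coding genes on the autosome-like
#'   contigs.
#' @param exons_per_gene,exon_length,intron_length Integer ranges
#'   (length-2 vectors) sampled uniformly per gene/exon/intron.
#' @param expression_dispersion Log-normal sigma of per-gene expression
#'   weights.
#' @param n_fragments Number of cDNA fragments to emit.
#' @param fragment_mean,fragment_sd Normal fragment-length parameters (nt);
#'   lengths are truncated to `[read_length, source length]`.
#' @param read_length Read length (nt) of each mate.
#' @param antisense_rate Probability a fragment is emitted from the strand
#'   opposite its source transcript (0 = perfectly strand-specific).
#' @param substitution_rate i.i.d. per-base substitution probability.
#' @param duplication_mean_extra Mean number of extra PCR copies per unique
#'   fragment (geometric); 0 disables duplication. The expected duplicate
#'   fraction is `m/(1+m)`.
#' @param three_prime_bias 0 = uniform fragment starts; larger values draw
#'   starts exponentially closer to the 3' end (weight `exp(b*x)` for
#'   relative position x of the start along the transcript).
#' @param rrna_fraction,mito_fraction,intronic_fraction,intergenic_fraction,spikein_fraction
#'   Category fractions; they must sum to at most 1 and the remainder is
#'   exonic.
#' @param orientation Library chemistry: `"reverse-stranded"` (dUTP,
#'   default), `"forward-stranded"` or `"unstranded"`.
#' @param n_spikeins Spike-in panel size (default 92).
#' @param spike_decoy_fraction Fraction of spike-in pairs emitted with
#'   exactly one unmapped mate (the other mate is a mapped genomic decoy),
#'   exercising the "unaligned itself, or has an unaligned mate" rule.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_genes = 120L,
                              exons_per_gene = c(2L, 6L),
                              exon_length = c(120L, 400L),
                              intron_length = c(100L, 600L),
                              expression_dispersion = 1,
                              n_fragments = 20000L,
                              fragment_mean = 300, fragment_sd = 30,
                              read_length = 75L,
                              antisense_rate = 0,
                              substitution_rate = 0.003,
                              duplication_mean_extra = 0.1,
                              three_prime_bias = 0,
                              rrna_fraction = 0.01,
                              mito_fraction = 0.05,
                              intronic_fraction = 0.15,
                              intergenic_fraction = 0.03,
                              spikein_fraction = 0.02,
                              orientation = "reverse-stranded",
                              n_spikeins = 92L,
                              spike_decoy_fraction = 0.15) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              expression_dispersion = expression_dispersion,
              n_fragments = as.integer(n_fragments),
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              read_length = as.integer(read_length),
              antisense_rate = antisense_rate,
              substitution_rate = substitution_rate,
              duplication_mean_extra = duplication_mean_extra,
              three_prime_bias = three_prime_bias,
              rrna_fraction = rrna_fraction, mito_fraction = mito_fraction,
              intronic_fraction = intronic_fraction,
              intergenic_fraction = intergenic_fraction,
              spikein_fraction = spikein_fraction,
              orientation = match.arg(orientation,
                c("reverse-stranded", "forward-stranded", "unstranded")),
              n_spikeins = as.integer(n_spikeins),
              spike_decoy_fraction = spike_decoy_fraction)
  rates <- c(cfg$antisense_rate, cfg$substitution_rate, cfg$rrna_fraction,
             cfg$mito_fraction, cfg$intronic_fraction,
             cfg$intergenic_fraction, cfg$spikein_fraction,
             cfg$spike_decoy_fraction)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  fracs <- cfg$rrna_fraction + cfg$mito_fraction + cfg$intronic_fraction +
    cfg$intergenic_fraction + cfg$spikein_fraction
  if (fracs > 1) stop("category fractions sum to more than 1")
  if (cfg$duplication_mean_extra < 0 || cfg$three_prime_bias < 0)
    stop("duplication_mean_extra and three_prime_bias must be nonnegative")
  if (length(cfg$exons_per_gene) != 2L || length(cfg$exon_length) != 2L ||
      length(cfg$intron_length) != 2L)
    stop("exons_per_gene, exon_length and intron_length must be length-2 ranges")
  structure(cfg, class = "simulation_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.sample_range <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

#' Generate a toy reference, annotation and spike-in panel
#'
#' Lays out `n_genes` spliced genes plus two single-exon rRNA genes across
#' two autosome-like contigs, one mitochondrial contig carrying a single
#' long unspliced gene, and a spike-in panel whose concentrations are
#' log-uniform over four orders of magnitude (lengths 250-2000 nt). The GTF,
#' genome FASTA and panel files are written under `dir`; outputs are
#' byte-identical for identical configs.
#'
#' @param config A `simulation_config`.
#' @param dir Output directory (created if needed).
#' @return A `toy_reference` list: `reference` (named character vector of
#'   contig sequences), `contigs` (named lengths), file paths (`gtf_path`,
#'   `genome_path`, `panel_fasta`, `panel_table`), the `spikein_panel`, and
#'   the gene/exon layout tables.
#' @export
generate_reference_and_annotation <- function(config, dir = tempfile("toyref")) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .with_seed(config$seed, {
    n <- config$n_genes
    gene_contig <- rep(c("chr1", "chr2"), length.out = n)
    n_ex <- .sample_range(n, config$exons_per_gene)
    strand <- sample(c("+", "-"), n, replace = TRUE)

    exon_rows <- vector("list", n)
    cursor <- c(chr1 = 1000L, chr2 = 1000L)
    gene_tab <- data.table::data.table(
      gene_id = sprintf("gene%03d", seq_len(n)),
      transcript_id = sprintf("tx%03d", seq_len(n)),
      contig = gene_contig, strand = strand, n_exons = n_ex,
      biotype = "protein_coding")
    for (i in seq_len(n)) {
      el <- .sample_range(n_ex[i], config$exon_length)
      il <- if (n_ex[i] > 1L) .sample_range(n_ex[i] - 1L,
                                            config$intron_length) else integer(0)
      starts <- integer(n_ex[i]); ends <- integer(n_ex[i])
      p <- cursor[[gene_contig[i]]]
      for (k in seq_len(n_ex[i])) {
        starts[k] <- p; ends[k] <- p + el[k]
        p <- ends[k] + if (k < n_ex[i]) il[k] else 0L
      }
      cursor[[gene_contig[i]]] <- p + sample(800:2500, 1L)
      exon_rows[[i]] <- data.table::data.table(
        gene_id = gene_tab$gene_id[i], transcript_id = gene_tab$transcript_id[i],
        contig = gene_contig[i], strand = strand[i],
        start = starts, end = ends, biotype = "protein_coding")
    }
    # two single-exon rRNA genes on chr1, after the coding genes
    rrna <- data.table::rbindlist(lapply(1:2, function(k) {
      s <- cursor[["chr1"]]
      cursor[["chr1"]] <<- s + 1500L + sample(800:2500, 1L)
      data.table::data.table(gene_id = sprintf("rrna%02d", k),
                             transcript_id = sprintf("rrna_tx%02d", k),
                             contig = "chr1", strand = "+",
                             start = s, end = s + 1500L, biotype = "rRNA")
    }))
    # one long unspliced mitochondrial gene
    mito <- data.table::data.table(gene_id = "mtGene", transcript_id = "mtTx",
                                   contig = "chrM", strand = "+",
                                   start = 200L, end = 15800L,
                                   biotype = "protein_coding")
    exons <- rbind(data.table::rbindlist(exon_rows), rrna, mito)

    contig_len <- c(
      chr1 = as.integer(cursor[["chr1"]] + 2000L),
      chr2 = as.integer(cursor[["chr2"]] + 2000L),
      chrM = 16000L)
    reference <- vapply(contig_len, .rand_dna, character(1))

    # spike-in panel: log-uniform concentrations over 4 orders of magnitude
    ns <- config$n_spikeins
    sp_len <- sample(250:2000, ns, replace = TRUE)
    sp_conc <- 10^stats::runif(ns, -1.5, 2.5)
    panel <- data.table::data.table(
      id = sprintf("SPIKE_%03d", seq_len(ns)),
      sequence = vapply(sp_len, .rand_dna, character(1)),
      concentration = sp_conc, length = sp_len)
    data.table::setattr(panel, "class", c("spikein_panel", class(panel)))

    # --- write files ---
    gtf_path <- file.path(dir, "annotation.gtf")
    genome_path <- file.path(dir, "genome.fa")
    panel_fasta <- file.path(dir, "spikein.fa")
    panel_table <- file.path(dir, "spikein.tsv")

    attrs <- function(g, t, b) sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";', g, t, b)
    gene_rows <- exons[, .(start = min(start), end = max(end)), by =
                         .(gene_id, transcript_id, contig, strand, biotype)]
    fmt <- function(type, contig, start, end, strand, attr)
      sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\t%s",
              contig, type, start + 1L, end, strand, attr)
    lines <- c(
      fmt("gene", gene_rows$contig, gene_rows$start, gene_rows$end,
          gene_rows$strand,
          sprintf('gene_id "%s"; gene_biotype "%s";',
                  gene_rows$gene_id, gene_rows$biotype)),
      fmt("transcript", gene_rows$contig, gene_rows$start, gene_rows$end,
          gene_rows$strand,
          attrs(gene_rows$gene_id, gene_rows$transcript_id, gene_rows$biotype)),
      fmt("exon", exons$contig, exons$start, exons$end, exons$strand,
          attrs(exons$gene_id, exons$transcript_id, exons$biotype)))
    con <- file(gtf_path, open = "wb"); writeLines(lines, con, sep = "\n")
    close(con)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference),
                                genome_path)
    write_spikein_panel(panel, panel_fasta, panel_table)

    genes_out <- rbind(gene_tab,
                       data.table::data.table(gene_id = c(rrna$gene_id, "mtGene"),
                         transcript_id = c(rrna$transcript_id, "mtTx"),
                         contig = c(rrna$contig, "chrM"),
                         strand = "+", n_exons = 1L,
                         biotype = c(rrna$biotype, "protein_coding")))
    structure(list(reference = reference, contigs = contig_len,
                   gtf_path = gtf_path, genome_path = genome_path,
                   panel_fasta = panel_fasta, panel_table = panel_table,
                   panel = panel, genes = genes_out, exons = exons[]),
              class = "toy_reference")
  })
}

# map transcript-coordinate intervals to genomic blocks through the exon
# structure of each source transcript. iv: data.table(rid, transcript_id, a, b)
# (transcript coords, 0-based half-open). Returns data.table(rid, gstart, gend).
.tx_to_genome <- function(iv, exons) {
  exd <- data.table::copy(exons)
  data.table::setorder(exd, transcript_id, start)
  exd[, elen := end - start]
  # transcript coordinates run 5'->3': genomic order for +, reversed for -
  exd[, ord := if (strand[1L] == "-") rev(seq_len(.N)) else seq_len(.N),
      by = transcript_id]
  data.table::setorder(exd, transcript_id, ord)
  exd[, toff := cumsum(data.table::shift(elen, fill = 0L)), by = transcript_id]
  m <- exd[iv, on = "transcript_id", allow.cartesian = TRUE]
  m <- m[a < toff + elen & toff < b]
  m[, `:=`(ca = pmax(a, toff), cb = pmin(b, toff + elen))]
  plus <- m$strand == "+"
  m[, gstart := ifelse(plus, start + (ca - toff), end - (cb - toff))]
  m[, gend := ifelse(plus, start + (cb - toff), end - (ca - toff))]
  m[, .(rid, gstart, gend)]
}

#' Simulate a strand-specific paired-end library
#'
#' Per fragment: a category is drawn from the configured fractions; exonic
#' fragments pick a gene proportional to log-normal expression weights, a
#' Normal fragment length (truncated to `[read_length, source length]`), a
#' uniform or 3'-weighted start, a strand that is sense with probability
#' `1 - antisense_rate`, i.i.d. substitutions, and `1 + Geometric` PCR
#' copies. Mate pairs are emitted as already-aligned records with correct
#' spliced cigars (N operations exactly at annotated introns) and flags per
#' the library orientation; spike-in fragments become unmapped pairs
#' carrying sequence. A truth record accounts for every emitted alignment.
#'
#' @param config A `simulation_config`.
#' @param ref A `toy_reference` from [generate_reference_and_annotation()]
#'   built from the same config.
#' @param sam_path,truth_path Optional output paths; when given, the SAM
#'   file and a TSV of the per-fragment truth table are written.
#' @return list: `alignments` (`qc_alignments`, coordinate-sorted, mapped
#'   before unmapped) and `truth` (a `simulation_truth` list: per-fragment
#'   table, expression weights, config, category tallies).
#' @export
#' Simulate a strand-specific paired-end library
#'
#' Per fragment: a category is drawn from the configured fractions; exonic
#' fragments pick a gene proportional to log-normal expression weights, a
#' Normal fragment length (truncated to `[read_length, source length]`), a
#' uniform or 3'-weighted start, a strand that is sense with probability
#' `1 - antisense_rate`, i.i.d. substitutions, and `1 + Geometric` PCR
#' copies. Mate pairs are emitted as already-aligned records with correct
#' spliced cigars (N operations exactly at annotated introns) and flags per
#' the library orientation; spike-in fragments become unmapped pairs
#' carrying sequence. A truth record accounts for every emitted alignment.
#'
#' @param config A `simulation_config`.
#' @param ref A `toy_reference` from [generate_reference_and_annotation()]
#'   built from the same config.
#' @param sam_path,truth_path Optional output paths; when given, the SAM
#'   file and a TSV of the per-fragment truth table are written.
#' @return list: `alignments` (`qc_alignments`, coordinate-sorted, mapped
#'   before unmapped) and `truth` (a `simulation_truth` list: per-fragment
#'   table, expression weights, config, category tallies).
#' @export
simulate_library <- function(config, ref, sam_path = NULL, truth_path = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(ref, "toy_reference"))
  .with_seed(config$seed + 1000003L, {
    rl <- config$read_length
    n <- config$n_fragments
    exons <- ref$exons
    bases <- c("A", "C", "G", "T")
    refseq <- ref$reference
    tx_len <- exons[, .(len = sum(end - start), contig = contig[1L],
                        strand = strand[1L], gene_id = gene_id[1L]),
                    by = transcript_id]

    coding <- ref$genes[biotype == "protein_coding" & contig != "chrM"]
    rrna_genes <- ref$genes[biotype == "rRNA"]
    weights <- stats::setNames(
      stats::rlnorm(nrow(coding), 0, config$expression_dispersion),
      coding$gene_id)

    cats <- c("spikein", "rrna", "mito", "intronic", "intergenic", "exonic")
    probs <- c(config$spikein_fraction, config$rrna_fraction,
               config$mito_fraction, config$intronic_fraction,
               config$intergenic_fraction, 0)
    probs[6] <- 1 - sum(probs)
    category <- sample(cats, n, replace = TRUE, prob = probs)

    frag <- data.table::data.table(frag = seq_len(n), category = category)
    frag[, qname := sprintf("f%06d", frag)]
    frag[, `:=`(source = NA_character_, src_len = NA_integer_,
                int_start = NA_integer_, int_contig = NA_character_,
                int_strand = NA_character_)]

    # --- source selection ---
    n_ex_frag <- sum(frag$category == "exonic")
    if (n_ex_frag > 0L) {
      g <- sample(coding$gene_id, n_ex_frag, replace = TRUE,
                  prob = weights[coding$gene_id])
      frag[category == "exonic",
           source := coding$transcript_id[match(g, coding$gene_id)]]
    }
    if (any(frag$category == "rrna"))
      frag[category == "rrna",
           source := sample(rrna_genes$transcript_id, .N, replace = TRUE)]
    frag[category == "mito", source := "mtTx"]
    spliced_src <- frag$category %in% c("exonic", "rrna", "mito")
    frag[spliced_src,
         src_len := tx_len$len[match(source, tx_len$transcript_id)]]

    introns <- exons[, if (.N > 1L) .(istart = end[-.N], iend = start[-1L],
                                      contig = contig[1L],
                                      strand = strand[1L]),
                     by = .(transcript_id, gene_id)]
    if (nrow(introns)) {
      introns[, ilen := iend - istart]
      introns <- introns[ilen >= rl]
    }
    spans <- exons[, .(s = min(start), e = max(end)),
                   by = .(gene_id, contig)]
    inter <- data.table::rbindlist(lapply(c("chr1", "chr2"), function(ct) {
      sp <- spans[contig == ct][order(s)]
      gaps_s <- c(0L, sp$e + 150L)
      gaps_e <- c(sp$s - 150L, unname(ref$contigs[ct]))
      data.table::data.table(contig = ct, s = gaps_s, e = gaps_e)
    }))
    inter <- inter[e - s >= rl + 50L]

    n_in <- sum(frag$category == "intronic")
    if (n_in > 0L) {
      pick <- sample(nrow(introns), n_in, replace = TRUE, prob = introns$ilen)
      frag[category == "intronic", `:=`(
        source = introns$transcript_id[pick], src_len = introns$ilen[pick],
        int_start = introns$istart[pick], int_contig = introns$contig[pick],
        int_strand = introns$strand[pick])]
    }
    n_ig <- sum(frag$category == "intergenic")
    if (n_ig > 0L) {
      pick <- sample(nrow(inter), n_ig, replace = TRUE, prob = inter$e - inter$s)
      frag[category == "intergenic", `:=`(
        source = "intergenic",
        src_len = inter$e[pick] - inter$s[pick],
        int_start = inter$s[pick], int_contig = inter$contig[pick],
        int_strand = sample(c("+", "-"), n_ig, replace = TRUE))]
    }
    n_sp <- sum(frag$category == "spikein")
    if (n_sp > 0L) {
      pk <- ref$panel
      pick <- sample(nrow(pk), n_sp, replace = TRUE,
                     prob = pk$concentration * pk$length)
      frag[category == "spikein", `:=`(source = pk$id[pick],
                                       src_len = pk$length[pick])]
    }

    # --- fragment geometry ---
    frag[, frag_len := pmax(rl, pmin(src_len, as.integer(round(
      stats::rnorm(.N, config$fragment_mean, config$fragment_sd)))))]
    b <- config$three_prime_bias
    frag[, max_start := src_len - frag_len]
    u <- stats::runif(n)
    frag[, tstart := ifelse(max_start == 0L, 0L, as.integer(floor(
      if (b > 0) max_start * log1p(u * expm1(b)) / b
      else u * (max_start + 1L))))]
    frag[tstart > max_start, tstart := max_start]

    frag[, sense := stats::runif(n) >= config$antisense_rate]
    frag[, src_strand := NA_character_]
    frag[spliced_src,
         src_strand := tx_len$strand[match(source, tx_len$transcript_id)]]
    frag[category %in% c("intronic", "intergenic"), src_strand := int_strand]
    frag[, fstrand := ifelse(sense, src_strand,
                             ifelse(src_strand == "+", "-", "+"))]
    frag[category == "intergenic", fstrand := int_strand]

    # --- PCR copies (mapped categories only) ---
    m_dup <- config$duplication_mean_extra
    frag[, n_copies := 1L]
    if (m_dup > 0) {
      genomic <- frag$category != "spikein"
      frag[genomic, n_copies := 1L + stats::rgeom(sum(genomic),
                                                  prob = 1 / (1 + m_dup))]
    }

    # ======== genomic (mapped) reads ========
    gmap <- frag[category != "spikein"]
    mapped <- NULL
    two <- NULL
    if (nrow(gmap) > 0L) {
      two <- gmap[rep(seq_len(.N), each = 2L)]
      two[, mateA := rep(c(TRUE, FALSE), nrow(gmap))]
      # mate A covers source coords [tstart, tstart+rl), mate B the 3' end
      two[, a := ifelse(mateA, tstart, tstart + frag_len - rl)]
      two[, bcoord := a + rl]
      two[, rid := seq_len(.N)]
      two[, genomic_src := category %in% c("intronic", "intergenic")]

      spl <- two[genomic_src == FALSE]
      blocks_spl <- .tx_to_genome(
        spl[, .(rid, transcript_id = source, a, b = bcoord)],
        exons[transcript_id %in% unique(spl$source)])
      lin <- two[genomic_src == TRUE]
      blocks_lin <- lin[, .(rid, gstart = int_start + a,
                            gend = int_start + bcoord)]
      blocks <- rbind(blocks_spl, blocks_lin)
      data.table::setorder(blocks, rid, gstart)

      per_read <- blocks[, .(pos = min(gstart), endp = max(gend),
                             cigar = {
                               mlen <- gend - gstart
                               if (.N == 1L) sprintf("%dM", mlen)
                               else {
                                 gap <- gstart[-1L] - gend[-.N]
                                 paste0(paste0(mlen[-.N], "M", gap, "N",
                                               collapse = ""),
                                        mlen[.N], "M")
                               }
                             }), by = rid]
      two[, pos := per_read$pos[match(rid, per_read$rid)]]
      two[, endp := per_read$endp[match(rid, per_read$rid)]]
      two[, cigar := per_read$cigar[match(rid, per_read$rid)]]
      two[, contig := ifelse(genomic_src, int_contig,
                             tx_len$contig[match(source,
                                                 tx_len$transcript_id)])]

      # FR geometry: source 5' mate sits genomic-left for "+" sources,
      # genomic-right for "-" sources; intronic/intergenic coordinates are
      # already genomic so mate A is always left.
      two[, gleft := ifelse(genomic_src, mateA, (src_strand == "+") == mateA)]
      two[, rev := !gleft]
      two[, mate_strand := ifelse(gleft, "+", "-")]
      # chemistry: reverse-stranded (dUTP) sequences the fragment strand as
      # read2; forward-stranded as read1; unstranded picks at random.
      if (config$orientation == "unstranded") {
        pickr <- stats::runif(nrow(gmap)) < 0.5
        two[, is_read2 := rep(pickr, each = 2L) == mateA]
      } else if (config$orientation == "reverse-stranded") {
        two[, is_read2 := mate_strand == fstrand]
      } else {
        two[, is_read2 := mate_strand != fstrand]
      }

      # sequences from the forward reference, then substitutions
      blocks[, contig := two$contig[match(rid, two$rid)]]
      blocks[, part := substring(refseq[contig], gstart + 1L, gend)]
      seqs <- blocks[, .(seq = paste(part, collapse = "")), by = rid]
      two[, seq := seqs$seq[match(rid, seqs$rid)]]

      nsub <- stats::rbinom(nrow(two), rl, config$substitution_rate)
      for (i in which(nsub > 0L)) {
        s <- two$seq[i]
        p <- sample.int(rl, nsub[i])
        for (pp in p) {
          old <- substr(s, pp, pp)
          substr(s, pp, pp) <- sample(setdiff(bases, old), 1L)
        }
        data.table::set(two, i, "seq", s)
      }
      two[, n_subs := nsub]

      two[, flag := FLAG_PAIRED + FLAG_PROPER +
            ifelse(rev, FLAG_REVERSE, 0L) + ifelse(rev, 0L, FLAG_MREV) +
            ifelse(is_read2, FLAG_READ2, FLAG_READ1)]
      mate_pos <- two[, .(pA = pos[1L], pB = pos[2L]), by = frag]
      two[, pnext := ifelse(mateA, mate_pos$pB[match(frag, mate_pos$frag)],
                            mate_pos$pA[match(frag, mate_pos$frag)])]
      span <- two[, .(l = min(pos), r = max(endp)), by = frag]
      two[, tlen := ifelse(gleft, 1L, -1L) *
            (span$r[match(frag, span$frag)] - span$l[match(frag, span$frag)])]

      reps <- two[rep(seq_len(.N), times = n_copies)]
      reps[, copy := seq_len(.N), by = .(frag, mateA)]
      reps[, qname := ifelse(copy == 1L, qname,
                             sprintf("%s.d%02d", qname, copy - 1L))]
      qual_str <- strrep("I", rl)
      mapped <- reps[, .(qname, flag, rname = contig, pos, mapq = 60L,
                         cigar, rnext = "=", pnext, tlen, seq,
                         qual = qual_str)]
    }

    # ======== spike-in (unmapped) reads ========
    smap <- frag[category == "spikein"]
    unmapped <- NULL
    decoy <- NULL
    qual_str <- strrep("I", rl)
    if (nrow(smap) > 0L) {
      stwo <- smap[rep(seq_len(.N), each = 2L)]
      stwo[, mate1 := rep(c(TRUE, FALSE), nrow(smap))]
      stwo[, a := ifelse(mate1, tstart, tstart + frag_len - rl)]
      pk <- ref$panel
      sseq <- substring(pk$sequence[match(stwo$source, pk$id)],
                        stwo$a + 1L, stwo$a + rl)
      sseq[!stwo$mate1] <- .revcomp(sseq[!stwo$mate1])
      nsub_s <- stats::rbinom(nrow(stwo), rl, config$substitution_rate)
      for (i in which(nsub_s > 0L)) {
        s <- sseq[i]
        p <- sample.int(rl, nsub_s[i])
        for (pp in p) {
          old <- substr(s, pp, pp)
          substr(s, pp, pp) <- sample(setdiff(bases, old), 1L)
        }
        sseq[i] <- s
      }
      stwo[, seq := sseq]
      stwo[, n_subs := nsub_s]

      dec_frag <- smap$frag[stats::runif(nrow(smap)) <
                              config$spike_decoy_fraction]
      stwo[, is_decoy := frag %in% dec_frag & mate1]
      stwo[, flag := FLAG_PAIRED + FLAG_UNMAP + FLAG_MUNMAP +
             ifelse(mate1, FLAG_READ1, FLAG_READ2)]
      stwo[is_decoy == TRUE, flag := FLAG_PAIRED + FLAG_MUNMAP + FLAG_READ1]
      stwo[frag %in% dec_frag & !mate1,
           flag := FLAG_PAIRED + FLAG_UNMAP + FLAG_READ2]
      stwo[, `:=`(dcontig = NA_character_, dpos = NA_integer_,
                  dgene = NA_character_)]
      ndec <- sum(stwo$is_decoy)
      if (ndec > 0L) {
        cand <- exons[gene_id %in% coding$gene_id & end - start >= rl]
        ei <- sample(nrow(cand), ndec, replace = TRUE)
        dstart <- cand$start[ei] + as.integer(floor(stats::runif(ndec) *
          (cand$end[ei] - cand$start[ei] - rl + 1L)))
        stwo[is_decoy == TRUE, `:=`(dcontig = cand$contig[ei],
                                    dpos = dstart,
                                    dgene = cand$gene_id[ei])]
        stwo[is_decoy == TRUE,
             seq := substring(refseq[dcontig], dpos + 1L, dpos + rl)]
        # decoys are genomic reads: they carry substitution errors too
        stwo[is_decoy == TRUE, n_subs := 0L]
        dn <- stats::rbinom(ndec, rl, config$substitution_rate)
        drows <- which(stwo$is_decoy)
        for (j in seq_along(drows)) {
          if (dn[j] == 0L) next
          i <- drows[j]
          s <- stwo$seq[i]
          p <- sample.int(rl, dn[j])
          for (pp in p) {
            old <- substr(s, pp, pp)
            substr(s, pp, pp) <- sample(setdiff(bases, old), 1L)
          }
          data.table::set(stwo, i, "seq", s)
          data.table::set(stwo, i, "n_subs", dn[j])
        }
      }
      unmapped <- stwo[is_decoy == FALSE,
                       .(qname, flag, rname = NA_character_,
                         pos = NA_integer_, mapq = 0L, cigar = NA_character_,
                         rnext = NA_character_, pnext = NA_integer_,
                         tlen = 0L, seq, qual = qual_str)]
      if (ndec > 0L)
        decoy <- stwo[is_decoy == TRUE,
                      .(qname, flag, rname = dcontig, pos = dpos,
                        mapq = 60L, cigar = sprintf("%dM", rl),
                        rnext = NA_character_, pnext = NA_integer_,
                        tlen = 0L, seq, qual = qual_str)]
      smap <- merge(smap,
                    stwo[, .(n_subs_r1 = n_subs[mate1],
                             n_subs_r2 = n_subs[!mate1],
                             has_decoy = any(is_decoy),
                             decoy_gene = dgene[mate1]), by = frag],
                    by = "frag", all.x = TRUE)
    }

    # ======== truth bookkeeping ========
    truth_frag <- data.table::copy(frag)
    truth_frag[, `:=`(n_subs_r1 = NA_integer_, n_subs_r2 = NA_integer_,
                      has_decoy = FALSE, decoy_gene = NA_character_)]
    if (!is.null(two)) {
      gsubs <- two[, .(r1 = sum(n_subs[!is_read2]),
                       r2 = sum(n_subs[is_read2])), by = frag]
      truth_frag[match(gsubs$frag, frag), `:=`(n_subs_r1 = gsubs$r1,
                                               n_subs_r2 = gsubs$r2)]
    }
    if (nrow(smap) > 0L) {
      truth_frag[match(smap$frag, frag), `:=`(
        n_subs_r1 = smap$n_subs_r1, n_subs_r2 = smap$n_subs_r2,
        has_decoy = smap$has_decoy, decoy_gene = smap$decoy_gene)]
    }

    # ======== assemble, coordinate-sort (mapped first, unmapped last) ========
    bindable <- function(lst) {
      lst <- lst[!vapply(lst, is.null, logical(1))]
      if (length(lst)) data.table::rbindlist(lst, use.names = TRUE) else NULL
    }
    aln <- bindable(list(mapped, decoy))
    if (!is.null(aln)) {
      corder <- names(ref$contigs)
      aln[, cidx := match(rname, corder)]
      data.table::setorder(aln, cidx, pos, qname, flag)
      aln[, cidx := NULL]
    }
    aln <- bindable(list(aln, unmapped))
    if (is.null(aln))
      aln <- data.table::data.table(qname = character(), flag = integer(),
        rname = character(), pos = integer(), mapq = integer(),
        cigar = character(), rnext = character(), pnext = integer(),
        tlen = integer(), seq = character(), qual = character())
    aln[, `:=`(flag = as.integer(flag), pos = as.integer(pos),
               mapq = as.integer(mapq), pnext = as.integer(pnext),
               tlen = as.integer(tlen))]
    aln <- .as_qc_alignments(aln, ref$contigs)

    truth <- structure(list(
      fragments = truth_frag[, .(frag, qname, category, source,
                                 strand = fstrand, sense, tstart, frag_len,
                                 n_copies, n_subs_r1, n_subs_r2, has_decoy,
                                 decoy_gene)],
      expression_weights = data.table::data.table(gene_id = coding$gene_id,
                                                  weight = unname(weights)),
      config = config,
      n_fragments_emitted = nrow(frag),
      n_records = nrow(aln)), class = "simulation_truth")

    if (!is.null(sam_path)) write_alignments(aln, sam_path)
    if (!is.null(truth_path))
      data.table::fwrite(truth$fragments, truth_path, sep = "\t")
    list(alignments = aln, truth = truth)
  })
}
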