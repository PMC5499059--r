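# Internal helpers shared across modules: SAM flag bits, seeded RNG scoping,
# and vectorised CIGAR decomposition. All coordinates are 0-based half-open;
# SAM/GTF 1-based conventions are converted at the file boundary only.

FLAG_PAIRED  <- 1L
FLAG_PROPER  <- 2L
FLAG_UNMAP   <- 4L
FLAG_MUNMAP  <- 8L
FLAG_REVERSE <- 16L
FLAG_MREV    <- 32L
FLAG_READ1   <- 64L
FLAG_READ2   <- 128L
FLAG_DUP     <- 1024L

.has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

CIGAR_OPS <- c("M", "I", "D", "N", "S")

# Decompose cigar strings into one row per operation.
# Returns data.table(idx, op, len) where idx indexes the input vector.
.cigar_table <- function(cigar) {
  ok <- !is.na(cigar) & cigar != "*"
  toks <- vector("list", length(cigar))
  if (any(ok)) {
    m <- gregexpr("[0-9]+[A-Z=]", cigar[ok], perl = TRUE)
    toks[ok] <- regmatches(cigar[ok], m)
  }
  nops <- lengths(toks)
  tok <- unlist(toks, use.names = FALSE)
  if (is.null(tok)) tok <- character(0)
  nc <- nchar(tok)
  dt <- data.table::data.table(
    idx = rep(seq_along(cigar), nops),
    op  = substring(tok, nc, nc),
    len = as.integer(substring(tok, 1L, nc - 1L))
  )
  bad <- !dt$op %in% CIGAR_OPS
  if (any(bad))
    stop("unsupported cigar operation(s): ",
         paste(unique(dt$op[bad]), collapse = ", "),
         " (only M, I, D, N, S are handled)")
  dt
}

# Reference-consuming M blocks of each record, plus the query offset of each
# block. pos must be the 0-based leftmost mapped coordinate per idx.
# Returns data.table(idx, gstart, gend, qstart) with 0-based half-open gstart/gend
# and 0-based qstart into the stored sequence.
.m_blocks <- function(cigar, pos) {
  ops <- .cigar_table(cigar)
  if (nrow(ops) == 0L)
    return(data.table::data.table(idx = integer(), gstart = integer(),
                                  gend = integer(), qstart = integer()))
  ops[, ref_len := ifelse(op %in% c("M", "D", "N"), len, 0L)]
  ops[, qry_len := ifelse(op %in% c("M", "I", "S"), len, 0L)]
  ops[, ref_off := cumsum(data.table::shift(ref_len, fill = 0L)), by = idx]
  ops[, qry_off := cumsum(data.table::shift(qry_len, fill = 0L)), by = idx]
  mb <- ops[op == "M"]
  mb[, gstart := pos[idx] + ref_off]
  mb[, gend := gstart + len]
  mb[, qstart := qry_off]
  mb[, .(idx, gstart, gend, qstart)]
}

# N-skip intervals of each record with the lengths of the immediately
# flanking M operations (0 when the neighbour is not an M).
.n_skips <- function(cigar, pos) {
  ops <- .cigar_table(cigar)
  if (nrow(ops) == 0L)
    return(data.table::data.table(idx = integer(), nstart = integer(),
                                  nend = integer(), left_m = integer(),
                                  right_m = integer()))
  ops[, ref_len := ifelse(op %in% c("M", "D", "N"), len, 0L)]
  ops[, ref_off := cumsum(data.table::shift(ref_len, fill = 0L)), by = idx]
  ops[, `:=`(prev_op = data.table::shift(op), next_op = data.table::shift(op, -1L),
             prev_len = data.table::shift(len), next_len = data.table::shift(len, -1L)),
      by = idx]
  ns <- ops[op == "N"]
  ns[, nstart := pos[idx] + ref_off]
  ns[, nend := nstart + len]
  ns[, left_m := ifelse(!is.na(prev_op) & prev_op == "M", prev_len, 0L)]
  ns[, right_m := ifelse(!is.na(next_op) & next_op == "M", next_len, 0L)]
  ns[, .(idx, nstart, nend, left_m, right_m)]
}

# Query length implied by a cigar (sum of M/I/S operations).
.cigar_query_len <- function(cigar) {
  ops <- .cigar_table(cigar)
  out <- integer(length(cigar))
  if (nrow(ops)) {
    q <- ops[op %in% c("M", "I", "S"), .(n = sum(len)), by = idx]
    out[q$idx] <- q$n
  }
  out
}

# Strand of the original cDNA fragment inferred from flags under a library
# orientation. reverse-stranded (dUTP): the second-in-pair read carries the
# transcript strand; forward-stranded: the first-in-pair read does;
# unstranded: the read's own mapped strand (no biological meaning).
.fragment_strand <- function(flag, orientation = c("reverse-stranded",
                                                   "forward-stranded",
                                                   "unstranded")) {
  orientation <- match.arg(orientation)
  read_strand <- ifelse(.has_flag(flag, FLAG_REVERSE), "-", "+")
  flip <- function(s) ifelse(s == "+", "-", "+")
  second <- .has_flag(flag, FLAG_READ2)
  switch(orientation,
    "reverse-stranded" = ifelse(second, read_strand, flip(read_strand)),
    "forward-stranded" = ifelse(second, flip(read_strand), read_strand),
    "unstranded"       = read_strand)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
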