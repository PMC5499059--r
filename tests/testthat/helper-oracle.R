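# Independent brute-force oracles: naive per-read loops with no shared code
# with the package internals. Used for truth-consistency checks.

# parse one cigar string into (op, len) the slow way
oracle_cigar <- function(cigar) {
  ops <- character(0); lens <- integer(0)
  num <- ""
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch %in% as.character(0:9)) num <- paste0(num, ch)
    else { ops <- c(ops, ch); lens <- c(lens, as.integer(num)); num <- "" }
  }
  list(op = ops, len = lens)
}

# M blocks of one record (0-based half-open) by walking the cigar
oracle_blocks <- function(cigar, pos) {
  cg <- oracle_cigar(cigar)
  out <- NULL
  g <- pos; q <- 0L
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op == "M") {
      out <- rbind(out, data.frame(gstart = g, gend = g + len, qstart = q))
      g <- g + len; q <- q + len
    } else if (op %in% c("D", "N")) g <- g + len
    else if (op %in% c("I", "S")) q <- q + len
  }
  out
}

# naive mismatch count of one mapped record against a reference list
oracle_mismatches <- function(rec, reference) {
  bl <- oracle_blocks(rec$cigar, rec$pos)
  mm <- 0L; al <- 0L
  for (i in seq_len(nrow(bl))) {
    rd <- substr(rec$seq, bl$qstart[i] + 1L, bl$qstart[i] + bl$gend[i] -
                   bl$gstart[i])
    rf <- substr(reference[[rec$rname]], bl$gstart[i] + 1L, bl$gend[i])
    v1 <- strsplit(rd, "")[[1]]; v2 <- strsplit(rf, "")[[1]]
    mm <- mm + sum(v1 != v2); al <- al + length(v1)
  }
  c(mismatches = mm, aligned = al)
}

# naive per-junction sense/antisense tally over records, reverse-stranded
oracle_strand_specificity <- function(df, junctions, min_overhang = 3L) {
  tally <- list()
  for (i in seq_len(nrow(df))) {
    if (bitwAnd(df$flag[i], 4L) != 0L || bitwAnd(df$flag[i], 1024L) != 0L)
      next
    if (!grepl("N", df$cigar[i], fixed = TRUE)) next
    cg <- oracle_cigar(df$cigar[i])
    g <- df$pos[i]
    for (k in seq_along(cg$op)) {
      op <- cg$op[k]; len <- cg$len[k]
      if (op == "N") {
        ok <- k > 1L && k < length(cg$op) && cg$op[k - 1L] == "M" &&
          cg$op[k + 1L] == "M" && cg$len[k - 1L] >= min_overhang &&
          cg$len[k + 1L] >= min_overhang
        if (ok) {
          j <- which(junctions$contig == df$rname[i] &
                       junctions$donor_end == g &
                       junctions$acceptor_start == g + len)
          if (length(j) == 1L) {
            read_rev <- bitwAnd(df$flag[i], 16L) != 0L
            second <- bitwAnd(df$flag[i], 128L) != 0L
            rs <- if (read_rev) "-" else "+"
            fs <- if (second) rs else (if (rs == "+") "-" else "+")
            key <- paste(df$rname[i], g, g + len)
            if (is.null(tally[[key]])) tally[[key]] <- c(0L, 0L)
            if (fs == junctions$strand[j]) tally[[key]][1] <-
                tally[[key]][1] + 1L
            else tally[[key]][2] <- tally[[key]][2] + 1L
          }
        }
      }
      if (op %in% c("M", "D", "N")) g <- g + len
    }
  }
  if (length(tally) == 0L) return(list(value = NA_real_, observed = 0L))
  anti0 <- sum(vapply(tally, function(x) x[2] == 0L, logical(1)))
  list(value = anti0 / length(tally), observed = length(tally))
}

# naive duplicate rate: group paired mapped fragments by endpoint key
oracle_duplicate_rate <- function(df) {
  keys <- c()
  for (qn in unique(df$qname)) {
    rows <- df[df$qname == qn, ]
    if (nrow(rows) != 2L || any(bitwAnd(rows$flag, 4L) != 0L)) next
    r1 <- rows[bitwAnd(rows$flag, 64L) != 0L, ]
    r2 <- rows[bitwAnd(rows$flag, 128L) != 0L, ]
    if (nrow(r1) != 1L || nrow(r2) != 1L) next
    u5 <- function(r) {
      cg <- oracle_cigar(r$cigar)
      reflen <- sum(cg$len[cg$op %in% c("M", "D", "N")])
      lead <- if (cg$op[1] == "S") cg$len[1] else 0L
      trail <- if (cg$op[length(cg$op)] == "S") cg$len[length(cg$op)] else 0L
      if (bitwAnd(r$flag, 16L) != 0L) r$pos + reflen + trail else r$pos - lead
    }
    st <- function(r) if (bitwAnd(r$flag, 16L) != 0L) "-" else "+"
    keys <- c(keys, paste(r1$rname, u5(r1), st(r1),
                          r2$rname, u5(r2), st(r2)))
  }
  n <- length(keys)
  dup <- n - length(unique(keys))
  list(rate = dup / n, fragments = n, duplicates = dup)
}

# two-pass textbook Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
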