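# Independent oracles and tiny fixture builders used across the suite.

# Brute-force two-sided Fisher p-value: enumerate every 2x2 table with the
# observed margins, compute each table's probability from the factorial
# formula, and sum those no more probable than the observed table (with the
# same relative tie tolerance as the conditional test).
oracle_fisher <- function(tt, tf, ft, ff) {
  r1 <- tt + tf; r2 <- ft + ff; c1 <- tt + ft
  n <- r1 + r2
  if (n == 0) return(NA_real_)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
    lfactorial(n - c1) - lfactorial(n) -
    (lfactorial(xs) + lfactorial(r1 - xs) + lfactorial(c1 - xs) +
       lfactorial(r2 - c1 + xs))
  p <- exp(logp)
  p_obs <- p[xs == tt]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Naive per-base depth: walk every read's CIGAR by hand and add 1 for every
# reference position consumed by an aligned (M/=/X) or deleted (D) op.
oracle_coverage <- function(pos, cigar, start, end) {
  depth <- integer(end - start + 1L)
  for (i in seq_along(pos)) {
    ops <- regmatches(cigar[i], gregexpr("\\d+[MIDNSHP=X]", cigar[i]))[[1]]
    at <- pos[i]
    for (o in ops) {
      len <- as.integer(sub("[A-Z=]$", "", o))
      op <- sub("^\\d+", "", o)
      if (op %in% c("M", "=", "X", "D")) {
        span <- at:(at + len - 1L)
        hit <- span >= start & span <= end
        depth[span[hit] - start + 1L] <- depth[span[hit] - start + 1L] + 1L
        at <- at + len
      } else if (op == "N") {
        at <- at + len
      }
      # I/S/H/P consume no reference
    }
  }
  depth
}

# Write a minimal single-contig SAM file from a list of records.
write_test_sam <- function(records, path, chrom = "chr", len = 1000L) {
  lines <- c("@HD\tVN:1.6\tSO:unknown",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, len))
  for (r in records) {
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                              r$qname, r$flag %||% 0L, chrom, r$pos,
                              r$mapq %||% 60L, r$cigar, r$seq))
  }
  writeLines(lines, path)
  path
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# A sequence of given length with fixed bases planted at given offsets.
seq_with <- function(len, at = integer(0), base = character(0),
                     fill = "A") {
  x <- rep(fill, len)
  x[at] <- base
  paste(x, collapse = "")
}

# One-editing-site catalogue on the test contig.
editing_catalogue <- function(position = 30L, strand = "+", chrom = "chr") {
  event_catalogue(data.frame(
    event_id = "ed1", kind = "editing", chrom = chrom, strand = strand,
    position = position, intron_start = NA, intron_end = NA,
    transcript_group = "tx", stringsAsFactors = FALSE))
}

# One-intron catalogue on the test contig.
splicing_catalogue <- function(intron_start = 40L, intron_end = 80L,
                               strand = "+", chrom = "chr") {
  event_catalogue(data.frame(
    event_id = "int1", kind = "splicing", chrom = chrom, strand = strand,
    position = NA, intron_start = intron_start, intron_end = intron_end,
    transcript_group = "tx", stringsAsFactors = FALSE))
}

# Annotation matrix built directly from a state-letter matrix.
matrix_from_states <- function(states, catalogue, replicate = "rep1") {
  df <- data.frame(read_id = sprintf("r%03d", seq_len(nrow(states))),
                   replicate = replicate, strand = "+", length = 100L,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(states, stringsAsFactors = FALSE))
  names(df)[-(1:4)] <- catalogue$event_id
  annotation_matrix(df, catalogue)
}
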