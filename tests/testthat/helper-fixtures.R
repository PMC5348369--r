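# Shared fixture builders and independent brute-force oracles.

# Build a Genome from named sequence strings via a temporary FASTA,
# exercising the same loader the pipeline uses.
genome_from_strings <- function(...) {
  seqs <- c(...)
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]]))), fa)
  on.exit(unlink(fa))
  load_genome(fa)
}

# Minimal SAM writer: records is a data.frame with qname, flag, seq
# (rname/pos fixed to unmapped placeholders unless given).
write_mini_sam <- function(path, records = NULL, sq = c(chrT = 1000L)) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  lines <- header
  if (!is.null(records) && nrow(records) > 0) {
    rname <- if (is.null(records$rname)) rep("*", nrow(records)) else records$rname
    pos <- if (is.null(records$pos)) rep(0L, nrow(records)) else records$pos
    cigar <- ifelse(rname == "*", "*", paste0(nchar(records$seq), "M"))
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                              records$qname, records$flag, rname, pos,
                              ifelse(rname == "*", 0L, 60L), cigar,
                              records$seq))
  }
  writeLines(lines, path)
  path
}

# Brute-force exact-occurrence scan of a pattern over both strands of a
# genome given as named strings; returns a data.frame like align_anchor().
oracle_scan <- function(pattern, seq_strings) {
  w <- nchar(pattern)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  out <- lapply(names(seq_strings), function(chrom) {
    s <- seq_strings[[chrom]]
    n <- nchar(s)
    if (n < w) return(NULL)
    subs <- substring(s, 1:(n - w + 1), w:n)
    fwd <- which(subs == pattern)
    rev <- which(subs == rc)
    if (length(fwd) == 0 && length(rev) == 0) return(NULL)
    data.frame(chrom = chrom, start = c(fwd, rev), end = c(fwd, rev) + w - 1L,
               strand = rep(c("+", "-"), c(length(fwd), length(rev))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force occurrence count (both strands), overlap-aware.
oracle_count <- function(pattern, seq_strings) {
  nrow(oracle_scan(pattern, seq_strings))
}

# O(n*m) containment check: tumor circle common iff some normal circle on
# the same chromosome fully contains it.
oracle_split <- function(tumor, normal) {
  common <- logical(nrow(tumor))
  for (i in seq_len(nrow(tumor))) {
    for (j in seq_len(nrow(normal))) {
      if (tumor$chrom[i] == normal$chrom[j] &&
          normal$start[j] <= tumor$start[i] &&
          tumor$end[i] <= normal$end[j]) {
        common[i] <- TRUE
        break
      }
    }
  }
  list(common = tumor[common, , drop = FALSE],
       tumor_specific = tumor[!common, , drop = FALSE])
}

# Exhaustive breakpoint enumeration for one seed/read on the forward-genome
# orientation: returns all qualifying (b, s, e).
oracle_breakpoints <- function(R, chrom_seq, a5_start, a3_end, sig_up, sig_dn,
                               anchor_len = 20L) {
  L <- nchar(R)
  out <- NULL
  for (b in anchor_len:(L - anchor_len)) {
    e <- a5_start + b - 1L
    s <- a3_end - L + b + 1L
    if (s >= e) next
    if (s - 2L < 1L || e + 2L > nchar(chrom_seq)) next
    ok <- substr(chrom_seq, e - b + 1L, e) == substr(R, 1L, b) &&
      substr(chrom_seq, s, s + (L - b) - 1L) == substr(R, b + 1L, L) &&
      substr(chrom_seq, s - 2L, s - 1L) == sig_up &&
      substr(chrom_seq, e + 1L, e + 2L) == sig_dn
    if (ok) out <- rbind(out, data.frame(b = b, s = s, e = e))
  }
  out
}

# Small shared detection fixture (built once per test run).
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_fixture(tempfile("smallfix"), seed = 11, n_chroms = 2,
                             chrom_len = 20000, n_circles = 4,
                             span_range = c(60, 400), strand_mix = 0.5,
                             support_range = c(3, 8), linear_n = 50)
    }
    cache
  }
})
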