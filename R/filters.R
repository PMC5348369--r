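#' Filter configuration
#'
#' Bundles the three candidate filters' parameters: the expression filter's
#' minimum junction-read support (default 5), the genomic size filter's
#' minimum tail-to-head span (default 6 bases), and the validation
#' (uniqueness) filter's flank length and mode.
#'
#' @param min_reads Minimum supporting junction reads (>= 1; default 5).
#' @param min_size Minimum genomic size in bases (>= 1; default 6).
#' @param flank_len Flank length for the uniqueness filter (>= 20; default 50).
#' @param uniqueness_mode `"internal"` (exact genome-wide occurrence count)
#'   or `"external_blat"` (shell out to a BLAT executable).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_reads = 5L, min_size = 6L, flank_len = 50L,
                          uniqueness_mode = c("internal", "external_blat")) {
  uniqueness_mode <- match.arg(uniqueness_mode)
  min_reads <- as.integer(min_reads)
  min_size <- as.integer(min_size)
  flank_len <- as.integer(flank_len)
  if (is.na(min_reads) || min_reads < 1L) stop("min_reads must be >= 1")
  if (is.na(min_size) || min_size < 1L) stop("min_size must be >= 1")
  if (is.na(flank_len) || flank_len < 20L) stop("flank_len must be >= 20")
  structure(list(min_reads = min_reads, min_size = min_size,
                 flank_len = flank_len, uniqueness_mode = uniqueness_mode),
            class = "filter_config")
}

#' Expression filter
#'
#' Retains candidates supported by at least `min_reads` junction-spanning
#' reads (default 5). Order is preserved.
#'
#' @param candidates Quantified candidate data.frame from [quantify()].
#' @param min_reads Minimum support (>= 1).
#' @return Filtered data.frame.
#' @export
expression_filter <- function(candidates, min_reads = 5L) {
  if (min_reads < 1L) stop("min_reads must be >= 1")
  out <- candidates[candidates$n_reads >= min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genomic size of candidates
#'
#' The tail-to-head genomic distance of a circle, computed as the inclusive
#' span `end - start + 1` (coordinates are 1-based inclusive throughout).
#'
#' @param candidates Candidate data.frame (or a single candidate list with
#'   `start` and `end`).
#' @return Integer vector of sizes in bases.
#' @export
genomic_size <- function(candidates) {
  if (is.data.frame(candidates)) {
    as.integer(candidates$end - candidates$start + 1L)
  } else {
    as.integer(candidates$end - candidates$start + 1L)
  }
}

#' Genomic size filter
#'
#' Discards candidates whose genomic size is below `min_size` (default 6
#' bases).
#'
#' @param candidates Candidate data.frame.
#' @param min_size Minimum genomic size in bases.
#' @return Filtered data.frame.
#' @export
size_filter <- function(candidates, min_size = 6L) {
  out <- candidates[genomic_size(candidates) >= min_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact occurrence count of a pattern over both strands of the whole genome
count_genome_occurrences <- function(pattern, genome) {
  rc <- revcomp(pattern)
  sum(vapply(names(genome$str), function(chrom) {
    subject <- genome$seq[[chrom]]
    Biostrings::countPattern(pattern, subject) +
      Biostrings::countPattern(rc, subject)
  }, numeric(1)))
}

# head flank starts at the circle start; tail flank ends at the circle end;
# both truncated at chromosome edges
candidate_flanks <- function(chrom, start, end, genome, flank_len) {
  clen <- genome$lengths[[chrom]]
  list(
    head = fetch_plus(genome, chrom, start, min(start + flank_len - 1L, clen)),
    tail = fetch_plus(genome, chrom, max(end - flank_len + 1L, 1L), end)
  )
}

#' Validation (genomic uniqueness) filter
#'
#' Confirms that the head and tail coordinates of each circle sit at unique
#' locations of the genome, so junctions arising from repetitive regions are
#' discarded. In `internal` mode the `flank_len`-base flank starting at the
#' circle start and the flank ending at the circle end (truncated at
#' chromosome edges) are counted exactly genome-wide on both strands, and the
#' candidate is kept only if each flank occurs exactly once. In
#' `external_blat` mode a BLAT executable is invoked on the flanks and a
#' single hit per flank is required.
#'
#' @param candidates Candidate data.frame.
#' @param genome A `Genome`.
#' @param flank_len Flank length in bases (default 50).
#' @param uniqueness_mode `"internal"` or `"external_blat"`.
#' @param blat_path Path to the BLAT executable (external mode only).
#' @return Filtered data.frame.
#' @export
uniqueness_filter <- function(candidates, genome, flank_len = 50L,
                              uniqueness_mode = c("internal", "external_blat"),
                              blat_path = "blat") {
  uniqueness_mode <- match.arg(uniqueness_mode)
  if (nrow(candidates) == 0L) return(candidates)
  if (uniqueness_mode == "external_blat") {
    return(uniqueness_filter_blat(candidates, genome, flank_len, blat_path))
  }
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    fl <- candidate_flanks(candidates$chrom[i], candidates$start[i],
                           candidates$end[i], genome, flank_len)
    count_genome_occurrences(fl$head, genome) == 1 &&
      count_genome_occurrences(fl$tail, genome) == 1
  }, logical(1))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

uniqueness_filter_blat <- function(candidates, genome, flank_len, blat_path) {
  if (Sys.which(blat_path) == "" && !file.exists(blat_path)) {
    stop("external_blat uniqueness mode requested but BLAT executable '",
         blat_path, "' was not found")
  }
  genome_fa <- tempfile(fileext = ".fa")
  query_fa <- tempfile(fileext = ".fa")
  psl <- tempfile(fileext = ".psl")
  on.exit(unlink(c(genome_fa, query_fa, psl)), add = TRUE)
  write_genome_fasta(genome, genome_fa)
  qnames <- character(0)
  qseqs <- character(0)
  for (i in seq_len(nrow(candidates))) {
    fl <- candidate_flanks(candidates$chrom[i], candidates$start[i],
                           candidates$end[i], genome, flank_len)
    qnames <- c(qnames, paste0("cand", i, "_head"), paste0("cand", i, "_tail"))
    qseqs <- c(qseqs, fl$head, fl$tail)
  }
  Biostrings::writeXStringSet(
    stats::setNames(Biostrings::DNAStringSet(qseqs), qnames), query_fa)
  status <- system2(blat_path, c(genome_fa, query_fa, "-noHead", psl),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(psl)) {
    stop("BLAT invocation failed with status ", status)
  }
  tab <- utils::read.delim(psl, header = FALSE, stringsAsFactors = FALSE)
  hit_counts <- table(tab[[10]])  # PSL column 10 = query name
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    h <- hit_counts[paste0("cand", i, "_head")]
    t <- hit_counts[paste0("cand", i, "_tail")]
    !is.na(h) && !is.na(t) && h == 1 && t == 1
  }, logical(1))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply all three candidate filters
#'
#' Expression, genomic size, and validation (uniqueness) filters applied in
#' sequence. Each filter's predicate is per-candidate, so the final set is
#' invariant to filter order.
#'
#' @param candidates Quantified candidate data.frame.
#' @param genome A `Genome`.
#' @param config A [filter_config()].
#' @return Filtered data.frame.
#' @export
apply_filters <- function(candidates, genome, config = filter_config()) {
  out <- expression_filter(candidates, config$min_reads)
  out <- size_filter(out, config$min_size)
  uniqueness_filter(out, genome, config$flank_len, config$uniqueness_mode)
}
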