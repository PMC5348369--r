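#' @importFrom methods is
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

new_genome <- function(str) {
  # str: named character vector of uppercase chromosome sequences
  structure(
    list(
      str = str,
      seq = Biostrings::DNAStringSet(str),
      lengths = stats::setNames(nchar(str), names(str))
    ),
    class = "Genome"
  )
}

#' Load a reference genome from FASTA
#'
#' Reads all records of a FASTA file into an in-memory genome. Sequences are
#' uppercased; `N` is permitted, any other character outside `A/C/G/T/N` is an
#' error. Chromosome names are the first whitespace-delimited token of each
#' FASTA header and must be unique.
#'
#' @param fasta_path Path to a FASTA file.
#' @return An object of class `Genome`: a list with elements `str` (named
#'   character vector of sequences), `seq` (a [Biostrings::DNAStringSet]) and
#'   `lengths` (named integer vector of chromosome lengths).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' g <- load_genome(fa)
#' g$lengths
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("genome FASTA not found: ", fasta_path)
  }
  dss <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ", conditionMessage(e))
  )
  nm <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  str <- toupper(as.character(dss))
  names(str) <- nm
  bad <- vapply(str, function(s) {
    any(!strsplit(s, "", fixed = TRUE)[[1]] %in% VALID_BASES)
  }, logical(1))
  if (any(bad)) {
    stop("record '", nm[which(bad)[1]], "' contains characters outside A/C/G/T/N")
  }
  new_genome(str)
}

#' @export
print.Genome <- function(x, ...) {
  cat("Genome with", length(x$str), "chromosome(s), total",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp\n")
  invisible(x)
}

#' Construct a genomic interval
#'
#' 1-based inclusive coordinates on a named chromosome, as printed in genome
#' browsers (e.g. `chr14:102,466,325-102,500,789`).
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return A list of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end) {
    stop("invalid interval: require 1 <= start <= end")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

# plus-strand substring, bounds-checked
fetch_plus <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$str)) {
    stop("chromosome '", chrom, "' not in genome")
  }
  len <- genome$lengths[[chrom]]
  if (start < 1L || end > len) {
    stop("coordinates ", chrom, ":", start, "-", end,
         " out of bounds (length ", len, ")")
  }
  substr(genome$str[[chrom]], start, end)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract genomic sequence for an interval
#'
#' Returns the `end - start + 1` bases of the interval; for a `-` strand
#' interval the reverse complement is returned.
#'
#' @param genome A `Genome` from [load_genome()].
#' @param iv A [genomic_interval()].
#' @return A nucleotide string.
#' @export
fetch <- function(genome, iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  s <- fetch_plus(genome, iv$chrom, iv$start, iv$end)
  if (iv$strand == "-") revcomp(s) else s
}

#' Write a genome to FASTA
#'
#' @param genome A `Genome`.
#' @param path Output FASTA path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 60L) {
  Biostrings::writeXStringSet(genome$seq, path, width = width)
  invisible(path)
}
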