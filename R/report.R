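REPORT_COLUMNS <- c("chrom", "start", "end", "strand", "n_supporting_reads",
                    "genomic_size", "gene_class", "gene_names",
                    "boundary_class")

#' Bundle one sample's final circRNA records
#'
#' @param sample_id Sample identifier.
#' @param records Annotated record data.frame from [annotate_all()].
#' @param unmapped_read_count Total unmapped reads in the library (>= 0).
#' @param parameters A [filter_config()] (or fuller parameter list) snapshot.
#' @param log Optional named vector of per-stage read accounting.
#' @return A list of class `sample_result`; records are sorted by
#'   (chrom, start, end).
#' @export
sample_result <- function(sample_id, records, unmapped_read_count,
                          parameters = filter_config(), log = NULL) {
  stopifnot(unmapped_read_count >= 0)
  if (nrow(records) > 0L) {
    ord <- order(records$chrom, records$start, records$end)
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(
    list(sample_id = sample_id, records = records,
         unmapped_read_count = as.integer(unmapped_read_count),
         parameters = parameters, log = log),
    class = "sample_result"
  )
}

#' @export
print.sample_result <- function(x, ...) {
  cat("sample_result '", x$sample_id, "': ", nrow(x$records),
      " circRNA(s), ", x$unmapped_read_count, " unmapped reads\n", sep = "")
  invisible(x)
}

#' Write the circRNA quantification report
#'
#' Tab-delimited, Unix newlines, one row per final circRNA with genomic
#' location, supporting-read count, genomic size, and gene/exon annotations.
#' Round-trips through [read_report()].
#'
#' @param result A [sample_result()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  r <- result$records
  df <- data.frame(
    chrom = r$chrom, start = r$start, end = r$end, strand = r$strand,
    n_supporting_reads = r$n_reads, genomic_size = r$size,
    gene_class = r$gene_class, gene_names = r$gene_names,
    boundary_class = r$boundary_class, stringsAsFactors = FALSE
  )
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    stop("cannot write report to '", path, "': ", conditionMessage(e)))
  on.exit(close(con), add = TRUE)
  writeLines(paste(REPORT_COLUMNS, collapse = "\t"), con)
  if (nrow(df) > 0L) {
    writeLines(do.call(paste, c(unname(as.list(df)), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a circRNA quantification report
#'
#' @param path Report TSV written by [write_report()].
#' @param sample_id Sample identifier (defaults to the file stem).
#' @param unmapped_read_count Library unmapped-read total, if known.
#' @return A [sample_result()].
#' @export
read_report <- function(path, sample_id = NULL, unmapped_read_count = 0L) {
  if (is.null(sample_id)) {
    sample_id <- sub("_report$", "", tools::file_path_sans_ext(basename(path)))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         gene_names = "character"))
  if (!all(REPORT_COLUMNS %in% names(df))) {
    stop("'", path, "' is not a circRNA report (missing columns: ",
         paste(setdiff(REPORT_COLUMNS, names(df)), collapse = ", "), ")")
  }
  df$gene_names[is.na(df$gene_names)] <- ""
  records <- data.frame(
    chrom = df$chrom, start = as.integer(df$start), end = as.integer(df$end),
    strand = df$strand, n_reads = as.integer(df$n_supporting_reads),
    size = as.integer(df$genomic_size), gene_class = df$gene_class,
    gene_names = df$gene_names, boundary_class = df$boundary_class,
    stringsAsFactors = FALSE
  )
  sample_result(sample_id, records, unmapped_read_count)
}

#' Write the fused-junction FASTA
#'
#' One record per circRNA, id `chrom:start-end:strand`. The sequence is the
#' last `total_len/2` bases of the circle (ending at its genomic end)
#' concatenated with its first `total_len/2` bases (starting at its genomic
#' start), so the back-splice fusion point sits between positions
#' `total_len/2` and `total_len/2 + 1` (25|26 at the default 50). For
#' circles smaller than `total_len/2` each side contributes `min(span,
#' total_len/2)` bases with no wrap-around. Minus-strand records are
#' reverse-complemented into transcript orientation.
#'
#' @param result A [sample_result()].
#' @param genome A `Genome`.
#' @param path Output FASTA path.
#' @param total_len Total junction-sequence length; must be even (default 50).
#' @return `path`, invisibly.
#' @export
junction_fasta <- function(result, genome, path, total_len = 50L) {
  if (total_len %% 2L != 0L) stop("total_len must be even")
  half <- total_len %/% 2L
  r <- result$records
  seqs <- character(nrow(r))
  ids <- character(nrow(r))
  for (i in seq_len(nrow(r))) {
    span <- r$end[i] - r$start[i] + 1L
    k <- min(span, half)
    tail_side <- fetch_plus(genome, r$chrom[i], r$end[i] - k + 1L, r$end[i])
    head_side <- fetch_plus(genome, r$chrom[i], r$start[i], r$start[i] + k - 1L)
    s <- paste0(tail_side, head_side)
    if (r$strand[i] == "-") s <- revcomp(s)
    seqs[i] <- s
    ids[i] <- sprintf("%s:%d-%d:%s", r$chrom[i], r$start[i], r$end[i],
                      r$strand[i])
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  Biostrings::writeXStringSet(dss, path, width = 60L)
  invisible(path)
}
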