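#' Load gene models from a GTF file
#'
#' Reads Ensembl-dialect GTF `gene` and `exon` features into a list of gene
#' models. Unknown feature types are ignored. Exons are deduplicated by
#' coordinate across transcripts of the same gene; when no `gene` feature is
#' present, the gene span is inferred as the hull of its exons.
#'
#' @param gtf_path Path to a GTF file with `gene_id` attributes.
#' @return A list of class `gene_models`; each element is a list with
#'   `gene_id`, `gene_name`, `chrom`, `start`, `end`, `strand`, and `exons`
#'   (data.frame with `start`, `end`, sorted, non-overlapping per gene).
#' @export
load_gene_models <- function(gtf_path) {
  if (!file.exists(gtf_path)) stop("GTF not found: ", gtf_path)
  gr <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e) stop("malformed GTF '", gtf_path, "': ", conditionMessage(e))
  )
  type <- as.character(gr$type)
  keep <- type %in% c("gene", "exon")
  gr <- gr[keep]
  type <- type[keep]
  if (length(gr) == 0L) {
    return(structure(list(), class = "gene_models"))
  }
  gid <- if ("gene_id" %in% names(S4Vectors::mcols(gr))) gr$gene_id else rep(NA_character_, length(gr))
  if (anyNA(gid) || any(gid == "")) {
    bad <- which(is.na(gid) | gid == "")
    stop("GTF feature(s) missing gene_id attribute at record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  gname <- if ("gene_name" %in% names(S4Vectors::mcols(gr))) gr$gene_name else gid
  gname <- ifelse(is.na(gname) | gname == "", gid, gname)

  chrom <- as.character(GenomicRanges::seqnames(gr))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"

  models <- lapply(unique(gid), function(g) {
    i <- which(gid == g)
    ichr <- unique(chrom[i])
    if (length(ichr) > 1L) {
      stop("gene '", g, "' spans multiple chromosomes in GTF")
    }
    ex <- i[type[i] == "exon"]
    exons <- unique(data.frame(start = starts[ex], end = ends[ex]))
    exons <- exons[order(exons$start, exons$end), , drop = FALSE]
    rownames(exons) <- NULL
    gene_rows <- i[type[i] == "gene"]
    span_start <- min(c(starts[gene_rows], exons$start))
    span_end <- max(c(ends[gene_rows], exons$end))
    list(
      gene_id = g,
      gene_name = gname[i][1],
      chrom = ichr,
      start = as.integer(span_start),
      end = as.integer(span_end),
      strand = strand[i][1],
      exons = exons
    )
  })
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  structure(models, class = "gene_models")
}

#' Write gene models to GTF
#'
#' Serializes models produced by [load_gene_models()] (or the simulator) back
#' to Ensembl-dialect GTF with one `gene` line and one `exon` line per exon.
#'
#' @param models A `gene_models` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  if (length(models) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- unlist(lapply(models, function(m) {
    attr_str <- sprintf('gene_id "%s"; gene_name "%s";', m$gene_id, m$gene_name)
    gene_line <- paste(m$chrom, "backsplicer", "gene", m$start, m$end, ".",
                       m$strand, ".", attr_str, sep = "\t")
    exon_lines <- paste(m$chrom, "backsplicer", "exon",
                        m$exons$start, m$exons$end, ".",
                        m$strand, ".", attr_str, sep = "\t")
    c(gene_line, exon_lines)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x), "gene(s)\n")
  invisible(x)
}
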