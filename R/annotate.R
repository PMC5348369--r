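#' Classify a circle's gene context
#'
#' A circle whose start and end both fall inside one gene's span is a spliced
#' product of a single gene (`intra_gene`); when its two ends implicate two
#' or more distinct genes it is `inter_gene`; when neither end touches a gene
#' it is `unannotated`. A junction with exactly one genic end (the other end
#' intergenic) is classified `unannotated` with no gene listed — it is
#' neither a clean single-gene product nor evidence of a multi-gene fusion.
#' Overlap is strand-agnostic.
#'
#' @param candidate A candidate row/list with `chrom`, `start`, `end`.
#' @param gene_models A `gene_models` list from [load_gene_models()].
#' @return A list with `gene_class` (one of `intra_gene`, `inter_gene`,
#'   `unannotated`) and `gene_names` (alphabetically sorted character
#'   vector).
#' @export
classify_gene_context <- function(candidate, gene_models) {
  chrom <- candidate$chrom
  s <- candidate$start
  e <- candidate$end
  hit_start <- character(0)
  hit_end <- character(0)
  for (m in gene_models) {
    if (m$chrom != chrom) next
    if (m$start <= s && s <= m$end) hit_start <- c(hit_start, m$gene_name)
    if (m$start <= e && e <= m$end) hit_end <- c(hit_end, m$gene_name)
  }
  all_hits <- sort(unique(c(hit_start, hit_end)))
  if (length(all_hits) == 0L) {
    return(list(gene_class = "unannotated", gene_names = character(0)))
  }
  if (length(all_hits) >= 2L) {
    return(list(gene_class = "inter_gene", gene_names = all_hits))
  }
  # exactly one gene hit: intra-gene only if it contains both ends
  if (all_hits %in% hit_start && all_hits %in% hit_end) {
    list(gene_class = "intra_gene", gene_names = all_hits)
  } else {
    list(gene_class = "unannotated", gene_names = character(0))
  }
}

#' Classify a circle's exon-boundary status
#'
#' `exon_exon_boundary` when the circle start equals some annotated exon
#' start and the circle end equals some annotated exon end (the two exons may
#' differ); `within_exon` when both ends fall strictly inside exons;
#' `other` otherwise (intronic or intergenic ends, or ends at only one exon
#' edge). Matching is by exact genomic coordinate, strand-agnostic.
#'
#' @param candidate A candidate row/list with `chrom`, `start`, `end`.
#' @param gene_models A `gene_models` list.
#' @return One of `"exon_exon_boundary"`, `"within_exon"`, `"other"`.
#' @export
classify_exon_boundary <- function(candidate, gene_models) {
  chrom <- candidate$chrom
  s <- candidate$start
  e <- candidate$end
  start_at_edge <- FALSE
  end_at_edge <- FALSE
  start_inside <- FALSE
  end_inside <- FALSE
  for (m in gene_models) {
    if (m$chrom != chrom) next
    ex <- m$exons
    if (nrow(ex) == 0L) next
    if (any(ex$start == s)) start_at_edge <- TRUE
    if (any(ex$end == e)) end_at_edge <- TRUE
    if (any(ex$start < s & s < ex$end)) start_inside <- TRUE
    if (any(ex$start < e & e < ex$end)) end_inside <- TRUE
  }
  if (start_at_edge && end_at_edge) return("exon_exon_boundary")
  if (start_inside && end_inside) return("within_exon")
  "other"
}

#' Annotate filtered candidates
#'
#' Produces the final per-circle records: genomic size plus gene-context and
#' exon-boundary classes. Annotation is a pure function of its inputs.
#'
#' @param candidates Filtered candidate data.frame.
#' @param gene_models A `gene_models` list.
#' @return data.frame of records with columns `chrom`, `start`, `end`,
#'   `strand`, `n_reads`, `size`, `gene_class`, `gene_names` (comma-joined,
#'   empty string when none), `boundary_class` (plus `read_ids` if present
#'   in the input).
#' @export
annotate_all <- function(candidates, gene_models) {
  n <- nrow(candidates)
  size <- genomic_size(candidates)
  gene_class <- character(n)
  gene_names <- character(n)
  boundary_class <- character(n)
  for (i in seq_len(n)) {
    cand <- list(chrom = candidates$chrom[i], start = candidates$start[i],
                 end = candidates$end[i])
    gc <- classify_gene_context(cand, gene_models)
    gene_class[i] <- gc$gene_class
    gene_names[i] <- paste(gc$gene_names, collapse = ",")
    boundary_class[i] <- classify_exon_boundary(cand, gene_models)
  }
  out <- data.frame(
    chrom = candidates$chrom, start = candidates$start, end = candidates$end,
    strand = candidates$strand,
    n_reads = if (n) candidates$n_reads else integer(0),
    size = size, gene_class = gene_class, gene_names = gene_names,
    boundary_class = boundary_class, stringsAsFactors = FALSE
  )
  if (!is.null(candidates$read_ids)) out$read_ids <- candidates$read_ids
  rownames(out) <- NULL
  out
}
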