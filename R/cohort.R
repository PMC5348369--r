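PROLIFERATION_GENES <- c("BIRC5", "CCNB1", "CDC20", "CEP55", "MKI67", "NDC80",
                         "NUF2", "PTTG1", "RRM2", "TYMS", "UBE2C")

coord_df <- function(chrom = character(0), start = integer(0),
                     end = integer(0)) {
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

sample_coords <- function(sample) {
  r <- sample$records
  unique(coord_df(r$chrom, r$start, r$end))
}

#' Count total and unique circRNAs across samples
#'
#' A unique circRNA is a distinct (chromosome, start, end) coordinate,
#' counted once even if it occurs in two or more samples; strand is ignored
#' for cross-sample identity. The total is the sum of per-sample circle
#' counts.
#'
#' @param samples A list of [sample_result()] objects.
#' @return A list with `coords` (deduplicated coordinate data.frame),
#'   `n_unique`, and `n_total`.
#' @export
unique_circles <- function(samples) {
  per <- lapply(samples, sample_coords)
  all_rows <- do.call(rbind, c(list(coord_df()), per))
  uniq <- unique(all_rows)
  rownames(uniq) <- NULL
  uniq <- uniq[order(uniq$chrom, uniq$start, uniq$end), , drop = FALSE]
  rownames(uniq) <- NULL
  list(coords = uniq, n_unique = nrow(uniq),
       n_total = sum(vapply(samples, function(s) nrow(s$records), integer(1))))
}

#' Ratio of unique circRNAs to samples
#'
#' @param unique_count Number of unique circRNAs.
#' @param n_samples Number of samples (>= 1).
#' @return The unrounded ratio.
#' @export
ratio_to_samples <- function(unique_count, n_samples) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  unique_count / n_samples
}

#' Recurrent circRNAs across a sample group
#'
#' Coordinates present in at least `fraction` of the samples (inclusive at
#' the boundary: a circle seen in exactly 10% of samples qualifies at the
#' default).
#'
#' @param samples A list of [sample_result()] objects.
#' @param fraction Recurrence fraction in (0, 1] (default 0.10).
#' @return A coordinate data.frame.
#' @export
recurrence_set <- function(samples, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- length(samples)
  if (n == 0L) return(coord_df())
  per <- lapply(samples, sample_coords)
  all_rows <- do.call(rbind, per)
  key <- paste(all_rows$chrom, all_rows$start, all_rows$end, sep = "\r")
  counts <- table(key)
  keep_keys <- names(counts)[as.vector(counts) / n >= fraction]
  uniq <- unique(all_rows)
  uk <- paste(uniq$chrom, uniq$start, uniq$end, sep = "\r")
  out <- uniq[uk %in% keep_keys, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split tumor circRNAs into common and tumor-specific sets
#'
#' A tumor circle is *common* with normal tissue when its interval is
#' identical to, or fully contained within, some normal circle's interval on
#' the same chromosome — smaller circles inside a normal circle's genomic
#' region are assumed to share its regulatory context. All other tumor
#' circles are *tumor-specific*. The two outputs partition the tumor set.
#'
#' @param tumor_set,normal_set Coordinate data.frames (`chrom`, `start`,
#'   `end`), e.g. from [unique_circles()]`$coords`.
#' @return A list with `common` and `tumor_specific` data.frames.
#' @export
split_specific <- function(tumor_set, normal_set) {
  tumor_set <- coord_df(tumor_set$chrom, tumor_set$start, tumor_set$end)
  normal_set <- coord_df(normal_set$chrom, normal_set$start, normal_set$end)
  if (nrow(tumor_set) == 0L || nrow(normal_set) == 0L) {
    return(list(common = coord_df(), tumor_specific = tumor_set))
  }
  lev <- sort(unique(c(tumor_set$chrom, normal_set$chrom)))
  tq <- GenomicRanges::GRanges(factor(tumor_set$chrom, levels = lev),
                               IRanges::IRanges(tumor_set$start, tumor_set$end))
  nq <- GenomicRanges::GRanges(factor(normal_set$chrom, levels = lev),
                               IRanges::IRanges(normal_set$start, normal_set$end))
  hits <- GenomicRanges::findOverlaps(tq, nq, type = "within")
  is_common <- seq_len(nrow(tumor_set)) %in% S4Vectors::queryHits(hits)
  common <- tumor_set[is_common, , drop = FALSE]
  specific <- tumor_set[!is_common, , drop = FALSE]
  rownames(common) <- rownames(specific) <- NULL
  list(common = common, tumor_specific = specific)
}

#' Normalize a circRNA count by unmapped library size
#'
#' circRNAs per million unmapped reads, so libraries of different depth are
#' comparable.
#'
#' @param circ_count Number of circRNAs in the sample.
#' @param unmapped_reads Total unmapped reads (> 0).
#' @param per Scale constant (default 1e6).
#' @return Normalized count.
#' @export
normalize_counts <- function(circ_count, unmapped_reads, per = 1e6) {
  if (any(unmapped_reads <= 0)) stop("unmapped_reads must be > 0")
  circ_count / unmapped_reads * per
}

#' Build a proliferation panel
#'
#' An 11-gene proliferation signature (BIRC5, CCNB1, CDC20, CEP55, MKI67,
#' NDC80, NUF2, PTTG1, RRM2, TYMS, UBE2C) with a genes-by-samples expression
#' matrix. All panel genes must be present with no missing values.
#'
#' @param expression Numeric matrix, rownames = gene symbols, colnames =
#'   sample ids.
#' @param genes Panel gene symbols (default: the 11-gene signature).
#' @return A list of class `proliferation_panel`.
#' @export
proliferation_panel <- function(expression, genes = PROLIFERATION_GENES) {
  missing <- setdiff(genes, rownames(expression))
  if (length(missing) > 0L) {
    stop("panel gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  expression <- expression[genes, , drop = FALSE]
  if (anyNA(expression)) stop("expression matrix contains missing values")
  structure(list(genes = genes, expression = expression),
            class = "proliferation_panel")
}

#' Proliferation score
#'
#' A per-sample proliferation scalar: each panel gene is z-scored across the
#' cohort's samples, and the sample's score is the mean z across the 11
#' genes. This is a documented mean-z summary of the proliferation panel
#' used as the risk-of-relapse style proliferation axis. A zero-variance
#' gene contributes 0 to every sample (with a warning).
#'
#' @param panel A [proliferation_panel()].
#' @param sample_id Optional single sample id; when given, that sample's
#'   scalar score is returned instead of the full named vector.
#' @return Named numeric vector of scores (or a scalar).
#' @export
proliferation_score <- function(panel, sample_id = NULL) {
  expr <- panel$expression
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1, stats::sd)
  zero_var <- sdv == 0 | is.na(sdv)
  if (any(zero_var)) {
    warning("zero-variance panel gene(s): ",
            paste(rownames(expr)[zero_var], collapse = ", "),
            " - their z-scores set to 0")
    sdv[zero_var] <- 1
  }
  z <- sweep(sweep(expr, 1, mu, "-"), 1, sdv, "/")
  z[zero_var, ] <- 0
  scores <- colMeans(z)
  if (!is.null(sample_id)) {
    if (!sample_id %in% names(scores)) {
      stop("sample '", sample_id, "' not in expression matrix")
    }
    return(scores[[sample_id]])
  }
  scores
}

#' Pearson correlation
#'
#' Standard product-moment correlation between two numeric vectors of equal
#' length (>= 3), both with nonzero variance.
#'
#' @param x,y Numeric vectors.
#' @return Pearson r.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance")
  }
  stats::cor(x, y)
}

#' Two-group comparison
#'
#' Paired t-test on within-pair differences, or Welch's unequal-variance
#' t-test; two-sided. Identical paired vectors return statistic 0 and
#' p = 1; constant nonzero paired differences have zero variance and are an
#' error.
#'
#' @param a,b Numeric vectors (equal length required for `paired`).
#' @param mode `"paired"` or `"welch"`.
#' @return A list with `statistic` and `p_value`.
#' @export
compare_groups <- function(a, b, mode = c("paired", "welch")) {
  mode <- match.arg(mode)
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 observations per group")
  if (mode == "paired") {
    if (length(a) != length(b)) stop("paired mode requires equal lengths")
    d <- a - b
    if (all(d == 0)) return(list(statistic = 0, p_value = 1))
    if (stats::sd(d) == 0) {
      stop("degenerate paired input: differences are constant (zero variance)")
    }
    tt <- stats::t.test(a, b, paired = TRUE)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
  }
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Assemble a cohort table
#'
#' @param samples List of [sample_result()] objects.
#' @param group_labels Named character vector mapping sample_id to group
#'   name (e.g. `tumor`, `normal_adjacent`).
#' @param pairs Optional data.frame with columns `tumor_id`, `normal_id`.
#' @return A list of class `cohort_table`.
#' @export
cohort_table <- function(samples, group_labels, pairs = NULL) {
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  names(samples) <- ids
  missing <- setdiff(names(group_labels), ids)
  if (length(missing) > 0L) {
    stop("labeled sample(s) absent from cohort: ",
         paste(missing, collapse = ", "))
  }
  if (!is.null(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      gt <- group_labels[[pairs$tumor_id[i]]]
      gn <- group_labels[[pairs$normal_id[i]]]
      if (identical(gt, gn)) {
        stop("pair members must carry distinct group labels: ",
             pairs$tumor_id[i], " / ", pairs$normal_id[i])
      }
    }
  }
  structure(list(samples = samples, group_labels = group_labels,
                 pairs = pairs), class = "cohort_table")
}

#' Per-group cohort summary
#'
#' For each group: sample count, total and unique circRNA counts, the
#' unrounded unique-to-samples ratio, and the number of unique circRNAs seen
#' in at least `recurrence_fraction` of samples. When both a tumor-like and
#' a normal-like group are present, tumor-specific circRNAs are called by
#' the containment rule of [split_specific()].
#'
#' @param cohort A [cohort_table()].
#' @param recurrence_fraction Recurrence threshold (default 0.10).
#' @param tumor_group,normal_group Group names used for the tumor-specific
#'   comparison (defaults `"tumor"` and `"normal_adjacent"`).
#' @return A list with `summary` (data.frame, one row per group) and
#'   `tumor_specific` (coordinate data.frame or NULL).
#' @export
cohort_summary <- function(cohort, recurrence_fraction = 0.10,
                           tumor_group = "tumor",
                           normal_group = "normal_adjacent") {
  groups <- unique(unname(cohort$group_labels))
  rows <- lapply(groups, function(g) {
    ids <- names(cohort$group_labels)[cohort$group_labels == g]
    smp <- cohort$samples[ids]
    uc <- unique_circles(smp)
    data.frame(
      group = g, n_samples = length(smp), total_circRNAs = uc$n_total,
      unique_circRNAs = uc$n_unique,
      ratio_unique_to_samples = ratio_to_samples(uc$n_unique, length(smp)),
      n_recurrent = nrow(recurrence_set(smp, recurrence_fraction)),
      stringsAsFactors = FALSE
    )
  })
  summary <- do.call(rbind, rows)
  tumor_specific <- NULL
  if (all(c(tumor_group, normal_group) %in% groups)) {
    t_ids <- names(cohort$group_labels)[cohort$group_labels == tumor_group]
    n_ids <- names(cohort$group_labels)[cohort$group_labels == normal_group]
    tset <- unique_circles(cohort$samples[t_ids])$coords
    nset <- unique_circles(cohort$samples[n_ids])$coords
    sp <- split_specific(tset, nset)
    tumor_specific <- sp$tumor_specific
    summary$n_tumor_specific <- ifelse(summary$group == tumor_group,
                                       nrow(tumor_specific), NA_integer_)
  }
  list(summary = summary, tumor_specific = tumor_specific)
}
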