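#' Extract unmapped reads from a SAM/BAM file
#'
#' Returns exactly the alignment records with the unmapped flag (0x4) set.
#' Each mate of a pair is treated as an independent read. SAM input is
#' converted on the fly with [Rsamtools::asBam()].
#'
#' @param alignment_path Path to a SAM or BAM file.
#' @return A list with `reads` (data.frame: `read_id`, `sequence`,
#'   `mate_index` — 1/2 for paired mates, 0 for single-end) and
#'   `n_unmapped` (total unmapped record count, used downstream for
#'   library-size normalization).
#' @export
extract_unmapped <- function(alignment_path) {
  if (!file.exists(alignment_path)) {
    stop("alignment file not found: ", alignment_path)
  }
  bam <- alignment_path
  if (!grepl("\\.bam$", alignment_path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(alignment_path, destination = dest,
                       overwrite = TRUE, indexDestination = FALSE),
      error = function(e) stop("cannot read alignment file '", alignment_path,
                               "': ", conditionMessage(e))
    )
    on.exit(unlink(bam), add = TRUE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE),
    what = c("qname", "flag", "seq")
  )
  res <- tryCatch(
    Rsamtools::scanBam(bam, param = param)[[1]],
    error = function(e) stop("cannot read alignment file '", alignment_path,
                             "': ", conditionMessage(e))
  )
  flag <- res$flag
  mate <- integer(length(flag))
  mate[bitwAnd(flag, 64L) > 0L] <- 1L
  mate[bitwAnd(flag, 128L) > 0L] <- 2L
  reads <- data.frame(
    read_id = as.character(res$qname),
    sequence = toupper(as.character(res$seq)),
    mate_index = mate,
    stringsAsFactors = FALSE
  )
  list(reads = reads, n_unmapped = nrow(reads))
}

#' Split a read into terminal anchors
#'
#' Takes the first and last `anchor_len` bases of a read. Reads shorter than
#' `2 * anchor_len` cannot host two disjoint anchors and are skipped
#' (`NULL` returned); the pipeline counts them in its log statistics.
#'
#' @param sequence Read nucleotide string.
#' @param anchor_len Anchor length in bases (default 20).
#' @return A list `(five_prime, three_prime)` of anchor sequences, or `NULL`.
#' @export
make_anchors <- function(sequence, anchor_len = 20L) {
  n <- nchar(sequence)
  if (n < 2L * anchor_len) return(NULL)
  list(
    five_prime = substr(sequence, 1L, anchor_len),
    three_prime = substr(sequence, n - anchor_len + 1L, n)
  )
}

empty_alignments <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

#' Exact-match alignment of one anchor against the genome
#'
#' Finds all zero-mismatch occurrences of the anchor on both strands of every
#' chromosome. Anchors containing `N` yield no alignments. A `-` strand
#' alignment at `[start, end]` means the reverse complement of the plus-strand
#' genome there equals the anchor. Results are ordered by
#' (chrom, start, strand), `+` before `-`.
#'
#' @param anchor Anchor nucleotide string.
#' @param genome A `Genome`.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
align_anchor <- function(anchor, genome) {
  if (grepl("N", anchor, fixed = TRUE)) return(empty_alignments())
  w <- nchar(anchor)
  rc <- revcomp(anchor)
  out <- lapply(names(genome$str), function(chrom) {
    subject <- genome$seq[[chrom]]
    fwd <- Biostrings::start(Biostrings::matchPattern(anchor, subject))
    rev <- Biostrings::start(Biostrings::matchPattern(rc, subject))
    if (length(fwd) == 0L && length(rev) == 0L) return(NULL)
    data.frame(
      chrom = chrom,
      start = c(fwd, rev),
      end = c(fwd, rev) + w - 1L,
      strand = rep(c("+", "-"), c(length(fwd), length(rev))),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_alignments())
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Batch exact alignment of many constant-width anchors via a precomputed
# dictionary (Biostrings PDict). Returns a named list: anchor sequence ->
# alignment data.frame in the same order convention as align_anchor().
align_anchors_batch <- function(anchors, genome, anchor_len) {
  anchors <- unique(anchors)
  anchors <- anchors[!grepl("N", anchors, fixed = TRUE) & nchar(anchors) == anchor_len]
  hits <- stats::setNames(
    lapply(anchors, function(a) NULL),
    anchors
  )
  if (length(anchors) == 0L) return(hits)
  dss <- Biostrings::DNAStringSet(anchors)
  pd_fwd <- Biostrings::PDict(dss)
  pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(dss))
  for (chrom in names(genome$str)) {
    subject <- genome$seq[[chrom]]
    for (sense in c("+", "-")) {
      pd <- if (sense == "+") pd_fwd else pd_rev
      m <- Biostrings::matchPDict(pd, subject)
      st <- Biostrings::startIndex(m)
      for (i in seq_along(anchors)) {
        s <- st[[i]]
        if (is.null(s) || length(s) == 0L) next
        df <- data.frame(chrom = chrom, start = s, end = s + anchor_len - 1L,
                         strand = sense, stringsAsFactors = FALSE)
        hits[[anchors[i]]] <- rbind(hits[[anchors[i]]], df)
      }
    }
  }
  lapply(hits, function(df) {
    if (is.null(df)) return(empty_alignments())
    df <- df[order(df$chrom, df$start, df$strand), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
}

#' Detect head-to-tail anchor configurations
#'
#' An unmapped read spanning a back-splice junction has its 5' (head) anchor
#' aligning downstream of its 3' (tail) anchor on the transcribed strand —
#' the reverse of collinear order. Both anchors must map uniquely (exactly
#' one alignment each), to the same chromosome and strand, with implied
#' genomic span at most `max_span`. Collinear pairs are rejected.
#'
#' @param five_alns,three_alns Alignment data.frames from [align_anchor()]
#'   for the read's 5' and 3' anchors.
#' @param max_span Maximum implied genomic span in bases (default 100,000).
#' @return A list of candidate seeds (possibly empty); each seed is a list
#'   with `chrom`, `strand`, `head_anchor`, `tail_anchor`.
#' @export
detect_head_to_tail <- function(five_alns, three_alns, max_span = 100000L) {
  if (nrow(five_alns) != 1L || nrow(three_alns) != 1L) return(list())
  five <- as.list(five_alns[1, ])
  three <- as.list(three_alns[1, ])
  if (five$chrom != three$chrom || five$strand != three$strand) return(list())
  if (five$strand == "+") {
    head_to_tail <- five$start > three$end
    span <- five$end - three$start + 1L
  } else {
    # on the minus strand "downstream" runs toward lower plus coordinates
    head_to_tail <- three$start > five$end
    span <- three$end - five$start + 1L
  }
  if (!head_to_tail || span > max_span) return(list())
  list(list(chrom = five$chrom, strand = five$strand,
            head_anchor = five, tail_anchor = three))
}

#' Refine the back-splice breakpoint and check splice signals
#'
#' Extends a seed's anchors toward the read interior to find a breakpoint
#' `b` (in forward-genome read orientation) such that the read prefix of
#' length `b` matches the genome ending at the circle end `e` and the suffix
#' matches starting at the circle start `s`, with zero mismatches across the
#' whole read. Only breakpoints flanked by canonical splice signals are
#' accepted: for a `+` strand circle, `AG` immediately upstream of `s` and
#' `GT` immediately downstream of `e`; for `-`, the plus-strand genome shows
#' `AC` upstream of `s` and `CT` downstream of `e`. The smallest qualifying
#' `b` wins. `-` strand reads are reverse-complemented into forward-genome
#' orientation before extension.
#'
#' @param seed A seed from [detect_head_to_tail()].
#' @param read Read nucleotide string (or a list with `$sequence`).
#' @param genome A `Genome`.
#' @param anchor_len Anchor length used to build the seed.
#' @param max_span Maximum genomic span of the refined circle.
#' @return A list with `chrom`, `start`, `end`, `strand`,
#'   `splice_signal = TRUE`, or `NULL` if no breakpoint qualifies.
#' @export
refine_breakpoint <- function(seed, read, genome, anchor_len = 20L,
                              max_span = 100000L) {
  sequence <- if (is.list(read)) read$sequence else read
  L <- nchar(sequence)
  if (L < 2L * anchor_len) return(NULL)
  if (seed$strand == "+") {
    R <- sequence
    a5_start <- seed$head_anchor$start   # anchor matching the read prefix
    a3_end <- seed$tail_anchor$end       # anchor matching the read suffix
    sig_up <- "AG"; sig_dn <- "GT"
  } else {
    R <- revcomp(sequence)
    a5_start <- seed$tail_anchor$start
    a3_end <- seed$head_anchor$end
    sig_up <- "AC"; sig_dn <- "CT"
  }
  chrom <- seed$chrom
  chrom_seq <- genome$str[[chrom]]
  clen <- genome$lengths[[chrom]]
  for (b in seq.int(anchor_len, L - anchor_len)) {
    e <- a5_start + b - 1L
    s <- a3_end - L + b + 1L
    if (s >= e) next
    if (e - s + 1L > max_span) next
    if (s - 2L < 1L || e + 2L > clen) next
    if (e - b + 1L < 1L || s + (L - b) - 1L > clen) next
    if (substr(chrom_seq, e - b + 1L, e) != substr(R, 1L, b)) next
    if (substr(chrom_seq, s, s + (L - b) - 1L) != substr(R, b + 1L, L)) next
    if (substr(chrom_seq, s - 2L, s - 1L) != sig_up) next
    if (substr(chrom_seq, e + 1L, e + 2L) != sig_dn) next
    return(list(chrom = chrom, start = s, end = e, strand = seed$strand,
                splice_signal = TRUE))
  }
  NULL
}

#' Merge per-read candidates into quantified junctions
#'
#' Candidates with identical (chrom, start, end, strand) are merged and their
#' supporting read identifiers unioned, so a read id is counted once per
#' junction even if both mates support it. Output is sorted by coordinate;
#' the operation is idempotent and order-independent.
#'
#' @param candidates Either a list of per-read candidate lists (each with
#'   `chrom`, `start`, `end`, `strand`, `read_id` or `read_ids`) or an
#'   already-quantified data.frame with a `read_ids` list column.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `n_reads`, and list column `read_ids`.
#' @export
quantify <- function(candidates) {
  if (is.data.frame(candidates)) {
    rows <- lapply(seq_len(nrow(candidates)), function(i) {
      list(chrom = candidates$chrom[i], start = candidates$start[i],
           end = candidates$end[i], strand = candidates$strand[i],
           read_ids = candidates$read_ids[[i]])
    })
  } else {
    rows <- lapply(candidates, function(cc) {
      ids <- if (!is.null(cc$read_ids)) cc$read_ids else cc$read_id
      list(chrom = cc$chrom, start = cc$start, end = cc$end,
           strand = cc$strand, read_ids = ids)
    })
  }
  if (length(rows) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_reads = integer(0), stringsAsFactors = FALSE)
    out$read_ids <- list()
    return(out)
  }
  key <- vapply(rows, function(r)
    paste(r$chrom, r$start, r$end, r$strand, sep = "\r"), character(1))
  groups <- split(rows, key)
  merged <- lapply(groups, function(grp) {
    ids <- sort(unique(unlist(lapply(grp, `[[`, "read_ids"))))
    list(chrom = grp[[1]]$chrom, start = as.integer(grp[[1]]$start),
         end = as.integer(grp[[1]]$end), strand = grp[[1]]$strand, ids = ids)
  })
  out <- data.frame(
    chrom = vapply(merged, `[[`, character(1), "chrom"),
    start = vapply(merged, `[[`, integer(1), "start"),
    end = vapply(merged, `[[`, integer(1), "end"),
    strand = vapply(merged, `[[`, character(1), "strand"),
    n_reads = vapply(merged, function(m) length(m$ids), integer(1)),
    stringsAsFactors = FALSE
  )
  out$read_ids <- lapply(merged, `[[`, "ids")
  ord <- order(out$chrom, out$start, out$end, out$strand)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the detection stage on one sample
#'
#' Full per-sample detection: extract unmapped reads, anchor, realign,
#' seed head-to-tail pairs, refine breakpoints against splice signals, and
#' quantify supporting reads per junction. Filtering and annotation are
#' separate stages (see [apply_filters()] and [annotate_all()]).
#'
#' @param alignment_path SAM/BAM with unmapped reads.
#' @param genome A `Genome`.
#' @param anchor_len Anchor length (default 20).
#' @param max_span Maximum genomic span (default 100,000).
#' @return A list with `candidates` (quantified data.frame),
#'   `n_unmapped`, and `log` (named integer vector of per-stage read
#'   accounting: short, with N, multi-mapping, collinear/unpaired,
#'   no qualifying breakpoint).
#' @export
detect_junctions <- function(alignment_path, genome, anchor_len = 20L,
                             max_span = 100000L) {
  ex <- extract_unmapped(alignment_path)
  reads <- ex$reads
  log <- c(n_unmapped = ex$n_unmapped, n_short = 0L, n_with_n = 0L,
           n_multi_mapping = 0L, n_not_head_to_tail = 0L,
           n_no_breakpoint = 0L, n_junction_reads = 0L)

  anchor_pairs <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    a <- make_anchors(reads$sequence[i], anchor_len)
    if (is.null(a)) {
      log["n_short"] <- log["n_short"] + 1L
    }
    anchor_pairs[[i]] <- a
  }
  all_anchors <- unlist(lapply(anchor_pairs, function(a)
    if (is.null(a)) NULL else c(a$five_prime, a$three_prime)))
  hits <- align_anchors_batch(all_anchors, genome, anchor_len)

  per_read <- list()
  for (i in seq_len(nrow(reads))) {
    a <- anchor_pairs[[i]]
    if (is.null(a)) next
    if (grepl("N", a$five_prime, fixed = TRUE) ||
        grepl("N", a$three_prime, fixed = TRUE)) {
      log["n_with_n"] <- log["n_with_n"] + 1L
      next
    }
    five <- hits[[a$five_prime]]
    three <- hits[[a$three_prime]]
    if (is.null(five)) five <- empty_alignments()
    if (is.null(three)) three <- empty_alignments()
    if (nrow(five) > 1L || nrow(three) > 1L) {
      log["n_multi_mapping"] <- log["n_multi_mapping"] + 1L
      next
    }
    seeds <- detect_head_to_tail(five, three, max_span)
    if (length(seeds) == 0L) {
      log["n_not_head_to_tail"] <- log["n_not_head_to_tail"] + 1L
      next
    }
    cand <- refine_breakpoint(seeds[[1]], reads$sequence[i], genome,
                              anchor_len, max_span)
    if (is.null(cand)) {
      log["n_no_breakpoint"] <- log["n_no_breakpoint"] + 1L
      next
    }
    cand$read_id <- reads$read_id[i]
    per_read[[length(per_read) + 1L]] <- cand
    log["n_junction_reads"] <- log["n_junction_reads"] + 1L
  }
  list(candidates = quantify(per_read), n_unmapped = ex$n_unmapped, log = log)
}
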