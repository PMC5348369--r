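# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Simulate a random genome
#'
#' I.i.d. bases at the requested GC content across `n_chroms` chromosomes
#' named `chr1..chrN`. Deterministic under `seed`.
#'
#' @param seed Integer RNG seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Chromosome length in bases (>= 1000).
#' @param gc GC fraction in `[0, 1]` (default 0.41, human-like).
#' @return A `Genome`.
#' @export
make_genome <- function(seed, n_chroms = 2L, chrom_len = 100000L, gc = 0.41) {
  if (chrom_len < 1000L) stop("chrom_len must be >= 1000")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  with_seed(seed, {
    prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    str <- vapply(seq_len(n_chroms), function(i) {
      paste(sample(names(prob), chrom_len, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1))
    names(str) <- paste0("chr", seq_len(n_chroms))
    new_genome(str)
  })
}

ANNOTATION_CATEGORIES <- data.frame(
  gene_class = c("intra_gene", "intra_gene", "inter_gene", "unannotated"),
  boundary_class = c("exon_exon_boundary", "within_exon", "other", "other"),
  stringsAsFactors = FALSE
)

# write a replacement into a genome at [at, at + nchar(what) - 1], keeping
# the string and DNAStringSet representations in sync
poke <- function(genome, chrom, at, what) {
  substr(genome$str[[chrom]], at, at + nchar(what) - 1L) <- what
  genome$seq[[chrom]] <- Biostrings::DNAString(genome$str[[chrom]])
  genome
}

#' Plant circRNAs (with splice signals and gene models) into a genome
#'
#' Places `n` non-overlapping circles, writes canonical splice signals at
#' their boundaries (`AG` at `start-2..start-1` and `GT` at `end+1..end+2`
#' for `+` circles; `AC`/`CT` respectively for `-` circles, the minus-strand
#' signals as seen on the plus genome), assigns each a supporting-read count,
#' and builds gene models so the circles cycle through the four annotation
#' categories: intra-gene at exon-exon boundaries, intra-gene within an
#' exon, inter-gene, and unannotated. Optionally duplicates one circle's
#' 200-bp head-flank region elsewhere in the genome to exercise the
#' uniqueness filter.
#'
#' @param genome A `Genome` (modified copy returned).
#' @param n Number of circles.
#' @param span_range Genomic span range in bases (min >= 6).
#' @param strand_mix Fraction of circles planted on the `-` strand.
#' @param seed Integer RNG seed.
#' @param support_range Range of back-splice read counts per circle.
#' @param duplicate_circle Optional circle index whose head flank is copied
#'   to a second genomic location.
#' @return A list with `genome` (signals written in) and `truth` (list with
#'   `circles` data.frame, `genes` gene models, `seed`).
#' @export
plant_circles <- function(genome, n, span_range = c(60L, 5000L),
                          strand_mix = 0.5, seed = 1L,
                          support_range = c(5L, 20L),
                          duplicate_circle = NULL) {
  if (n == 0L) {
    return(list(genome = genome,
                truth = list(circles = empty_truth(), genes = structure(list(), class = "gene_models"),
                             seed = seed)))
  }
  if (span_range[1] < 6L) {
    stop("span_range minimum must be >= 6 (the size filter's domain)")
  }
  # placement margin also reserves room before the first circle for the
  # optional duplicated-flank copy (200 bp at chr1:26-225, disjoint from any
  # circle's own flank region since starts are >= margin + 1)
  margin <- 300L
  chroms <- names(genome$str)
  assignment <- rep(chroms, length.out = n)      # round-robin over chromosomes
  with_seed(seed, {
    spans <- sample(seq.int(span_range[1], span_range[2]), n, replace = TRUE)
    strands <- ifelse(stats::runif(n) < strand_mix, "-", "+")
    support <- sample(seq.int(support_range[1], support_range[2]), n,
                      replace = TRUE)
    starts <- integer(n)
    for (chrom in chroms) {
      idx <- which(assignment == chrom)
      k <- length(idx)
      if (k == 0L) next
      slot <- genome$lengths[[chrom]] %/% k
      for (j in seq_along(idx)) {
        i <- idx[j]
        room <- slot - spans[i] - 2L * margin
        if (room < 1L) {
          stop("insufficient room: span ", spans[i], " + margins exceed slot ",
               slot, " on ", chrom)
        }
        starts[i] <- (j - 1L) * slot + margin + sample.int(room, 1L)
      }
    }
    ends <- starts + spans - 1L

    cats <- ANNOTATION_CATEGORIES[rep(seq_len(4L), length.out = n), ]
    genes <- list()
    gene_names <- character(n)
    for (i in seq_len(n)) {
      chrom <- assignment[i]
      s <- starts[i]; e <- ends[i]
      if (strands[i] == "+") {
        genome <- poke(genome, chrom, s - 2L, "AG")
        genome <- poke(genome, chrom, e + 1L, "GT")
      } else {
        genome <- poke(genome, chrom, s - 2L, "AC")
        genome <- poke(genome, chrom, e + 1L, "CT")
      }
      cat_i <- cats$boundary_class[i]
      if (cats$gene_class[i] == "intra_gene" && cat_i == "exon_exon_boundary") {
        gid <- sprintf("G%03d", i)
        genes[[gid]] <- list(
          gene_id = gid, gene_name = paste0("GENE", i), chrom = chrom,
          start = s - 100L, end = e + 100L, strand = strands[i],
          exons = data.frame(start = c(s, e - 29L), end = c(s + 29L, e))
        )
        gene_names[i] <- paste0("GENE", i)
      } else if (cats$gene_class[i] == "intra_gene" && cat_i == "within_exon") {
        gid <- sprintf("G%03d", i)
        genes[[gid]] <- list(
          gene_id = gid, gene_name = paste0("GENE", i), chrom = chrom,
          start = s - 100L, end = e + 100L, strand = strands[i],
          exons = data.frame(start = s - 10L, end = e + 10L)
        )
        gene_names[i] <- paste0("GENE", i)
      } else if (cats$gene_class[i] == "inter_gene") {
        ga <- sprintf("G%03dA", i); gb <- sprintf("G%03dB", i)
        genes[[ga]] <- list(
          gene_id = ga, gene_name = paste0("GENE", i, "A"), chrom = chrom,
          start = s - 120L, end = s + 40L, strand = strands[i],
          exons = data.frame(start = s - 120L, end = s - 80L)
        )
        genes[[gb]] <- list(
          gene_id = gb, gene_name = paste0("GENE", i, "B"), chrom = chrom,
          start = e - 40L, end = e + 120L, strand = strands[i],
          exons = data.frame(start = e + 80L, end = e + 120L)
        )
        gene_names[i] <- paste0("GENE", i, "A,GENE", i, "B")
      } else {
        gene_names[i] <- ""
      }
    }

    if (!is.null(duplicate_circle)) {
      stopifnot(duplicate_circle >= 1L, duplicate_circle <= n)
      src_chrom <- assignment[duplicate_circle]
      src_start <- starts[duplicate_circle] - 60L
      segment <- fetch_plus(genome, src_chrom, src_start, src_start + 199L)
      # free region before the first circle on chr1 (placement margin is 300)
      genome <- poke(genome, chroms[1], 26L, segment)
    }

    circles <- data.frame(
      circle = seq_len(n), chrom = assignment, start = starts, end = ends,
      strand = strands, span = spans, n_reads = support,
      gene_class = cats$gene_class, gene_names = gene_names,
      boundary_class = cats$boundary_class, stringsAsFactors = FALSE
    )
    list(genome = genome,
         truth = list(circles = circles,
                      genes = structure(genes, class = "gene_models"),
                      seed = seed))
  })
}

empty_truth <- function() {
  data.frame(circle = integer(0), chrom = character(0), start = integer(0),
             end = integer(0), strand = character(0), span = integer(0),
             n_reads = integer(0), gene_class = character(0),
             gene_names = character(0), boundary_class = character(0),
             stringsAsFactors = FALSE)
}

# forward-genome junction string for circle (s, e): b bases ending at e,
# then read_len - b bases starting at s
junction_read_seq <- function(genome, chrom, s, e, b, read_len) {
  paste0(fetch_plus(genome, chrom, e - b + 1L, e),
         fetch_plus(genome, chrom, s, s + (read_len - b) - 1L))
}

mutate_seq <- function(s, err_rate) {
  if (err_rate <= 0) return(s)
  bases <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(bases)) < err_rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

#' Simulate unmapped reads over planted circles
#'
#' For each planted circle, emits its configured number of back-splice reads
#' (a genomic suffix ending at the circle end fused to a prefix starting at
#' the circle start, with the fusion at a random interior offset at least
#' `anchor_len` from both read ends, so both anchors always map). Reads from
#' `-` strand circles are reverse-complemented. Additionally emits
#' `linear_n` contiguous-substring reads, which detection must reject. All
#' reads are written as unmapped (flag 4) SAM records; deterministic under
#' `seed`.
#'
#' @param genome A `Genome` with planted circles.
#' @param truth Truth list from [plant_circles()].
#' @param path Output SAM path.
#' @param read_len Read length (>= `2 * anchor_len`; default 50).
#' @param linear_n Number of linear decoy reads.
#' @param seed Integer RNG seed.
#' @param anchor_len Anchor length respected by the fusion-offset bounds.
#' @param err_rate Per-base substitution rate (default 0; the detection core
#'   is exact-match, so errors knock reads out).
#' @return `path`, invisibly.
#' @export
simulate_reads <- function(genome, truth, path, read_len = 50L,
                           linear_n = 0L, seed = 1L, anchor_len = 20L,
                           err_rate = 0) {
  if (read_len < 2L * anchor_len) {
    stop("read_len must be >= 2 * anchor_len")
  }
  circles <- truth$circles
  with_seed(seed, {
    qnames <- character(0)
    seqs <- character(0)
    for (i in seq_len(nrow(circles))) {
      s <- circles$start[i]; e <- circles$end[i]
      span <- e - s + 1L
      b_lo <- max(anchor_len, read_len - span)
      b_hi <- min(read_len - anchor_len, span)
      if (b_lo > b_hi) {
        stop("circle ", i, " (span ", span,
             ") too small for junction reads of length ", read_len)
      }
      for (j in seq_len(circles$n_reads[i])) {
        b <- sample(seq.int(b_lo, b_hi), 1L)
        rs <- junction_read_seq(genome, circles$chrom[i], s, e, b, read_len)
        if (circles$strand[i] == "-") rs <- revcomp(rs)
        qnames <- c(qnames, sprintf("circ%d_r%d", i, j))
        seqs <- c(seqs, mutate_seq(rs, err_rate))
      }
    }
    for (j in seq_len(linear_n)) {
      chrom <- sample(names(genome$str), 1L)
      pos <- sample.int(genome$lengths[[chrom]] - read_len + 1L, 1L)
      rs <- fetch_plus(genome, chrom, pos, pos + read_len - 1L)
      if (stats::runif(1) < 0.5) rs <- revcomp(rs)
      qnames <- c(qnames, sprintf("lin%d", j))
      seqs <- c(seqs, mutate_seq(rs, err_rate))
    }
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(genome$lengths),
                        genome$lengths))
    records <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", qnames, seqs)
    writeLines(c(header, records), path)
  })
  invisible(path)
}

#' Simulate a tumor/normal cohort with a proliferation panel
#'
#' Draws per-sample proliferation scores (standard normal, then standardized
#' exactly across the cohort) and circRNA counts
#' `round(mean_group + b * score + eps)` with `b = target_r * sd` and
#' `eps ~ N(0, sd * sqrt(1 - target_r^2))`, so the population Pearson
#' correlation between score and count equals `target_r` within each group.
#' The 11-gene expression matrix is an affine image of the scores per gene,
#' so the mean-z proliferation score reproduces the drawn scores exactly.
#' Unmapped library sizes are drawn uniformly over 5-22 million reads.
#' Tumor and normal samples are paired positionally when group sizes match.
#'
#' @param n_tumor,n_normal Samples per group (>= 3).
#' @param count_model List with `mean_tumor`, `mean_normal`, `sd` of the
#'   per-sample circRNA counts (defaults 20, 25, 8).
#' @param target_r Target Pearson correlation between proliferation score
#'   and circRNA count (|r| <= 1).
#' @param seed Integer RNG seed.
#' @return A list with `table` (data.frame: `sample_id`, `group`,
#'   `pair_id`, `score`, `circ_count`, `unmapped_reads`) and `panel`
#'   (a [proliferation_panel()]).
#' @export
simulate_cohort <- function(n_tumor, n_normal,
                            count_model = list(mean_tumor = 20,
                                               mean_normal = 25, sd = 8),
                            target_r = -0.22, seed = 1L) {
  if (n_tumor < 3L || n_normal < 3L) stop("need at least 3 samples per group")
  if (abs(target_r) > 1) stop("infeasible target_r: |r| must be <= 1")
  with_seed(seed, {
    n <- n_tumor + n_normal
    group <- rep(c("tumor", "normal_adjacent"), c(n_tumor, n_normal))
    sample_id <- c(sprintf("T%03d", seq_len(n_tumor)),
                   sprintf("N%03d", seq_len(n_normal)))
    raw <- stats::rnorm(n)
    score <- (raw - mean(raw)) / stats::sd(raw)   # exactly standardized
    mu <- ifelse(group == "tumor", count_model$mean_tumor,
                 count_model$mean_normal)
    b <- target_r * count_model$sd
    eps_sd <- count_model$sd * sqrt(1 - target_r^2)
    counts <- round(mu + b * score + stats::rnorm(n, sd = eps_sd))
    counts[counts < 0] <- 0L
    unmapped <- round(stats::runif(n, 5e6, 2.2e7))
    pair_id <- rep(NA_character_, n)
    if (n_tumor == n_normal) {
      pair_id <- c(sprintf("P%03d", seq_len(n_tumor)),
                   sprintf("P%03d", seq_len(n_normal)))
    }
    tab <- data.frame(sample_id = sample_id, group = group, pair_id = pair_id,
                      score = score, circ_count = as.integer(counts),
                      unmapped_reads = as.integer(unmapped),
                      stringsAsFactors = FALSE)
    base_mu <- stats::runif(11, 5, 10)
    base_sd <- stats::runif(11, 0.5, 2)
    expr <- outer(base_sd, score) + base_mu
    rownames(expr) <- PROLIFERATION_GENES
    colnames(expr) <- sample_id
    list(table = tab, panel = proliferation_panel(expr))
  })
}

#' Build a complete detection fixture on disk
#'
#' Composes [make_genome()], [plant_circles()] and [simulate_reads()] and
#' writes `genome.fa`, `genes.gtf`, `reads.sam` and `truth.tsv` into a
#' directory.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed (sub-seeds derived as seed, seed+1, seed+2).
#' @param n_chroms,chrom_len,gc Passed to [make_genome()].
#' @param n_circles,span_range,strand_mix,support_range,duplicate_circle
#'   Passed to [plant_circles()].
#' @param linear_n,read_len,anchor_len Passed to [simulate_reads()].
#' @return A list with the written `paths`, the planted `genome`, and the
#'   `truth` list.
#' @export
make_fixture <- function(dir, seed = 1L, n_chroms = 2L, chrom_len = 100000L,
                         gc = 0.41, n_circles = 10L,
                         span_range = c(60L, 5000L), strand_mix = 0.5,
                         support_range = c(5L, 20L), duplicate_circle = NULL,
                         linear_n = 1000L, read_len = 50L, anchor_len = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome0 <- make_genome(seed, n_chroms, chrom_len, gc)
  planted <- plant_circles(genome0, n_circles, span_range, strand_mix,
                           seed = seed + 1L, support_range = support_range,
                           duplicate_circle = duplicate_circle)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "genes.gtf"),
    sam = file.path(dir, "reads.sam"),
    truth = file.path(dir, "truth.tsv")
  )
  write_genome_fasta(planted$genome, paths$genome)
  write_gene_models(planted$truth$genes, paths$gtf)
  simulate_reads(planted$genome, planted$truth, paths$sam,
                 read_len = read_len, linear_n = linear_n,
                 seed = seed + 2L, anchor_len = anchor_len)
  utils::write.table(planted$truth$circles, paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(paths = paths, genome = planted$genome, truth = planted$truth)
}
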