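test_that("extract_unmapped returns exactly the unmapped records with mate indices", {
  sam <- tempfile(fileext = ".sam")
  seqs <- strrep(c("ACGT", "TTGA", "GGCC", "ATAT", "CGCG"), 5)
  write_mini_sam(sam, data.frame(
    qname = c("m1", "m2", "m3", "p1", "p1"),
    flag = c(0L, 0L, 16L, 77L, 133L),     # 3 mapped-ish? no: 0/0/16 mapped, 77/133 unmapped pair
    rname = c("chrT", "chrT", "chrT", "*", "*"),
    pos = c(10L, 50L, 90L, 0L, 0L),
    seq = seqs, stringsAsFactors = FALSE))
  ex <- extract_unmapped(sam)
  expect_equal(ex$n_unmapped, 2L)
  expect_setequal(ex$reads$read_id, "p1")
  expect_setequal(ex$reads$mate_index, c(1L, 2L))

  # only mate 2 unmapped
  write_mini_sam(sam, data.frame(
    qname = c("q1", "q1"), flag = c(73L, 133L),
    rname = c("chrT", "*"), pos = c(5L, 0L),
    seq = c(strrep("ACGT", 5), strrep("TTGA", 5)), stringsAsFactors = FALSE))
  ex <- extract_unmapped(sam)
  expect_equal(nrow(ex$reads), 1L)
  expect_equal(ex$reads$mate_index, 2L)

  # header only
  write_mini_sam(sam)
  ex <- extract_unmapped(sam)
  expect_equal(nrow(ex$reads), 0L)
  expect_equal(ex$n_unmapped, 0L)

  expect_error(extract_unmapped(tempfile(fileext = ".sam")), "not found")
  unlink(sam)
})

test_that("make_anchors takes terminal k-mers and skips short reads", {
  r50 <- paste(rep(c("A", "C"), 25), collapse = "")
  a <- make_anchors(r50)
  expect_equal(a$five_prime, substr(r50, 1, 20))
  expect_equal(a$three_prime, substr(r50, 31, 50))

  r40 <- strrep("AC", 20)
  a40 <- make_anchors(r40)
  expect_equal(paste0(a40$five_prime, a40$three_prime), r40)

  expect_null(make_anchors(strrep("A", 39)))
})

test_that("align_anchor agrees with a brute-force scan on random genomes", {
  set.seed(21)
  for (rep_i in 1:5) {
    strs <- c(
      chrA = paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = ""),
      chrB = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    )
    g <- genome_from_strings(chrA = strs[["chrA"]], chrB = strs[["chrB"]])
    # unique planted anchor, a twice-planted anchor, and an rc-only anchor
    anchors <- c(substr(strs[["chrA"]], 37, 56),
                 substr(strs[["chrB"]], 101, 120),
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(substr(strs[["chrA"]], 201, 220)))))
    for (a in anchors) {
      expect_equal(align_anchor(a, g), oracle_scan(a, strs))
    }
  }
})

test_that("align_anchor finds reverse-complement-only and duplicated placements", {
  base <- paste(rep("ACGGT", 60), collapse = "")
  anchor <- "TTTTGGGGCCCCAAAATTGG"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(anchor)))
  s <- base
  substr(s, 41, 60) <- rc
  g <- genome_from_strings(chr1 = s)
  hits <- align_anchor(anchor, g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 41L)

  s2 <- base
  substr(s2, 11, 30) <- anchor
  substr(s2, 101, 120) <- anchor
  g2 <- genome_from_strings(chr1 = s2)
  hits2 <- align_anchor(anchor, g2)
  expect_equal(nrow(hits2), 2L)
  expect_equal(hits2$start, c(11L, 101L))

  expect_equal(nrow(align_anchor("ANNA", g)), 0L)
})

test_that("batch anchor alignment matches single-anchor alignment", {
  fx <- small_fixture()
  ex <- extract_unmapped(fx$paths$sam)
  anchors <- unique(unlist(lapply(ex$reads$sequence[1:20], function(s) {
    a <- make_anchors(s)
    c(a$five_prime, a$three_prime)
  })))
  batch <- backsplicer:::align_anchors_batch(anchors, fx$genome, 20L)
  for (a in anchors) {
    expect_equal(batch[[a]], align_anchor(a, fx$genome))
  }
})

test_that("detect_head_to_tail accepts reversed-order unique pairs only", {
  aln <- function(s, e, strand = "+", chrom = "chr1") {
    data.frame(chrom = chrom, start = s, end = e, strand = strand,
               stringsAsFactors = FALSE)
  }
  # head (5') anchor downstream of tail (3') anchor: a seed
  seeds <- detect_head_to_tail(aln(261, 280), aln(101, 120))
  expect_length(seeds, 1)
  expect_equal(seeds[[1]]$head_anchor$start, 261)
  # collinear order: no seed
  expect_length(detect_head_to_tail(aln(101, 120), aln(261, 280)), 0)
  # different chromosomes or strands: no seed
  expect_length(detect_head_to_tail(aln(261, 280), aln(101, 120, chrom = "chr2")), 0)
  expect_length(detect_head_to_tail(aln(261, 280), aln(101, 120, strand = "-")), 0)
  # minus strand: geometry flips
  expect_length(detect_head_to_tail(aln(101, 120, "-"), aln(261, 280, "-")), 1)
  expect_length(detect_head_to_tail(aln(261, 280, "-"), aln(101, 120, "-")), 0)
  # span cap
  expect_length(detect_head_to_tail(aln(200261, 200280), aln(101, 120)), 0)
  # multi-mapping anchors contribute nothing
  two <- rbind(aln(261, 280), aln(500, 519))
  expect_length(detect_head_to_tail(two, aln(101, 120)), 0)
})

test_that("refine_breakpoint recovers planted junctions on both strands", {
  fx <- small_fixture()
  ex <- extract_unmapped(fx$paths$sam)
  juncs <- ex$reads[grepl("^circ", ex$reads$read_id), ]
  truth <- fx$truth$circles
  hit <- 0L
  for (i in seq_len(nrow(juncs))) {
    a <- make_anchors(juncs$sequence[i])
    seeds <- detect_head_to_tail(align_anchor(a$five_prime, fx$genome),
                                 align_anchor(a$three_prime, fx$genome))
    expect_length(seeds, 1)
    cand <- refine_breakpoint(seeds[[1]], juncs$sequence[i], fx$genome)
    expect_false(is.null(cand))
    ci <- as.integer(sub("^circ(\\d+)_.*$", "\\1", juncs$read_id[i]))
    expect_equal(cand$start, truth$start[ci])
    expect_equal(cand$end, truth$end[ci])
    expect_equal(cand$strand, truth$strand[ci])
    expect_true(cand$splice_signal)
    hit <- hit + 1L
  }
  expect_equal(hit, sum(truth$n_reads))
})

test_that("refine_breakpoint picks the smallest breakpoint among several valid ones", {
  # genome engineered so (s, e) and (s+4, e+4) both qualify: the 4-mer GTAG
  # repeats across the junction and the splice signals hold at both shifts
  set.seed(9)
  bases <- sample(c("A", "C", "G", "T"), 1200, replace = TRUE)
  s <- 701L; e <- 280L  # circle start s (acceptor side), end e (donor side): s > e is wrong;
  s <- 280L; e <- 701L
  gstr <- paste(bases, collapse = "")
  substr(gstr, s - 2L, s - 1L) <- "AG"
  substr(gstr, s, s + 3L) <- "GTAG"
  substr(gstr, e + 1L, e + 6L) <- "GTAGGT"
  g <- genome_from_strings(chr1 = gstr)
  b_true <- 25L
  read <- paste0(fetch(g, genomic_interval("chr1", e - b_true + 1L, e)),
                 fetch(g, genomic_interval("chr1", s, s + (50L - b_true) - 1L)))
  a <- make_anchors(read)
  seeds <- detect_head_to_tail(align_anchor(a$five_prime, g),
                               align_anchor(a$three_prime, g))
  expect_length(seeds, 1)
  cand <- refine_breakpoint(seeds[[1]], read, g)
  bps <- oracle_breakpoints(read, gstr, seeds[[1]]$head_anchor$start,
                            seeds[[1]]$tail_anchor$end, "AG", "GT")
  expect_gte(nrow(bps), 2)               # the shift really creates a second solution
  expect_equal(cand$start, bps$s[which.min(bps$b)])
  expect_equal(cand$end, bps$e[which.min(bps$b)])
})

test_that("refine_breakpoint returns NULL without canonical splice signals", {
  set.seed(10)
  gstr <- paste(sample(c("A", "C"), 1000, replace = TRUE), collapse = "")
  s <- 301L; e <- 600L   # A/C genome cannot host AG/GT signals
  g <- genome_from_strings(chr1 = gstr)
  read <- paste0(fetch(g, genomic_interval("chr1", e - 24L, e)),
                 fetch(g, genomic_interval("chr1", s, s + 24L)))
  a <- make_anchors(read)
  seeds <- detect_head_to_tail(align_anchor(a$five_prime, g),
                               align_anchor(a$three_prime, g))
  expect_length(seeds, 1)
  expect_null(refine_breakpoint(seeds[[1]], read, g))
})

test_that("quantify merges identical junctions, dedupes read ids, and is order-invariant", {
  cand <- function(id, s = 100L, e = 400L, chrom = "chr1", strand = "+") {
    list(chrom = chrom, start = s, end = e, strand = strand, read_id = id)
  }
  cands <- c(lapply(paste0("r", 1:7), cand),
             list(cand("r1")),                      # duplicate read id
             list(cand("x1", s = 900L, e = 1400L)))
  q <- quantify(cands)
  expect_equal(nrow(q), 2L)
  expect_equal(q$n_reads, c(7L, 1L))
  expect_equal(q$read_ids[[1]], paste0("r", 1:7))

  set.seed(3)
  q2 <- quantify(cands[sample(length(cands))])
  expect_equal(q2, q)
  expect_equal(quantify(q), q)                      # idempotent
  expect_equal(nrow(quantify(list())), 0L)
})
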