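rec_row <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = "+", n_reads = 6L, size = as.integer(end - start + 1),
             gene_class = "unannotated", gene_names = "",
             boundary_class = "other", stringsAsFactors = FALSE)
}

mk_sample <- function(id, coords, unmapped = 1000000L) {
  rec <- do.call(rbind, lapply(coords, function(cc)
    rec_row(cc[[1]], cc[[2]], cc[[3]])))
  if (is.null(rec)) rec <- rec_row("chr1", 1, 1)[0, ]
  sample_result(id, rec, unmapped)
}

test_that("unique circRNAs are counted once across samples", {
  X <- list("chr1", 100, 500); Y <- list("chr1", 900, 1300); Z <- list("chr2", 10, 90)
  samples <- list(mk_sample("a", list(X)), mk_sample("b", list(X, Y)),
                  mk_sample("c", list(X, Z)))
  uc <- unique_circles(samples)
  expect_equal(uc$n_unique, 3L)
  expect_equal(uc$n_total, 5L)

  one <- unique_circles(samples[1])
  expect_equal(one$n_unique, one$n_total)

  empty <- unique_circles(list())
  expect_equal(c(empty$n_unique, empty$n_total), c(0L, 0L))

  # permutation-invariant and idempotent on its own coordinate set
  uc2 <- unique_circles(rev(samples))
  expect_equal(uc2$coords, uc$coords)
})

test_that("ratio of unique circRNAs to samples is reported unrounded", {
  expect_equal(ratio_to_samples(10, 4), 2.5)
  expect_equal(ratio_to_samples(0, 7), 0)
  expect_equal(ratio_to_samples(208, 13), 16)  # a printed cohort row reproduced
  expect_error(ratio_to_samples(5, 0), "n_samples")
})

test_that("recurrence uses an inclusive fraction threshold", {
  X <- list("chr1", 100, 500)
  mk10 <- c(list(mk_sample("s1", list(X))),
            lapply(2:10, function(i) mk_sample(paste0("s", i), list(
              list("chr2", i * 1000, i * 1000 + 50)))))
  expect_equal(nrow(recurrence_set(mk10, 0.10)), 10L)  # 1/10 qualifies at 10%
  mk11 <- c(mk10, list(mk_sample("s11", list(list("chr3", 5, 60)))))
  rs11 <- recurrence_set(mk11, 0.10)
  expect_equal(nrow(rs11), 0L)                         # 1/11 < 10%
  # fraction 1.0 is the intersection across samples
  both <- list(mk_sample("a", list(X, list("chr2", 1, 70))),
               mk_sample("b", list(X)))
  inter <- recurrence_set(both, 1.0)
  expect_equal(nrow(inter), 1L)
  expect_equal(inter$start, 100L)
  expect_error(recurrence_set(both, 0), "fraction")
})

test_that("tumor circles contained in normal circles are common, others specific", {
  tumor <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(100L, 100L, 100L), end = c(200L, 400L, 200L))
  normal <- data.frame(chrom = "chr1", start = 50L, end = 300L)
  sp <- split_specific(tumor, normal)
  expect_equal(nrow(sp$common), 1L)             # [100,200] inside [50,300]
  expect_equal(sp$common$end, 200L)
  expect_equal(nrow(sp$tumor_specific), 2L)     # overlap-not-contained + other chrom
  # identical interval counts as common
  sp2 <- split_specific(data.frame(chrom = "chr1", start = 50L, end = 300L), normal)
  expect_equal(nrow(sp2$common), 1L)
  # partition property
  expect_equal(nrow(sp$common) + nrow(sp$tumor_specific), nrow(tumor))
})

test_that("split_specific matches brute-force containment on random interval sets", {
  set.seed(14)
  for (rep_i in 1:5) {
    n <- 120; m <- 150
    tumor <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                        start = sample(1:5000, n, TRUE))
    tumor$end <- tumor$start + sample(10:800, n, TRUE)
    normal <- data.frame(chrom = sample(c("chr1", "chr2"), m, TRUE),
                         start = sample(1:5000, m, TRUE))
    normal$end <- normal$start + sample(10:800, m, TRUE)
    got <- split_specific(tumor, normal)
    want <- oracle_split(tumor, normal)
    expect_equal(nrow(got$common), nrow(want$common))
    expect_setequal(paste(got$tumor_specific$chrom, got$tumor_specific$start,
                          got$tumor_specific$end),
                    paste(want$tumor_specific$chrom, want$tumor_specific$start,
                          want$tumor_specific$end))
  }
})

test_that("normalization scales to circRNAs per million unmapped reads", {
  expect_equal(normalize_counts(10, 5e6), 2)
  expect_equal(normalize_counts(0, 5e6), 0)
  expect_equal(normalize_counts(10, 1e7), normalize_counts(10, 5e6) / 2)
  expect_error(normalize_counts(10, 0), "unmapped_reads")
})

test_that("proliferation score is the mean z across the 11-gene panel", {
  genes <- backsplicer:::PROLIFERATION_GENES
  n <- 8
  constant <- matrix(5, nrow = 11, ncol = n,
                     dimnames = list(genes, paste0("s", 1:n)))
  expect_warning(sc <- proliferation_score(proliferation_panel(constant)),
                 "zero-variance")
  expect_true(all(sc == 0))

  # build the matrix analytically: per-gene z-scores are known by design
  set.seed(2)
  z <- matrix(rnorm(11 * n), nrow = 11)
  z <- t(scale(t(z)))                      # rows exactly mean 0, sd 1
  expr <- 5 + 2 * z
  rownames(expr) <- genes; colnames(expr) <- paste0("s", 1:n)
  sc2 <- proliferation_score(proliferation_panel(expr))
  expect_equal(unname(sc2), colMeans(z), tolerance = 1e-12)

  expect_error(proliferation_panel(expr[1:5, ]), "absent")
  expect_equal(proliferation_score(proliferation_panel(expr), "s3"),
               sc2[["s3"]])
})

test_that("correlation and group tests behave at their boundary cases", {
  expect_equal(correlate(1:10, -(1:10)), -1)
  set.seed(8)
  x <- rnorm(10000); y <- rnorm(10000)
  expect_lt(abs(correlate(x, y)), 0.05)
  expect_error(correlate(1:3, rep(2, 3)), "zero variance")
  expect_error(correlate(1:4, 1:5), "equal length")

  same <- c(3, 1, 4, 1, 5)
  r <- compare_groups(same, same, "paired")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_error(compare_groups(c(1, 2, 3), c(2, 3, 4), "paired"), "constant")

  set.seed(9)
  a <- rnorm(200); b <- rnorm(200, mean = 1)
  w <- compare_groups(a, b, "welch")
  expect_lt(w$p_value, 0.001)
  # agreement with the reference implementation
  expect_equal(w$statistic, unname(t.test(a, b)$statistic))
  expect_error(compare_groups(1, 1:3, "welch"), "at least 2")
})

test_that("cohort summary reproduces brute-force per-group counts", {
  X <- list("chr1", 100, 500)
  samples <- list(
    mk_sample("t1", list(X, list("chr1", 150, 450), list("chr2", 10, 60))),
    mk_sample("t2", list(X)),
    mk_sample("n1", list(list("chr1", 50, 600))),
    mk_sample("n2", list(list("chr2", 1000, 1100)))
  )
  labels <- c(t1 = "tumor", t2 = "tumor",
              n1 = "normal_adjacent", n2 = "normal_adjacent")
  cohort <- cohort_table(samples, labels)
  cs <- cohort_summary(cohort, recurrence_fraction = 0.75)
  tum <- cs$summary[cs$summary$group == "tumor", ]
  expect_equal(tum$total_circRNAs, 4L)
  expect_equal(tum$unique_circRNAs, 3L)
  expect_equal(tum$ratio_unique_to_samples, 1.5)
  expect_equal(tum$n_recurrent, 1L)  # only X is in >= 75% of tumor samples
  # X and chr1:150-450 sit inside the normal circle chr1:50-600 -> common
  expect_equal(tum$n_tumor_specific, 1L)
  expect_equal(cs$tumor_specific$chrom, "chr2")

  expect_error(cohort_table(samples, c(bad = "tumor")), "absent")
  expect_error(
    cohort_table(samples, labels,
                 pairs = data.frame(tumor_id = "t1", normal_id = "t2")),
    "distinct group labels")
})
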