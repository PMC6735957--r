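mk_matrix <- function(values, nr, nc) {
  expression_matrix(matrix(values, nr, nc,
                           dimnames = list(sprintf("t%d", seq_len(nr)),
                                           sprintf("s%d", seq_len(nc)))))
}

test_that("quantile normalization matches the hand-computed example", {
  m <- mk_matrix(c(5, 2, 3, 4, 1, 8), 3, 2)
  q <- quantile_normalize(m)
  expect_equal(unname(unclass(q)[, 1]), c(6.5, 1.5, 3.5))
  expect_equal(unname(unclass(q)[, 2]), c(3.5, 1.5, 6.5))
  # identical columns and single columns are fixed points
  m2 <- mk_matrix(c(1, 5, 2, 1, 5, 2), 3, 2)
  expect_equal(unclass(quantile_normalize(m2)), unclass(m2))
  m3 <- mk_matrix(c(9, 1, 4), 3, 1)
  expect_equal(unclass(quantile_normalize(m3)), unclass(m3))
})

test_that("after normalization all columns share one multiset of values", {
  set.seed(31)
  m <- mk_matrix(rlnorm(200 * 6), 200, 6)
  q <- quantile_normalize(m)
  ref <- unname(sort(unclass(q)[, 1]))
  for (j in 2:6)
    expect_equal(unname(sort(unclass(q)[, j])), ref, tolerance = 1e-12)
  expect_identical(dimnames(q), dimnames(m))
  # agrees with an independent implementation on tie-free data
  skip_if_not_installed("limma")
  expect_equal(unclass(q), unclass(limma::normalizeQuantiles(unclass(m))),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ties within a column share the mean of their target values", {
  m <- mk_matrix(c(1, 1, 5, 2, 4, 9), 3, 2)
  q <- quantile_normalize(m)
  # column 1 has a duplicated minimum: both entries get the same value,
  # the mean of the two smallest reference quantiles
  ref <- rowMeans(apply(unclass(m), 2, sort))
  expect_equal(unname(unclass(q)[1:2, 1]), rep(mean(ref[1:2]), 2))
  expect_equal(unname(unclass(q)[3, 1]), unname(ref[3]))
})

test_that("tissue specificity is 1 for single-tissue patterns", {
  expect_equal(tissue_specificity_score(c(7, 0, 0, 0)), 1)
  expect_equal(tissue_specificity_score(c(0, 0, 3)), 1)
})

test_that("two-tissue uniform pattern scores ~0.4421", {
  # p = (1/2, 1/2); midpoint with a unit vector has H = 0.811278 bits
  expect_equal(tissue_specificity_score(c(5, 5)), 1 - sqrt(0.311278),
               tolerance = 1e-4)
})

test_that("specificity decreases with the number of uniform tissues", {
  s <- vapply(2:8, function(n) tissue_specificity_score(rep(3, n)),
              numeric(1))
  expect_true(all(diff(s) < 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("specificity pipeline is invariant to rescaling only through the log step", {
  set.seed(13)
  for (i in 1:20) {
    e <- rlnorm(5)
    s1 <- tissue_specificity_score(e)
    s2 <- tissue_specificity_score(e * 7)
    expect_true(s1 >= 0 && s1 <= 1)
    # log2(e+1) normalization is not scale-free, so scores differ, but
    # both stay valid and rank the same top tissue
    expect_true(s2 >= 0 && s2 <= 1)
  }
  expect_error(tissue_specificity_score(c(0, 0, 0)), "all-zero")
  expect_error(tissue_specificity_score(5), "2 tissues")
})

test_that("matrix-level specificity recovers a planted single-tissue pattern", {
  samples <- sample_table(data.frame(
    sample_id = sprintf("s%d", 1:6),
    individual_id = sprintf("i%d", 1:6),
    tissue = rep(c("brain", "liver", "testis"), each = 2),
    sex = "female", age = 40, race = "EUR", condition = "normal"))
  vals <- rbind(c(9, 11, 0, 0, 0, 0),    # brain-only
                c(2, 2, 2, 2, 2, 2))     # flat
  dimnames(vals) <- list(c("spec", "flat"), samples$sample_id)
  tab <- tissue_specificity_table(expression_matrix(vals), samples)
  expect_equal(tab$score[1], 1)
  expect_identical(tab$top_tissue[1], "brain")
  expect_lt(tab$score[2], 0.5)
})

test_that("splicing efficiency covers its worked cases and monotonicity", {
  expect_equal(splicing_efficiency(c(2, 3), 0), 1)
  expect_equal(splicing_efficiency(0, 4), 0)
  expect_equal(splicing_efficiency(c(3, 1), 1), 0.8)
  expect_true(is.na(splicing_efficiency(0, 0)))
  expect_error(splicing_efficiency(numeric(0), 1), "annotated")
  sp <- vapply(seq(0, 10, by = 0.5), function(s)
    splicing_efficiency(c(3, 1), s), numeric(1))
  expect_true(all(diff(sp) < 0))
  expect_true(all(sp >= 0 & sp <= 1))
})

test_that("conservation averages per-base scores with missing bases as 0", {
  t <- tm("t", "chr1", "+", c(101, 301), c(200, 400))  # 200 nt
  # constant 0.5 over everything
  track <- data.frame(chrom = "chr1", start0 = 0L, end0 = 1000L,
                      value = 0.5)
  expect_equal(conservation_score(t, track), 0.5)
  # exactly the first exon covered at 1.0, second exon uncovered
  track2 <- data.frame(chrom = "chr1", start0 = 100L, end0 = 200L,
                       value = 1)
  expect_equal(conservation_score(t, track2), 0.5)
  track3 <- data.frame(chrom = "chr2", start0 = 0L, end0 = 1000L,
                       value = 1)
  expect_equal(conservation_score(t, track3), 0)
})

test_that("inter-individual variability is sd/mean and scale invariant", {
  expect_equal(interindividual_variability(c(3, 3, 3)), 0)
  expect_equal(interindividual_variability(c(2, 4)), sqrt(2) / 3,
               tolerance = 1e-12)
  set.seed(2)
  x <- rlnorm(10)
  expect_equal(interindividual_variability(x),
               interindividual_variability(x * 13), tolerance = 1e-12)
  expect_true(is.na(interindividual_variability(c(0, 0))))
  expect_error(interindividual_variability(5), "2 donors")
})

test_that("the Q3 + 1.5 IQR filter matches brute-force quartiles", {
  expect_true(moderate_expression_filter(c(0, 0.05, 0.1, 0.15, 0.2)))
  expect_false(moderate_expression_filter(c(0, 0, 0, 0)))
  expect_true(moderate_expression_filter(0.2))
  expect_false(moderate_expression_filter(0.1))   # strict >
  set.seed(6)
  for (i in 1:50) {
    x <- round(rlnorm(sample(1:12, 1), meanlog = -2), 3)
    q <- unname(quantile(x, c(0.25, 0.75), type = 7))
    expect_identical(moderate_expression_filter(x),
                     q[2] + 1.5 * (q[2] - q[1]) > 0.1)
  }
})

test_that("recurrence counts tissues and samples above a strict 0.1", {
  samples <- sample_table(data.frame(
    sample_id = sprintf("s%d", 1:5),
    individual_id = sprintf("i%d", 1:5),
    tissue = c("brain", "brain", "brain", "liver", "liver"),
    sex = "male", age = 50, race = "EUR", condition = "normal"))
  vals <- rbind(none = c(0, 0, 0, 0, 0),
                one_tissue = c(0.2, 0.3, 0.2, 0, 0),
                boundary = c(0.1, 0.1, 0.1, 0.1, 0.1),
                both = c(0.2, 0, 0, 0.5, 0.11))
  colnames(vals) <- samples$sample_id
  r <- recurrence_summary(expression_matrix(vals), samples)
  expect_equal(r$n_tissues_expressed, c(0L, 1L, 0L, 2L))
  expect_equal(r$n_samples_expressed, c(0L, 3L, 0L, 3L))
})

test_that("catalog percentages round half-up to one decimal", {
  expect_equal(catalog_percentages(23001, 27520), 83.6)
  expect_equal(catalog_percentages(0, 10), 0)
  expect_equal(catalog_percentages(1, 1600), 0.1)   # 0.0625 -> 0.1
  expect_equal(catalog_percentages(1, 800), 0.1)    # 0.125 half-up
  expect_error(catalog_percentages(1, 0), "denominator")
})
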