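test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(23)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  # NAs (flagged fits) are passed through, not adjusted
  expect_equal(bh_fdr(c(0.02, NA, 0.04)),
               c(brute_bh(c(0.02, 0.04))[1], NA, brute_bh(c(0.02, 0.04))[2]))
})

test_that("constant expression yields zero effects with p = 1", {
  ch <- generate_expression_cohort("T1", n_individuals = 10L,
                                   tissues = "brain", seed = 1L)
  r <- suppressWarnings(fit_trait_lmm(rep(4, nrow(ch$samples)), ch$samples))
  expect_true(all(r$estimate == 0))
  expect_true(all(r$p_value == 1))
  expect_false(any(r$singular))
})

test_that("single-level covariates are dropped with a warning", {
  ch <- generate_expression_cohort("T1", n_individuals = 20L,
                                   tissues = "brain", seed = 2L)
  expect_warning(
    fit_trait_lmm(unclass(ch$matrix)["T1", ], ch$samples,
                  covariates = c("tissue", "sex", "age")),
    "tissue")
})

test_that("an injected sex effect of 2 is recovered within 0.15", {
  ch <- generate_expression_cohort(
    "T1", n_individuals = 200L, tissues = "brain",
    effects = list(T1 = c(sex = 2)),
    individual_sd = 0.3, residual_sd = 0.5, seed = 101L)
  r <- suppressWarnings(
    fit_trait_lmm(unclass(ch$matrix)["T1", ], ch$samples))
  sexrow <- r[r$covariate == "sex", ]
  expect_equal(abs(sexrow$estimate), 2, tolerance = 0.15 / 2)
  expect_lt(sexrow$p_value, 1e-10)
  # fold change direction: males up
  fc <- sexrow$fold_change
  expect_true(fc > 1.5 || fc < 1 / 1.5)
})

test_that("null covariates keep type-I error near nominal", {
  # 150 null transcripts, no injected effects anywhere
  ch <- generate_expression_cohort(
    sprintf("N%03d", 1:150), n_individuals = 60L,
    tissues = c("brain", "heart"), seed = 77L)
  sc <- trait_association_scan(ch$matrix, ch$samples)
  sex <- sc[grepl("^sex", sc$term) & !sc$singular, ]
  rate <- mean(sex$p_value < 0.05)
  # 3-sigma binomial band around 0.05 with n = 150
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 150) + 1e-9)
  # BH leaves (essentially) nothing significant under the null
  expect_lte(sum(sex$fdr < 0.05), 1L)
})

test_that("differential expression gates on strict FC > 1.5", {
  # construct two conditions with raw means in exact ratio 1.5 and a
  # p-value that is certainly significant
  samples <- sample_table(data.frame(
    sample_id = sprintf("s%02d", 1:40),
    individual_id = sprintf("i%02d", rep(1:20, 2)),
    tissue = "lung", sex = rep(c("male", "female"), 20),
    age = rep(seq(30, 68, 2), 2), race = "EUR",
    condition = rep(c("normal", "tumor"), each = 20)))
  vals <- matrix(rep(c(2, 3), each = 20), nrow = 1,
                 dimnames = list("t1", samples$sample_id))
  de <- suppressWarnings(
    differential_expression(expression_matrix(vals), samples, "lung"))
  expect_equal(de$fold_change, 1.5, tolerance = 1e-12)
  expect_false(de$de_call)   # FC not strictly > 1.5
})

test_that("planted 4-fold transcripts are called and nulls are not", {
  eff <- stats::setNames(lapply(1:10, function(i) c(condition = 2)),
                         sprintf("T%03d", 1:10))
  ch <- generate_expression_cohort(
    sprintf("T%03d", 1:100), n_individuals = 30L, tissues = "lung",
    effects = eff, residual_sd = 0.2, individual_sd = 0.3,
    tumor_fraction = 0.5, seed = 55L)
  de <- differential_expression(ch$matrix, ch$samples, "lung")
  truth <- de$transcript_id %in% names(eff)
  expect_gte(sum(de$de_call & truth), 9L)
  false_calls <- sum(de$de_call & !truth)
  expect_lte(false_calls / max(1L, sum(de$de_call)), 0.05)
})

test_that("clinical outcome gates: FC for metastasis, none for stage", {
  set.seed(91)
  n <- 60L
  samples <- data.frame(
    sample_id = sprintf("s%02d", 1:n),
    individual_id = sprintf("i%02d", 1:n),
    tissue = "kidney", sex = sample(c("male", "female"), n, TRUE),
    age = runif(n, 40, 75), race = sample(c("EUR", "AFR"), n, TRUE),
    condition = "tumor",
    metastasis = rep(c(0L, 1L), each = n / 2),
    stage = sample(1:4, n, TRUE))
  met <- samples$metastasis == 1L
  # transcript A: strong 3-fold metastasis effect, expressed
  a <- 2^(3 + 1.585 * met + rnorm(n, 0, 0.2))
  # transcript B: significant but tiny fold change (~1.2)
  b <- 2^(3 + 0.263 * met + rnorm(n, 0, 0.05))
  # transcript C: strong effect but essentially unexpressed
  cc <- 2^(-8 + 2 * met + rnorm(n, 0, 0.2))
  vals <- rbind(A = a, B = b, C = cc)
  colnames(vals) <- samples$sample_id
  m <- expression_matrix(vals)
  res <- suppressWarnings(
    clinical_outcome_association(m, samples, "metastasis"))
  expect_true(res$retained[res$transcript_id == "A"])
  expect_false(res$retained[res$transcript_id == "B"])   # FC gate
  expect_false(res$retained[res$transcript_id == "C"])   # expression gate
  expect_false(res$expressed[res$transcript_id == "C"])

  # stage: no FC gate, FDR + expression only
  d <- 2^(3 + 0.15 * samples$stage + rnorm(n, 0, 0.05))
  vals2 <- rbind(D = d)
  colnames(vals2) <- samples$sample_id
  m2 <- expression_matrix(vals2)
  res2 <- suppressWarnings(
    clinical_outcome_association(m2, samples, "stage"))
  expect_true(res2$retained[1])
  fcd <- 2^0.15  # per-stage fold change ~1.11, far below 1.5
  expect_lt(fcd, 1.5)
})

test_that("Cox models recover hazard ratios and classify direction", {
  set.seed(3)
  expr <- stats::setNames(rnorm(300), sprintf("IND%04d", 1:300))
  sv <- generate_survival(expr, baseline_hazard = 0.05, log_hr = 0.7,
                          censoring_rate = 0, seed = 19L)
  st <- survival_samples(sv, expr, seed = 4L)
  cx <- cox_survival(expr, st)
  expect_true(cx$converged)
  expect_equal(cx$hazard_ratio, exp(0.7), tolerance = 0.15)
  expect_identical(cx$direction, "risky")
  expect_lt(cx$p_value, 1e-6)

  # independence: HR near 1, not significant
  sv0 <- generate_survival(expr, baseline_hazard = 0.05, log_hr = 0,
                           censoring_rate = 0.01, seed = 20L)
  st0 <- survival_samples(sv0, expr, seed = 5L)
  cx0 <- cox_survival(expr, st0)
  expect_true(cx0$hazard_ratio > 0.8 && cx0$hazard_ratio < 1.25)
  expect_gt(cx0$p_value, 0.05)

  # protective direction rule
  svp <- generate_survival(expr, baseline_hazard = 0.05, log_hr = -0.7,
                           censoring_rate = 0, seed = 21L)
  stp <- survival_samples(svp, expr, seed = 6L)
  expect_identical(cox_survival(expr, stp)$direction, "protective")
})

test_that("Cox prerequisites are enforced", {
  expr <- stats::setNames(rnorm(30), sprintf("IND%04d", 1:30))
  sv <- generate_survival(expr, baseline_hazard = 0.05, seed = 1L)
  st <- survival_samples(sv, expr)
  st$survival_event <- 0L
  expect_error(cox_survival(expr, st), "no observed events")
  sv2 <- sv; sv2$survival_event <- c(rep(1L, 5), rep(0L, 25))
  st2 <- survival_samples(sv2, expr)
  expect_error(cox_survival(expr, st2), "fewer than 10")
})

test_that("duplicate samples per individual keep the first sample_id", {
  set.seed(41)
  expr <- c(5, 99, 1, 2, rnorm(26, 3))   # s_b duplicates individual of s_a
  sv <- generate_survival(stats::setNames(rnorm(30), sprintf("P%02d", 1:30)),
                          baseline_hazard = 0.2, seed = 2L)
  st <- survival_samples(sv, expr)
  st$sample_id <- sprintf("smp%02d", 1:30)
  st$individual_id[2] <- st$individual_id[1]   # smp01/smp02 same person
  km <- km_median_split(expr, st)
  # 29 patients survive deduplication
  expect_equal(sum(km$fit$n), 29)
})

test_that("median split uses only patients with survival information", {
  n <- 20L
  expr <- as.numeric(1:n)
  st <- data.frame(
    sample_id = sprintf("s%02d", 1:n),
    individual_id = sprintf("i%02d", 1:n),
    tissue = "brain", sex = "male", age = 60, race = "EUR",
    condition = "tumor",
    survival_time = c(rep(NA, 10), rexp(10, 0.1)),
    survival_event = c(rep(NA, 10), rep(1L, 10)))
  km <- km_median_split(expr, st)
  # median over patients 11..20 (expression 11..20) -> 15.5
  expect_equal(km$median, 15.5)
  expect_equal(sum(km$fit$n), 10)
})

test_that("log-rank separates distinct hazards and not identical ones", {
  set.seed(10)
  n <- 120L
  expr <- c(rep(0, n / 2), rep(4, n / 2))
  names(expr) <- sprintf("IND%04d", 1:n)
  sv <- generate_survival(expr, baseline_hazard = 0.02, log_hr = 0.8,
                          censoring_rate = 0, seed = 30L)
  st <- survival_samples(sv, expr, seed = 7L)
  km <- km_median_split(expr, st)
  expect_lt(km$p_value, 0.01)

  svn <- generate_survival(expr * 0 + 1, baseline_hazard = 0.02,
                           log_hr = 0, censoring_rate = 0, seed = 31L)
  stn <- survival_samples(svn, expr, seed = 8L)
  kmn <- km_median_split(rnorm(n), stn)
  expect_gt(kmn$p_value, 0.05)
})

test_that("enrichment odds ratio matches the two-ratio definition", {
  r <- tissue_enrichment_or(5, 10, 2, 40)
  expect_equal(r$odds_ratio, 10)
  expect_lt(r$p_value, 0.05)
  expect_equal(tissue_enrichment_or(3, 9, 5, 15)$odds_ratio, 1)
  expect_equal(tissue_enrichment_or(0, 9, 5, 15)$odds_ratio, 0)
  expect_true(is.na(tissue_enrichment_or(3, 0, 5, 15)$odds_ratio))
  expect_error(tissue_enrichment_or(-1, 2, 3, 4), ">= 0")
  # OR > 1 exactly when the specific fraction is larger among biased
  set.seed(12)
  for (i in 1:25) {
    k <- sample(1:30, 4, replace = TRUE)
    r <- tissue_enrichment_or(k[1], k[2], k[3], k[4])
    expect_identical(r$odds_ratio > 1,
                     k[1] / (k[1] + k[2]) > k[3] / (k[3] + k[4]))
  }
})

test_that("GWAS overlap counts SNPs across the whole locus, inclusive", {
  t <- tm("t", "chr5", "+", c(1000, 5000), c(1500, 5500))
  snps <- data.frame(
    id = c("out_left", "at_start", "in_exon", "in_intron", "at_end",
           "out_right", "other_chrom"),
    chrom = c("chr5", "chr5", "chr5", "chr5", "chr5", "chr5", "chr1"),
    pos = c(999L, 1000L, 1200L, 3000L, 5500L, 5501L, 1200L))
  r <- gwas_overlap_count(t, snps)
  expect_equal(r$count, 4L)
  expect_setequal(r$hits, c("at_start", "in_exon", "in_intron", "at_end"))
  expect_error(
    gwas_overlap_count(t, data.frame(id = "z", chrom = "chr5", pos = 0L)),
    "1-based")
})
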