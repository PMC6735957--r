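#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure with monotonicity enforcement; p-values
#' outside `[0, 1]` are rejected. `NA`s are propagated and excluded from
#' the adjustment, matching the behaviour expected when singular fits are
#' flagged out of an analysis.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of FDR-adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# log2 FPKM with a small pseudocount; the response scale of every linear
# mixed model in the package.
log2_fpkm <- function(x, pseudocount = 0.01) log2(x + pseudocount)

# Build a per-sample model frame, dropping covariates that carry a
# single level among the included samples (with a warning).
build_model_frame <- function(expr, samples, covariates) {
  df <- data.frame(y = expr,
                   individual_id = factor(samples$individual_id))
  kept <- character(0)
  for (cv in covariates) {
    v <- samples[[cv]]
    if (is.null(v)) stop("sample table lacks covariate: ", cv)
    if (cv %in% c("age", "stage")) {
      v <- as.numeric(v)
    } else {
      # unordered factor, most frequent level as reference
      tb <- sort(table(v), decreasing = TRUE)
      v <- factor(v, levels = names(tb))
    }
    if (length(unique(v[!is.na(v)])) < 2L) {
      warning("covariate '", cv, "' has a single level; dropped")
      next
    }
    df[[cv]] <- v
    kept <- c(kept, cv)
  }
  attr(df, "kept") <- kept
  df
}

#' Fit the trait linear mixed model for one transcript
#'
#' `expression ~ tissue + sex + race + age` with a per-individual random
#' intercept (block random effect), fitted with [nlme::lme()]. Reported
#' p-values are the Wald tests of the fixed-effect coefficients.
#' Expression is modelled on the log2 scale (small pseudocount); the
#' fold-change column is the ratio of raw group mean expressions and is
#' only defined for two-level factor covariates.
#'
#' @param expr Per-sample expression (raw FPKM) aligned with `samples`.
#' @param samples [sample_table()] rows for the same samples.
#' @param covariates Fixed-effect covariates (default
#'   `c("tissue", "sex", "race", "age")`). Single-level covariates are
#'   dropped with a warning.
#' @param log_transform Model `log2(expr + pseudocount)` (default) or the
#'   raw values.
#' @param pseudocount Added before the log (default 0.01).
#' @return `data.table`, one row per fixed-effect term (intercept
#'   excluded): `covariate`, `term`, `estimate`, `fold_change`,
#'   `p_value`, `singular`. A singular/non-converged fit yields one
#'   flagged row with `NA`s so it can be excluded from FDR adjustment.
#' @export
fit_trait_lmm <- function(expr, samples,
                          covariates = c("tissue", "sex", "race", "age"),
                          log_transform = TRUE, pseudocount = 0.01) {
  samples <- sample_table(samples)
  if (length(expr) != nrow(samples))
    stop("expression vector and sample table disagree in length")
  if (length(unique(samples$individual_id)) < 2L)
    stop("need at least 2 individuals")
  y <- if (log_transform) log2_fpkm(expr, pseudocount) else expr
  df <- build_model_frame(y, samples, covariates)
  kept <- attr(df, "kept")
  if (length(kept) == 0L) stop("no usable covariate left")

  # degenerate response: no variance, all effects 0 by convention
  if (stats::sd(df$y) == 0) {
    return(data.table::data.table(
      covariate = kept, term = kept, estimate = 0, fold_change = NA_real_,
      p_value = 1, singular = FALSE))
  }

  form <- stats::as.formula(paste("y ~", paste(kept, collapse = " + ")))
  fit <- tryCatch(
    nlme::lme(fixed = form, random = ~ 1 | individual_id, data = df,
              method = "REML",
              control = nlme::lmeControl(returnObject = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(data.table::data.table(
      covariate = kept, term = kept, estimate = NA_real_,
      fold_change = NA_real_, p_value = NA_real_, singular = TRUE))
  }
  tt <- summary(fit)$tTable
  terms <- rownames(tt)[rownames(tt) != "(Intercept)"]
  cov_of <- function(term) kept[which.max(vapply(kept, function(cv)
    startsWith(term, cv) * nchar(cv), numeric(1)))]
  res <- data.table::data.table(
    covariate = vapply(terms, cov_of, character(1)),
    term = terms,
    estimate = tt[terms, "Value"],
    fold_change = NA_real_,
    p_value = tt[terms, "p-value"],
    singular = FALSE)
  # raw-scale fold change for two-level factors: mean(level2)/mean(level1)
  for (cv in kept) {
    v <- df[[cv]]
    if (is.factor(v) && nlevels(v) == 2L) {
      m1 <- mean(expr[v == levels(v)[1L]])
      m2 <- mean(expr[v == levels(v)[2L]])
      if (m1 > 0)
        data.table::set(res, i = which(res$covariate == cv),
                        j = "fold_change", value = m2 / m1)
    }
  }
  res
}

#' Trait association scan over a matrix
#'
#' Runs [fit_trait_lmm()] for every transcript and BH-adjusts p-values
#' per term across transcripts (never across analyses). Singular fits
#' are excluded from the adjustment.
#'
#' @inheritParams fit_trait_lmm
#' @param m [expression_matrix()]; columns must match `samples$sample_id`.
#' @return Long `data.table`: `transcript_id`, `covariate`, `term`,
#'   `estimate`, `fold_change`, `p_value`, `fdr`, `singular`.
#' @export
trait_association_scan <- function(m, samples,
                                   covariates = c("tissue", "sex",
                                                  "race", "age"),
                                   log_transform = TRUE,
                                   pseudocount = 0.01) {
  samples <- sample_table(samples)
  idx <- match(colnames(m), samples$sample_id)
  if (anyNA(idx)) stop("matrix columns missing from sample table")
  samples <- samples[idx]
  res <- lapply(rownames(m), function(tid) {
    r <- suppressWarnings(
      fit_trait_lmm(unclass(m)[tid, ], samples, covariates,
                    log_transform, pseudocount))
    r$transcript_id <- tid
    r
  })
  out <- data.table::rbindlist(res)
  out$fdr <- NA_real_
  for (tm in unique(out$term)) {
    sel <- out$term == tm & !out$singular
    out$fdr[sel] <- bh_fdr(out$p_value[sel])
  }
  data.table::setcolorder(out, "transcript_id")
  out[]
}

#' Tumor/normal differential expression within one tissue
#'
#' Per transcript, a linear mixed model of (log2) expression on
#' condition plus sex, race and age, with a per-individual random
#' intercept. A transcript is called differentially expressed when its
#' condition FDR < `fdr_threshold` and the raw-scale fold change exceeds
#' `fc_threshold` in either direction (`max(FC, 1/FC) > fc_threshold`,
#' strict). The matrix is expected to be quantile-normalized.
#'
#' @param m [expression_matrix()] (quantile-normalized FPKM).
#' @param samples [sample_table()].
#' @param tissue Tissue to analyse; must have both tumor and normal
#'   samples.
#' @param fdr_threshold,fc_threshold Call thresholds (defaults 0.05 and
#'   1.5).
#' @return `data.table`: `transcript_id`, `estimate`, `fold_change`
#'   (tumor/normal raw means), `p_value`, `fdr`, `de_call`, `direction`.
#' @export
differential_expression <- function(m, samples, tissue,
                                    fdr_threshold = 0.05,
                                    fc_threshold = 1.5) {
  samples <- sample_table(samples)
  sel <- samples$tissue == tissue
  if (!any(sel)) stop("no samples for tissue ", tissue)
  samples <- samples[sel]
  if (length(unique(samples$condition)) < 2L)
    stop("tissue ", tissue, " lacks tumor or normal samples")
  m <- m[, samples$sample_id, drop = FALSE]
  res <- lapply(rownames(m), function(tid) {
    x <- unclass(m)[tid, ]
    r <- suppressWarnings(
      fit_trait_lmm(x, samples,
                    covariates = c("condition", "sex", "race", "age")))
    r <- r[r$covariate == "condition"]
    tumor <- mean(x[samples$condition == "tumor"])
    normal <- mean(x[samples$condition == "normal"])
    fc <- if (normal > 0) tumor / normal else NA_real_
    est <- r$estimate[1L]
    # condition coded with most frequent level as reference; orient the
    # estimate as tumor-vs-normal
    if (!is.na(est) && r$term[1L] == "conditionnormal") est <- -est
    data.table::data.table(
      transcript_id = tid, estimate = est, fold_change = fc,
      p_value = r$p_value[1L], singular = r$singular[1L])
  })
  out <- data.table::rbindlist(res)
  out$fdr <- NA_real_
  ok <- !out$singular
  out$fdr[ok] <- bh_fdr(out$p_value[ok])
  fc2 <- pmax(out$fold_change, 1 / out$fold_change)
  out$de_call <- !is.na(out$fdr) & out$fdr < fdr_threshold &
    !is.na(fc2) & fc2 > fc_threshold
  out$direction <- ifelse(is.na(out$fold_change), NA_character_,
                          ifelse(out$fold_change >= 1, "up", "down"))
  out[]
}

#' Clinical-outcome association within one tumor
#'
#' Extends the trait mixed model with a clinical outcome. For binary
#' outcomes (`metastasis`, `recurrence`) a transcript is retained when
#' FDR < 0.05, the fold change exceeds 1.5 in either direction, and the
#' transcript is moderately-to-highly expressed in that tumor
#' ([moderate_expression_filter()]). For `stage` (ordered, treated as
#' numeric 1..4) there is no fold-change gate: FDR and the expression
#' filter decide.
#'
#' @param m [expression_matrix()] of tumor samples (or a superset).
#' @param samples [sample_table()] carrying the outcome column.
#' @param outcome One of `"metastasis"`, `"recurrence"`, `"stage"`.
#' @param tissue Optional tumor tissue to restrict to.
#' @param fdr_threshold,fc_threshold Gates (defaults 0.05, 1.5).
#' @return `data.table` with per-transcript estimate, fold change (binary
#'   outcomes), p, fdr, `expressed` (filter result) and `retained`.
#' @export
clinical_outcome_association <- function(m, samples, outcome,
                                         tissue = NULL,
                                         fdr_threshold = 0.05,
                                         fc_threshold = 1.5) {
  outcome <- match.arg(outcome, c("metastasis", "recurrence", "stage"))
  samples <- sample_table(samples)
  if (!outcome %in% names(samples))
    stop("sample table lacks outcome column: ", outcome)
  sel <- samples$condition == "tumor" & !is.na(samples[[outcome]])
  if (!is.null(tissue)) sel <- sel & samples$tissue == tissue
  if (!any(sel)) stop("no usable tumor samples for outcome ", outcome)
  samples <- samples[sel]
  ov <- samples[[outcome]]
  if (length(unique(ov)) < 2L)
    stop("outcome ", outcome, " has a single level")
  m <- m[, samples$sample_id, drop = FALSE]
  binary <- outcome != "stage"
  res <- lapply(rownames(m), function(tid) {
    x <- unclass(m)[tid, ]
    r <- suppressWarnings(
      fit_trait_lmm(x, samples,
                    covariates = c(outcome, "sex", "race", "age")))
    r <- r[r$covariate == outcome]
    fc <- NA_real_
    if (binary) {
      g <- as.logical(ov)
      m0 <- mean(x[!g]); m1 <- mean(x[g])
      if (m0 > 0) fc <- m1 / m0
    }
    data.table::data.table(
      transcript_id = tid, estimate = r$estimate[1L], fold_change = fc,
      p_value = r$p_value[1L], singular = r$singular[1L],
      expressed = moderate_expression_filter(x))
  })
  out <- data.table::rbindlist(res)
  out$fdr <- NA_real_
  ok <- !out$singular
  out$fdr[ok] <- bh_fdr(out$p_value[ok])
  sig <- !is.na(out$fdr) & out$fdr < fdr_threshold
  if (binary) {
    fc2 <- pmax(out$fold_change, 1 / out$fold_change)
    out$retained <- sig & !is.na(fc2) & fc2 > fc_threshold & out$expressed
  } else {
    out$retained <- sig & out$expressed
  }
  out[]
}

# One sample per individual: keep the lexicographically first sample_id.
dedupe_individuals <- function(samples) {
  o <- order(samples$sample_id)
  s <- samples[o]
  s[!duplicated(s$individual_id)]
}

#' Multivariate Cox survival model for one transcript
#'
#' Cox proportional-hazards regression of overall survival on transcript
#' expression with sex, age and race as confounders, one sample per
#' individual (lexicographically first `sample_id`). The proportional-
#' hazards assumption is checked per covariate with the scaled Schoenfeld
#' residual test ([survival::cox.zph()]); when age violates it
#' (p < `ph_alpha`) the model is refitted with age stratified into
#' quartiles. The hazard ratio classifies the transcript as protective
#' (HR < 1) or risky (HR > 1).
#'
#' @param expr Per-sample expression aligned with `samples`.
#' @param samples [sample_table()] with `survival_time` and
#'   `survival_event` columns.
#' @param min_events Minimum number of observed events (default 10).
#' @param ph_alpha Significance level of the PH test (default 0.05).
#' @return One-row `data.table`: `hazard_ratio`, `p_value`, `direction`,
#'   `n`, `events`, `age_stratified`, `converged`.
#' @export
cox_survival <- function(expr, samples, min_events = 10L,
                         ph_alpha = 0.05) {
  samples <- sample_table(samples)
  if (!all(c("survival_time", "survival_event") %in% names(samples)))
    stop("sample table lacks survival columns")
  if (length(expr) != nrow(samples))
    stop("expression vector and sample table disagree in length")
  samples$.expr <- expr
  samples <- samples[!is.na(samples$survival_time) &
                       !is.na(samples$survival_event)]
  samples <- dedupe_individuals(samples)
  events <- sum(samples$survival_event > 0)
  if (events == 0L) stop("no observed events")
  if (events < min_events)
    stop("fewer than ", min_events, " events (", events, ")")
  df <- data.frame(time = samples$survival_time,
                   event = as.integer(samples$survival_event > 0),
                   expression = samples$.expr,
                   sex = factor(samples$sex), age = samples$age,
                   race = factor(samples$race))
  covs <- c("expression",
            Filter(function(cv) length(unique(df[[cv]])) > 1L,
                   c("sex", "age", "race")))
  form <- stats::as.formula(
    paste("survival::Surv(time, event) ~", paste(covs, collapse = " + ")))
  fit <- tryCatch(suppressWarnings(survival::coxph(form, data = df)),
                  error = function(e) NULL)
  flagged <- function(conv) data.table::data.table(
    hazard_ratio = NA_real_, p_value = NA_real_,
    direction = NA_character_, n = nrow(df), events = events,
    age_stratified = FALSE, converged = conv)
  if (is.null(fit)) return(flagged(FALSE))
  age_strat <- FALSE
  if ("age" %in% covs) {
    zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
    if (!is.null(zph) && "age" %in% rownames(zph$table) &&
        zph$table["age", "p"] < ph_alpha) {
      qs <- unique(stats::quantile(df$age, c(0.25, 0.5, 0.75), type = 7))
      df$age_stratum <- cut(df$age, breaks = c(-Inf, qs, Inf))
      covs2 <- c(setdiff(covs, "age"), "survival::strata(age_stratum)")
      form2 <- stats::as.formula(
        paste("survival::Surv(time, event) ~",
              paste(covs2, collapse = " + ")))
      fit2 <- tryCatch(suppressWarnings(survival::coxph(form2, data = df)),
                       error = function(e) NULL)
      if (!is.null(fit2)) { fit <- fit2; age_strat <- TRUE }
    }
  }
  sm <- summary(fit)$coefficients
  hr <- unname(sm["expression", "exp(coef)"])
  data.table::data.table(
    hazard_ratio = hr,
    p_value = unname(sm["expression", "Pr(>|z|)"]),
    direction = if (hr < 1) "protective" else if (hr > 1) "risky"
                else NA_character_,
    n = nrow(df), events = events,
    age_stratified = age_strat, converged = TRUE)
}

#' Kaplan-Meier analysis with a median expression split
#'
#' Patients with available survival information (one sample per
#' individual) are split at the median expression computed over those
#' same patients: high = expression > median, low = expression <= median.
#' Kaplan-Meier curves are estimated per group and compared with the
#' log-rank test.
#'
#' @inheritParams cox_survival
#' @param min_group Minimum patients per group (default 2).
#' @return List with `fit` (a [survival::survfit()] object), `group`
#'   (factor aligned with the retained patients), `median` (the split
#'   point) and `p_value` (log-rank).
#' @export
km_median_split <- function(expr, samples, min_group = 2L) {
  samples <- sample_table(samples)
  if (length(expr) != nrow(samples))
    stop("expression vector and sample table disagree in length")
  samples$.expr <- expr
  samples <- samples[!is.na(samples$survival_time) &
                       !is.na(samples$survival_event)]
  samples <- dedupe_individuals(samples)
  med <- stats::median(samples$.expr)
  group <- factor(ifelse(samples$.expr > med, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) < min_group))
    stop("degenerate split: fewer than ", min_group,
         " patients in a group")
  df <- data.frame(time = samples$survival_time,
                   event = as.integer(samples$survival_event > 0),
                   group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(lr$chisq, df = length(lr$n) - 1L, lower.tail = FALSE)
  list(fit = fit, group = group, median = med, p_value = p)
}

#' Tissue enrichment odds ratio (Fisher's exact test, one-tailed)
#'
#' For trait-biased transcripts versus non-biased ones:
#' `OR = (a/b) / (c/d)` where `a` biased transcripts are specific to the
#' tissue, `b` biased transcripts are not, `c` non-biased are specific
#' and `d` non-biased are not. The one-tailed p-value tests enrichment
#' (OR > 1). Tissue-specific means specificity score > 0.6 upstream.
#'
#' @param biased_specific,biased_other,nonbiased_specific,nonbiased_other
#'   Non-negative counts `a`, `b`, `c`, `d`.
#' @return List with `odds_ratio` (NA when a denominator is 0) and
#'   `p_value`.
#' @export
tissue_enrichment_or <- function(biased_specific, biased_other,
                                 nonbiased_specific, nonbiased_other) {
  a <- biased_specific; b <- biased_other
  cc <- nonbiased_specific; d <- nonbiased_other
  if (any(c(a, b, cc, d) < 0)) stop("counts must be >= 0")
  tab <- matrix(c(a, b, cc, d), nrow = 2L,
                dimnames = list(c("specific", "other"),
                                c("biased", "nonbiased")))
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  or <- if (b == 0 || d == 0) NA_real_ else (a / b) / (cc / d)
  list(odds_ratio = or, p_value = p)
}

#' Count GWAS SNPs overlapping a transcript locus
#'
#' A SNP overlaps when its 1-based position falls within the transcript's
#' locus span (first exon start to last exon end, introns included,
#' bounds inclusive) on the same chromosome; strand is ignored.
#'
#' @param t A `transcript_model`.
#' @param snps SNP table as returned by [read_snp_bed()] (columns `id`,
#'   `chrom`, `pos`).
#' @return List with `count` and `hits` (the overlapping SNP ids).
#' @export
gwas_overlap_count <- function(t, snps) {
  snps <- data.table::as.data.table(snps)
  if (any(snps$pos < 1L)) stop("SNP positions must be 1-based (>= 1)")
  span <- locus_span(t)
  hit <- snps$chrom == t$chrom & snps$pos >= span[1L] & snps$pos <= span[2L]
  list(count = sum(hit), hits = snps$id[hit])
}
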