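# Shared fixture builders and independent oracles for the test suite.

# terse transcript constructor
tm <- function(id, chrom, strand, starts, ends, gene = paste0(id, "g"),
               source = "assembled", biotype = "other") {
  transcript_model(id, gene, chrom, strand, starts, ends,
                   source = source, biotype = biotype)
}

# brute-force exonic base enumeration (oracle for transcript_length)
brute_length <- function(t) {
  length(unlist(apply(t$exons, 1L, function(e) seq(e[1L], e[2L]))))
}

# exhaustive pair-counting AUC oracle (ties count 1/2)
brute_auc <- function(pos, neg) {
  g <- outer(pos, neg, ">"); e <- outer(pos, neg, "==")
  (sum(g) + 0.5 * sum(e)) / (length(pos) * length(neg))
}

# trapezoidal AUC from a ROC table ordered by decreasing threshold,
# anchored at (0,0) and (1,1) in (FPR, TPR) space
trapezoid_auc <- function(roc) {
  fpr <- c(0, 1 - roc$specificity, 1)
  tpr <- c(0, roc$sensitivity, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# exhaustive optimal-cutoff oracle: scan every candidate threshold
brute_cutoff <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  d <- vapply(thr, function(x) {
    sens <- mean(pos >= x); spec <- mean(neg < x)
    sqrt((1 - sens)^2 + (1 - spec)^2)
  }, numeric(1))
  max(thr[d == min(d)])
}

# brute-force BH: fdr_i = min over j with p_(j) >= p_(i)... step-up form
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# split a generated annotation into coding / lncRNA transcript sets
split_annotation <- function(ann) {
  list(coding = transcript_set(Filter(function(t)
         t$biotype == "protein_coding", unclass(ann$models))),
       lnc = transcript_set(Filter(function(t)
         t$biotype == "lncRNA", unclass(ann$models))))
}

# survival sample table around generated outcomes
survival_samples <- function(sv, expr, seed = 1L) {
  set.seed(seed)
  n <- nrow(sv)
  sample_table(data.frame(
    sample_id = sv$individual_id, individual_id = sv$individual_id,
    tissue = "brain",
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = stats::runif(n, 40, 75),
    race = sample(c("EUR", "AFR"), n, replace = TRUE),
    condition = "tumor",
    survival_time = sv$survival_time,
    survival_event = sv$survival_event))
}
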