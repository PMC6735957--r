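#' Quantile normalization of an expression matrix
#'
#' Forces every sample (column) onto the common distribution given by the
#' across-sample means of order statistics, the standard correction for
#' library-size and batch differences in large FPKM compendia. Ties
#' within a column receive the mean of the target values they would have
#' occupied, so the map is well defined and permutation-equivariant.
#'
#' @param m An [expression_matrix()] or plain numeric matrix with
#'   dimnames; at least one column.
#' @return Matrix of the same shape and dimnames; afterwards every column
#'   holds the identical multiset of values.
#' @export
quantile_normalize <- function(m) {
  x <- unclass(as.matrix(m))
  if (ncol(x) < 1L) stop("need at least one sample")
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    o <- order(col)
    v <- numeric(length(col))
    v[o] <- ref
    # tied input values share the mean of their assigned targets
    v <- stats::ave(v, match(col, col))
    out[, j] <- v
  }
  if (inherits(m, "expression_matrix")) expression_matrix(out) else out
}

# Shannon entropy in bits; 0 * log2(0) treated as 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Jensen-Shannon divergence of two probability vectors, in bits.
js_divergence <- function(p1, p2) {
  entropy_bits((p1 + p2) / 2) - (entropy_bits(p1) + entropy_bits(p2)) / 2
}

#' Jensen-Shannon tissue-specificity score
#'
#' The per-tissue expression vector `e` (FPKM) is normalized to a
#' probability vector `p` with `p_i = log2(e_i + 1) / sum(log2(e_j + 1))`
#' and compared, via the square-root Jensen-Shannon metric, against each
#' extremal single-tissue pattern `e^t` (the unit vector at tissue `t`).
#' The score is `max_t 1 - sqrt(JS(p, e^t))`. Entropy is taken in bits
#' (log base 2) so the JS divergence -- and hence the score -- lies in
#' `[0, 1]`; 1 means expression confined to a single tissue.
#'
#' @param e Numeric vector of per-tissue expression (length >= 2), named
#'   or not; at least one entry must be positive.
#' @return Score in `[0, 1]`.
#' @export
tissue_specificity_score <- function(e) {
  if (length(e) < 2L) stop("need expression over at least 2 tissues")
  if (any(e < 0)) stop("negative expression")
  if (all(e == 0)) stop("all-zero expression pattern")
  w <- log2(e + 1)
  p <- w / sum(w)
  best <- -Inf
  for (t in seq_along(p)) {
    et <- numeric(length(p)); et[t] <- 1
    best <- max(best, 1 - sqrt(js_divergence(p, et)))
  }
  best
}

#' Tissue-specificity scores for a whole matrix
#'
#' Collapses samples to per-tissue expression (mean FPKM by default, the
#' summary is configurable) and scores every transcript.
#'
#' @param m [expression_matrix()].
#' @param samples [sample_table()] covering the matrix columns.
#' @param summarize Function collapsing a tissue's samples (default
#'   [mean()]).
#' @return `data.table` with `transcript_id`, `score` and `top_tissue`
#'   (the argmax tissue); transcripts with all-zero expression get `NA`.
#' @export
tissue_specificity_table <- function(m, samples, summarize = mean) {
  samples <- sample_table(samples)
  if (!all(colnames(m) %in% samples$sample_id))
    stop("matrix columns missing from sample table")
  tis <- samples$tissue[match(colnames(m), samples$sample_id)]
  tissues <- sort(unique(tis))
  bytis <- do.call(cbind, lapply(tissues, function(tt)
    rowMeans2(m[, tis == tt, drop = FALSE], summarize)))
  colnames(bytis) <- tissues
  score <- rep(NA_real_, nrow(m)); top <- rep(NA_character_, nrow(m))
  for (i in seq_len(nrow(m))) {
    e <- bytis[i, ]
    if (all(e == 0)) next
    w <- log2(e + 1); p <- w / sum(w)
    s <- vapply(seq_along(p), function(t) {
      et <- numeric(length(p)); et[t] <- 1
      1 - sqrt(js_divergence(p, et))
    }, numeric(1))
    score[i] <- max(s)
    top[i] <- tissues[which.max(s)]
  }
  data.table::data.table(transcript_id = rownames(m),
                         score = score, top_tissue = top)
}

rowMeans2 <- function(x, f) {
  if (identical(f, mean)) rowMeans(x) else apply(x, 1L, f)
}

#' Splicing efficiency of a gene
#'
#' When transcripts are quantified against an annotation augmented with
#' one artificial isoform per gene spanning the whole locus (unspliced
#' pre-mRNA surrogate), the splicing efficiency is the abundance fraction
#' captured by the originally annotated isoforms:
#' `sum(annotated) / (sum(annotated) + spanning)`.
#'
#' @param annotated Numeric vector of annotated-isoform abundances (>= 0,
#'   at least one isoform).
#' @param spanning Abundance of the locus-spanning unspliced isoform.
#' @return Value in `[0, 1]`, or `NA` when total abundance is 0.
#' @export
splicing_efficiency <- function(annotated, spanning) {
  if (length(annotated) < 1L) stop("need at least one annotated isoform")
  if (any(annotated < 0) || spanning < 0) stop("negative abundance")
  tot <- sum(annotated) + spanning
  if (tot == 0) return(NA_real_)
  sum(annotated) / tot
}

#' Mean conservation score over a transcript's exonic bases
#'
#' Sums a per-base score track (e.g. phastCons) over the transcript's
#' exonic bases and divides by the transcript length. Bases absent from
#' the track contribute 0, so sparse tracks are handled without
#' imputation.
#'
#' @param t A `transcript_model`.
#' @param track Per-base score table as returned by [read_bedgraph()]
#'   (`chrom`, `start0`, `end0` half-open, `value`).
#' @return Mean per-base score (numeric scalar).
#' @export
conservation_score <- function(t, track) {
  track <- data.table::as.data.table(track)
  tr <- track[track$chrom == t$chrom]
  total <- 0
  if (nrow(tr)) {
    s1 <- tr$start0 + 1L   # convert half-open 0-based to 1-based inclusive
    e1 <- tr$end0
    for (i in seq_len(nrow(t$exons))) {
      ov <- interval_overlap(t$exons[i, 1L], t$exons[i, 2L], s1, e1)
      total <- total + sum(ov * tr$value)
    }
  }
  total / transcript_length(t)
}

#' Inter-individual expression variability (coefficient of variation)
#'
#' Sample standard deviation (n-1 denominator) of per-donor expression
#' divided by the mean. Scale-invariant. Callers are expected to restrict
#' to autosomal transcripts expressed (FPKM > 0.1) in at least one donor;
#' a zero mean yields `NA`.
#'
#' @param x Numeric vector of per-donor expression, length >= 2.
#' @return CV, or `NA` when the mean is 0.
#' @export
interindividual_variability <- function(x) {
  if (length(x) < 2L) stop("need at least 2 donors")
  if (any(x < 0)) stop("negative expression")
  mu <- mean(x)
  if (mu == 0) return(NA_real_)
  stats::sd(x) / mu
}

#' Moderate-to-high expression filter (Q3 + 1.5 IQR rule)
#'
#' A transcript counts as moderately-to-highly expressed in a tissue when
#' the upper Tukey fence of its per-sample FPKM distribution exceeds
#' 0.1 FPKM: `Q3 + 1.5 * (Q3 - Q1) > 0.1`, quartiles by linear
#' interpolation. With a single sample both quartiles equal the value, so
#' the rule degenerates to `value > 0.1`.
#'
#' @param fpkm Per-sample FPKM within one tissue (length >= 1).
#' @param threshold Expression cutoff (default 0.1 FPKM).
#' @return Logical scalar.
#' @export
moderate_expression_filter <- function(fpkm, threshold = 0.1) {
  if (length(fpkm) == 0L) stop("need at least one sample")
  q <- stats::quantile(fpkm, c(0.25, 0.75), type = 7, names = FALSE)
  q[2L] + 1.5 * (q[2L] - q[1L]) > threshold
}

#' Per-transcript recurrence summary
#'
#' Counts, per transcript, the tissues and samples in which it is
#' expressed (FPKM strictly > 0.1).
#'
#' @param m [expression_matrix()].
#' @param samples [sample_table()]; every matrix column must carry a
#'   tissue annotation.
#' @param threshold Expression threshold (strict; default 0.1 FPKM).
#' @return `data.table` with `transcript_id`, `n_tissues_expressed`,
#'   `n_samples_expressed`.
#' @export
recurrence_summary <- function(m, samples, threshold = 0.1) {
  samples <- sample_table(samples)
  idx <- match(colnames(m), samples$sample_id)
  if (anyNA(idx))
    stop("sample(s) missing from metadata: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  tis <- samples$tissue[idx]
  if (anyNA(tis) || any(!nzchar(tis))) stop("sample missing tissue annotation")
  expressed <- unclass(m) > threshold
  data.table::data.table(
    transcript_id = rownames(m),
    n_tissues_expressed = apply(expressed, 1L, function(z)
      length(unique(tis[z]))),
    n_samples_expressed = rowSums(expressed))
}

#' Catalog percentages with half-up rounding
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal -- the
#' presentation convention used for catalog composition statements such
#' as "83.6% (23,001/27,520) intergenic".
#'
#' @param numerator,denominator Non-negative counts (vectorized);
#'   denominator > 0.
#' @return Numeric percentages with one decimal.
#' @export
catalog_percentages <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  if (any(numerator < 0)) stop("numerator must be >= 0")
  floor(100 * numerator / denominator * 10 + 0.5) / 10
}
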