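#' Transcript Confidence Score components
#'
#' From per-sample evidence for a single transcript, computes the three
#' ingredients of the confidence score:
#' \describe{
#'   \item{J}{the uniquely-mapped junction-read count in the maximally
#'     expressed sample (ties on FPKM resolved toward the larger junction
#'     count);}
#'   \item{E}{the 95th percentile of per-sample FPKM, linear
#'     interpolation between order statistics ([stats::quantile()] type 7);}
#'   \item{R}{the number of samples with FPKM strictly > 0.1 (sample
#'     recurrence).}
#' }
#'
#' @param fpkm Numeric vector of per-sample FPKM (>= 0).
#' @param junction_reads Integer vector of per-sample junction-read
#'   counts, aligned with `fpkm`. Single-exon transcripts have no
#'   junctions and carry zeros here.
#' @return Named numeric vector `c(J=, E=, R=)`.
#' @export
tcs_components <- function(fpkm, junction_reads) {
  if (length(fpkm) == 0L)
    stop("empty evidence: at least one sample required")
  if (length(junction_reads) != length(fpkm))
    stop("fpkm and junction_reads must be aligned")
  if (any(fpkm < 0) || any(junction_reads < 0))
    stop("negative evidence values")
  top <- which(fpkm == max(fpkm))
  J <- max(junction_reads[top])
  E <- unname(stats::quantile(fpkm, 0.95, type = 7))
  R <- sum(fpkm > 0.1)
  c(J = as.numeric(J), E = E, R = as.numeric(R))
}

#' Score context: normalizers over a transcript universe
#'
#' The maxima of J, E and R over all transcripts scored in one run
#' (known positives, decoys and candidates together), so that scores are
#' comparable within the run.
#'
#' @param components Matrix or data.frame with columns `J`, `E`, `R`, one
#'   row per transcript in the universe.
#' @return Named numeric vector `c(max_j=, max_e=, max_r=)`.
#' @export
score_context <- function(components) {
  components <- as.data.frame(components)
  ctx <- c(max_j = max(components$J), max_e = max(components$E),
           max_r = max(components$R))
  if (any(ctx <= 0))
    stop("all score-context normalizers must be > 0")
  ctx
}

#' Transcript Confidence Score
#'
#' `TCS = 100/3 * (J/max_j + E/max_e + R/max_r)`, a composite of junction
#' support, expression level and sample recurrence scaled to `[0, 100]`.
#' Components exceeding their normalizer indicate a universe/context
#' mismatch and are an error.
#'
#' @param components Named vector `c(J=, E=, R=)` (from
#'   [tcs_components()]) or a matrix/data.frame of such rows.
#' @param ctx Named vector `c(max_j=, max_e=, max_r=)` from
#'   [score_context()].
#' @return Numeric score(s) in `[0, 100]`.
#' @export
transcript_confidence_score <- function(components, ctx) {
  if (is.null(dim(components)))
    components <- matrix(components[c("J", "E", "R")], nrow = 1L,
                         dimnames = list(NULL, c("J", "E", "R")))
  components <- as.matrix(as.data.frame(components)[, c("J", "E", "R")])
  if (any(ctx[c("max_j", "max_e", "max_r")] <= 0))
    stop("normalizers must be > 0")
  if (any(components[, "J"] > ctx[["max_j"]]) ||
      any(components[, "E"] > ctx[["max_e"]]) ||
      any(components[, "R"] > ctx[["max_r"]]))
    stop("component exceeds its normalizer: universe/context mismatch")
  unname(100 / 3 * (components[, "J"] / ctx[["max_j"]] +
                    components[, "E"] / ctx[["max_e"]] +
                    components[, "R"] / ctx[["max_r"]]))
}

#' Score a long-format evidence table
#'
#' Convenience wrapper: computes per-transcript components over an
#' evidence table (`transcript_id`, `sample_id`, `junction_reads`,
#' `fpkm`), derives the context from the whole table and scores every
#' transcript.
#'
#' @param evidence Long-format `data.frame`/`data.table` of per-sample
#'   evidence rows.
#' @return `data.table` with columns `transcript_id`, `J`, `E`, `R`,
#'   `tcs`, plus the context as attribute `"score_context"`.
#' @export
compute_tcs_table <- function(evidence) {
  ev <- data.table::as.data.table(evidence)
  need <- c("transcript_id", "sample_id", "junction_reads", "fpkm")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("evidence table missing column(s): ", paste(miss, collapse = ", "))
  junction_reads <- fpkm <- transcript_id <- NULL  # NSE notes
  comp <- ev[, {
    k <- tcs_components(fpkm, junction_reads)
    list(J = k[["J"]], E = k[["E"]], R = k[["R"]])
  }, by = transcript_id]
  ctx <- score_context(comp[, c("J", "E", "R")])
  comp$tcs <- transcript_confidence_score(comp, ctx)
  data.table::setattr(comp, "score_context", ctx)
  comp[]
}

#' Generate shuffled decoy transcripts
#'
#' For each template, draws a random genomic placement that preserves the
#' template's exon/intron length structure and strand: a chromosome is
#' chosen with probability proportional to its length (among chromosomes
#' long enough), a start position uniformly, and the placement is
#' accepted iff the full locus span avoids all exclusion intervals
#' (rejection sampling, bounded attempts). The negatives produced this
#' way emulate intergenic background transcription for the ROC analysis.
#'
#' @param templates A [transcript_set()] of real transcripts.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param exclusion Optional `data.frame` of 1-based inclusive intervals
#'   to avoid (columns `chrom`, `start`, `end`), typically annotated gene
#'   loci.
#' @param seed Integer RNG seed; identical seeds give identical decoys.
#' @param max_attempts Attempts per template before giving up.
#' @return A [transcript_set()] of decoys, ids prefixed `decoy_`; decoys
#'   may overlap each other.
#' @export
shuffle_decoys <- function(templates, chrom_sizes, exclusion = NULL,
                           seed = 1L, max_attempts = 1000L) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (!is.null(exclusion)) exclusion <- data.table::as.data.table(exclusion)
  set.seed(seed)
  out <- vector("list", length(templates))
  for (k in seq_along(templates)) {
    t <- templates[[k]]
    span <- locus_span(t)
    span_len <- span[2L] - span[1L] + 1L
    offs <- t$exons - span[1L]          # exon offsets within the span
    fits <- chrom_sizes >= span_len
    if (!any(fits))
      stop("no chromosome can hold template ", t$transcript_id)
    w <- as.numeric(chrom_sizes[fits])
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      chrom <- sample(names(chrom_sizes)[fits], 1L, prob = w)
      start <- sample.int(chrom_sizes[[chrom]] - span_len + 1L, 1L)
      end <- start + span_len - 1L
      clash <- !is.null(exclusion) && nrow(exclusion) > 0L &&
        any(exclusion$chrom == chrom &
            interval_overlap(start, end, exclusion$start, exclusion$end) > 0L)
      if (!clash) {
        out[[k]] <- transcript_model(
          transcript_id = paste0("decoy_", t$transcript_id),
          gene_id = paste0("decoy_", t$gene_id),
          chrom = chrom, strand = t$strand,
          exon_start = offs[, "start"] + start,
          exon_end = offs[, "end"] + start,
          source = "decoy", biotype = t$biotype)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place decoy for template ", t$transcript_id,
           " after ", max_attempts, " attempts")
  }
  transcript_set(out)
}

#' ROC curve and AUC from positive/negative score sets
#'
#' Thresholds are the distinct observed scores; a transcript is predicted
#' positive iff its score is >= the threshold. The AUC is the
#' Mann-Whitney pair statistic (ties counted 1/2), which equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param positive_scores,negative_scores Non-empty numeric vectors.
#' @return List with `roc` (`data.frame`: `threshold`, `sensitivity`,
#'   `specificity`) and `auc`.
#' @export
roc_and_auc <- function(positive_scores, negative_scores) {
  if (length(positive_scores) == 0L || length(negative_scores) == 0L)
    stop("both score sets must be non-empty")
  thr <- sort(unique(c(positive_scores, negative_scores)), decreasing = TRUE)
  sens <- vapply(thr, function(x) mean(positive_scores >= x), numeric(1))
  spec <- vapply(thr, function(x) mean(negative_scores < x), numeric(1))
  np <- length(positive_scores); nn <- length(negative_scores)
  r <- rank(c(positive_scores, negative_scores))   # midranks handle ties
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  list(roc = data.frame(threshold = thr, sensitivity = sens,
                        specificity = spec),
       auc = auc)
}

#' ROC-optimal score cutoff
#'
#' The threshold whose ROC point minimizes the Euclidean distance
#' `sqrt((1 - sensitivity)^2 + (1 - specificity)^2)` to the perfect
#' corner (sensitivity = specificity = 1). Ties are broken toward the
#' larger threshold, i.e. the stricter filter.
#'
#' @param roc `data.frame` of ROC points as produced by [roc_and_auc()].
#' @return The optimal threshold (numeric scalar).
#' @export
optimal_cutoff <- function(roc) {
  if (nrow(roc) == 0L) stop("empty ROC")
  d <- sqrt((1 - roc$sensitivity)^2 + (1 - roc$specificity)^2)
  best <- which(d == min(d))
  max(roc$threshold[best])
}

#' Filter transcripts by confidence score
#'
#' Transcripts scoring below the cutoff are excluded; retention is
#' `score >= cutoff`.
#'
#' @param scores Named numeric vector of per-transcript scores.
#' @param cutoff Finite numeric cutoff.
#' @return Character vector of retained transcript ids.
#' @export
filter_by_tcs <- function(scores, cutoff) {
  stopifnot(is.finite(cutoff))
  names(scores)[scores >= cutoff]
}

#' Verify a transcript by mean per-base coverage
#'
#' A transcript counts as verified in a sample when its mean read depth
#' over exonic bases is strictly greater than 2.
#'
#' @param depths Numeric vector of per-base depths over the transcript's
#'   exonic bases (length = transcript length).
#' @return Logical scalar.
#' @export
verify_by_coverage <- function(depths) {
  if (length(depths) == 0L) stop("empty coverage track")
  if (any(depths < 0)) stop("negative depth")
  mean(depths) > 2
}
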