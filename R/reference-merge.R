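#' Redundancy test between two transcript models
#'
#' Multi-exon pair: redundant iff the intron chains are identical on the
#' same strand (terminal exon ends are free to differ). Single-exon pair:
#' redundant iff the same-strand genomic overlap exceeds 80% of the
#' shorter transcript (strict `>`). A mixed single/multi-exon pair is
#' never redundant.
#'
#' @param a,b `transcript_model`s on the same chromosome.
#' @return Logical scalar.
#' @export
is_redundant <- function(a, b) {
  if (a$chrom != b$chrom) return(FALSE)
  if (a$strand != b$strand) return(FALSE)
  na <- nrow(a$exons); nb <- nrow(b$exons)
  if (na > 1L && nb > 1L)
    return(identical(intron_chain(a), intron_chain(b)))
  if (na == 1L && nb == 1L) {
    ov <- interval_overlap(a$exons[1L, 1L], a$exons[1L, 2L],
                           b$exons[1L, 1L], b$exons[1L, 2L])
    shorter <- min(transcript_length(a), transcript_length(b))
    return(ov > 0.8 * shorter)
  }
  FALSE
}

#' Merge reference catalogs under the redundancy rules
#'
#' Redundancy classes are the transitive closure of [is_redundant()];
#' within each class exactly one representative survives: the transcript
#' from the highest-priority source, ties broken by lexicographically
#' smallest transcript id. The operation is idempotent and its output
#' contains no redundant pair.
#'
#' @param models A [transcript_set()].
#' @param priority Character vector of source tags from highest to lowest
#'   priority; sources not listed rank below all listed ones.
#' @return A [transcript_set()] of surviving representatives.
#' @export
merge_references <- function(models,
                             priority = c("GENCODE", "RefSeq",
                                          "lncRNAdb", "assembled")) {
  n <- length(models)
  if (n == 0L) return(transcript_set())
  # union-find over the redundancy graph, chromosome+strand blocked
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  key <- vapply(models, function(t) paste0(t$chrom, t$strand), character(1))
  for (idx in split(seq_len(n), key)) {
    if (length(idx) < 2L) next
    for (ii in seq_along(idx)[-1L]) for (jj in seq_len(ii - 1L)) {
      i <- idx[ii]; j <- idx[jj]
      if (is_redundant(models[[i]], models[[j]])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  prio <- function(t) {
    p <- match(t$source, priority)
    if (is.na(p)) length(priority) + 1L else p
  }
  survivors <- vapply(split(seq_len(n), root), function(cls) {
    pr <- vapply(models[cls], prio, integer(1))
    cls <- cls[pr == min(pr)]
    ids <- vapply(models[cls], `[[`, character(1), "transcript_id")
    cls[order(ids)][1L]
  }, integer(1))
  transcript_set(unclass(models)[sort(survivors)])
}

#' Assign a class code to a query transcript against a reference set
#'
#' A minimal subset of the cuffcompare code table, sufficient for novelty
#' calling and genomic-context classification:
#' \describe{
#'   \item{`=`}{intron chain identical to a same-strand reference
#'     transcript; for single-exon pairs, same-strand reciprocal overlap
#'     > 0.8 of each transcript.}
#'   \item{`c`}{query's intron chain is a contiguous sub-chain of a
#'     same-strand reference transcript and the query is exonically
#'     contained in it.}
#'   \item{`u`}{no overlap with any reference locus span (intergenic).}
#'   \item{`o`}{same-strand exonic overlap not covered above.}
#'   \item{`x`}{exonic overlap on the opposite strand only.}
#'   \item{`i`}{query fully inside an intron of a same-strand reference.}
#'   \item{`other`}{any remaining overlap configuration.}
#' }
#'
#' @param query A `transcript_model`.
#' @param reference A [transcript_set()] to compare against.
#' @return Single-character class code.
#' @export
assign_class_code <- function(query, reference) {
  same_exonic <- FALSE; opp_exonic <- FALSE
  span_overlap <- FALSE; same_intronic <- FALSE
  has_c <- FALSE
  qspan <- locus_span(query)
  qn <- nrow(query$exons)
  qchain <- intron_chain(query)
  for (ref in reference) {
    if (ref$chrom != query$chrom) next
    rspan <- locus_span(ref)
    if (interval_overlap(qspan[1L], qspan[2L], rspan[1L], rspan[2L]) == 0L)
      next
    span_overlap <- TRUE
    same <- ref$strand == query$strand
    ov <- exonic_overlap_bases(query, ref)
    if (same) {
      rn <- nrow(ref$exons)
      if (qn > 1L && rn > 1L) {
        if (identical(qchain, intron_chain(ref))) return("=")
      } else if (qn == 1L && rn == 1L) {
        if (ov > 0.8 * transcript_length(query) &&
            ov > 0.8 * transcript_length(ref)) return("=")
      }
      if (is_subchain_contained(query, ref)) has_c <- TRUE
      if (ov > 0L) same_exonic <- TRUE
      if (ov == 0L && rn > 1L) {
        ic <- intron_chain(ref)
        if (any(qspan[1L] >= ic[, "start"] & qspan[2L] <= ic[, "end"]))
          same_intronic <- TRUE
      }
    } else if (ov > 0L) {
      opp_exonic <- TRUE
    }
  }
  if (has_c) return("c")
  if (!span_overlap) return("u")
  if (same_exonic) return("o")
  if (opp_exonic) return("x")
  if (same_intronic) return("i")
  "other"
}

# TRUE iff query's intron chain is a contiguous sub-chain of ref's and
# every query exonic base lies inside a ref exon (cuffcompare 'c').
# Identical multi-exon chains are caught upstream as '='.
is_subchain_contained <- function(query, ref) {
  qc <- intron_chain(query); rc <- intron_chain(ref)
  if (nrow(qc) > nrow(rc)) return(FALSE)
  if (nrow(qc) > 0L) {
    hit <- FALSE
    for (off in 0:(nrow(rc) - nrow(qc))) {
      if (identical(qc, rc[off + seq_len(nrow(qc)), , drop = FALSE])) {
        hit <- TRUE; break
      }
    }
    if (!hit) return(FALSE)
  }
  exonic_overlap_bases(query, ref) == transcript_length(query)
}

#' Is a query transcript novel relative to a reference?
#'
#' Novel iff its class code is neither `=` (known model) nor `c`
#' (truncated fragment of a known model).
#'
#' @inheritParams assign_class_code
#' @return Logical scalar.
#' @export
flag_novel <- function(query, reference) {
  !assign_class_code(query, reference) %in% c("=", "c")
}
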