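#' Coding-potential evidence row(s)
#'
#' Per-transcript calls from external coding-potential predictors (CPC,
#' CPAT) and downstream hit flags (Pfam domain search on three-frame
#' conceptual translations, mass-spectrometry peptide matches, Ribo-Seq
#' translation evidence). The predictors themselves are consumed as
#' precomputed evidence, never re-run here. Missing flags are an error by
#' design: silently defaulting a coding call would corrupt the catalog.
#'
#' @param df data.frame with logical/0-1 columns `cpc_noncoding`,
#'   `cpat_noncoding`, `pfam_hit`, `ms_hit`, `riboseq_hit` and a
#'   `transcript_id` column.
#' @return Validated `data.table` with logical flag columns.
#' @export
coding_evidence <- function(df) {
  dt <- data.table::as.data.table(df)
  need <- c("transcript_id", "cpc_noncoding", "cpat_noncoding",
            "pfam_hit", "ms_hit", "riboseq_hit")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("coding evidence missing column(s): ", paste(miss, collapse = ", "))
  for (cl in need[-1L]) {
    v <- dt[[cl]]
    if (anyNA(v)) stop("missing value in evidence column ", cl)
    data.table::set(dt, j = cl, value = as.logical(v))
  }
  if (anyDuplicated(dt$transcript_id)) stop("duplicated transcript_id")
  dt
}

#' Preliminary noncoding call
#'
#' A transcript is preliminarily noncoding when either CPC or CPAT
#' predicts it to lack coding potential (union, not intersection).
#'
#' @param ev One-row coding evidence (list/data.frame with
#'   `cpc_noncoding`, `cpat_noncoding`), or vectors recycled elementwise.
#' @return Logical.
#' @export
is_preliminary_noncoding <- function(ev) {
  as.logical(ev$cpc_noncoding) | as.logical(ev$cpat_noncoding)
}

#' Final noncoding filter
#'
#' Applied to preliminary noncoding transcripts only: any hit in Pfam (at
#' any of the ga/nc/tc cutoffs), in the mass-spectrometry data or in the
#' Ribo-Seq samples removes the transcript.
#'
#' @param ev Coding evidence (as in [is_preliminary_noncoding()]).
#' @return Logical; `TRUE` means the transcript survives.
#' @export
passes_final_noncoding <- function(ev) {
  if (!all(is_preliminary_noncoding(ev)))
    stop("final noncoding filter applied to a transcript that failed the preliminary filter")
  !(as.logical(ev$pfam_hit) | as.logical(ev$ms_hit) | as.logical(ev$riboseq_hit))
}

#' Identify lncRNAs among candidate transcripts
#'
#' Retains candidates that (i) are longer than 200 nt (strict), (ii) are
#' preliminarily noncoding (CPC or CPAT) and (iii) survive the final
#' evidence filter (no Pfam/MS/Ribo-Seq hit).
#'
#' @param candidates A [transcript_set()].
#' @param evidence A [coding_evidence()] table covering every candidate.
#' @return Character vector of retained transcript ids.
#' @export
identify_lncrnas <- function(candidates, evidence) {
  ev <- coding_evidence(evidence)
  ids <- names(candidates)
  miss <- setdiff(ids, ev$transcript_id)
  if (length(miss))
    stop("no coding evidence for transcript(s): ",
         paste(miss, collapse = ", "))
  ev <- ev[match(ids, ev$transcript_id)]
  len <- vapply(candidates, transcript_length, integer(1))
  prelim <- is_preliminary_noncoding(ev)
  clean <- !(ev$pfam_hit | ev$ms_hit | ev$riboseq_hit)
  ids[len > 200L & prelim & clean]
}

#' Classify a lncRNA by genomic context
#'
#' Evaluation order: `intergenic` when the class code against the coding
#' set is `u`; else `sense` when there is >= 1 bp same-strand exonic
#' overlap with a coding transcript; else `antisense` when the lncRNA
#' overlaps a coding gene locus (exons or introns) on the opposite
#' strand; everything left is `others` (e.g. same-strand intronic).
#'
#' @param lnc A `transcript_model`.
#' @param coding A [transcript_set()] of protein-coding transcripts.
#' @return One of `"intergenic"`, `"sense"`, `"antisense"`, `"others"`.
#' @export
classify_context <- function(lnc, coding) {
  code <- assign_class_code(lnc, coding)
  if (code == "u") return("intergenic")
  span <- locus_span(lnc)
  sense <- FALSE; anti <- FALSE
  for (ref in coding) {
    if (ref$chrom != lnc$chrom) next
    rspan <- locus_span(ref)
    if (interval_overlap(span[1L], span[2L], rspan[1L], rspan[2L]) == 0L)
      next
    if (ref$strand == lnc$strand) {
      if (exonic_overlap_bases(lnc, ref) > 0L) sense <- TRUE
    } else {
      anti <- TRUE
    }
  }
  if (sense) return("sense")
  if (anti) return("antisense")
  "others"
}

#' Classify a whole lncRNA set
#'
#' @param lncs A [transcript_set()] of lncRNAs.
#' @param coding A [transcript_set()] of protein-coding transcripts.
#' @return `data.table` with `transcript_id` and `class` columns; every
#'   transcript receives exactly one label.
#' @export
classify_context_all <- function(lncs, coding) {
  data.table::data.table(
    transcript_id = names(lncs),
    class = vapply(lncs, classify_context, character(1), coding = coding))
}

#' Catalog redundancy by 1-bp exon overlap
#'
#' The criterion used when comparing independently built lncRNA catalogs:
#' two transcripts are considered redundant when any exon of one overlaps
#' any exon of the other by at least one base, ignoring strand.
#'
#' @param a,b `transcript_model`s.
#' @return Logical scalar; symmetric in its arguments.
#' @export
catalogs_overlap <- function(a, b) {
  exonic_overlap_bases(a, b) >= 1L
}
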