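#' Genomic interval
#'
#' Plain 1-based inclusive interval, the coordinate convention used
#' throughout the package (GTF convention). BED-style inputs are converted
#' on read, never stored half-open.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start,end 1-based inclusive positions, `end >= start >= 1`.
#' @param strand One of `"+"`, `"-"`, `"."`. `"."` is only legal for
#'   features that are genuinely unstranded (SNPs); transcripts must be
#'   stranded.
#' @return A `genomic_interval` list.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("chrom must be a non-empty string")
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || start < 1L) stop("start must be >= 1")
  if (is.na(end) || end < start) stop("end must be >= start")
  if (!strand %in% c("+", "-", ".")) stop("strand must be '+', '-' or '.'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' Transcript model
#'
#' A stranded, multi-exon gene model on a single chromosome with a source
#' catalog tag. Exons are stored as a two-column integer matrix
#' (start, end), 1-based inclusive, sorted by start and non-overlapping.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`; transcripts must be stranded because the
#'   downstream genomic-context classification is strand-aware.
#' @param exon_start,exon_end Parallel integer vectors of exon coordinates.
#' @param source Catalog tag, e.g. `"GENCODE"`, `"RefSeq"`, `"lncRNAdb"`,
#'   `"assembled"`.
#' @param biotype One of `"protein_coding"`, `"lncRNA"`, `"other"`.
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_start, exon_end,
                             source = "assembled", biotype = "other") {
  if (!nzchar(transcript_id)) stop("transcript_id must be non-empty")
  if (!nzchar(chrom)) stop("chrom must be non-empty")
  if (!strand %in% c("+", "-"))
    stop("transcript ", transcript_id, ": strand must be '+' or '-'")
  if (!biotype %in% c("protein_coding", "lncRNA", "other"))
    stop("biotype must be protein_coding, lncRNA or other")
  exon_start <- as.integer(exon_start); exon_end <- as.integer(exon_end)
  if (length(exon_start) == 0L || length(exon_start) != length(exon_end))
    stop("transcript ", transcript_id, ": need matching, non-empty exon vectors")
  o <- order(exon_start)
  exon_start <- exon_start[o]; exon_end <- exon_end[o]
  if (any(is.na(exon_start)) || any(exon_start < 1L))
    stop("transcript ", transcript_id, ": exon start must be >= 1")
  if (any(exon_end < exon_start))
    stop("transcript ", transcript_id, ": exon end < start")
  if (length(exon_start) > 1L &&
      any(exon_start[-1L] <= exon_end[-length(exon_end)]))
    stop("transcript ", transcript_id, ": exons overlap or touch")
  structure(list(
    transcript_id = transcript_id,
    gene_id = gene_id,
    chrom = chrom,
    strand = strand,
    exons = cbind(start = exon_start, end = exon_end),
    source = source,
    biotype = biotype
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%d-%d(%s) %d exon(s), %d nt [%s/%s]\n",
              x$transcript_id, x$gene_id, x$chrom,
              locus_span(x)[1L], locus_span(x)[2L], x$strand,
              nrow(x$exons), transcript_length(x), x$source, x$biotype))
  invisible(x)
}

#' Spliced transcript length in nucleotides
#'
#' Sum of exon lengths; the quantity the `> 200` bp size-selection filter
#' is applied to.
#'
#' @param t A `transcript_model`.
#' @return Integer number of exonic bases.
#' @export
transcript_length <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  sum(t$exons[, "end"] - t$exons[, "start"] + 1L)
}

#' Intron chain of a transcript
#'
#' The ordered introns (gaps between consecutive exons). Identity of
#' intron chains is the redundancy/equivalence criterion for multi-exon
#' transcripts: two models with the same chain differ at most in their
#' terminal exon ends.
#'
#' @param t A `transcript_model`.
#' @return Integer matrix with columns `start`, `end` (1-based inclusive
#'   intronic coordinates); zero rows for a single-exon transcript.
#' @export
intron_chain <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  n <- nrow(t$exons)
  if (n < 2L)
    return(cbind(start = integer(0), end = integer(0)))
  cbind(start = unname(t$exons[-n, "end"]) + 1L,
        end   = unname(t$exons[-1L, "start"]) - 1L)
}

# Genomic span of the whole locus (first exon start, last exon end).
locus_span <- function(t) {
  c(t$exons[1L, "start"], t$exons[nrow(t$exons), "end"])
}

#' Bundle transcript models into a named set
#'
#' @param models List of `transcript_model`s; names are taken from the
#'   models' transcript ids and must be unique.
#' @return A `transcript_set` (named list).
#' @export
transcript_set <- function(models = list()) {
  stopifnot(all(vapply(models, inherits, logical(1), "transcript_model")))
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids))
    stop("duplicated transcript_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(models) <- ids
  structure(models, class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("<transcript_set> %d transcript(s)\n", length(x)))
  invisible(x)
}

#' @export
`[.transcript_set` <- function(x, i) {
  transcript_set(unclass(x)[i])
}

# Overlap length of two 1-based inclusive intervals (0 if disjoint).
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

# Total number of bases of `a`'s exons falling inside `b`'s exons.
exonic_overlap_bases <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  tot <- 0L
  for (i in seq_len(nrow(a$exons)))
    tot <- tot + sum(interval_overlap(a$exons[i, 1L], a$exons[i, 2L],
                                      b$exons[, 1L], b$exons[, 2L]))
  tot
}
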