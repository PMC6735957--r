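#' Read transcript models from a GTF file
#'
#' Parses `exon` features into [transcript_model()] objects. Attributes in
#' both the canonical GTF dialect (`key "value";`) and the bare
#' `key=value` dialect are accepted. Coordinates are kept 1-based
#' inclusive as in the file. Exons listed out of order are sorted by
#' start. Optional `source_tag` and `biotype` attributes override the
#' second GTF column / the default biotype.
#'
#' @param path Path to a GTF file.
#' @return A [transcript_set()], one model per `transcript_id`.
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(transcript_set())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stop("malformed GTF line ", lineno[bad[1L]], ": expected 9 tab-separated fields")

  feat <- vapply(fields, `[[`, character(1), 3L)
  is_exon <- feat == "exon"
  if (!any(is_exon)) return(transcript_set())
  fields <- fields[is_exon]; lineno <- lineno[is_exon]

  chrom  <- vapply(fields, `[[`, character(1), 1L)
  src    <- vapply(fields, `[[`, character(1), 2L)
  start  <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 4L)))
  end    <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 5L)))
  strand <- vapply(fields, `[[`, character(1), 7L)
  attrs  <- vapply(fields, `[[`, character(1), 9L)

  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1L]
    stop("malformed GTF line ", lineno[i], ": non-numeric coordinate")
  }
  if (any(end < start)) {
    i <- which(end < start)[1L]
    stop("invalid exon on line ", lineno[i], ": end < start")
  }

  att <- lapply(attrs, parse_gtf_attributes)
  get_att <- function(key, default = NA_character_)
    vapply(att, function(a) if (!is.null(a[[key]])) a[[key]] else default,
           character(1))
  tid <- get_att("transcript_id")
  gid <- get_att("gene_id")
  if (anyNA(tid))
    stop("malformed GTF line ", lineno[which(is.na(tid))[1L]],
         ": missing transcript_id attribute")
  if (anyNA(gid))
    stop("malformed GTF line ", lineno[which(is.na(gid))[1L]],
         ": missing gene_id attribute")
  src_att <- get_att("source_tag")
  src <- ifelse(is.na(src_att), src, src_att)
  biotype <- get_att("biotype", "other")

  models <- lapply(split(seq_along(tid), tid)[unique(tid)], function(i) {
    transcript_model(
      transcript_id = tid[i[1L]], gene_id = gid[i[1L]],
      chrom = chrom[i[1L]], strand = strand[i[1L]],
      exon_start = start[i], exon_end = end[i],
      source = src[i[1L]], biotype = biotype[i[1L]])
  })
  transcript_set(models)
}

# Accepts `key "value"; key2 "v2";` and `key=value;key2=v2`.
parse_gtf_attributes <- function(s) {
  out <- list()
  for (tok in strsplit(s, ";", fixed = TRUE)[[1L]]) {
    tok <- trimws(tok)
    if (!nzchar(tok)) next
    m <- regmatches(tok, regexec('^(\\S+)\\s+"([^"]*)"$', tok))[[1L]]
    if (length(m) == 3L) { out[[m[2L]]] <- m[3L]; next }
    m <- regmatches(tok, regexec("^([^=[:space:]]+)[[:space:]]*=[[:space:]]*(.*)$",
                                 tok))[[1L]]
    if (length(m) == 3L) { out[[m[2L]]] <- gsub('^"|"$', "", m[3L]); next }
    m <- regmatches(tok, regexec("^(\\S+)\\s+(\\S+)$", tok))[[1L]]
    if (length(m) == 3L) out[[m[2L]]] <- m[3L]
  }
  out
}

#' Write transcript models to GTF
#'
#' One `exon` row per exon, grouped by transcript, canonical GTF quoting.
#' `source_tag` and `biotype` attributes round-trip through [read_gtf()].
#'
#' @param models A [transcript_set()] or list of [transcript_model()]s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#gtf written by lncforge", con)
  for (t in models) {
    at <- sprintf('gene_id "%s"; transcript_id "%s"; source_tag "%s"; biotype "%s";',
                  t$gene_id, t$transcript_id, t$source, t$biotype)
    for (i in seq_len(nrow(t$exons)))
      writeLines(paste(t$chrom, t$source, "exon",
                       t$exons[i, "start"], t$exons[i, "end"],
                       ".", t$strand, ".", at, sep = "\t"), con)
  }
  invisible(path)
}

#' Expression matrix constructor
#'
#' Transcripts-by-samples abundance matrix (FPKM). Negative entries and
#' duplicated row/column labels are rejected.
#'
#' @param values Numeric matrix with rownames (transcript ids) and
#'   colnames (sample ids).
#' @return The validated matrix with class `expression_matrix`.
#' @export
expression_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs transcript rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicated transcript ids")
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids")
  if (any(values < 0, na.rm = TRUE)) stop("negative abundance values")
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Read an expression matrix from TSV
#'
#' First column `transcript_id`, remaining columns one per sample.
#'
#' @param path TSV file path.
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt[[1L]]
  storage.mode(m) <- "double"
  expression_matrix(m)
}

#' Write an expression matrix to TSV
#'
#' @param m An [expression_matrix()] (or plain named matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  dt <- data.table::data.table(transcript_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(unclass(m)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

# Columns every sample table must carry; the remainder are optional
# clinical annotations used only by the association layer.
.sample_required <- c("sample_id", "individual_id", "tissue", "sex",
                      "age", "race", "condition")
.sample_optional <- c("stage", "metastasis", "recurrence",
                      "survival_time", "survival_event")

#' Validate a sample metadata table
#'
#' @param df data.frame with columns `sample_id`, `individual_id`,
#'   `tissue`, `sex`, `age`, `race`, `condition` and optionally `stage`,
#'   `metastasis`, `recurrence`, `survival_time`, `survival_event`.
#' @return The table as a `data.table`, validated.
#' @export
sample_table <- function(df) {
  df <- data.table::as.data.table(df)
  miss <- setdiff(.sample_required, names(df))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample_id must be unique")
  if (any(df$age < 0, na.rm = TRUE)) stop("age must be >= 0")
  if (!all(df$condition %in% c("normal", "tumor")))
    stop("condition must be 'normal' or 'tumor'")
  if ("survival_time" %in% names(df) &&
      any(df$survival_time < 0, na.rm = TRUE))
    stop("survival_time must be >= 0")
  df
}

#' Read a sample metadata table from TSV
#' @param path TSV file path with the fixed column names of [sample_table()].
#' @return Validated `data.table`.
#' @export
read_sample_table <- function(path) {
  sample_table(data.table::fread(path, sep = "\t", header = TRUE))
}

#' Read SNPs from a BED-like file
#'
#' BED is half-open 0-based; positions are converted to 1-based on read.
#' Single-base records (end = start0 + 1) are expected for SNPs. Optional
#' columns 4-6 are name, trait label and association p-value.
#'
#' @param path BED file path.
#' @return `data.table` with columns `id`, `chrom`, `pos` (1-based),
#'   `trait`, `p_value`.
#' @export
read_snp_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns")
  out <- data.table::data.table(
    id = if (ncol(dt) >= 4L) as.character(dt[[4L]])
         else paste0("snp", seq_len(nrow(dt))),
    chrom = as.character(dt[[1L]]),
    pos = as.integer(dt[[2L]]) + 1L,
    trait = if (ncol(dt) >= 5L) as.character(dt[[5L]]) else NA_character_,
    p_value = if (ncol(dt) >= 6L) as.numeric(dt[[6L]]) else NA_real_)
  if (any(out$pos < 1L)) stop("SNP position must be >= 1 after conversion")
  out
}

#' Read a bedGraph-style per-base score track
#'
#' Four columns: chrom, 0-based start, end (half-open), value. Returned
#' as-is (half-open) with canonical names; consumers convert per query.
#'
#' @param path bedGraph/TSV path.
#' @return `data.table` with columns `chrom`, `start0`, `end0`, `value`.
#' @export
read_bedgraph <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 4L) stop("bedGraph needs 4 columns")
  out <- dt[, 1:4]
  data.table::setnames(out, c("chrom", "start0", "end0", "value"))
  out[]
}
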