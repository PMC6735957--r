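#' Generate a toy annotation with planted genomic-context classes
#'
#' Builds a small genome of non-overlapping protein-coding genes plus
#' lncRNAs placed so that each realizes a requested genomic-context class
#' relative to the coding set:
#' \describe{
#'   \item{intergenic}{placed in gaps, >= 5 kb away from any gene locus;}
#'   \item{sense}{first exon overlaps a coding exon on the same strand;}
#'   \item{antisense}{inside a coding gene's intron on the opposite
#'     strand;}
#'   \item{others}{inside a coding gene's intron on the same strand.}
#' }
#' Every generated transcript is recorded in the returned truth table.
#' The same seed reproduces the annotation byte-for-byte.
#'
#' @param n_genes Number of protein-coding genes.
#' @param class_counts Named integer vector of lncRNAs to plant per class
#'   (`intergenic`, `sense`, `antisense`, `others`).
#' @param exon_count_range Range of exon counts for coding genes
#'   (minimum 2 so introns exist for intronic placements).
#' @param chrom_sizes Named vector of toy chromosome lengths.
#' @param seed RNG seed.
#' @return List with `models` (a [transcript_set()]: coding genes then
#'   lncRNAs) and `truth` (`data.table`: `transcript_id`, `gene_id`,
#'   `biotype`, `role`, `class_label`, `chrom`, `strand`).
#' @export
generate_annotation <- function(n_genes = 20L,
                                class_counts = c(intergenic = 5L,
                                                 sense = 3L,
                                                 antisense = 3L,
                                                 others = 3L),
                                exon_count_range = c(2L, 5L),
                                chrom_sizes = c(chrA = 1000000L,
                                                chrB = 1000000L),
                                seed = 1L) {
  stopifnot(exon_count_range[1L] >= 2L)
  set.seed(seed)
  n_lnc <- sum(class_counts)
  if (n_genes == 0L && n_lnc == 0L)
    return(list(models = transcript_set(),
                truth = empty_truth()))
  if (n_genes == 0L && n_lnc > 0L && any(class_counts[c("sense",
      "antisense", "others")] > 0L, na.rm = TRUE))
    stop("non-intergenic lncRNAs need coding genes to anchor to")

  chroms <- names(chrom_sizes)
  cursor <- stats::setNames(rep(10000L, length(chroms)), chroms)
  gap <- 20000L

  coding <- list()
  for (g in seq_len(n_genes)) {
    ch <- chroms[(g - 1L) %% length(chroms) + 1L]
    ne <- sample(seq(exon_count_range[1L], exon_count_range[2L]), 1L)
    st <- structure_random(ne, exon_len = c(100L, 300L),
                           intron_len = c(2000L, 6000L))
    start <- cursor[[ch]]
    span <- max(st$end)
    if (start + span + gap > chrom_sizes[[ch]])
      stop("infeasible packing: chromosome ", ch, " too small for ",
           n_genes, " genes")
    cursor[[ch]] <- start + span + gap
    coding[[g]] <- transcript_model(
      transcript_id = sprintf("PC%03d.1", g),
      gene_id = sprintf("PCG%03d", g),
      chrom = ch, strand = if (g %% 2L == 0L) "-" else "+",
      exon_start = st$start + start, exon_end = st$end + start,
      source = "GENCODE", biotype = "protein_coding")
  }

  lncs <- list(); labels <- character(0)
  want <- rep(names(class_counts), times = class_counts)
  k <- 0L
  for (lab in want) {
    k <- k + 1L
    id <- sprintf("LNC%03d.1", k)
    gid <- sprintf("LNCG%03d", k)
    lnc <- switch(lab,
      intergenic = {
        ch <- chroms[(k - 1L) %% length(chroms) + 1L]
        start <- cursor[[ch]] + 5000L
        len <- sample(300:800, 1L)
        if (start + len + gap > chrom_sizes[[ch]])
          stop("infeasible packing: no intergenic space left on ", ch)
        cursor[[ch]] <- start + len + gap
        transcript_model(id, gid, ch, sample(c("+", "-"), 1L),
                         start, start + len - 1L,
                         source = "assembled", biotype = "lncRNA")
      },
      sense = {
        # hosts cycle deterministically so same-class placements never
        # collide into redundant copies (requires class count <= n_genes)
        host <- coding[[(k - 1L) %% n_genes + 1L]]
        ex <- host$exons[1L, ]
        transcript_model(id, gid, host$chrom, host$strand,
                         ex["start"] + 10L, ex["start"] + 400L,
                         source = "assembled", biotype = "lncRNA")
      },
      antisense = ,
      others = {
        host <- coding[[(k - 1L) %% n_genes + 1L]]
        ic <- intron_chain(host)
        i <- (k - 1L) %% nrow(ic) + 1L
        len <- min(500L, ic[i, "end"] - ic[i, "start"] - 100L)
        strand <- if (lab == "antisense")
          setdiff(c("+", "-"), host$strand) else host$strand
        transcript_model(id, gid, host$chrom, strand,
                         ic[i, "start"] + 50L,
                         ic[i, "start"] + 50L + len - 1L,
                         source = "assembled", biotype = "lncRNA")
      })
    lncs[[k]] <- lnc
    labels <- c(labels, lab)
  }

  models <- transcript_set(c(coding, lncs))
  truth <- data.table::data.table(
    transcript_id = names(models),
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    biotype = vapply(models, `[[`, character(1), "biotype"),
    role = c(rep("coding", length(coding)), rep("lncRNA", length(lncs))),
    class_label = c(rep(NA_character_, length(coding)), labels),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    strand = vapply(models, `[[`, character(1), "strand"))
  list(models = models, truth = truth)
}

empty_truth <- function() {
  data.table::data.table(transcript_id = character(0),
                         gene_id = character(0), biotype = character(0),
                         role = character(0), class_label = character(0),
                         chrom = character(0), strand = character(0))
}

# Random exon layout (offsets from 0) with given exon/intron length ranges.
structure_random <- function(n_exons, exon_len, intron_len) {
  el <- sample(seq(exon_len[1L], exon_len[2L]), n_exons, replace = TRUE)
  il <- if (n_exons > 1L)
    sample(seq(intron_len[1L], intron_len[2L]), n_exons - 1L,
           replace = TRUE) else integer(0)
  start <- integer(n_exons); end <- integer(n_exons)
  pos <- 0L
  for (i in seq_len(n_exons)) {
    start[i] <- pos
    end[i] <- pos + el[i] - 1L
    if (i < n_exons) pos <- end[i] + il[i] + 1L
  }
  list(start = start, end = end)
}

#' Generate an expression cohort with injected covariate effects
#'
#' Log2-scale linear model per transcript and sample:
#' `baseline + tissue effect + injected covariate effects +
#' individual random intercept + residual noise`, exponentiated to FPKM
#' (`2^eta`), emulating log-normal RNA-seq abundances. Each individual
#' contributes one normal sample per tissue; a fraction additionally
#' contributes a tumor sample of the first tissue so tumor/normal
#' contrasts have within-individual pairing.
#'
#' Injected effects are the ground truth the association layer is
#' expected to recover: `sex` is added for male samples, `race` for the
#' "AFR" level, `age` per year (centred), `condition` for tumor samples
#' -- all in log2 units, so a `condition` effect of 2 is a true 4-fold
#' change.
#'
#' @param transcript_ids Character vector of transcripts to simulate.
#' @param n_individuals Number of donors.
#' @param tissues Tissue names (one normal sample each per donor).
#' @param effects Named list keyed by transcript id; each element a named
#'   numeric vector with any of `sex`, `age`, `race`, `condition`.
#'   Transcripts absent from the list carry zero effects.
#' @param baseline Mean log2 FPKM (default 3, i.e. 8 FPKM).
#' @param tissue_sd SD of per-transcript-tissue offsets (default 0.5).
#' @param individual_sd SD of the per-individual random intercept
#'   (default 0.3).
#' @param residual_sd Residual SD (default 0.5).
#' @param tumor_fraction Fraction of donors contributing a tumor sample
#'   (default 0).
#' @param seed RNG seed.
#' @return List with `matrix` (an [expression_matrix()]), `samples`
#'   (a [sample_table()]) and `effects` (the full truth table actually
#'   used).
#' @export
generate_expression_cohort <- function(transcript_ids,
                                       n_individuals = 50L,
                                       tissues = c("brain", "heart"),
                                       effects = list(),
                                       baseline = 3,
                                       tissue_sd = 0.5,
                                       individual_sd = 0.3,
                                       residual_sd = 0.5,
                                       tumor_fraction = 0,
                                       seed = 1L) {
  set.seed(seed)
  nt <- length(transcript_ids)
  ind <- sprintf("IND%04d", seq_len(n_individuals))
  sex <- sample(c("male", "female"), n_individuals, replace = TRUE)
  age <- stats::runif(n_individuals, 20, 80)
  race <- sample(c("EUR", "AFR", "ASN"), n_individuals, replace = TRUE,
                 prob = c(0.5, 0.3, 0.2))

  sm <- data.table::data.table(
    individual_id = rep(ind, each = length(tissues)),
    tissue = rep(tissues, times = n_individuals),
    condition = "normal")
  if (tumor_fraction > 0) {
    tum <- ind[seq_len(max(1L, round(tumor_fraction * n_individuals)))]
    sm <- rbind(sm, data.table::data.table(
      individual_id = tum, tissue = tissues[1L], condition = "tumor"))
  }
  sm$sample_id <- sprintf("S%04d", seq_len(nrow(sm)))
  ii <- match(sm$individual_id, ind)
  sm$sex <- sex[ii]; sm$age <- age[ii]; sm$race <- race[ii]
  sm <- sample_table(sm[, c("sample_id", "individual_id", "tissue",
                            "sex", "age", "race", "condition")])

  eff <- function(tid, what) {
    v <- effects[[tid]]
    if (!is.null(v) && what %in% names(v)) v[[what]] else 0
  }
  truth <- data.table::data.table(
    transcript_id = transcript_ids,
    sex = vapply(transcript_ids, eff, numeric(1), "sex"),
    age = vapply(transcript_ids, eff, numeric(1), "age"),
    race = vapply(transcript_ids, eff, numeric(1), "race"),
    condition = vapply(transcript_ids, eff, numeric(1), "condition"))

  tis_off <- matrix(stats::rnorm(nt * length(tissues), 0, tissue_sd),
                    nrow = nt,
                    dimnames = list(transcript_ids, tissues))
  u <- matrix(stats::rnorm(nt * n_individuals, 0, individual_sd),
              nrow = nt, dimnames = list(transcript_ids, ind))

  agec <- sm$age - mean(sm$age)
  male <- as.numeric(sm$sex == "male")
  afr <- as.numeric(sm$race == "AFR")
  tumor <- as.numeric(sm$condition == "tumor")

  eta <- matrix(baseline, nrow = nt, ncol = nrow(sm),
                dimnames = list(transcript_ids, sm$sample_id))
  eta <- eta + tis_off[, sm$tissue, drop = FALSE]
  eta <- eta + u[, sm$individual_id, drop = FALSE]
  eta <- eta + outer(truth$sex, male) + outer(truth$age, agec) +
    outer(truth$race, afr) + outer(truth$condition, tumor)
  eta <- eta + matrix(stats::rnorm(length(eta), 0, residual_sd),
                      nrow = nt)
  m <- expression_matrix(2^eta)
  list(matrix = m, samples = sm, effects = truth)
}

#' Generate per-sample junction/expression evidence with decoy truth
#'
#' Emulates the separation between genuine transcripts and shuffled
#' intergenic decoys that the confidence-score ROC is built on: real
#' transcripts draw junction reads from Poisson(`real_junction_lambda`)
#' and FPKM from a log-normal around `real_fpkm_meanlog`; decoys from
#' Poisson(`decoy_junction_lambda`) and a low log-normal, giving them low
#' expression quantiles and low sample recurrence.
#'
#' @param real_ids,decoy_ids Transcript id vectors.
#' @param n_samples Samples per transcript (default 20).
#' @param real_junction_lambda,decoy_junction_lambda Poisson means
#'   (defaults 20 and 1).
#' @param real_fpkm_meanlog,decoy_fpkm_meanlog Log-normal location
#'   (natural log; defaults `log(5)` and `log(0.05)`).
#' @param fpkm_sdlog Log-normal scale (default 1).
#' @param seed RNG seed.
#' @return List with `evidence` (long `data.table`: `transcript_id`,
#'   `sample_id`, `junction_reads`, `fpkm`) and `truth` (`data.table`
#'   with `transcript_id`, `label` in `{real, decoy}`).
#' @export
generate_evidence <- function(real_ids, decoy_ids, n_samples = 20L,
                              real_junction_lambda = 20,
                              decoy_junction_lambda = 1,
                              real_fpkm_meanlog = log(5),
                              decoy_fpkm_meanlog = log(0.05),
                              fpkm_sdlog = 1,
                              seed = 1L) {
  set.seed(seed)
  gen <- function(ids, jl, ml) {
    if (length(ids) == 0L) return(NULL)
    data.table::data.table(
      transcript_id = rep(ids, each = n_samples),
      sample_id = rep(sprintf("S%03d", seq_len(n_samples)),
                      times = length(ids)),
      junction_reads = stats::rpois(length(ids) * n_samples, jl),
      fpkm = stats::rlnorm(length(ids) * n_samples, ml, fpkm_sdlog))
  }
  evidence <- rbind(gen(real_ids, real_junction_lambda,
                        real_fpkm_meanlog),
                    gen(decoy_ids, decoy_junction_lambda,
                        decoy_fpkm_meanlog))
  truth <- data.table::data.table(
    transcript_id = c(real_ids, decoy_ids),
    label = c(rep("real", length(real_ids)),
              rep("decoy", length(decoy_ids))))
  list(evidence = evidence, truth = truth)
}

#' Generate survival outcomes under a proportional-hazards model
#'
#' Event times are exponential with per-patient rate
#' `baseline_hazard * exp(log_hr * expression)`; censoring times are
#' independent exponentials with rate `censoring_rate` (0 = no
#' censoring). `log_hr = 0` makes survival independent of expression.
#'
#' @param expression Named numeric vector, one value per individual
#'   (names are individual ids).
#' @param baseline_hazard Baseline exponential event rate (> 0).
#' @param log_hr Log hazard ratio per unit expression.
#' @param censoring_rate Exponential rate of the censoring distribution
#'   (default 0: all events observed).
#' @param seed RNG seed.
#' @return `data.table`: `individual_id`, `survival_time`,
#'   `survival_event` (1 = event observed, 0 = censored).
#' @export
generate_survival <- function(expression, baseline_hazard = 0.1,
                              log_hr = 0, censoring_rate = 0,
                              seed = 1L) {
  stopifnot(baseline_hazard > 0, censoring_rate >= 0)
  if (is.null(names(expression)))
    names(expression) <- sprintf("IND%04d", seq_along(expression))
  set.seed(seed)
  n <- length(expression)
  tev <- stats::rexp(n, rate = baseline_hazard * exp(log_hr * expression))
  cen <- if (censoring_rate > 0) stats::rexp(n, censoring_rate)
         else rep(Inf, n)
  data.table::data.table(
    individual_id = names(expression),
    survival_time = pmin(tev, cen),
    survival_event = as.integer(tev <= cen))
}
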