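#' Marker QC thresholds
#'
#' Two-stage marker funnel settings. Discovery-stage criteria act on contig
#' annotations of candidate SNPs: assay designability strictly above
#' `min_designability`, at least `min_contig_reads` reads and
#' `min_contig_ests` ESTs in the contig, at least `min_minor_allele_reads`
#' reads of the least frequent allele, and at least `min_snp_spacing_bp`
#' between candidates in the same contig. Panel-stage criteria act on
#' genotype data and platform scores: GenTrain strictly above
#' `min_gentrain`, call frequency strictly above `min_call_frequency`, MAF
#' strictly above `min_maf`, heterozygote fraction strictly below
#' `max_het_excess`, call rate strictly above `min_call_rate`, and at most
#' `max_missing_count` missing calls (loci with more are excluded).
#'
#' Strictness follows the usual platform wording: "higher than" / "lower
#' than" are strict comparisons; the missing-call rule keeps loci at the
#' bound.
#'
#' @param min_designability,min_gentrain,min_call_frequency,min_maf,max_het_excess,min_call_rate
#'   proportions in \[0, 1\]
#' @param min_contig_reads,min_contig_ests,min_minor_allele_reads,min_snp_spacing_bp,max_missing_count
#'   non-negative counts
#' @return list of class `qc_thresholds`
#' @export
qc_thresholds <- function(min_designability = 0.6, min_contig_reads = 8,
                          min_contig_ests = 4, min_minor_allele_reads = 2,
                          min_snp_spacing_bp = 50, min_gentrain = 0.5,
                          min_call_frequency = 0.9, min_maf = 0.06,
                          max_het_excess = 0.8, min_call_rate = 0.8,
                          max_missing_count = 22) {
  th <- list(min_designability = min_designability,
             min_contig_reads = min_contig_reads,
             min_contig_ests = min_contig_ests,
             min_minor_allele_reads = min_minor_allele_reads,
             min_snp_spacing_bp = min_snp_spacing_bp,
             min_gentrain = min_gentrain,
             min_call_frequency = min_call_frequency,
             min_maf = min_maf, max_het_excess = max_het_excess,
             min_call_rate = min_call_rate,
             max_missing_count = max_missing_count)
  props <- th[c("min_designability", "min_gentrain", "min_call_frequency",
                "min_maf", "max_het_excess", "min_call_rate")]
  if (any(unlist(props) < 0 | unlist(props) > 1))
    stop("proportion thresholds must lie in [0, 1]")
  cnts <- th[c("min_contig_reads", "min_contig_ests", "min_minor_allele_reads",
               "min_snp_spacing_bp", "max_missing_count")]
  if (any(unlist(cnts) < 0)) stop("count thresholds must be >= 0")
  structure(th, class = "qc_thresholds")
}

qc_report <- function(locus_id, first_fail) {
  fail <- !is.na(first_fail)
  counts <- table(first_fail[fail])
  structure(list(table = data.frame(locus_id = locus_id,
                                    pass = !fail,
                                    first_fail = ifelse(fail, first_fail, ""),
                                    stringsAsFactors = FALSE),
                 counts = counts,
                 retained = locus_id[!fail]),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d/%d loci retained\n",
              length(x$retained), nrow(x$table)))
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

#' Discovery-stage candidate filtering
#'
#' Applies the contig-level discovery criteria to annotated candidate SNPs.
#' A criterion whose annotation column is entirely absent (`NA`) is skipped
#' with a warning; per-locus `NA` under an applied criterion fails that
#' locus (no evidence, no pass). The spacing rule removes both members of a
#' too-close pair.
#'
#' @param loci a [locus_meta()] table of candidates
#' @param thresholds a [qc_thresholds()]
#' @return a `qc_report` (per-locus pass/fail with the first failing
#'   criterion named, per-criterion counts, retained locus ids)
#' @export
filter_candidates <- function(loci, thresholds = qc_thresholds()) {
  th <- thresholds
  n <- nrow(loci)
  first_fail <- rep(NA_character_, n)
  note <- function(bad, name) {
    first_fail[is.na(first_fail) & bad] <<- name
  }
  crit <- function(col, f, name) {
    v <- loci[[col]]
    if (all(is.na(v))) {
      warning("annotation '", col, "' absent: criterion ", name, " skipped")
      return()
    }
    note(is.na(v) | !f(v), name)
  }
  crit("designability", function(v) v > th$min_designability, "designability")
  crit("n_reads", function(v) v >= th$min_contig_reads, "contig_reads")
  crit("n_est", function(v) v >= th$min_contig_ests, "contig_ests")
  crit("minor_allele_reads", function(v) v >= th$min_minor_allele_reads,
       "minor_allele_reads")
  # spacing: both members of a pair closer than the minimum fail
  if (!all(is.na(loci$position_in_contig))) {
    too_close <- logical(n)
    for (cg in split(seq_len(n), loci$contig_id)) {
      pos <- loci$position_in_contig[cg]
      if (anyDuplicated(stats::na.omit(pos)))
        stop("two candidates at the same position in contig ",
             loci$contig_id[cg[1]])
      o <- order(pos)
      gaps <- diff(pos[o])
      close_pair <- which(gaps < th$min_snp_spacing_bp)
      hit <- unique(c(o[close_pair], o[close_pair + 1L]))
      too_close[cg[hit]] <- TRUE
    }
    note(too_close, "snp_spacing")
  } else {
    warning("annotation 'position_in_contig' absent: spacing criterion skipped")
  }
  qc_report(loci$locus_id, first_fail)
}

#' Panel-stage genotype-data filtering
#'
#' Per locus computes the call rate (non-missing fraction), MAF from observed
#' allele counts, the observed heterozygote fraction and the missing-call
#' count, then applies the panel criteria together with the platform scores
#' in `scores`. When no per-locus call-frequency score is supplied the call
#' rate is reused for that criterion and a warning is logged (the two are the
#' same statistic unless the platform reports them separately). A
#' monomorphic locus fails the MAF criterion; it is not an error.
#'
#' @param matrix a [genotype_matrix()]
#' @param scores optional [locus_meta()] carrying `gentrain` (and optionally
#'   a `call_frequency` column)
#' @param thresholds a [qc_thresholds()]
#' @return list with `report` (a `qc_report`) and `genotypes` (the matrix
#'   restricted to retained loci)
#' @export
filter_panel <- function(matrix, scores = NULL, thresholds = qc_thresholds()) {
  gm <- matrix
  th <- thresholds
  d <- gm$dosage
  if (nrow(d) == 0 || ncol(d) == 0) stop("empty genotype matrix")
  N <- nrow(d)
  n_typed <- colSums(!is.na(d))
  n_missing <- N - n_typed
  call_rate <- n_typed / N
  p_alt <- ifelse(n_typed > 0, colSums(d, na.rm = TRUE) / (2 * n_typed), NA)
  maf <- pmin(p_alt, 1 - p_alt)
  het <- ifelse(n_typed > 0, colSums(d == 1L, na.rm = TRUE) / n_typed, NA)
  first_fail <- rep(NA_character_, ncol(d))
  note <- function(bad, name) {
    bad[is.na(bad)] <- TRUE
    first_fail[is.na(first_fail) & bad] <<- name
  }
  gentrain <- NULL
  call_freq <- NULL
  if (!is.null(scores)) {
    i <- match(colnames(d), scores$locus_id)
    gentrain <- scores$gentrain[i]
    if (!is.null(scores$call_frequency)) call_freq <- scores$call_frequency[i]
  }
  if (!is.null(gentrain) && !all(is.na(gentrain))) {
    note(!(gentrain > th$min_gentrain), "gentrain")
  } else if (!is.null(scores)) {
    warning("gentrain scores absent: criterion skipped")
  }
  if (is.null(call_freq)) {
    warning("no per-locus call-frequency score supplied; reusing call rate")
    call_freq <- call_rate
  }
  note(!(call_freq > th$min_call_frequency), "call_frequency")
  note(!(call_rate > th$min_call_rate), "call_rate")
  note(!(maf > th$min_maf), "maf")
  note(!(het < th$max_het_excess), "het_excess")
  note(!(n_missing <= th$max_missing_count), "missing_count")
  rep <- qc_report(colnames(d), first_fail)
  list(report = rep, genotypes = gm[, rep$retained])
}
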