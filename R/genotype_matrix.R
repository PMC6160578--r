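#' Diploid genotype matrix
#'
#' The central container of the package: a samples x loci matrix of diploid
#' biallelic calls stored as unordered allele dosages. Per locus, the two
#' alleles are indexed ref/alt and a call is the number of copies of the alt
#' allele (0, 1 or 2), with `NA` marking a missing call. Heterozygote order is
#' therefore normalized by construction ("AB" and "BA" are the same dosage 1).
#'
#' @param dosage integer matrix (samples x loci) with values in {0, 1, 2, NA};
#'   rownames are sample ids, colnames are locus ids, both unique.
#' @param ref_allele,alt_allele character vectors of per-locus allele codes
#'   (single characters by convention, not enforced); `alt_allele` may be `NA`
#'   at loci observed monomorphic. Recycled if length 1.
#' @return An object of class `genotype_matrix`.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("L1", "L2")))
#' gm <- genotype_matrix(d, ref_allele = "A", alt_allele = "B")
#' n_samples(gm)
#' @export
genotype_matrix <- function(dosage, ref_allele = "A", alt_allele = "B") {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  storage.mode(dosage) <- "integer"
  if ((is.null(rownames(dosage)) && nrow(dosage) > 0) ||
      (is.null(colnames(dosage)) && ncol(dosage) > 0))
    stop("`dosage` must have sample ids as rownames and locus ids as colnames")
  L <- ncol(dosage)
  ref_allele <- rep_len(as.character(ref_allele), L)
  alt_allele <- rep_len(as.character(alt_allele), L)
  gm <- structure(list(dosage = dosage,
                       ref_allele = stats::setNames(ref_allele, colnames(dosage)),
                       alt_allele = stats::setNames(alt_allele, colnames(dosage))),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  d <- gm$dosage
  if (anyDuplicated(rownames(d))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(d))) stop("duplicated locus ids")
  bad <- !is.na(d) & !(d %in% 0:2)
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  same <- !is.na(gm$alt_allele) & gm$ref_allele == gm$alt_allele
  if (any(same))
    stop("ref and alt allele identical at locus ", names(which(same))[1])
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.2f%% missing)\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`
#' @export
n_samples <- function(gm) nrow(gm$dosage)

#' @rdname genotype_matrix
#' @export
n_loci <- function(gm) ncol(gm$dosage)

#' @rdname genotype_matrix
#' @export
sample_ids <- function(gm) rownames(gm$dosage)

#' @rdname genotype_matrix
#' @export
locus_ids <- function(gm) colnames(gm$dosage)

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`
#' @param i sample index (integer, logical or sample ids)
#' @param j locus index (integer, logical or locus ids)
#' @param ... ignored
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  d <- x$dosage[i, j, drop = FALSE]
  structure(list(dosage = d,
                 ref_allele = x$ref_allele[colnames(d)],
                 alt_allele = x$alt_allele[colnames(d)]),
            class = "genotype_matrix")
}

#' Render calls as two-character genotype strings
#'
#' Dosage 0 becomes e.g. "AA", 1 "AB" (alphabetical allele order within the
#' pair is not forced; ref allele is printed first), 2 "BB"; missing calls
#' become `missing_token`. Loci with an unknown alt allele print dosage-0
#' calls only; any other dosage there is an error.
#'
#' @param gm a `genotype_matrix`
#' @param missing_token string used for missing calls (default `"--"`)
#' @return character matrix with the same dimnames as the dosage matrix
#' @export
calls_as_strings <- function(gm, missing_token = "--") {
  d <- gm$dosage
  out <- matrix(missing_token, nrow(d), ncol(d), dimnames = dimnames(d))
  for (j in seq_len(ncol(d))) {
    a <- gm$ref_allele[j]; b <- gm$alt_allele[j]
    dj <- d[, j]
    if (is.na(b) && any(dj > 0, na.rm = TRUE))
      stop("locus ", colnames(d)[j], " has alt calls but no alt allele")
    g <- c(paste0(a, a), paste0(a, b), paste0(b, b))
    ok <- !is.na(dj)
    out[ok, j] <- g[dj[ok] + 1L]
  }
  out
}

#' Per-sample metadata table
#'
#' Builds and validates the sample annotation used for match interpretation
#' and group labels. Register numbers are collection-unique identifiers that
#' are never reused; the category separates cultivated accessions, wild
#' genotypes and cross progeny.
#'
#' @param sample_id unique sample identifiers
#' @param accession_name free-text accession name (may repeat: homonymy)
#' @param register_number unique register number per accession sample
#' @param category one of `"cultivar"`, `"wild"`, `"progeny"`
#' @param group_label free-text grouping (country, population, ...)
#' @return data.frame of class `sample_meta`
#' @export
sample_meta <- function(sample_id, accession_name = sample_id,
                        register_number = sample_id,
                        category = "cultivar", group_label = NA_character_) {
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicated sample ids in metadata")
  category <- rep_len(as.character(category), n)
  bad <- !category %in% c("cultivar", "wild", "progeny")
  if (any(bad)) stop("unknown category: ", category[which(bad)[1]])
  out <- data.frame(sample_id = as.character(sample_id),
                    accession_name = rep_len(as.character(accession_name), n),
                    register_number = rep_len(as.character(register_number), n),
                    category = category,
                    group_label = rep_len(as.character(group_label), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_meta", "data.frame")
  out
}

#' Per-locus annotation table
#'
#' Holds discovery-stage annotations (contig, position, read support) and
#' platform genotyping scores (designability, GenTrain). Scores absent for a
#' locus are `NA`; the QC filters skip criteria whose annotation is missing.
#'
#' @param locus_id unique locus identifiers
#' @param contig_id contig of origin
#' @param position_in_contig 1-based position within the contig
#' @param ref_allele,alt_allele single-character alleles, distinct
#' @param designability,gentrain platform scores in \[0, 1\] or `NA`
#' @param n_reads,n_est,minor_allele_reads read-support counts or `NA`
#' @return data.frame of class `locus_meta`
#' @export
locus_meta <- function(locus_id, contig_id = NA_character_,
                       position_in_contig = NA_integer_,
                       ref_allele = "A", alt_allele = "B",
                       designability = NA_real_, gentrain = NA_real_,
                       n_reads = NA_integer_, n_est = NA_integer_,
                       minor_allele_reads = NA_integer_) {
  n <- length(locus_id)
  if (anyDuplicated(locus_id)) stop("duplicated locus ids")
  out <- data.frame(locus_id = as.character(locus_id),
                    contig_id = rep_len(as.character(contig_id), n),
                    position_in_contig = rep_len(as.integer(position_in_contig), n),
                    ref_allele = rep_len(as.character(ref_allele), n),
                    alt_allele = rep_len(as.character(alt_allele), n),
                    designability = rep_len(as.numeric(designability), n),
                    gentrain = rep_len(as.numeric(gentrain), n),
                    n_reads = rep_len(as.integer(n_reads), n),
                    n_est = rep_len(as.integer(n_est), n),
                    minor_allele_reads = rep_len(as.integer(minor_allele_reads), n),
                    stringsAsFactors = FALSE)
  if (any(!is.na(out$position_in_contig) & out$position_in_contig < 1))
    stop("position_in_contig must be >= 1")
  same <- !is.na(out$alt_allele) & out$ref_allele == out$alt_allele
  if (any(same)) stop("ref and alt allele identical at locus ",
                      out$locus_id[which(same)[1]])
  class(out) <- c("locus_meta", "data.frame")
  out
}
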