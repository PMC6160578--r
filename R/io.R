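#' Read a delimited genotype table
#'
#' Expected layout: a header row of locus ids, then one row per sample with
#' the sample id in the first column. Calls are two-character strings
#' (`"AA"`, `"AB"`) or slash pairs (`"A/B"`); heterozygote order is
#' normalized at parse time. Allele sets are inferred per locus; in the
#' default biallelic mode, a locus with more than two observed alleles is a
#' validation error. The ref allele of each locus is the alphabetically
#' first observed allele (a deterministic convention, not a statement about
#' ancestral state).
#'
#' @param path path to the delimited text file
#' @param sep field separator (default tab)
#' @param missing_token token marking a missing call (default `"--"`)
#' @param multiallelic if `TRUE`, return a `genotype_calls` character matrix
#'   of normalized `"A/B"` pairs instead of a biallelic `genotype_matrix`
#' @return a list with `genotypes` (a [genotype_matrix()] or, in
#'   multi-allelic mode, a `genotype_calls` matrix) and `meta`
#'   (a [sample_meta()] with default annotations)
#' @export
read_genotype_table <- function(path, sep = "\t", missing_token = "--",
                                multiallelic = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("genotype table needs a header and >=1 sample row")
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]
  loci <- header[-1]
  nf <- lengths(fields[-1])
  bad <- which(nf != length(header))
  if (length(bad))
    stop(sprintf("parse error at row %d: %d fields, expected %d",
                 bad[1] + 1L, nf[bad[1]], length(header)))
  samples <- vapply(fields[-1], `[`, "", 1L)
  if (anyDuplicated(samples)) stop("duplicated sample ids in table")
  raw <- do.call(rbind, lapply(fields[-1], function(f) f[-1]))
  dimnames(raw) <- list(samples, loci)
  pairs <- normalize_call_strings(raw, missing_token)
  if (multiallelic) {
    return(list(genotypes = structure(pairs, class = c("genotype_calls", class(pairs))),
                meta = sample_meta(samples)))
  }
  dos <- matrix(NA_integer_, nrow(pairs), ncol(pairs), dimnames = dimnames(pairs))
  ref <- alt <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    al <- sort(unique(unlist(strsplit(pairs[!is.na(pairs[, j]), j], "/", fixed = TRUE))))
    if (length(al) > 2)
      stop("validation error: locus ", loci[j], " has ", length(al),
           " alleles in biallelic mode")
    ref[j] <- if (length(al)) al[1] else "A"
    alt[j] <- if (length(al) == 2) al[2] else NA_character_
    dos[, j] <- pair_to_dosage(pairs[, j], ref[j], alt[j], samples, loci[j])
  }
  list(genotypes = genotype_matrix(dos, ref, alt), meta = sample_meta(samples))
}

# "AA" / "A/B" / missing -> normalized "A/B" (sorted) or NA
normalize_call_strings <- function(raw, missing_token) {
  out <- matrix(NA_character_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  idx <- which(raw != missing_token)
  val <- raw[idx]
  has_slash <- grepl("/", val, fixed = TRUE)
  al1 <- ifelse(has_slash, sub("/.*", "", val), substr(val, 1, 1))
  al2 <- ifelse(has_slash, sub(".*/", "", val), substr(val, 2, 2))
  badlen <- !has_slash & nchar(val) != 2
  if (any(badlen)) {
    k <- idx[which(badlen)[1]]
    stop("validation error: malformed call '", raw[k], "' for sample ",
         rownames(raw)[row(raw)[k]], " at locus ", colnames(raw)[col(raw)[k]])
  }
  lo <- pmin(al1, al2); hi <- pmax(al1, al2)
  out[idx] <- paste(lo, hi, sep = "/")
  out
}

pair_to_dosage <- function(pair, ref, alt, samples, locus) {
  d <- rep(NA_integer_, length(pair))
  ok <- !is.na(pair)
  hom_ref <- paste(ref, ref, sep = "/")
  if (!is.na(alt)) {
    het <- paste(sort(c(ref, alt)), collapse = "/")
    hom_alt <- paste(alt, alt, sep = "/")
    d[ok] <- match(pair[ok], c(hom_ref, het, hom_alt)) - 1L
  } else {
    d[ok] <- ifelse(pair[ok] == hom_ref, 0L, NA_integer_)
    if (anyNA(d[ok])) {
      k <- which(ok & is.na(d))[1]
      stop("validation error: unknown allele token '", pair[k],
           "' for sample ", samples[k], " at locus ", locus)
    }
  }
  if (anyNA(d[ok])) {
    k <- which(ok & is.na(d))[1]
    stop("validation error: unknown allele token '", pair[k],
         "' for sample ", samples[k], " at locus ", locus)
  }
  d
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]; byte-deterministic for a given matrix
#' (stable sample and locus order, fixed column order).
#'
#' @inheritParams calls_as_strings
#' @param path output path
#' @param sep field separator
#' @export
write_genotype_table <- function(gm, path, sep = "\t", missing_token = "--") {
  s <- calls_as_strings(gm, missing_token)
  hdr <- paste(c("sample_id", colnames(s)), collapse = sep)
  rows <- paste(rownames(s), apply(s, 1, paste, collapse = sep), sep = sep)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Import a VCF as a genotype matrix
#'
#' Reads diploid GT fields from a VCF (via the VariantAnnotation parser).
#' Only biallelic SNP records are imported; multi-allelic records and records
#' with non-diploid GT strings are skipped and counted. `"./."` (or `".|."`)
#' maps to a missing call.
#'
#' @param path path to a VCF file (plain or bgzipped)
#' @return list with `genotypes` ([genotype_matrix()]), `loci`
#'   ([locus_meta()]), and skip counts `n_skipped_multiallelic`,
#'   `n_skipped_nondiploid`
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf() requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  if (!"GT" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
    stop("VCF has no GT genotype field")
  gt <- VariantAnnotation::geno(vcf)$GT
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt != 1L
  gt1 <- gt[!multi, , drop = FALSE]
  parse_one <- function(x) {
    # returns dosage or NA; non-diploid flagged as -9
    out <- rep(NA_integer_, length(x))
    x <- gsub("|", "/", x, fixed = TRUE)
    known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
    miss <- x %in% c("./.", ".")
    hit <- match(x, names(known))
    out[!is.na(hit)] <- known[hit[!is.na(hit)]]
    out[is.na(hit) & !miss] <- -9L
    out
  }
  dos <- apply(gt1, 2, parse_one)
  dos <- matrix(as.integer(dos), nrow = nrow(gt1),
                dimnames = list(rownames(gt1), colnames(gt1)))
  nondip <- apply(dos, 1, function(r) any(r == -9L, na.rm = TRUE))
  dos <- dos[!nondip, , drop = FALSE]
  kept <- rownames(dos)
  idx <- which(!multi)[!nondip]
  rr <- SummarizedExperiment::rowRanges(vcf)[idx]
  ref <- as.character(VariantAnnotation::ref(vcf)[idx])
  altc <- vapply(methods::as(alt[idx], "CharacterList"), `[`, "", 1L)
  lm <- locus_meta(locus_id = kept,
                   contig_id = as.character(GenomicRanges::seqnames(rr)),
                   position_in_contig = GenomicRanges::start(rr),
                   ref_allele = ref, alt_allele = altc)
  gm <- genotype_matrix(t(dos), ref_allele = ref, alt_allele = altc)
  list(genotypes = gm, loci = lm,
       n_skipped_multiallelic = sum(multi),
       n_skipped_nondiploid = sum(nondip))
}

#' Export a genotype matrix as a minimal VCF
#'
#' Writes a deterministic VCF v4.2 text file with GT fields only. Loci whose
#' alt allele is unknown (observed monomorphic) are written with alt `"."`.
#'
#' @param gm a [genotype_matrix()]
#' @param path output path
#' @param loci optional [locus_meta()] supplying contig/position; defaults to
#'   a synthetic single-contig layout
#' @export
write_vcf <- function(gm, path, loci = NULL) {
  lid <- locus_ids(gm)
  if (is.null(loci)) {
    contig <- rep("chrUn", length(lid)); pos <- seq_along(lid)
  } else {
    i <- match(lid, loci$locus_id)
    contig <- loci$contig_id[i]; pos <- loci$position_in_contig[i]
  }
  gtmap <- c("0/0", "0/1", "1/1")
  d <- gm$dosage
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_ids(gm)), collapse = "\t"))
  rows <- vapply(seq_along(lid), function(j) {
    g <- ifelse(is.na(d[, j]), "./.", gtmap[d[, j] + 1L])
    alt <- gm$alt_allele[j]
    paste(c(contig[j], pos[j], lid[j], gm$ref_allele[j],
            ifelse(is.na(alt), ".", alt), ".", "PASS", ".", "GT", g),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write analysis reports to a directory
#'
#' Serializes any combination of pipeline results as deterministic TSV files
#' (stable column order, rows sorted by id) plus newick for trees. Re-running
#' on identical input yields byte-identical files.
#'
#' @param results named list; recognized elements: `pairs`
#'   (pair_distances), `gap` (gap_result), `redundancy` (redundancy_report),
#'   `flags` (match report), `locus_stats` (data.frame), `summary`
#'   (diversity summary), `amova` (amova_result), `tree` (phylo)
#' @param out_dir output directory, created if absent
#' @return invisibly, the paths written
#' @export
write_reports <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  wrote <- character()
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    wrote <<- c(wrote, p)
  }
  if (!is.null(results$pairs)) tsv(as.data.frame(results$pairs), "pairs.tsv")
  if (!is.null(results$gap)) {
    g <- results$gap
    tsv(data.frame(distance = as.integer(names(g$histogram)),
                   n_pairs = as.integer(g$histogram)), "histogram.tsv")
    tsv(data.frame(intra_threshold = g$intra_threshold,
                   gap_low = g$gap_interval[1], gap_high = g$gap_interval[2],
                   is_bimodal = g$is_bimodal), "gap.tsv")
  }
  if (!is.null(results$redundancy)) {
    r <- results$redundancy
    memb <- do.call(rbind, lapply(seq_along(r$groups), function(i) {
      g <- r$groups[[i]]
      data.frame(group_id = g$group_id, sample_id = sort(g$members),
                 max_within_distance = g$max_within_distance)
    }))
    if (is.null(memb))
      memb <- data.frame(group_id = integer(), sample_id = character(),
                         max_within_distance = integer())
    tsv(memb, "groups.tsv")
    tsv(data.frame(sample_id = sort(r$unique_genotypes)), "unique_genotypes.tsv")
  }
  if (!is.null(results$flags)) {
    tsv(results$flags$group_table, "flags.tsv")
    tsv(results$flags$homonymy, "homonymy.tsv")
  }
  if (!is.null(results$locus_stats)) {
    df <- as.data.frame(results$locus_stats)
    tsv(df[order(df$locus_id), ], "locus_stats.tsv")
  }
  if (!is.null(results$summary)) tsv(as.data.frame(results$summary), "diversity_summary.tsv")
  if (!is.null(results$amova)) tsv(variance_partition_report(results$amova), "amova.tsv")
  if (!is.null(results$tree)) {
    p <- file.path(out_dir, "tree.nwk")
    write_newick(results$tree, p)
    wrote <- c(wrote, p)
  }
  invisible(wrote)
}
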