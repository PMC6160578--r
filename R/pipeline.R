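#' Run configuration for the full pipeline
#'
#' Exactly one of `genotypes_path` (with optional `meta_path`) or `spec`
#' (a [cohort_spec()]) must be supplied: the pipeline either loads genotypes
#' or simulates a cohort.
#'
#' @param genotypes_path optional genotype table (TSV) or VCF path
#' @param meta_path optional sample metadata TSV (columns of
#'   [sample_meta()])
#' @param spec optional [cohort_spec()] to simulate instead of loading
#' @param thresholds [qc_thresholds()] for the panel filter
#' @param min_gap_width,fallback_threshold gap-detection parameters, see
#'   [distance_histogram()]
#' @param n_perm AMOVA permutations
#' @param n_boot bootstrap replicates for the NJ tree (0 disables the tree
#'   stage)
#' @param seed global seed; recorded in the run manifest
#' @param out_dir output directory
#' @return list of class `run_config`
#' @export
run_config <- function(genotypes_path = NULL, meta_path = NULL, spec = NULL,
                       thresholds = qc_thresholds(), min_gap_width = 50,
                       fallback_threshold = 10, n_perm = 999, n_boot = 100,
                       seed = 1L, out_dir = "ggkit_out") {
  if (is.null(genotypes_path) == is.null(spec))
    stop("exactly one of genotypes_path or spec must be set")
  structure(list(genotypes_path = genotypes_path, meta_path = meta_path,
                 spec = spec, thresholds = thresholds,
                 min_gap_width = min_gap_width,
                 fallback_threshold = fallback_threshold,
                 n_perm = n_perm, n_boot = n_boot, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration file
#'
#' Accepts JSON (keys matching the [run_config()] arguments; a `spec`
#' sub-object maps to [cohort_spec()], a `thresholds` sub-object to
#' [qc_thresholds()]) or a flat `key = value` text file for the scalar
#' options.
#'
#' @param path configuration file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  txt <- readLines(path)
  args <- if (grepl("^\\s*\\{", txt[1])) {
    x <- jsonlite::fromJSON(paste(txt, collapse = "\n"), simplifyVector = TRUE)
    if (!is.null(x$spec)) x$spec <- do.call(cohort_spec, as.list(x$spec))
    if (!is.null(x$thresholds))
      x$thresholds <- do.call(qc_thresholds, as.list(x$thresholds))
    x
  } else {
    kv <- txt[grepl("=", txt, fixed = TRUE)]
    keys <- trimws(sub("=.*", "", kv))
    vals <- trimws(sub("^[^=]*=", "", kv))
    lapply(stats::setNames(vals, keys),
           function(v) utils::type.convert(v, as.is = TRUE))
  }
  do.call(run_config, args)
}

stage <- function(name, expr) {
  message("[ggkit] stage: ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load or simulate genotypes, panel QC, pairwise
#' identity matching with gap detection and redundancy grouping on the
#' cultivated samples, per-locus diversity statistics on unique cultivated
#' genotypes (and wilds when present), one-way AMOVA of wild versus
#' cultivated samples, and a bootstrapped NJ tree over unique genotypes,
#' wilds and progeny. All reports are written to `config$out_dir` together
#' with a JSON run manifest (package version, seed, input digests). Rerun
#' with an identical config reproduces identical outputs.
#'
#' @param config a [run_config()]
#' @return invisible list with all stage results
#' @export
run_pipeline <- function(config) {
  cfg <- config
  sim <- NULL
  if (!is.null(cfg$spec)) {
    sim <- stage("simulate", simulate_cohort(cfg$spec))
    gm <- sim$genotypes; meta <- sim$meta
  } else {
    loaded <- stage("load", {
      if (grepl("\\.vcf(\\.gz)?$", cfg$genotypes_path))
        read_vcf(cfg$genotypes_path)
      else read_genotype_table(cfg$genotypes_path)
    })
    gm <- loaded$genotypes
    meta <- if (!is.null(cfg$meta_path)) {
      df <- utils::read.delim(cfg$meta_path, stringsAsFactors = FALSE)
      do.call(sample_meta, df[intersect(names(df), names(formals(sample_meta)))])
    } else loaded$meta
    if (is.null(meta)) meta <- sample_meta(sample_ids(gm))
  }
  if (!all(sample_ids(gm) %in% meta$sample_id))
    stop("inconsistent sample ids between genotypes and metadata")
  qc <- stage("qc", filter_panel(gm, thresholds = cfg$thresholds))
  gm <- qc$genotypes
  cult_ids <- meta$sample_id[meta$category == "cultivar"]
  cult_ids <- intersect(sample_ids(gm), cult_ids)
  id_set <- if (length(cult_ids) >= 2) cult_ids else sample_ids(gm)
  ident <- stage("identity", {
    pairs <- pairwise_distances(gm[id_set, ])
    gap <- distance_histogram(pairs, cfg$min_gap_width, cfg$fallback_threshold)
    red <- redundancy_groups(pairs, gap$intra_threshold)
    flags <- match_report(red, meta)
    message(sprintf("[ggkit]   %d pairs, threshold %d, %d groups",
                    nrow(pairs), gap$intra_threshold, length(red$groups)))
    list(pairs = pairs, gap = gap, redundancy = red, flags = flags)
  })
  reps <- c(vapply(ident$redundancy$groups,
                   function(g) sort(g$members)[1], ""),
            ident$redundancy$unique_genotypes)
  div <- stage("diversity", {
    st <- locus_statistics(gm, subset = reps)
    list(locus_stats = st, summary = summarize_diversity(st))
  })
  am <- NULL
  wild_ids <- intersect(sample_ids(gm), meta$sample_id[meta$category == "wild"])
  if (length(wild_ids) >= 2 && length(reps) >= 2) {
    am <- stage("amova", {
      sub <- c(reps, wild_ids)
      labels <- stats::setNames(ifelse(sub %in% wild_ids, "wild", "cultivated"), sub)
      amova_one_way(pairwise_distances(gm[sub, ]), labels,
                    n_perm = cfg$n_perm, seed = cfg$seed)
    })
  }
  tree <- NULL
  if (cfg$n_boot > 0) {
    tree <- stage("tree", {
      prog_ids <- intersect(sample_ids(gm),
                            meta$sample_id[meta$category == "progeny"])
      bootstrap_support(gm[c(reps, wild_ids, prog_ids), ],
                        n_reps = cfg$n_boot, seed = cfg$seed)
    })
  }
  results <- list(pairs = ident$pairs, gap = ident$gap,
                  redundancy = ident$redundancy, flags = ident$flags,
                  locus_stats = div$locus_stats, summary = div$summary,
                  amova = am, tree = tree)
  paths <- stage("write", write_reports(results, cfg$out_dir))
  manifest <- list(package = "ggkit",
                   version = as.character(utils::packageVersion("ggkit")),
                   seed = cfg$seed,
                   n_samples = n_samples(gm), n_loci = n_loci(gm),
                   qc_retained = length(qc$report$retained),
                   input_digests = if (!is.null(cfg$genotypes_path))
                     as.list(tools::md5sum(cfg$genotypes_path)) else
                       list(simulated = cfg$spec$seed),
                   output_digests = as.list(tools::md5sum(sort(paths))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(qc = qc$report, manifest = manifest, meta = meta)))
}
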