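#' Pairwise multilocus allele-difference distances
#'
#' For every unordered sample pair, counts the number of allele differences
#' summed over the loci at which both calls are non-missing. Per locus the
#' contribution is the multiset mismatch of the two diploid genotypes:
#' AA vs AA -> 0, AA vs AB -> 1, AA vs BB -> 2, AB vs AB -> 0 (equivalently
#' `|dosage_i - dosage_j|` for biallelic loci). A pair with zero comparable
#' loci has an undefined (`NA`) distance.
#'
#' @param matrix a [genotype_matrix()] with at least 2 samples
#' @return object of class `pair_distances`: a data.frame with columns
#'   `sample_i`, `sample_j`, `n_loci_compared`, `n_allele_diff`,
#'   `normalized_diff` (`n_allele_diff / (2 * n_loci_compared)`), plus
#'   attributes `diff_matrix` and `shared_matrix` (full symmetric forms)
#' @export
pairwise_distances <- function(matrix) {
  gm <- matrix
  G <- gm$dosage
  N <- nrow(G)
  if (N < 2) stop("need at least 2 samples")
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0L
  storage.mode(G0) <- "double"
  ids <- rownames(G)
  D <- base::matrix(0, N, N, dimnames = list(ids, ids))
  S <- base::matrix(0, N, N, dimnames = list(ids, ids))
  for (i in seq_len(N - 1)) {
    rest <- (i + 1):N
    Mi <- M[rest, , drop = FALSE] & base::matrix(M[i, ], length(rest),
                                                 ncol(G), byrow = TRUE)
    diff <- abs(G0[rest, , drop = FALSE] -
                  base::matrix(G0[i, ], length(rest), ncol(G), byrow = TRUE))
    d <- rowSums(diff * Mi)
    s <- rowSums(Mi)
    D[i, rest] <- d; D[rest, i] <- d
    S[i, rest] <- s; S[rest, i] <- s
  }
  ut <- upper.tri(D)
  ii <- row(D)[ut]; jj <- col(D)[ut]
  n_shared <- S[ut]
  ndiff <- D[ut]
  ndiff[n_shared == 0] <- NA
  out <- data.frame(sample_i = ids[ii], sample_j = ids[jj],
                    n_loci_compared = as.integer(n_shared),
                    n_allele_diff = as.integer(ndiff),
                    normalized_diff = ifelse(n_shared > 0, ndiff / (2 * n_shared), NA),
                    stringsAsFactors = FALSE)
  D[S == 0 & row(D) != col(D)] <- NA
  attr(out, "diff_matrix") <- D
  attr(out, "shared_matrix") <- S
  class(out) <- c("pair_distances", "data.frame")
  out
}

#' Distance histogram and intra/inter-cultivar gap detection
#'
#' Bins the integer allele-difference distances and looks for the gap that
#' separates clonal (intra-cultivar) from inter-cultivar variation: the
#' longest maximal run of consecutive empty integer distances, provided it
#' is at least `min_gap_width` wide. When such a gap exists the duplicate
#' threshold is set just below it (`gap low - 1`, i.e. the largest observed
#' distance on the clonal side); otherwise `is_bimodal` is `FALSE` and the
#' threshold falls back to `fallback_threshold`.
#'
#' @param pairs a [pairwise_distances()] result
#' @param min_gap_width minimal width of an empty run to count as the gap
#'   (default 50; the observed intra/inter gap in large collections is far
#'   wider, the guard avoids spurious micro-gaps in small cohorts)
#' @param fallback_threshold threshold used when no qualifying gap exists
#' @return object of class `gap_result`: list with `histogram` (named
#'   table), `intra_threshold`, `gap_interval` (`c(low, high)` or `NA`),
#'   `is_bimodal`
#' @export
distance_histogram <- function(pairs, min_gap_width = 50,
                               fallback_threshold = 10) {
  d <- pairs$n_allele_diff
  d <- d[!is.na(d)]
  if (!length(d)) stop("no defined pairwise distances")
  hist <- table(d)
  obs <- sort(unique(d))
  gap_interval <- c(NA_integer_, NA_integer_)
  is_bimodal <- FALSE
  intra_threshold <- fallback_threshold
  if (length(obs) > 1) {
    runs <- data.frame(low = obs[-length(obs)] + 1L, high = obs[-1] - 1L)
    runs$width <- runs$high - runs$low + 1L
    runs <- runs[runs$width >= min_gap_width, , drop = FALSE]
    if (nrow(runs)) {
      best <- runs[which.max(runs$width), ]
      gap_interval <- c(best$low, best$high)
      intra_threshold <- best$low - 1L
      is_bimodal <- TRUE
    }
  }
  structure(list(histogram = hist, intra_threshold = as.integer(intra_threshold),
                 gap_interval = as.integer(gap_interval),
                 is_bimodal = is_bimodal),
            class = "gap_result")
}

#' @export
print.gap_result <- function(x, ...) {
  if (x$is_bimodal)
    cat(sprintf("gap_result: bimodal, gap [%d, %d], intra threshold %d\n",
                x$gap_interval[1], x$gap_interval[2], x$intra_threshold))
  else
    cat(sprintf("gap_result: no qualifying gap, fallback threshold %d\n",
                x$intra_threshold))
  invisible(x)
}

#' Redundancy-group detection
#'
#' Builds a graph with an edge for every sample pair at distance at most
#' `threshold`; redundancy groups are the connected components of size 2 or
#' more (so a chain of somatic variants joins its cultivar's group even if
#' the two ends differ by more than the threshold). Samples in no component
#' are unique genotypes. Edges at distance 1 or more (putative somatic
#' variants) are listed separately as `near_match_edges`. Pairs with
#' undefined distances are treated as non-edges.
#'
#' @param pairs a [pairwise_distances()] result
#' @param threshold maximal within-group allele difference (>= 0), typically
#'   the `intra_threshold` of [distance_histogram()]
#' @return object of class `redundancy_report`: list with `groups` (each a
#'   list `group_id`, `members`, `max_within_distance`), `unique_genotypes`,
#'   `near_match_edges` (data.frame), `threshold`
#' @export
redundancy_groups <- function(pairs, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  ids <- sort(unique(c(pairs$sample_i, pairs$sample_j)))
  keep <- !is.na(pairs$n_allele_diff) & pairs$n_allele_diff <= threshold
  edges <- pairs[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("sample_i", "sample_j")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  memb <- comp$membership
  D <- attr(pairs, "diff_matrix")
  groups <- list()
  gid <- 0L
  for (k in seq_len(comp$no)) {
    members <- names(memb)[memb == k]
    if (length(members) < 2) next
    gid <- gid + 1L
    maxd <- max(D[members, members], na.rm = TRUE)
    groups[[gid]] <- list(group_id = gid, members = members,
                          max_within_distance = as.integer(maxd))
  }
  grouped <- unlist(lapply(groups, `[[`, "members"))
  near <- edges[edges$n_allele_diff >= 1, , drop = FALSE]
  rownames(near) <- NULL
  structure(list(groups = groups,
                 unique_genotypes = setdiff(ids, grouped),
                 near_match_edges = near,
                 threshold = as.integer(threshold)),
            class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf(
    "redundancy_report: %d groups (%d samples), %d unique genotypes, threshold %d\n",
    length(x$groups), length(unlist(lapply(x$groups, `[[`, "members"))),
    length(x$unique_genotypes), x$threshold))
  invisible(x)
}

#' Interpret redundancy groups against sample metadata
#'
#' Labels each redundancy group using accession names and register numbers:
#' `synonymy-candidate` when members carry different accession names,
#' `replicate-confirmation` when all members share one name under different
#' register numbers, with an additional `mutant-variant` flag when the group
#' contains near-match edges (distance >= 1). Homonymy candidates - the same
#' accession name appearing in different components (groups or unique
#' genotypes) - are reported separately. Groups whose members lack metadata
#' are labeled `unannotated`.
#'
#' @param report a [redundancy_groups()] result
#' @param meta a [sample_meta()] table
#' @return list with `group_table` (one row per group: label, members,
#'   names, max distance, mutant flag) and `homonymy` (one row per flagged
#'   accession name)
#' @export
match_report <- function(report, meta) {
  nm <- stats::setNames(meta$accession_name, meta$sample_id)
  reg <- stats::setNames(meta$register_number, meta$sample_id)
  near_pairs <- unique(c(report$near_match_edges$sample_i,
                         report$near_match_edges$sample_j))
  rows <- lapply(report$groups, function(g) {
    names_g <- nm[g$members]
    if (anyNA(names_g)) {
      label <- "unannotated"
    } else if (length(unique(names_g)) > 1) {
      label <- "synonymy-candidate"
    } else if (length(unique(reg[g$members])) > 1) {
      label <- "replicate-confirmation"
    } else {
      label <- "replicate-confirmation"
    }
    data.frame(group_id = g$group_id, n_members = length(g$members),
               label = label,
               mutant_variant = any(g$members %in% near_pairs),
               max_within_distance = g$max_within_distance,
               members = paste(sort(g$members), collapse = ","),
               accession_names = paste(sort(unique(names_g)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  group_table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_id = integer(), n_members = integer(), label = character(),
               mutant_variant = logical(), max_within_distance = integer(),
               members = character(), accession_names = character())
  # homonymy: same accession name in different components
  comp_of <- stats::setNames(rep(seq_along(report$groups),
                                 vapply(report$groups, function(g) length(g$members), 0L)),
                             unlist(lapply(report$groups, `[[`, "members")))
  uni <- report$unique_genotypes
  comp_of <- c(comp_of, stats::setNames(length(report$groups) + seq_along(uni), uni))
  known <- names(comp_of)[names(comp_of) %in% meta$sample_id]
  by_name <- split(comp_of[known], nm[known])
  flagged <- names(by_name)[vapply(by_name, function(v) length(unique(v)) > 1, NA)]
  homonymy <- data.frame(accession_name = sort(flagged),
                         n_components = vapply(sort(flagged),
                                               function(a) length(unique(by_name[[a]])), 0L),
                         stringsAsFactors = FALSE)
  rownames(homonymy) <- NULL
  list(group_table = group_table, homonymy = homonymy)
}
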