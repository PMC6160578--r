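#' Neighbor-joining tree construction
#'
#' Saitou-Nei agglomeration with the Studier-Keppler criterion
#' `Q_ij = (r - 2) d_ij - R_i - R_j`. Ties in the Q minimization are broken
#' deterministically by the smallest (i, j) index pair in creation order, so
#' equidistant inputs always give the same tree. Negative branch lengths are
#' clamped to 0 and the total clamped deficit is recorded in the
#' `"clamped_deficit"` attribute. On additive input the generating topology
#' and branch lengths are recovered exactly.
#'
#' @param distance_matrix symmetric numeric matrix with zero diagonal and
#'   sample ids as dimnames; `NA`/`NaN` entries are an error
#' @return an [ape][ape::read.tree] `phylo` tree (unrooted, stored with a
#'   trifurcating root node)
#' @export
nj_build <- function(distance_matrix) {
  D <- distance_matrix
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (anyNA(D)) stop("distance matrix contains NA/NaN entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  N <- nrow(D)
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(N))
  if (N < 2) stop("need at least 2 samples")
  if (N == 2) {
    warning("only 2 samples: returning the trivial two-tip tree")
    tr <- structure(list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                         edge.length = rep(D[1, 2] / 2, 2),
                         tip.label = labels, Nnode = 1L),
                    class = "phylo")
    return(tr)
  }
  active <- seq_len(N)          # provisional node ids, creation order
  next_id <- N + 1L
  parent <- integer(); child <- integer(); elen <- numeric()
  clamp_deficit <- 0
  clamp <- function(x) {
    if (x < 0) { clamp_deficit <<- clamp_deficit + (-x); 0 } else x
  }
  W <- D
  while (length(active) > 3) {
    r <- length(active)
    R <- rowSums(W)
    Q <- (r - 2) * W - outer(R, R, `+`)
    diag(Q) <- Inf
    mq <- min(Q)
    cand <- which(Q <= mq, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    dij <- W[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    parent <- c(parent, next_id, next_id)
    child <- c(child, active[i], active[j])
    elen <- c(elen, clamp(li), clamp(lj))
    dnew <- (W[i, -c(i, j)] + W[j, -c(i, j)] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    W <- rbind(cbind(W[keep, keep, drop = FALSE], dnew),
               c(dnew, 0))
    active <- c(active[keep], next_id)
    next_id <- next_id + 1L
  }
  # final three nodes join at the root (three-point formulas)
  dab <- W[1, 2]; dac <- W[1, 3]; dbc <- W[2, 3]
  root <- next_id
  parent <- c(parent, root, root, root)
  child <- c(child, active[1], active[2], active[3])
  elen <- c(elen, clamp((dab + dac - dbc) / 2),
            clamp((dab + dbc - dac) / 2),
            clamp((dac + dbc - dab) / 2))
  # renumber internals to ape convention: root = N + 1, then BFS order
  new_id <- integer(root)
  new_id[seq_len(N)] <- seq_len(N)
  kids <- split(child, parent)
  queue <- root; nxt <- N + 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    new_id[v] <- nxt; nxt <- nxt + 1L
    ch <- kids[[as.character(v)]]
    queue <- c(queue, ch[ch > N])
  }
  tr <- structure(list(edge = cbind(new_id[parent], new_id[child]),
                       edge.length = elen, tip.label = labels,
                       Nnode = N - 2L),
                  class = "phylo")
  attr(tr, "clamped_deficit") <- clamp_deficit
  tr
}

# per-edge leaf bipartitions, canonicalized (side not containing tip 1),
# keyed by sorted tip labels; only internal (non-root) nodes have one
tree_splits <- function(tr) {
  N <- length(tr$tip.label)
  root <- N + 1L
  internal <- setdiff(unique(tr$edge[, 1]), root)
  desc <- function(node) {
    tips <- character(0); stack <- node
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      ch <- tr$edge[tr$edge[, 1] == v, 2]
      tips <- c(tips, tr$tip.label[ch[ch <= N]])
      stack <- c(stack, ch[ch > N])
    }
    tips
  }
  out <- lapply(internal, function(v) {
    side <- desc(v)
    if (tr$tip.label[1] %in% side) side <- setdiff(tr$tip.label, side)
    paste(sort(side), collapse = "\r")
  })
  stats::setNames(unlist(out), internal)
}

# distance matrices straight from a dosage matrix; used by the bootstrap
# so that resampled (duplicated) locus sets bypass matrix validation
dist_from_dosage <- function(G, normalized = TRUE) {
  N <- nrow(G)
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0L
  storage.mode(G0) <- "double"
  D <- matrix(0, N, N, dimnames = list(rownames(G), rownames(G)))
  S <- matrix(0, N, N)
  for (i in seq_len(N - 1)) {
    rest <- (i + 1):N
    Mi <- M[rest, , drop = FALSE] & matrix(M[i, ], length(rest), ncol(G),
                                           byrow = TRUE)
    diff <- abs(G0[rest, , drop = FALSE] -
                  matrix(G0[i, ], length(rest), ncol(G), byrow = TRUE))
    d <- rowSums(diff * Mi); s <- rowSums(Mi)
    D[i, rest] <- d; D[rest, i] <- d
    S[i, rest] <- s; S[rest, i] <- s
  }
  if (normalized) {
    out <- D / (2 * S)
    diag(out) <- 0
    list(D = out, S = S)
  } else list(D = D, S = S)
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Builds the NJ tree from the full data, then resamples loci with
#' replacement `n_reps` times, recomputes pairwise distances and the NJ tree
#' for each replicate, and attaches to every internal edge of the main tree
#' the percentage of replicates containing the same leaf bipartition
#' (integer percentages as node labels). By default distances are normalized
#' allele-difference proportions so replicates with missing data remain
#' comparable; `normalized = FALSE` uses raw counts. A replicate in which
#' some sample pair has no comparable loci is discarded and counted.
#'
#' @param matrix a [genotype_matrix()]
#' @param n_reps number of bootstrap replicates (>= 1; 500 is conventional)
#' @param seed optional integer seed
#' @param normalized use per-allele proportions (default) or raw counts
#' @return the main `phylo` tree with `node.label` holding supports (root
#'   label empty) and attributes `n_reps_used`, `n_discarded`
#' @export
bootstrap_support <- function(matrix, n_reps = 500, seed = NULL,
                              normalized = TRUE) {
  gm <- matrix
  if (n_reps < 1) stop("n_reps must be >= 1")
  G <- gm$dosage
  full <- dist_from_dosage(G, normalized)
  if (anyNA(full$D)) stop("some sample pair shares no typed loci")
  main <- nj_build(full$D)
  main_splits <- tree_splits(main)
  counts <- stats::setNames(numeric(length(main_splits)), main_splits)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  used <- 0L; discarded <- 0L
  for (b in seq_len(n_reps)) {
    idx <- sample.int(ncol(G), replace = TRUE)
    db <- dist_from_dosage(G[, idx, drop = FALSE], normalized)
    if (anyNA(db$D)) { discarded <- discarded + 1L; next }
    used <- used + 1L
    sp <- tree_splits(nj_build(db$D))
    hit <- main_splits %in% sp
    counts[hit] <- counts[hit] + 1
  }
  if (used == 0) stop("all bootstrap replicates were discarded")
  support <- round(100 * counts / used)
  N <- length(main$tip.label)
  lab <- character(main$Nnode)
  lab[as.integer(names(main_splits)) - N] <- as.character(support)
  main$node.label <- lab
  attr(main, "n_reps_used") <- used
  attr(main, "n_discarded") <- discarded
  main
}

#' Serialize a tree to newick
#'
#' Writes branch lengths and (when present) internal-node support labels.
#' Labels containing newick-reserved characters (whitespace, parentheses,
#' commas, colons, semicolons, quotes, brackets) are single-quoted with
#' internal quotes doubled, per the newick convention. The base `ape` writer
#' is not used here because it rewrites such labels instead of quoting them.
#'
#' @param tree a `phylo` object
#' @param path optional output path; when `NULL` the string is returned
#' @param digits significant digits for branch lengths
#' @return the newick string, invisibly when written to a file
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  tr <- tree
  N <- length(tr$tip.label)
  root <- N + 1L
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  qlab <- function(x) {
    if (!nzchar(x)) return(x)
    if (grepl("[][ \t(),:;']", x))
      paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
    else x
  }
  fmt <- function(x) sprintf("%.*g", digits, x)
  rec <- function(node) {
    if (node <= N) return(qlab(tr$tip.label[node]))
    es <- kids[[as.character(node)]]
    parts <- vapply(es, function(e) {
      paste0(rec(tr$edge[e, 2]), ":", fmt(tr$edge.length[e]))
    }, "")
    lab <- if (!is.null(tr$node.label)) qlab(tr$node.label[node - N]) else ""
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  s <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
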