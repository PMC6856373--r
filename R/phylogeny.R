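# Distance-based phylogeny ----------------------------------------------

#' Pairwise p-distance matrix from an alignment
#'
#' Proportion of mismatching sites per sequence pair, with pairwise deletion
#' of sites where either sequence is gapped (or carries an ambiguity code).
#'
#' @param aln An [msa()].
#' @return Symmetric numeric matrix with zero diagonal, taxon ids as
#'   dimnames.
#' @export
p_distance <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  if (aln$n < 3L) stop("at least 3 sequences are required")
  codes <- msa_codes(aln)
  n <- aln$n
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- codes[i, ] > 0L & codes[j, ] > 0L
      if (!any(both))
        stop("sequence pair with zero comparable sites: ",
             aln$ids[i], " / ", aln$ids[j])
      d[i, j] <- d[j, i] <- mean(codes[i, both] != codes[j, both])
    }
  }
  d
}

#' Poisson correction of p-distances
#'
#' `d = -log(1 - p)`, the expected substitutions per site under a Poisson
#' model with equal rates and no back-substitution awareness beyond the
#' saturation correction.
#'
#' @param d Matrix of p-distances, all entries `< 1`.
#' @return Corrected distance matrix.
#' @export
poisson_correct <- function(d) {
  if (any(d >= 1)) stop("p-distance >= 1 cannot be Poisson-corrected")
  out <- -log(1 - d)
  diag(out) <- 0
  out
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion.  Ties in the
#' Q-minimisation are broken deterministically by the lexicographically
#' smallest index pair.  Negative branch lengths are handled by the
#' Kuhner-Felsenstein convention: clamped to zero with the deficit
#' transferred to the sibling branch, preserving path lengths.  The method
#' is exact on additive matrices: it recovers the generating topology and
#' branch lengths.
#'
#' @param d Symmetric distance matrix with zero diagonal and taxon-id
#'   dimnames (>= 3 taxa).
#' @return Unrooted tree of class `phylo` (ape), trifurcating at the root
#'   node.
#' @examples
#' d <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' neighbor_joining(d)
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d)) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("at least 3 taxa are required")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8, check.attributes = FALSE)))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have zero diagonal")
  if (any(d < 0)) stop("distance matrix must be non-negative")
  # canonical (lexicographic) taxon order: agglomeration and its
  # lowest-index-pair tie-breaking become independent of input order
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  labels <- rownames(d)
  # each active cluster carries its newick subtree string
  sub <- labels
  D <- unname(d)
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # lexicographically smallest (i, j), i < j, among minima
    qmin <- min(Q)
    cand <- which(Q <= qmin + abs(qmin) * 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    merged <- paste0("(", sub[i], ":", fmt(bi), ",", sub[j], ":", fmt(bj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- matrix(0, m - 1L, m - 1L)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[m - 1L, seq_along(keep)] <- D2[seq_along(keep), m - 1L] <- dnew[keep]
    D <- D2
    sub <- c(sub[keep], merged)
  }
  # final three clusters join at the root trifurcation (closed form)
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  if (b1 < 0) { b2 <- b2 + b1; b3 <- b3 + b1; b1 <- 0 }
  if (b2 < 0) { b1 <- b1 + b2; b3 <- b3 + b2; b2 <- 0 }
  if (b3 < 0) { b1 <- b1 + b3; b2 <- b2 + b3; b3 <- 0 }
  nwk <- paste0("(", sub[1], ":", fmt(b1), ",", sub[2], ":", fmt(b2), ",",
                sub[3], ":", fmt(b3), ");")
  ape::read.tree(text = nwk)
}

resample_columns <- function(aln, cols) {
  mat <- msa_matrix(aln)[, cols, drop = FALSE]
  seqs <- apply(mat, 1L, paste, collapse = "")
  names(seqs) <- aln$ids
  msa(seqs, ref_id = NULL)
}

aln_distance <- function(aln, distance = c("p", "poisson")) {
  distance <- match.arg(distance)
  d <- p_distance(aln)
  if (distance == "poisson") d <- poisson_correct(d)
  d
}

#' Neighbor-joining tree with column-bootstrap support
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_replicates` times (Felsenstein bootstrap); each internal
#' bipartition of the full-data tree is labelled with the percentage of
#' replicate trees containing it.  Replicates on which a distance cannot be
#' computed (a pair with zero comparable sites, or a saturated
#' Poisson-corrected pair) are skipped and counted.
#'
#' @param aln An [msa()] (>= 3 sequences).
#' @param n_replicates Number of bootstrap replicates (>= 1; trees in
#'   published NADD analyses use 1000).
#' @param seed Integer seed for the resampling.
#' @param distance `"p"` (p-distance, default) or `"poisson"`.
#' @return The full-data `phylo` tree with `node.label` set to support
#'   percentages (root label empty); attributes `n_replicates_used` and
#'   `n_replicates_skipped`.
#' @export
bootstrap_support <- function(aln, n_replicates = 100L, seed = 1L,
                              distance = c("p", "poisson")) {
  stopifnot(inherits(aln, "msa"))
  distance <- match.arg(distance)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  main <- neighbor_joining(aln_distance(aln, distance))
  reps <- list()
  skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(aln$n_col, aln$n_col, replace = TRUE)
      tr <- tryCatch(neighbor_joining(aln_distance(resample_columns(aln, cols),
                                                   distance)),
                     error = function(e) NULL)
      if (is.null(tr)) skipped <- skipped + 1L
      else reps[[length(reps) + 1L]] <- tr
    }
  })
  if (!length(reps)) stop("all bootstrap replicates were degenerate")
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / length(reps)
  lab <- sprintf("%.4g", support)
  lab[1L] <- ""   # root of the unrooted tree: not a bipartition
  main$node.label <- lab
  attr(main, "support") <- support
  attr(main, "n_replicates_used") <- length(reps)
  attr(main, "n_replicates_skipped") <- skipped
  main
}

#' Write / read Newick
#'
#' Thin wrappers over ape's Newick I/O; support values travel as internal
#' node labels.  With `path = NULL`, `write_newick()` returns the Newick
#' string.
#'
#' @param tree A `phylo` tree.
#' @param path Output (input) file path.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(path)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = path); invisible(path) }
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)
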