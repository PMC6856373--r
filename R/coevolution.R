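# MISTIC-style coevolution statistics ------------------------------------
#
# Per-column Kullback-Leibler conservation against a background
# distribution, pairwise mutual information z-scored against a
# column-shuffle null, cumulative MI per column, proximity MI against a
# residue contact set, and percentile edge tiers for circos-style export.

# BLOSUM62 marginal amino-acid background frequencies (Henikoff alignment
# blocks), normalised to sum 1; order follows AA20.
BLOSUM62_FREQS <- {
  f <- c(A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047,
         G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
         M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
         S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)
  f / sum(f)
}

#' Build an alignment object
#'
#' Container for an aligned set of protein sequences (gap character `"-"`),
#' optionally carrying a reference sequence whose ungapped residue numbering
#' is mapped onto alignment columns.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param ref_id Optional name of the reference sequence.
#' @return Object of class `msa`: list with `ids`, `seqs`, `n`, `n_col`,
#'   `ref_id`, and `ref_map` (integer vector over columns; the ungapped
#'   residue number in the reference, `NA` at reference gaps).
#' @export
msa <- function(seqs, ref_id = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("ragged alignment: sequences differ in length")
  ref_map <- NULL
  if (!is.null(ref_id)) {
    if (!ref_id %in% names(seqs)) stop("reference id not in alignment: ", ref_id)
    rchars <- strsplit(seqs[[ref_id]], "", fixed = TRUE)[[1]]
    nongap <- rchars != "-"
    ref_map <- ifelse(nongap, cumsum(nongap), NA_integer_)
  }
  structure(list(ids = names(seqs), seqs = seqs, n = length(seqs), n_col = w,
                 ref_id = ref_id, ref_map = ref_map),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("Protein alignment: ", x$n, " sequences x ", x$n_col, " columns", sep = "")
  if (!is.null(x$ref_id)) cat("; reference ", x$ref_id, sep = "")
  cat("\n")
  invisible(x)
}

#' Read an aligned FASTA file as an `msa`
#' @inheritParams msa
#' @param path Aligned FASTA path.
#' @export
read_msa <- function(path, ref_id = NULL) msa(read_fasta(path), ref_id = ref_id)

# n x m character matrix of the alignment
msa_matrix <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
}

# n x m integer codes into AA20; 0 for gaps and ambiguity codes (excluded
# from all frequency tables)
msa_codes <- function(aln) {
  mat <- msa_matrix(aln)
  codes <- match(mat, AA20, nomatch = 0L)
  dim(codes) <- dim(mat)
  rownames(codes) <- aln$ids
  codes
}

#' Sequence weights from identity clustering
#'
#' Clusters sequences by single linkage at a pairwise identity threshold
#' (identical positions / positions where both sequences are ungapped) and
#' weights each sequence by 1/cluster size, down-weighting redundant
#' sequences before any frequency estimate.
#'
#' @param aln An [msa()].
#' @param identity Clustering identity threshold (default 0.62).
#' @return Numeric weight per sequence (named).
#' @export
sequence_weights <- function(aln, identity = 0.62) {
  stopifnot(inherits(aln, "msa"))
  if (aln$n < 2L) return(stats::setNames(1, aln$ids))
  codes <- msa_codes(aln)
  n <- aln$n
  adj <- diag(TRUE, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- codes[i, ] > 0L & codes[j, ] > 0L
      id <- if (any(both)) mean(codes[i, both] == codes[j, both]) else 0
      adj[i, j] <- adj[j, i] <- id >= identity
    }
  }
  # connected components by BFS
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v]) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  w <- 1 / table(comp)[comp]
  stats::setNames(as.numeric(w), aln$ids)
}

#' Weighted per-column residue frequencies
#'
#' Sequence-weighted, pseudocounted residue frequencies per alignment
#' column.  Gaps and ambiguity codes carry no mass; each column is
#' renormalised over the 20 standard residues.  Columns whose weighted gap
#' fraction exceeds `gap_cutoff` are flagged (and excluded from MI
#' downstream).
#'
#' @param aln An [msa()].
#' @param weights Per-sequence weights; default [sequence_weights()] at the
#'   0.62 identity threshold.
#' @param lambda Pseudocount mass (default 0.05), spread uniformly over the
#'   20 residues.
#' @param gap_cutoff Weighted gap-fraction above which a column is flagged.
#' @return List: `freq` (20 x n_col matrix), `flagged` (logical per column),
#'   `weights`, `lambda`.
#' @export
column_frequencies <- function(aln, weights = sequence_weights(aln),
                               lambda = 0.05, gap_cutoff = 0.5) {
  stopifnot(inherits(aln, "msa"))
  if (aln$n < 2L) stop("alignment must contain at least 2 sequences")
  codes <- msa_codes(aln)
  m <- aln$n_col
  freq <- matrix(0, nrow = 20L, ncol = m, dimnames = list(AA20, NULL))
  gapfrac <- numeric(m)
  W <- sum(weights)
  for (j in seq_len(m)) {
    cj <- codes[, j]
    keep <- cj > 0L
    cnt <- numeric(20L)
    if (any(keep)) {
      tw <- tapply(weights[keep], cj[keep], sum)
      cnt[as.integer(names(tw))] <- tw
    }
    wj <- sum(cnt)
    gapfrac[j] <- 1 - wj / W
    freq[, j] <- (cnt + lambda / 20) / (wj + lambda)
  }
  list(freq = freq, flagged = gapfrac > gap_cutoff, gap_fraction = gapfrac,
       weights = weights, lambda = lambda)
}

#' Per-column Kullback-Leibler conservation
#'
#' `sum_a p_a log(p_a / q_a)` in natural-log units, with column frequencies
#' `p` taken gap-excluded and renormalised, against a strictly positive
#' background `q` (default: BLOSUM62 marginal frequencies).
#'
#' @param aln An [msa()], or a precomputed [column_frequencies()] list.
#' @param background Background distribution over the 20 residues.
#' @param ... Passed to [column_frequencies()].
#' @return Numeric KL score per column (`NA` for columns with no standard
#'   residues).
#' @export
kl_conservation <- function(aln, background = BLOSUM62_FREQS, ...) {
  cf <- if (inherits(aln, "msa")) column_frequencies(aln, ...) else aln
  if (length(background) != 20L || any(background <= 0))
    stop("background must be a strictly positive distribution over 20 residues")
  q <- background / sum(background)
  kl <- colSums(cf$freq * log(cf$freq / q))
  kl[cf$gap_fraction >= 1] <- NA_real_
  kl
}

# Pairwise weighted joint-count blocks for all column pairs at once.
# Returns the (20*m) x (20*m) cross-product matrix of the one-hot encoding;
# block (i,j) holds the weighted joint counts of columns i and j over
# sequences with standard residues in both.
joint_count_blocks <- function(codes, weights) {
  n <- nrow(codes); m <- ncol(codes)
  X <- matrix(0, nrow = n, ncol = 20L * m)
  idx <- which(codes > 0L)
  rows <- ((idx - 1L) %% n) + 1L
  cols <- ((idx - 1L) %/% n) + 1L
  X[cbind(rows, (cols - 1L) * 20L + codes[idx])] <- 1
  crossprod(X * weights, X)
}

# MI for every column pair from the joint-count cross-product; returns an
# m x m symmetric matrix (natural-log units), diagonal = per-column entropy
# H(X) estimated from the same (pseudocounted) machinery.
mi_from_blocks <- function(M, m, lambda) {
  # J array: [a, i, b, j]
  J <- array(M, dim = c(20L, m, 20L, m))
  Tt <- apply(J, c(2L, 4L), sum)                    # totals per pair
  mi <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) {
    for (j in i:m) {
      tot <- Tt[i, j]
      if (tot <= 0) next
      p <- (J[, i, , j] + lambda / 400) / (tot + lambda)
      pa <- rowSums(p); pb <- colSums(p)
      nz <- p > 0
      if (i == j) {
        pd <- diag(p)
        mi[i, i] <- -sum(pd[pd > 0] * log(pd[pd > 0] / sum(pd)))
      } else {
        mi[i, j] <- mi[j, i] <- sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
      }
    }
  }
  mi
}

#' Pairwise mutual information with shuffle-null z-scores
#'
#' Raw MI between alignment columns, `MI_ij = sum_ab p_ab log(p_ab /
#' (p_a p_b))`, from sequence-weighted, pseudocounted pair frequencies
#' estimated over sequences ungapped in both columns (marginals are derived
#' from the joint).  The null distribution is built by independently
#' permuting each column's residues across sequences `n_shuffles` times;
#' `z_ij = (MI_ij - null mean) / null sd`.  Columns flagged for excess gaps
#' are excluded (`NA` rows/columns).
#'
#' @param aln An [msa()].
#' @param n_shuffles Number of null permutations (>= 20; default 100).
#' @param seed Integer seed driving the permutations.
#' @param weights Per-sequence weights.
#' @param lambda Pseudocount mass (0 disables smoothing; at 0 the identity
#'   MI(X,X) = H(X) holds exactly).
#' @param gap_cutoff Weighted gap-fraction cutoff for excluding columns.
#' @return Symmetric z-score matrix with `NA` diagonal; attributes
#'   `raw_mi` (with per-column entropies on its diagonal), `null_mean`,
#'   `null_sd`, and `excluded` (flagged columns).
#' @export
mi_zscores <- function(aln, n_shuffles = 100L, seed = 1L,
                       weights = sequence_weights(aln), lambda = 0.05,
                       gap_cutoff = 0.5) {
  stopifnot(inherits(aln, "msa"))
  if (n_shuffles < 20L) stop("n_shuffles must be at least 20")
  codes <- msa_codes(aln)
  m <- aln$n_col
  cf <- column_frequencies(aln, weights = weights, lambda = lambda,
                           gap_cutoff = gap_cutoff)
  usable <- which(!cf$flagged)
  if (length(usable) < 2L) stop("fewer than 2 usable columns")
  sub <- codes[, usable, drop = FALSE]
  mu <- length(usable)
  obs <- mi_from_blocks(joint_count_blocks(sub, weights), mu, lambda)
  # canonical row order so the seeded null (and hence z) is invariant to the
  # order sequences arrive in
  canon <- order(apply(sub, 1L, paste, collapse = ","), weights)
  sub <- sub[canon, , drop = FALSE]
  weights <- weights[canon]
  null_sum <- matrix(0, mu, mu)
  null_sq <- matrix(0, mu, mu)
  with_seed(seed, {
    n <- nrow(sub)
    for (s in seq_len(n_shuffles)) {
      perm <- apply(sub, 2L, function(col) col[sample.int(n)])
      nullmi <- mi_from_blocks(joint_count_blocks(perm, weights), mu, lambda)
      null_sum <- null_sum + nullmi
      null_sq <- null_sq + nullmi^2
    }
  })
  nm <- null_sum / n_shuffles
  nv <- pmax(null_sq / n_shuffles - nm^2, 0)
  nsd <- sqrt(nv * n_shuffles / max(n_shuffles - 1L, 1L))
  zsub <- (obs - nm) / nsd
  zsub[nsd < 1e-12] <- 0        # degenerate pairs (e.g. invariant columns)
  expand <- function(x) {
    full <- matrix(NA_real_, m, m)
    full[usable, usable] <- x
    full
  }
  z <- expand(zsub)
  diag(z) <- NA_real_
  structure(z,
            raw_mi = expand(obs),
            null_mean = expand(nm),
            null_sd = expand(nsd),
            excluded = cf$flagged)
}

#' Cumulative mutual information per column
#'
#' `cMI_i = sum over j != i of z_ij for z_ij > threshold` — the amount of
#' above-threshold mutual information a column shares with the rest of the
#' alignment.
#'
#' @param z Symmetric z-score matrix (e.g. from [mi_zscores()]).
#' @param threshold Edge threshold (default 6.5).
#' @return Numeric cMI per column (0 when no edge passes).
#' @export
cumulative_mi <- function(z, threshold = 6.5) {
  stopifnot(is.matrix(z), nrow(z) == ncol(z))
  zz <- z
  zz[is.na(zz) | zz <= threshold] <- 0
  rowSums(zz)
}

#' Proximity mutual information
#'
#' For each residue, the mean cMI of its spatial neighbours (excluding the
#' residue itself), from either a contact list or a distance table cut at
#' `radius`.
#'
#' @param cmi Numeric cMI vector (positions 1..length).
#' @param contacts Data frame: columns `i`, `j` (a contact list), optionally
#'   `distance` — in which case pairs with `distance <= radius` count as
#'   contacts.
#' @param radius Distance cutoff; required when `contacts` has distances.
#' @return Numeric pMI per position; `NA` where a position has no contacts.
#' @export
proximity_mi <- function(cmi, contacts, radius = NULL) {
  n <- length(cmi)
  stopifnot(is.data.frame(contacts), all(c("i", "j") %in% names(contacts)))
  if ("distance" %in% names(contacts)) {
    if (is.null(radius)) stop("radius required with a distance table")
    contacts <- contacts[contacts$distance <= radius, , drop = FALSE]
  }
  if (any(contacts$i < 1 | contacts$i > n | contacts$j < 1 | contacts$j > n))
    stop("contact references a residue outside the cMI range 1..", n)
  nb <- vector("list", n)
  for (r in seq_len(nrow(contacts))) {
    i <- contacts$i[r]; j <- contacts$j[r]
    if (i == j) next
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  vapply(seq_len(n), function(i) {
    js <- unique(nb[[i]])
    if (!length(js)) NA_real_ else mean(cmi[js])
  }, numeric(1))
}

#' Tiered edge list from a z-score matrix
#'
#' Edges with `z > threshold`, partitioned by percentile rank of z among the
#' retained edges — the drawing convention of circos MI plots: top 5 percent
#' (`"top5"`), the 70th-95th percentile band (`"mid"`), and the remainder
#' (`"low"`).
#'
#' @inheritParams cumulative_mi
#' @return Data frame `col_i`, `col_j`, `z`, `tier`, sorted by decreasing z;
#'   zero rows when no edge passes the threshold.
#' @export
tier_edges <- function(z, threshold = 6.5) {
  stopifnot(is.matrix(z), nrow(z) == ncol(z))
  m <- nrow(z)
  ut <- which(upper.tri(z) & !is.na(z) & z > threshold, arr.ind = TRUE)
  if (!nrow(ut))
    return(data.frame(col_i = integer(0), col_j = integer(0),
                      z = numeric(0), tier = character(0),
                      stringsAsFactors = FALSE))
  zv <- z[ut]
  pr <- rank(zv, ties.method = "average") / length(zv)
  tier <- ifelse(pr > 0.95, "top5", ifelse(pr > 0.70, "mid", "low"))
  out <- data.frame(col_i = ut[, 1L], col_j = ut[, 2L], z = zv, tier = tier,
                    stringsAsFactors = FALSE)
  out[order(-out$z), , drop = FALSE]
}

#' Full coevolution analysis of an alignment
#'
#' Runs the whole MISTIC-style pipeline: sequence weighting, per-column KL
#' conservation, MI z-scores against a shuffle null, cumulative MI, optional
#' proximity MI, and tiered edges.
#'
#' @inheritParams mi_zscores
#' @param identity Clustering identity threshold for the sequence weights.
#' @param contacts Optional contact table for [proximity_mi()] (positions in
#'   reference numbering when the alignment has a reference, otherwise
#'   alignment columns).
#' @param radius Optional distance cutoff for `contacts`.
#' @param threshold Edge threshold on z (default 6.5).
#' @param background Background for the KL score.
#' @return Object of class `mi_network`: list with `columns` (data frame:
#'   `column`, `ref_residue`, `kl`, `cmi`, `pmi`), `z`, `edges`, and the
#'   settings used.
#' @export
coevolution <- function(aln, n_shuffles = 100L, seed = 1L, lambda = 0.05,
                        gap_cutoff = 0.5, threshold = 6.5,
                        identity = 0.62, background = BLOSUM62_FREQS,
                        contacts = NULL, radius = NULL) {
  stopifnot(inherits(aln, "msa"))
  w <- sequence_weights(aln, identity = identity)
  kl <- kl_conservation(aln, background = background, weights = w,
                        lambda = lambda, gap_cutoff = gap_cutoff)
  z <- mi_zscores(aln, n_shuffles = n_shuffles, seed = seed, weights = w,
                  lambda = lambda, gap_cutoff = gap_cutoff)
  cmi <- cumulative_mi(z, threshold = threshold)
  pmi <- rep(NA_real_, aln$n_col)
  if (!is.null(contacts)) {
    if (!is.null(aln$ref_map)) {
      # contacts are in reference numbering: map cMI onto reference residues
      ref_cols <- which(!is.na(aln$ref_map))
      cmi_ref <- cmi[ref_cols]
      pmi_ref <- proximity_mi(cmi_ref, contacts, radius = radius)
      pmi[ref_cols] <- pmi_ref
    } else {
      pmi <- proximity_mi(cmi, contacts, radius = radius)
    }
  }
  columns <- data.frame(column = seq_len(aln$n_col),
                        ref_residue = if (is.null(aln$ref_map)) NA_integer_
                                      else aln$ref_map,
                        kl = kl, cmi = cmi, pmi = pmi)
  structure(list(columns = columns, z = z,
                 edges = tier_edges(z, threshold = threshold),
                 weights = w,
                 settings = list(n_shuffles = n_shuffles, seed = seed,
                                 lambda = lambda, gap_cutoff = gap_cutoff,
                                 threshold = threshold, identity = identity)),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat("MI coevolution network: ", nrow(x$columns), " columns, ",
      nrow(x$edges), " edges above z > ", x$settings$threshold, "\n", sep = "")
  if (nrow(x$edges)) {
    cat("  tiers:", paste(names(table(x$edges$tier)),
                          table(x$edges$tier), collapse = ", ", sep = "="), "\n")
  }
  invisible(x)
}
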