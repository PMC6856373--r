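two_col_aln <- function() {
  msa(setNames(c("AC", "AC", "VT", "VT", "AC", "VT", "AC", "VT"),
               paste0("s", 1:8)))
}

test_that("identical sequences cluster together and share weight", {
  aln <- msa(setNames(c("ACDE", "ACDE"), c("a", "b")))
  w <- sequence_weights(aln, identity = 0.62)
  expect_equal(unname(w), c(0.5, 0.5))
  # distinct random sequences stay singletons with unit weight
  set.seed(31)
  seqs <- vapply(1:8, function(i) random_protein(30), character(1))
  names(seqs) <- paste0("r", 1:8)
  w2 <- sequence_weights(msa(seqs), identity = 0.62)
  expect_equal(unname(w2), rep(1, 8))
})

test_that("unweighted frequencies equal brute-force tallies up to the pseudocount", {
  set.seed(32)
  seqs <- vapply(1:10, function(i) random_protein(12), character(1))
  names(seqs) <- paste0("r", 1:10)
  aln <- msa(seqs)
  cf <- column_frequencies(aln, weights = setNames(rep(1, 10), names(seqs)),
                           lambda = 0)
  mat <- do.call(rbind, strsplit(seqs, ""))
  for (j in c(1, 5, 12)) {
    tally <- table(factor(mat[, j], levels = naddkit:::AA20)) / 10
    expect_equal(unname(cf$freq[, j]), unname(c(tally)))
  }
})

test_that("all-gap columns are flagged and excluded", {
  aln <- msa(setNames(c("A-C", "A-C", "V-T", "V-T"), paste0("s", 1:4)))
  cf <- column_frequencies(aln)
  expect_true(cf$flagged[2])
  expect_false(any(cf$flagged[c(1, 3)]))
  z <- mi_zscores(aln, n_shuffles = 20, seed = 1)
  expect_true(all(is.na(z[2, ])))
  expect_error(mi_zscores(msa(setNames(c("-A", "-C", "-D"), c("a", "b", "c"))),
                          n_shuffles = 20), "usable columns")
})

test_that("KL conservation is zero against a matching background and maximal when invariant", {
  # uniform column vs uniform background
  aln <- msa(setNames(c("AC", "CA", "DV", "VD"), paste0("s", 1:4)))
  w <- setNames(rep(1, 4), aln$ids)
  kl_unif <- kl_conservation(
    msa(setNames(naddkit:::AA20, paste0("u", 1:20))),
    background = setNames(rep(0.05, 20), naddkit:::AA20),
    weights = setNames(rep(1, 20), paste0("u", 1:20)), lambda = 0)
  expect_equal(unname(kl_unif), 0, tolerance = 1e-12)
  # a column drawn exactly at background frequencies scores ~0 with pseudocount
  bg <- naddkit:::BLOSUM62_FREQS
  reps <- round(bg * 1000)
  col <- rep(names(bg), reps)
  aln2 <- msa(setNames(col, paste0("q", seq_along(col))))
  kl2 <- kl_conservation(aln2, weights = setNames(rep(1, length(col)),
                                                  paste0("q", seq_along(col))),
                         lambda = 0.05)
  expect_lt(abs(kl2), 0.01)
  # an invariant column is the most conserved column of a random alignment
  set.seed(33)
  seqs <- vapply(1:30, function(i) paste0("W", random_protein(9)), character(1))
  names(seqs) <- paste0("s", 1:30)
  kl3 <- kl_conservation(msa(seqs))
  expect_equal(which.max(kl3), 1L)
})

test_that("raw MI is symmetric, non-negative, and MI(X,X) equals H(X)", {
  aln <- two_col_aln()
  z <- mi_zscores(aln, n_shuffles = 20, seed = 1, lambda = 0)
  raw <- attr(z, "raw_mi")
  expect_equal(raw[1, 2], raw[2, 1], tolerance = 1e-12)
  expect_gte(raw[1, 2], 0)
  # duplicated columns: MI equals the column entropy (balanced binary: ln 2)
  expect_equal(raw[1, 2], log(2), tolerance = 1e-9)
  expect_equal(raw[1, 1], log(2), tolerance = 1e-9)
  expect_equal(abs(raw[1, 2] - raw[1, 1]), 0, tolerance = 1e-9)
})

test_that("planted covarying pair attains the top z-score", {
  aln <- make_covarying_msa(n_seqs = 64, n_cols = 30,
                            planted_pairs = list(c(4, 19)), seed = 42)
  z <- mi_zscores(aln, n_shuffles = 50, seed = 7)
  expect_equal(max(z, na.rm = TRUE), z[4, 19])
  # i.i.d. columns have near-zero mean z
  noise <- make_covarying_msa(n_seqs = 64, n_cols = 20,
                              planted_pairs = list(), seed = 43)
  zn <- mi_zscores(noise, n_shuffles = 100, seed = 8)
  expect_lt(abs(mean(zn[upper.tri(zn)], na.rm = TRUE)), 0.5)
})

test_that("outputs are invariant to sequence order and reproducible under a seed", {
  aln <- make_covarying_msa(n_seqs = 32, n_cols = 12,
                            planted_pairs = list(c(2, 9)), seed = 5)
  perm <- sample(seq_along(aln$seqs))
  aln_perm <- msa(aln$seqs[perm])
  z1 <- mi_zscores(aln, n_shuffles = 30, seed = 3)
  z2 <- mi_zscores(aln_perm, n_shuffles = 30, seed = 3)
  expect_equal(unclass(z1)[1:12, 1:12], unclass(z2)[1:12, 1:12],
               tolerance = 1e-9, ignore_attr = TRUE)
  z3 <- mi_zscores(aln, n_shuffles = 30, seed = 3)
  expect_identical(unclass(z1), unclass(z3))
})

test_that("cumulative MI sums above-threshold z per column", {
  z <- matrix(0, 4, 4)
  expect_equal(cumulative_mi(z), rep(0, 4))
  z[1, 3] <- z[3, 1] <- 10
  expect_equal(cumulative_mi(z), c(10, 0, 10, 0))
  set.seed(44)
  zr <- matrix(rnorm(64, sd = 5), 8, 8)
  zr <- (zr + t(zr)) / 2
  diag(zr) <- NA
  brute <- vapply(1:8, function(i)
    sum(zr[i, -i][zr[i, -i] > 6.5]), numeric(1))
  expect_equal(cumulative_mi(zr), brute)
})

test_that("proximity MI averages neighbour cMI over a contact set", {
  contacts <- data.frame(i = c(1, 2), j = c(2, 3))
  pmi <- proximity_mi(c(0, 10, 0), contacts)
  expect_equal(pmi, c(10, 0, 10))
  # dense contacts: every pMI is the mean of the others
  cmi <- c(1, 5, 9, 3)
  dense <- expand.grid(i = 1:4, j = 1:4)
  dense <- dense[dense$i < dense$j, ]
  pmi2 <- proximity_mi(cmi, dense)
  expect_equal(pmi2, vapply(1:4, function(i) mean(cmi[-i]), numeric(1)))
  # no contacts -> undefined
  expect_true(all(is.na(proximity_mi(cmi, dense[0, ]))))
  expect_error(proximity_mi(cmi, data.frame(i = 1, j = 9)), "outside")
})

test_that("edge tiers partition by percentile as drawn in circos plots", {
  z <- matrix(0, 15, 15)
  k <- 0
  for (i in 1:14) for (j in (i + 1):15) {
    k <- k + 1
    if (k <= 100) z[i, j] <- z[j, i] <- 6.5 + k
  }
  edges <- tier_edges(z)
  expect_equal(nrow(edges), 100)
  expect_equal(sum(edges$tier == "top5"), 5)
  expect_equal(sum(edges$tier == "mid"), 25)
  expect_equal(sum(edges$tier == "low"), 70)
  expect_equal(edges$tier[1], "top5")   # sorted by decreasing z
  one <- matrix(c(0, 10, 10, 0), 2, 2)
  expect_equal(tier_edges(one)$tier, "top5")
  none <- matrix(1, 3, 3)
  expect_equal(nrow(tier_edges(none)), 0)
})

test_that("the full pipeline maps columns to reference numbering", {
  seqs <- setNames(c("AC-DE", "AC-DE", "VTRDE", "VTRTE", "ACRDE", "VT-TE"),
                   paste0("s", 1:6))
  net <- coevolution(msa(seqs, ref_id = "s1"), n_shuffles = 20, seed = 2)
  expect_s3_class(net, "mi_network")
  expect_equal(net$columns$ref_residue, c(1, 2, NA, 3, 4))
  expect_equal(nrow(net$columns), 5)
  expect_true(all(c("kl", "cmi", "pmi") %in% names(net$columns)))
})
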