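# random additive distance matrix from a random binary tree with positive
# branch lengths; returns the matrix (path lengths between leaves)
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.1, 2))
  d <- ape::cophenetic.phylo(tr)
  ids <- sort(rownames(d))
  list(tree = ape::unroot(tr), d = d[ids, ids])
}

test_that("p-distance counts mismatches with pairwise deletion", {
  aln <- msa(setNames(c("AAAA", "AAAT", "AA-T"), c("a", "b", "c")))
  d <- p_distance(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["b", "c"], 0)        # gap site excluded
  expect_equal(d["a", "c"], 1 / 3)
  expect_equal(d, t(d))
  set.seed(61)
  x <- random_protein(50); y <- random_protein(50)
  brute <- mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  d2 <- p_distance(msa(setNames(c(x, y, random_protein(50)), c("x", "y", "z"))))
  expect_equal(d2["x", "y"], brute)
  expect_error(p_distance(msa(setNames(c("A-", "-C", "AC"), c("a", "b", "c")))),
               "zero comparable")
})

test_that("Poisson correction applies the closed form and rejects saturation", {
  d <- matrix(c(0, 0.25, 0.25, 0), 2, 2)
  expect_equal(poisson_correct(d)[1, 2], -log(0.75))
  expect_equal(poisson_correct(d)[1, 2], 0.2877, tolerance = 1e-4)
  expect_equal(poisson_correct(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_error(poisson_correct(matrix(c(0, 1, 1, 0), 2, 2)), "Poisson")
})

test_that("neighbor joining recovers the additive quartet exactly", {
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  # topology AB|CD
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))
  # branch lengths: path-length matrix reproduces the input exactly
  got <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(got, d, tolerance = 1e-9)
})

test_that("three taxa resolve to the closed-form star", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(ape::cophenetic.phylo(tr)[c("a", "b", "c"), c("a", "b", "c")], d,
               tolerance = 1e-9)
})

test_that("NJ is exact on random additive matrices and agrees with ape::nj", {
  for (seed in 1:10) {
    ad <- random_additive(sample(5:9, 1), seed = 700 + seed)
    tr <- neighbor_joining(ad$d)
    got <- ape::cophenetic.phylo(tr)[rownames(ad$d), colnames(ad$d)]
    expect_equal(got, ad$d, tolerance = 1e-8)
    # same unrooted topology as the generating tree and as ape's NJ
    expect_equal(as.numeric(ape::dist.topo(tr, ad$tree)), 0)
    expect_equal(as.numeric(ape::dist.topo(tr, ape::unroot(ape::nj(ad$d)))), 0)
  }
})

test_that("invalid distance matrices are rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(bad), "3 taxa")
  asym <- matrix(c(0, 1, 3, 2, 0, 1, 3, 1, 0), 3, 3)
  expect_error(neighbor_joining(asym), "symmetric")
  negd <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3)
  expect_error(neighbor_joining(negd), "non-negative")
})

test_that("negative NJ branches are clamped with the deficit transferred", {
  # a non-additive matrix known to produce a negative branch estimate
  d <- matrix(c(0, 0.1, 0.6, 0.6,
                0.1, 0, 0.6, 0.6,
                0.6, 0.6, 0, 0.01,
                0.6, 0.6, 0.01, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap separates two clades with high support", {
  aln <- make_clade_msa(n_per_clade = 5, n_cols = 200, within_id = 0.95,
                        between_id = 0.60, seed = 17)
  tr <- bootstrap_support(aln, n_replicates = 100, seed = 4)
  expect_s3_class(tr, "phylo")
  clades <- attr(aln, "clades")
  rooted <- ape::root(tr, names(clades)[clades == "A"][1])
  expect_true(ape::is.monophyletic(rooted, names(clades)[clades == "B"]))
  # support of the clade-B bipartition
  expect_gte(bipart_support(tr, names(clades)[clades == "B"]), 99)
})

test_that("a single bootstrap replicate gives all-or-nothing support", {
  aln <- make_clade_msa(n_per_clade = 3, n_cols = 80, seed = 9)
  tr <- bootstrap_support(aln, n_replicates = 1, seed = 2)
  sup <- attr(tr, "support")[-1]
  expect_true(all(sup %in% c(0, 100)))
})

test_that("bootstrap supports are invariant to taxon order and seed-reproducible", {
  aln <- make_clade_msa(n_per_clade = 4, n_cols = 120, seed = 23)
  t1 <- bootstrap_support(aln, n_replicates = 25, seed = 5)
  t2 <- bootstrap_support(aln, n_replicates = 25, seed = 5)
  expect_identical(write_newick(t1), write_newick(t2))
  perm <- msa(aln$seqs[rev(seq_along(aln$seqs))])
  t3 <- bootstrap_support(perm, n_replicates = 25, seed = 5)
  # compare support of the central bipartition (clade A vs clade B)
  cladeB <- paste0("cladeB_", 1:4)
  expect_equal(bipart_support(t1, cladeB), bipart_support(t3, cladeB))
})

test_that("newick round trip preserves structure and supports", {
  aln <- make_clade_msa(n_per_clade = 3, n_cols = 100, seed = 3)
  tr <- bootstrap_support(aln, n_replicates = 10, seed = 1)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(as.numeric(ape::dist.topo(back, tr)), 0)
  expect_identical(write_newick(back), write_newick(tr))
  simple <- neighbor_joining(matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3,
                                    dimnames = list(c("A", "B", "C"),
                                                    c("A", "B", "C"))))
  expect_match(write_newick(simple), "^\\(.*A.*B.*C.*\\);$")
})
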