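test_that("the canonical architecture string is assembled in coordinate order", {
  hits <- data.frame(domain_name = c("NUDIX", "NUDIX-like", "zf-NADH-PPase"),
                     start = c(130, 10, 95), end = c(250, 90, 125))
  expect_equal(architecture_of(hits), "NUDIX-like_zf-NADH-PPase_NUDIX")
  single <- data.frame(domain_name = "NUDIX", start = 5, end = 120)
  expect_equal(architecture_of(single), "NUDIX")
  expect_error(architecture_of(single[0, ]), "no domain hits")
})

test_that("overlapping hits resolve by score, then length, then start", {
  hits <- data.frame(domain_name = c("A", "B"),
                     start = c(1, 40), end = c(50, 60),
                     score = c(30, 10))
  expect_equal(architecture_of(hits), "A")
  # tie on score: longer hit wins
  tie <- data.frame(domain_name = c("S", "L"),
                    start = c(1, 5), end = c(30, 60), score = c(10, 10))
  expect_equal(architecture_of(tie), "L")
  # small overlap below the 30% threshold keeps both
  touching <- data.frame(domain_name = c("A", "B"),
                         start = c(1, 48), end = c(50, 120),
                         score = c(30, 10))
  expect_equal(architecture_of(touching), "A_B")
})

test_that("architecture tabulation reports counts and percentages", {
  archs <- c(rep("NUDIX-like_zf-NADH-PPase_NUDIX", 54),
             rep("NUDIX-like_NUDIX", 36), rep("NUDIX", 10))
  tab <- tabulate_architectures(archs)
  expect_equal(tab$count, c(54, 36, 10))
  expect_equal(tab$percent_rounded, c(54.0, 36.0, 10.0))
  expect_equal(sum(tab$percent), 100)
  one <- tabulate_architectures(rep("NUDIX", 7))
  expect_equal(one$percent_rounded, 100.0)
  expect_error(tabulate_architectures(character(0)), "empty")
})

test_that("tabulation matches a brute-force tally and ignores input order", {
  set.seed(21)
  archs <- sample(c("A", "B_C", "D", "E_F_G"), 500, replace = TRUE,
                  prob = c(0.5, 0.3, 0.15, 0.05))
  tab <- tabulate_architectures(archs)
  brute <- sort(table(archs), decreasing = TRUE)
  expect_equal(setNames(tab$count, tab$architecture), c(unclass(brute)))
  expect_equal(tabulate_architectures(rev(archs)), tab)
  expect_true(abs(sum(tab$percent_rounded) - 100) <= 0.3)
})

test_that("taxonomy rollup reports counts and parent percentages", {
  cls <- data.frame(sequence_id = paste0("s", 1:10), is_nadd = TRUE)
  lin <- data.frame(sequence_id = paste0("s", 1:10),
                    kingdom = c(rep("Fungi", 8), rep("Metazoa", 2)),
                    phylum = c(rep("Ascomycota", 6), rep("Basidiomycota", 2),
                               rep("Chordata", 2)))
  out <- taxonomy_rollup(cls, lin, ranks = c("kingdom", "phylum"))
  king <- out[out$rank == "kingdom", ]
  expect_equal(king$taxon, c("Fungi", "Metazoa"))
  expect_equal(king$count, c(8, 2))
  expect_equal(king$percent_of_parent, c(80, 20))
  phy <- out[out$rank == "phylum", ]
  asc <- phy[phy$taxon == "Ascomycota", ]
  expect_equal(asc$percent_of_parent, 100 * 6 / 8)
  expect_equal(asc$percent_of_total, 60)
  # child counts sum to the parent count
  for (p in unique(phy$parent))
    expect_equal(sum(phy$count[phy$parent == p]),
                 king$count[king$taxon == p])
})

test_that("single-taxon rollup yields 100% and missing lineages go unassigned", {
  cls <- data.frame(sequence_id = c("a", "b", "c", "d"), is_nadd = TRUE)
  lin <- data.frame(sequence_id = c("a", "b", "c"), phylum = "Ascomycota")
  out <- taxonomy_rollup(cls, lin, ranks = "phylum")
  expect_equal(out$taxon, c("Ascomycota", "unassigned"))
  expect_equal(out$count, c(3, 1))
  all_same <- taxonomy_rollup(
    data.frame(sequence_id = c("a", "b", "c"), is_nadd = TRUE),
    data.frame(sequence_id = c("a", "b", "c"), phylum = "P"), "phylum")
  expect_equal(all_same$percent_of_parent_rounded, 100.0)
})

test_that("rollup percentages reproduce the published rounding convention", {
  # 478 fungal of 7479 positives -> 6.4%; 1 of 478 -> 0.2%
  expect_equal(naddkit:::round_percent(100 * 478 / 7479), 6.4)
  expect_equal(naddkit:::round_percent(100 * 1 / 478), 0.21)
  expect_equal(summarize_rate(1, 478), 0.2)
  # sub-1% values keep two decimals (0.24% archaea-style)
  expect_equal(naddkit:::round_percent(0.239), 0.24)
  expect_equal(naddkit:::round_percent(3.195), 3.2)
})

test_that("profiling TSV readers accept both lineage dialects", {
  wide <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tkingdom\tphylum",
               "s1\tFungi\tAscomycota", "s2\tFungi\tBasidiomycota"), wide)
  lw <- read_lineages(wide)
  expect_equal(names(lw), c("sequence_id", "kingdom", "phylum"))
  semi <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tlineage",
               "s1\tFungi;Ascomycota", "s2\tFungi;Basidiomycota"), semi)
  ls <- read_lineages(semi, ranks = c("kingdom", "phylum"))
  expect_equal(ls$phylum, c("Ascomycota", "Basidiomycota"))
  expect_equal(lw$kingdom, ls$kingdom)
})

test_that("generated profiling tables flow through profile_tables", {
  tabs <- make_profiling_tables(
    c("NUDIX-like_zf-NADH-PPase_NUDIX" = 11, "NUDIX-like_NUDIX" = 7,
      "NUDIX" = 2),
    list(Fungi = list(Ascomycota = 14, Basidiomycota = 4), Metazoa = 2),
    seed = 5)
  out <- profile_tables(tabs$classification, tabs$lineages, tabs$domains,
                        ranks = c("kingdom", "phylum"))
  expect_equal(out$architectures$architecture[1], "NUDIX-like_zf-NADH-PPase_NUDIX")
  expect_equal(out$architectures$count, c(11, 7, 2))
  king <- out$taxonomy[out$taxonomy$rank == "kingdom", ]
  expect_equal(king$count[king$taxon == "Fungi"], 18)
  expect_equal(king$count[king$taxon == "Metazoa"], 2)
})
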