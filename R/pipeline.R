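# Pipeline surface -------------------------------------------------------
#
# File-in / file-out wrappers tying the analysis steps into the discovery
# pipeline; each writes tab-separated tables with a provenance comment
# header.  A thin command-line wrapper over these functions ships at
# inst/cli/naddkit.R.

provenance_header <- function(settings = list()) {
  cfg <- if (length(settings))
    paste(names(settings), unlist(settings), sep = "=", collapse = " ") else ""
  sprintf("# naddkit %s%s",
          as.character(utils::packageVersion("naddkit")),
          if (nzchar(cfg)) paste0("; ", cfg) else "")
}

write_tsv <- function(df, path, settings = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_header(settings), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     dec = ".")
  invisible(path)
}

#' Scan a FASTA file with a pattern
#'
#' Runs [scan_prosite()] over every record of a FASTA file.
#'
#' @param fasta FASTA path or named character vector of sequences.
#' @param pattern Pattern text, a `prosite_pattern`, or a bundled motif name
#'   (`"nadd"`, `"nudix_box"`, `"signature_full"`, `"signature_core"`).
#' @param mode Scan mode (`"greedy"`, `"lazy"`, `"all"`).
#' @param out_tsv Optional output TSV path (columns `sequence_id`,
#'   `pattern_id`, `start`, `end`, `matched_seq`).
#' @return Data frame of match spans.
#' @export
scan_fasta <- function(fasta, pattern, mode = "greedy", out_tsv = NULL) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && is.null(names(fasta)))
    read_fasta(fasta) else fasta
  pattern_id <- if (is.character(pattern) && length(pattern) == 1L) pattern
                else format(resolve_pattern(pattern))
  pat <- resolve_pattern(pattern)
  rows <- lapply(names(seqs), function(id)
    scan_prosite(pat, seqs[[id]], mode = mode, sequence_id = id))
  out <- do.call(rbind, rows)
  out <- cbind(out[, "sequence_id", drop = FALSE],
               pattern_id = rep(pattern_id, nrow(out)),
               out[, c("start", "end", "matched_seq")])
  if (!is.null(out_tsv))
    write_tsv(out, out_tsv, list(cmd = "scan", mode = mode))
  out
}

#' Classify a FASTA file and write results
#'
#' @param fasta FASTA path or named character vector.
#' @param out_tsv Optional classification TSV path.
#' @param summary_json Optional JSON path for the summary counts
#'   (`n_total`, `n_matched`, `percent`).
#' @return The [batch_classify()] table.
#' @export
classify_fasta <- function(fasta, out_tsv = NULL, summary_json = NULL) {
  cls <- batch_classify(fasta)
  if (!is.null(out_tsv))
    write_tsv(as.data.frame(cls), out_tsv, list(cmd = "classify"))
  if (!is.null(summary_json)) {
    s <- list(n_total = attr(cls, "n_total"), n_matched = attr(cls, "n_matched"),
              percent = attr(cls, "percent"))
    jsonlite::write_json(s, summary_json, auto_unbox = TRUE, digits = NA)
  }
  cls
}

#' Profile classified sequences
#'
#' Produces the two distribution tables of the pipeline: a taxonomy rollup
#' of positives per rank and a domain-architecture distribution.
#'
#' @param classification Classification table (data frame or TSV path).
#' @param lineages Lineage table (data frame or TSV path).
#' @param domains Domain-hit table (data frame or TSV path).
#' @param ranks Lineage ranks to roll up, outermost first.
#' @param out_dir Optional directory for `taxonomy.tsv` and
#'   `architectures.tsv`.
#' @return List with `taxonomy` and `architectures` data frames.
#' @export
profile_tables <- function(classification, lineages, domains,
                           ranks = NULL, out_dir = NULL) {
  if (is.character(classification))
    classification <- utils::read.delim(classification, comment.char = "#")
  if (is.character(lineages)) lineages <- read_lineages(lineages)
  if (is.character(domains)) domains <- read_domain_hits(domains)
  if (is.null(ranks)) ranks <- setdiff(names(lineages), "sequence_id")
  tax <- taxonomy_rollup(classification, lineages, ranks = ranks)
  pos_ids <- classification$sequence_id[as.logical(classification$is_nadd)]
  dom_pos <- domains[domains$sequence_id %in% pos_ids, , drop = FALSE]
  archs <- vapply(split(dom_pos, dom_pos$sequence_id), architecture_of,
                  character(1))
  arch_tab <- tabulate_architectures(unname(archs))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(tax, file.path(out_dir, "taxonomy.tsv"), list(cmd = "profile"))
    write_tsv(arch_tab, file.path(out_dir, "architectures.tsv"),
              list(cmd = "profile"))
  }
  list(taxonomy = tax, architectures = arch_tab)
}

#' Coevolution analysis of an aligned FASTA
#'
#' @param alignment Aligned FASTA path or an [msa()].
#' @param ref_id Optional reference sequence id (maps columns to ungapped
#'   residue numbers).
#' @param out_prefix Optional path prefix; writes `<prefix>_columns.tsv`
#'   (column, ref_residue, KL, cMI, pMI) and `<prefix>_edges.tsv`
#'   (col_i, col_j, z, tier).
#' @param ... Passed to [coevolution()].
#' @return An `mi_network`.
#' @export
coevolve_msa <- function(alignment, ref_id = NULL, out_prefix = NULL, ...) {
  aln <- if (inherits(alignment, "msa")) alignment
         else read_msa(alignment, ref_id = ref_id)
  if (!is.null(ref_id) && is.null(aln$ref_map)) aln <- msa(aln$seqs, ref_id)
  net <- coevolution(aln, ...)
  if (!is.null(out_prefix)) {
    write_tsv(net$columns, paste0(out_prefix, "_columns.tsv"),
              net$settings[c("seed", "n_shuffles", "threshold")])
    write_tsv(net$edges, paste0(out_prefix, "_edges.tsv"),
              net$settings[c("seed", "n_shuffles", "threshold")])
  }
  net
}

#' Neighbor-joining tree from an aligned FASTA
#'
#' @param alignment Aligned FASTA path or an [msa()].
#' @param n_bootstrap Bootstrap replicates; 0 skips support values.
#' @param seed Integer seed for the bootstrap.
#' @param distance `"p"` or `"poisson"`.
#' @param out_newick Optional Newick output path.
#' @return A `phylo` tree (with `node.label` support when bootstrapped).
#' @export
tree_from_msa <- function(alignment, n_bootstrap = 100L, seed = 1L,
                          distance = "p", out_newick = NULL) {
  aln <- if (inherits(alignment, "msa")) alignment else read_msa(alignment)
  tree <- if (n_bootstrap > 0L)
    bootstrap_support(aln, n_replicates = n_bootstrap, seed = seed,
                      distance = distance)
  else neighbor_joining(aln_distance(aln, distance))
  if (!is.null(out_newick)) write_newick(tree, out_newick)
  tree
}

#' Fit kinetics from a CSV file
#'
#' @param csv Kinetics CSV path (columns `substrate_mM`, `rate`, optional
#'   `replicate`) or a data frame.
#' @param E0 Enzyme concentration in uM.
#' @param substrate Optional substrate label.
#' @param out_json Optional JSON output path for the full fit.
#' @return An `mm_fit`.
#' @export
kinetics_from_csv <- function(csv, E0, substrate = NULL, out_json = NULL) {
  df <- if (is.character(csv)) read_kinetics_csv(csv) else csv
  fit <- fit_michaelis_menten(df, E0 = E0, substrate = substrate)
  if (!is.null(out_json)) mm_fit_json(fit, out_json)
  fit
}

#' Write a bundle of synthetic fixtures
#'
#' Generates a small self-consistent fixture set: pattern positives and
#' negatives (FASTA), a covarying alignment and a clade alignment (aligned
#' FASTA), kinetics measurements (CSV) and profiling tables (TSV), all
#' derived deterministically from one seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_positive,n_negative Sequence counts for the classification
#'   fixture.
#' @return Named character vector of the files written, invisibly.
#' @export
simulate_fixtures <- function(dir, seed = 1L, n_positive = 5L, n_negative = 15L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pat <- nadd_pattern()
  pos <- vapply(seq_len(n_positive), function(i)
    unname(make_pattern_positive(pat, flank_length = 20L, seed = seed + i)),
    character(1))
  neg <- vapply(seq_len(n_negative), function(i)
    unname(make_pattern_negative(pat, seed = seed + 1000L + i)),
    character(1))
  seqs <- stats::setNames(c(pos, neg),
                          c(sprintf("pos%02d", seq_len(n_positive)),
                            sprintf("neg%02d", seq_len(n_negative))))
  files <- c(sequences = file.path(dir, "sequences.fasta"),
             covarying = file.path(dir, "covarying.afa"),
             clades = file.path(dir, "clades.afa"),
             kinetics = file.path(dir, "kinetics.csv"),
             lineages = file.path(dir, "lineages.tsv"),
             domains = file.path(dir, "domains.tsv"))
  write_fasta(seqs, files["sequences"])
  write_fasta(make_covarying_msa(seed = seed)$seqs, files["covarying"])
  write_fasta(make_clade_msa(seed = seed)$seqs, files["clades"])
  kin <- make_mm_data(seed = seed)
  utils::write.csv(kin, files["kinetics"], row.names = FALSE, quote = FALSE)
  prof <- make_profiling_tables(
    c("NUDIX-like_zf-NADH-PPase_NUDIX" = 11, "NUDIX-like_NUDIX" = 7,
      "NUDIX" = 2),
    list(Fungi = list(Ascomycota = 14, Basidiomycota = 4), Metazoa = 2),
    seed = seed)
  write_tsv(prof$lineages, files["lineages"], list(cmd = "simulate"))
  write_tsv(prof$domains, files["domains"], list(cmd = "simulate"))
  invisible(files)
}
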