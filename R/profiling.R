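# Taxonomy and domain-architecture profiling -----------------------------

#' Read a per-sequence lineage table
#'
#' Accepts either a wide TSV (`sequence_id` plus one column per rank) or a
#' two-column TSV with a single semicolon-delimited `lineage` column, in
#' which case `ranks` names the levels in order.
#'
#' @param path TSV path with a header row.
#' @param ranks Rank names used to split a semicolon-delimited lineage
#'   column; ignored for wide tables.
#' @return Data frame with `sequence_id` and one character column per rank.
#' @export
read_lineages <- function(path, ranks = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"sequence_id" %in% names(df))
    stop("lineage table must have a 'sequence_id' column")
  if ("lineage" %in% names(df)) {
    parts <- strsplit(df$lineage, ";", fixed = TRUE)
    depth <- max(lengths(parts))
    if (is.null(ranks)) ranks <- paste0("rank", seq_len(depth))
    if (length(ranks) < depth)
      stop("lineage strings deeper than the supplied rank names")
    mat <- t(vapply(parts, function(p) {
      p <- trimws(p)
      c(p, rep(NA_character_, depth - length(p)))
    }, character(depth)))
    out <- data.frame(sequence_id = df$sequence_id, stringsAsFactors = FALSE)
    out[ranks[seq_len(depth)]] <- as.data.frame(mat, stringsAsFactors = FALSE)
    out
  } else {
    df
  }
}

#' Read a Pfam-style domain-hit table
#'
#' @param path TSV with header columns `sequence_id`, `domain_name`,
#'   `start`, `end` and optionally `score`.
#' @return Data frame of domain hits (1-based inclusive coordinates).
#' @export
read_domain_hits <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sequence_id", "domain_name", "start", "end")
  if (!all(need %in% names(df)))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  if (!"score" %in% names(df)) df$score <- NA_real_
  if (any(df$start > df$end)) stop("domain hit with start > end")
  df
}

#' Domain-architecture string of one protein
#'
#' Orders a protein's domain hits by start coordinate and joins their names
#' with `"_"` (e.g. the canonical NADD architecture
#' `"NUDIX-like_zf-NADH-PPase_NUDIX"`).  Conflicting hits — overlapping by
#' more than `overlap_frac` of the shorter hit's length — are resolved
#' greedily: the higher-scoring hit is kept; score ties go to the longer
#' hit, remaining ties to the smaller start.  Repeated adjacent identical
#' domains are kept as-is (Pfam repeat families such as Ank_2 are distinct
#' names, not counts).
#'
#' @param hits Data frame of hits for ONE sequence: `domain_name`, `start`,
#'   `end`, optional `score`.
#' @param overlap_frac Overlap tolerance as a fraction of the shorter hit.
#' @return Single architecture string.
#' @examples
#' architecture_of(data.frame(domain_name = c("NUDIX-like", "zf-NADH-PPase", "NUDIX"),
#'                            start = c(10, 95, 130), end = c(90, 125, 250)))
#' @export
architecture_of <- function(hits, overlap_frac = 0.30) {
  if (is.null(hits) || nrow(hits) == 0L) stop("no domain hits supplied")
  if (!"score" %in% names(hits)) hits$score <- NA_real_
  sc <- ifelse(is.na(hits$score), -Inf, hits$score)
  len <- hits$end - hits$start + 1L
  ord <- order(-sc, -len, hits$start)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
      if (ov > overlap_frac * min(len[i], len[j])) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept <- kept[order(hits$start[kept])]
  paste(hits$domain_name[kept], collapse = "_")
}

#' Architecture distribution table
#'
#' Counts and percentages per architecture string, descending by count
#' (ties by name).  Percentages follow the reporting convention: one decimal
#' half away from zero, two decimals when the value is below 1.
#'
#' @param architectures Character vector of architecture strings (one per
#'   sequence).
#' @return Data frame `architecture`, `count`, `percent` (raw),
#'   `percent_rounded`.
#' @export
tabulate_architectures <- function(architectures) {
  if (!length(architectures)) stop("empty architecture list")
  tab <- table(architectures)
  out <- data.frame(architecture = names(tab),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$architecture), , drop = FALSE]
  out$percent <- 100 * out$count / sum(out$count)
  out$percent_rounded <- round_percent(out$percent)
  rownames(out) <- NULL
  out
}

# one decimal half away from zero; two decimals for values under 1
# (reproduces printed values like 3.2, 0.24 and 0.07)
round_percent <- function(x) {
  ifelse(abs(x) < 1, round_half_away(x, 2L), round_half_away(x, 1L))
}

#' Taxonomy rollup of classified sequences
#'
#' Counts NADD-positive sequences per taxon at each requested lineage rank.
#' Each row reports the count, the percentage of its parent taxon at the
#' previous rank, and the percentage of all positives; positives without a
#' lineage are rolled up under `"unassigned"`.  Rows are ordered rank by
#' rank, descending count then name.
#'
#' @param classification Data frame with `sequence_id` and logical
#'   `is_nadd` (e.g. from [batch_classify()]); only positives are counted.
#' @param lineages Data frame from [read_lineages()].
#' @param ranks Character vector of rank column names, outermost first.
#' @return Data frame `rank`, `taxon`, `parent`, `count`,
#'   `percent_of_parent`, `percent_of_total`, plus rounded display columns.
#' @examples
#' cls <- data.frame(sequence_id = c("a", "b", "c"), is_nadd = TRUE)
#' lin <- data.frame(sequence_id = c("a", "b", "c"),
#'                   kingdom = "Fungi", phylum = "Ascomycota")
#' taxonomy_rollup(cls, lin, ranks = c("kingdom", "phylum"))
#' @export
taxonomy_rollup <- function(classification, lineages,
                            ranks = setdiff(names(lineages), "sequence_id")) {
  stopifnot(all(c("sequence_id", "is_nadd") %in% names(classification)))
  pos <- classification$sequence_id[as.logical(classification$is_nadd)]
  n_total <- length(pos)
  if (!n_total) stop("no positive sequences to roll up")
  missing_ranks <- setdiff(ranks, names(lineages))
  if (length(missing_ranks))
    stop("ranks not found in lineage table: ", paste(missing_ranks, collapse = ", "))
  lin <- lineages[match(pos, lineages$sequence_id), ranks, drop = FALSE]
  lin[] <- lapply(lin, function(x) {
    x <- as.character(x)
    x[is.na(x) | !nzchar(x)] <- "unassigned"
    x
  })
  rows <- list()
  for (k in seq_along(ranks)) {
    key <- do.call(paste, c(lin[seq_len(k)], sep = "\r"))
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    taxon <- vapply(parts, function(p) p[k], character(1))
    parent <- if (k == 1L) rep("total", length(tab))
              else vapply(parts, function(p) p[k - 1L], character(1))
    parent_count <- if (k == 1L) rep(n_total, length(tab))
    else {
      pkey <- vapply(parts, function(p) paste(p[seq_len(k - 1L)], collapse = "\r"),
                     character(1))
      ptab <- table(do.call(paste, c(lin[seq_len(k - 1L)], sep = "\r")))
      as.integer(ptab[pkey])
    }
    df <- data.frame(rank = ranks[k], taxon = taxon, parent = parent,
                     count = as.integer(tab),
                     percent_of_parent = 100 * as.integer(tab) / parent_count,
                     percent_of_total = 100 * as.integer(tab) / n_total,
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$taxon), , drop = FALSE]
    rows[[k]] <- df
  }
  out <- do.call(rbind, rows)
  out$percent_of_parent_rounded <- round_percent(out$percent_of_parent)
  out$percent_of_total_rounded <- round_percent(out$percent_of_total)
  rownames(out) <- NULL
  attr(out, "n_total") <- n_total
  out
}
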