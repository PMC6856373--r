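# Brute-force regex-translation scanning oracle: for every start position,
# test every candidate length between the pattern's min and max span by
# anchored regex on the substring.  Independent of the backtracking engine.
oracle_scan_all <- function(pattern, sequence) {
  if (!inherits(pattern, "prosite_pattern")) pattern <- parse_prosite(pattern)
  rx <- paste0("^", sub("\\$$", "", sub("^\\^", "", prosite_to_regex(pattern))), "$")
  s <- toupper(sequence)
  L <- nchar(s)
  lo <- min_span(pattern)
  hi <- max_span(pattern)
  starts <- if (isTRUE(attr(pattern, "anchored_n"))) 1L else seq_len(L)
  res <- list()
  for (p in starts) {
    lens <- lo:min(hi, L - p + 1L)
    lens <- lens[lens >= lo]
    if (!length(lens)) next
    ends <- p + lens - 1L
    if (isTRUE(attr(pattern, "anchored_c"))) ends <- ends[ends == L]
    if (!length(ends)) next
    hit <- ends[grepl(rx, substring(s, p, ends), perl = TRUE)]
    if (length(hit))
      res[[length(res) + 1L]] <- data.frame(start = p, end = hit)
  }
  if (!length(res)) return(data.frame(start = integer(0), end = integer(0)))
  out <- do.call(rbind, res)
  out[order(out$start, out$end), , drop = FALSE]
}

# uniform random protein sequence over the 20 standard residues
random_protein <- function(len) {
  paste(sample(naddkit:::AA20, len, replace = TRUE), collapse = "")
}

# random small Prosite pattern (mix of element kinds and repeats)
random_small_pattern <- function(max_elements = 4L) {
  k <- sample(2:max_elements, 1L)
  els <- vapply(seq_len(k), function(i) {
    kind <- sample(c("exact", "class", "negated", "wildcard"), 1L,
                   prob = c(0.35, 0.25, 0.1, 0.3))
    core <- switch(kind,
      exact = sample(naddkit:::AA20, 1L),
      class = paste0("[", paste(sample(naddkit:::AA20, sample(2:4, 1L)),
                                collapse = ""), "]"),
      negated = paste0("{", paste(sample(naddkit:::AA20, sample(1:2, 1L)),
                                  collapse = ""), "}"),
      wildcard = "x")
    rep <- sample(c("", "(2)", "(1,3)", "(2,4)"), 1L,
                  prob = c(0.5, 0.15, 0.15, 0.2))
    paste0(core, rep)
  }, character(1))
  paste(els, collapse = "-")
}
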