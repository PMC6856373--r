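# 20 standard one-letter amino-acid codes, alphabetical
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ambiguity codes accepted in sequences: X (any), B (D/N), Z (E/Q),
# U (Sec), O (Pyl).  They are matched only by wildcard elements.
AA_AMBIG <- c("X", "B", "Z", "U", "O")
AA_ALPHABET <- c(AA20, AA_AMBIG)

#' Parse a Prosite-syntax pattern
#'
#' Parses a motif written in Prosite pattern syntax into an ordered list of
#' elements, each an exact residue, a residue class `[...]`, a negated class
#' `{...}` or a wildcard `x`, optionally carrying a repeat count `(n)` or
#' repeat range `(n,m)`.
#'
#' Two spellings are accepted and give identical results: the canonical
#' Prosite dialect with `-` separators, an optional trailing `.` and optional
#' `<`/`>` terminal anchors, and the compact dialect with no separators
#' (as motifs are usually printed in articles).
#'
#' @param text Pattern string, e.g. `"G-x(5)-E"` or `"Gx(5)E"`.
#' @return An object of class `prosite_pattern`: a list of elements, each a
#'   list with `kind` (one of `"exact"`, `"class"`, `"negated"`,
#'   `"wildcard"`), `residues` (character vector, empty for wildcards),
#'   `min` and `max` repeat counts.  Attributes `source_text`, `anchored_n`
#'   and `anchored_c` record the original spelling and anchoring.
#' @examples
#' p <- parse_prosite("[CS]-x(2)-[CD]")
#' length(p)
#' min_span(p)
#' @seealso [scan_prosite()], [prosite_to_regex()], [nadd_pattern()]
#' @export
parse_prosite <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("pattern text must be a single non-empty string")
  src <- text
  s <- gsub("[-[:space:]]", "", text)
  s <- sub("\\.$", "", s)
  anchored_n <- FALSE
  anchored_c <- FALSE
  if (startsWith(s, "<")) {
    anchored_n <- TRUE
    s <- substring(s, 2L)
  }
  if (endsWith(s, ">")) {
    anchored_c <- TRUE
    s <- substring(s, 1L, nchar(s) - 1L)
  }
  if (!nzchar(s)) stop("pattern contains no elements")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  elements <- list()
  i <- 1L
  n <- length(chars)
  read_class <- function(open, close) {
    j <- i + 1L
    while (j <= n && chars[j] != close) {
      if (chars[j] %in% c("[", "{", "(")) stop("unbalanced brackets in pattern: ", src)
      j <- j + 1L
    }
    if (j > n) stop("unbalanced brackets in pattern: ", src)
    body <- chars[(i + 1L):(j - 1L)]
    if (i + 1L > j - 1L || !length(body)) stop("empty class '", open, close, "' in pattern: ", src)
    if (!all(body %in% AA20))
      stop("class contains non-standard residue letter(s): ",
           paste(setdiff(body, AA20), collapse = ""))
    i <<- j + 1L
    unique(body)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      res <- read_class("[", "]")
      el <- list(kind = "class", residues = res, min = 1L, max = 1L)
    } else if (ch == "{") {
      res <- read_class("{", "}")
      el <- list(kind = "negated", residues = res, min = 1L, max = 1L)
    } else if (ch == "x") {
      el <- list(kind = "wildcard", residues = character(0), min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch %in% AA20) {
      el <- list(kind = "exact", residues = ch, min = 1L, max = 1L)
      i <- i + 1L
    } else if (ch %in% c("<", ">")) {
      stop("anchor '", ch, "' allowed only at the pattern ends")
    } else if (ch == "(") {
      stop("repeat count must follow an element (or an anchor carries a repeat): ", src)
    } else {
      stop("unknown character '", ch, "' in pattern: ", src)
    }
    # optional repeat (n) or (n,m) attaches to the element just read
    if (i <= n && chars[i] == "(") {
      j <- i + 1L
      while (j <= n && chars[j] != ")") j <- j + 1L
      if (j > n) stop("unbalanced parentheses in pattern: ", src)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      if (!grepl("^[0-9]+(,[0-9]+)?$", body))
        stop("malformed repeat '(", body, ")' in pattern: ", src)
      parts <- as.integer(strsplit(body, ",", fixed = TRUE)[[1]])
      mn <- parts[1]
      mx <- if (length(parts) == 2L) parts[2] else parts[1]
      if (mn < 1L) stop("repeat minimum must be >= 1: (", body, ")")
      if (mn > mx) stop("inverted repeat range '(", body, ")' (min > max)")
      el$min <- mn
      el$max <- mx
      i <- j + 1L
    }
    elements[[length(elements) + 1L]] <- el
  }
  if (!length(elements)) stop("pattern contains no elements")
  structure(elements,
            class = "prosite_pattern",
            source_text = src,
            anchored_n = anchored_n,
            anchored_c = anchored_c)
}

#' Minimum and maximum span of a pattern
#'
#' The shortest and longest sequence stretch a pattern can cover: the sums of
#' the per-element minimum and maximum repeat counts.
#'
#' @param pattern A `prosite_pattern`.
#' @return Integer length of the shortest (`min_span`) or longest
#'   (`max_span`) possible match.
#' @examples
#' min_span(nadd_pattern())  # 99
#' max_span(nadd_pattern())  # 147
#' @export
min_span <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  sum(vapply(pattern, function(e) e$min, integer(1)))
}

#' @rdname min_span
#' @export
max_span <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  sum(vapply(pattern, function(e) e$max, integer(1)))
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("Prosite pattern: ", attr(x, "source_text"), "\n", sep = "")
  cat("  elements: ", length(x),
      "; span: ", min_span(x), "-", max_span(x), " aa", sep = "")
  if (isTRUE(attr(x, "anchored_n"))) cat("; N-anchored")
  if (isTRUE(attr(x, "anchored_c"))) cat("; C-anchored")
  cat("\n")
  invisible(x)
}

#' @export
format.prosite_pattern <- function(x, ...) attr(x, "source_text")

#' Translate a pattern to a regular expression
#'
#' Element-by-element translation of a parsed Prosite pattern to a regular
#' expression over the accepted sequence alphabet: wildcards become `.`
#' (so ambiguity codes X/B/Z/U/O are matched), classes become character
#' sets, negated classes become sets that also exclude the ambiguity codes
#' (ambiguity codes never satisfy a class, a negated class, or an exact
#' residue), and repeats become bounded quantifiers.  The translation is
#' used as the brute-force scanning oracle in the test suite and for
#' interoperability with external regex tools.
#'
#' @param pattern A `prosite_pattern`.
#' @param lazy If `TRUE`, quantifiers are emitted lazy (`{n,m}?`); the
#'   default is greedy.  Irrelevant when matching is anchored on both ends.
#' @return A single regex string.  Terminal anchors translate to `^`/`$`.
#' @export
prosite_to_regex <- function(pattern, lazy = FALSE) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  piece <- vapply(pattern, function(e) {
    core <- switch(e$kind,
      wildcard = ".",
      exact    = e$residues,
      class    = paste0("[", paste(e$residues, collapse = ""), "]"),
      negated  = paste0("[^", paste(c(e$residues, AA_AMBIG), collapse = ""), "]"))
    q <- if (e$min == 1L && e$max == 1L) ""
         else if (e$min == e$max) sprintf("{%d}", e$min)
         else sprintf("{%d,%d}", e$min, e$max)
    if (nzchar(q) && lazy && e$min != e$max) q <- paste0(q, "?")
    paste0(core, q)
  }, character(1))
  paste0(if (isTRUE(attr(pattern, "anchored_n"))) "^" else "",
         paste(piece, collapse = ""),
         if (isTRUE(attr(pattern, "anchored_c"))) "$" else "")
}

# residue match table: for each element, which alphabet characters satisfy it.
# X/B/Z/U/O satisfy only wildcards (conservative: avoids false positive calls
# on ambiguous residues).
element_match_vector <- function(e) {
  ok <- switch(e$kind,
    wildcard = rep(TRUE, length(AA_ALPHABET)),
    exact    = AA_ALPHABET %in% e$residues,
    class    = AA_ALPHABET %in% e$residues,
    negated  = !(AA_ALPHABET %in% e$residues) & AA_ALPHABET %in% AA20)
  names(ok) <- AA_ALPHABET
  ok
}

validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single string")
  s <- toupper(sequence)
  if (!nzchar(s)) stop("empty sequence")
  codes <- match(strsplit(s, "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (anyNA(codes))
    stop("sequence contains characters outside the accepted alphabet (",
         paste(AA_ALPHABET, collapse = ""), ")")
  codes
}

# Reachability engine.  reach(k, p) = set of end-exclusive positions after
# matching elements k..K starting at residue p; memoised across starts, so a
# whole-sequence scan shares one table.  Per-element run lengths are
# precomputed from cumulative sums of the match indicator, making each
# variable repeat a single range union rather than a character loop.
make_matcher <- function(pattern, codes) {
  K <- length(pattern)
  L <- length(codes)
  # csum[[k]][p+1] = number of residues in 1..p satisfying element k
  csum <- lapply(pattern, function(e) {
    ok <- element_match_vector(e)[codes]
    c(0L, cumsum(as.integer(ok)))
  })
  memo <- new.env(parent = emptyenv(), size = 4L * (K + 1L) * (L + 2L))
  reach <- function(k, p) {
    if (k > K) return(p)
    if (p > L + 1L) return(integer(0))
    key <- sprintf("%d.%d", k, p)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    e <- pattern[[k]]
    cs <- csum[[k]]
    # longest run of matching residues starting at p
    rmax <- min(e$max, L - p + 1L)
    if (rmax >= 1L) {
      run <- cs[p + rmax] - cs[p]
      if (run < rmax) {
        # binary-free shrink: run length = count of consecutive matches
        r <- 0L
        while (r < rmax && cs[p + r + 1L] - cs[p + r] == 1L) r <- r + 1L
        rmax <- r
      }
    }
    out <- integer(0)
    if (rmax >= e$min) {
      for (r in e$min:rmax) out <- c(out, reach(k + 1L, p + r))
      out <- unique.default(out)
    }
    memo[[key]] <- out
    out
  }
  list(reach = reach, K = K, L = L)
}

#' Scan a protein sequence with a Prosite pattern
#'
#' Finds occurrences of a pattern in one sequence.  Variable-length repeats
#' are matched by bounded backtracking with memoisation; every reported span
#' satisfies the element list in order.
#'
#' @param pattern A `prosite_pattern` or a pattern string (parsed on the fly).
#' @param sequence A single protein sequence string; matching is
#'   case-insensitive (the sequence is uppercased), and characters must lie
#'   in the accepted alphabet: the 20 standard residues plus X, B, Z, U, O.
#' @param mode One of `"greedy"` (default; per matching start, the longest
#'   valid end — mirrors ScanProsite's one-match-per-position reporting),
#'   `"lazy"` (shortest valid end) or `"all"` (every distinct start/end pair).
#' @param sequence_id Identifier copied into the result rows.
#' @return A data frame with columns `sequence_id`, `start`, `end` (1-based,
#'   inclusive) and `matched_seq`, sorted by (start, end); zero rows when the
#'   pattern does not occur.
#' @examples
#' scan_prosite(nudix_box(), "GAAAAAEAAAAAAAREIAEEAGV")
#' @export
scan_prosite <- function(pattern, sequence, mode = c("greedy", "lazy", "all"),
                         sequence_id = "seq") {
  if (!inherits(pattern, "prosite_pattern")) pattern <- parse_prosite(pattern)
  mode <- match.arg(mode)
  codes <- validate_sequence(sequence)
  s <- toupper(sequence)
  L <- length(codes)
  m <- make_matcher(pattern, codes)
  starts <- if (isTRUE(attr(pattern, "anchored_n"))) 1L else seq_len(L)
  res_start <- integer(0)
  res_end <- integer(0)
  for (p in starts) {
    ends <- m$reach(1L, p)
    if (isTRUE(attr(pattern, "anchored_c"))) ends <- ends[ends == L + 1L]
    if (!length(ends)) next
    ends <- sort.int(ends)
    pick <- switch(mode,
                   greedy = ends[length(ends)],
                   lazy = ends[1L],
                   all = ends)
    res_start <- c(res_start, rep.int(p, length(pick)))
    res_end <- c(res_end, pick - 1L)
  }
  data.frame(sequence_id = rep.int(sequence_id, length(res_start)),
             start = res_start,
             end = res_end,
             matched_seq = if (length(res_start))
               substring(s, res_start, res_end) else character(0),
             stringsAsFactors = FALSE)
}

# Per-element position trace of one match.  Among repeat assignments that
# land exactly on `end`, earlier elements take as many residues as possible
# (leftmost-greedy), giving a deterministic trace.  Returns a data frame with
# one row per element: element index, kind, start, end of the block it
# consumed.
trace_match <- function(pattern, sequence, start, end) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  codes <- validate_sequence(sequence)
  m <- make_matcher(pattern, codes)
  target <- end + 1L
  K <- length(pattern)
  starts_at <- integer(K)
  reps <- integer(K)
  p <- start
  for (k in seq_len(K)) {
    e <- pattern[[k]]
    found <- FALSE
    for (r in rev(seq.int(e$min, e$max))) {
      if (p + r > target) next
      # element must actually match r residues here
      ok <- m$reach(k, p)          # ensures memo filled
      nxt <- m$reach(k + 1L, p + r)
      cs_ok <- all(element_match_vector(e)[codes[seq.int(p, length.out = r)]])
      if (cs_ok && target %in% nxt) {
        starts_at[k] <- p
        reps[k] <- r
        p <- p + r
        found <- TRUE
        break
      }
    }
    if (!found) stop("no match of the pattern at [", start, ", ", end, "]")
  }
  data.frame(element = seq_len(K),
             kind = vapply(pattern, function(e) e$kind, character(1)),
             start = starts_at,
             end = starts_at + reps - 1L,
             stringsAsFactors = FALSE)
}
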