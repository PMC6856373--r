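# Motif catalog ---------------------------------------------------------
#
# The designed NADD detection pattern covers the region from the first
# zinc-coordinating cysteine to the conserved methionine of the nicotinamide
# pocket (C98-M201 in EcNudC numbering): the zinc-binding domain
# [CS]x(2)[CD]x(12,15)[CN]x(5,35)[YF], conserved N-terminal-domain residues,
# the Nudix box GFx(4)Ex(7)REx(2)EE and the core of the NADD signature
# Q[PQ]W[PA]xP.
NADD_PATTERN_TEXT <-
  "[CS]x(2)[CD]x(12,15)[CN]x(5,35)[YF]Px(3)Px(2)Ix(25,32)GFx(4)Ex(7)REx(2)EEx(13,14)Q[PQ]W[PA]xPx(2,9)[QLIMA]M"

# The catalytic Nudix box GX5EX7REUXEEXGU, with the bulky hydrophobic U
# positions written as [ILV]; fixed length 23.
NUDIX_BOX_TEXT <- "G-x(5)-E-x(7)-R-E-[ILV]-x-E-E-x-G-[ILV]"

# Eight-residue NADD signature array (full form, length 9 including its
# wildcard) and the core used inside the detection pattern.
NADD_SIGNATURE_FULL_TEXT <- "S-Q-P-W-P-F-P-x-S"
NADD_SIGNATURE_CORE_TEXT <- "Q-[PQ]-W-[PA]-x-P"

#' Bundled NADD motifs
#'
#' Parsed forms of the motifs used by the NADD classifier: the full designed
#' detection pattern (`nadd_pattern()`, 33 elements, spanning 99-147
#' residues), the Nudix box (`nudix_box()`, fixed length 23), and the NADD
#' signature in full (`nadd_signature_full()`, fixed length 9) and core
#' (`nadd_signature_core()`) forms.
#'
#' @return A `prosite_pattern`.
#' @examples
#' nadd_pattern()
#' @export
nadd_pattern <- function() parse_prosite(NADD_PATTERN_TEXT)

#' @rdname nadd_pattern
#' @export
nudix_box <- function() parse_prosite(NUDIX_BOX_TEXT)

#' @rdname nadd_pattern
#' @export
nadd_signature_full <- function() parse_prosite(NADD_SIGNATURE_FULL_TEXT)

#' @rdname nadd_pattern
#' @export
nadd_signature_core <- function() parse_prosite(NADD_SIGNATURE_CORE_TEXT)

# look up a named motif or parse free pattern text
resolve_pattern <- function(pattern) {
  if (inherits(pattern, "prosite_pattern")) return(pattern)
  stopifnot(is.character(pattern), length(pattern) == 1L)
  switch(tolower(pattern),
         nadd = nadd_pattern(),
         nudix_box = nudix_box(),
         signature_full = nadd_signature_full(),
         signature_core = nadd_signature_core(),
         parse_prosite(pattern))
}

#' Classify one protein sequence as NADD
#'
#' A sequence is called NADD iff the designed detection pattern matches at
#' least once (any match; scan mode cannot change the verdict because only
#' existence is used).  For positives the first greedy match is reported,
#' together with the three zinc-coordinating positions traced from pattern
#' elements 1, 3 and 5 (the `[CS]`/`[CD]`/`[CN]` positions; the fourth
#' zinc-coordinating cysteine of the EcNudC structure is not a pattern
#' element and is not reported).  The Nudix box and the signature core are
#' located independently of the verdict.
#'
#' @param sequence Protein sequence string (or named length-1 vector; the
#'   name is used as the sequence id).
#' @param sequence_id Identifier; defaults to the name of `sequence`.
#' @return A list of class `nadd_annotation`: `sequence_id`, `is_nadd`,
#'   `nadd_span` (data frame row or `NULL`), `zinc_positions` (integer
#'   vector of length 3 or `NULL`), `nudix_box_span`, `signature_core_span`.
#' @examples
#' pos <- make_pattern_positive(nadd_pattern(), flank_length = 0, seed = 1)
#' classify_nadd(pos)$is_nadd
#' @export
classify_nadd <- function(sequence, sequence_id = NULL) {
  if (is.null(sequence_id))
    sequence_id <- if (!is.null(names(sequence))) names(sequence)[1] else "seq"
  sequence <- toupper(unname(sequence[1]))
  pat <- nadd_pattern()
  hits <- scan_prosite(pat, sequence, mode = "greedy", sequence_id = sequence_id)
  is_nadd <- nrow(hits) > 0L
  nadd_span <- NULL
  zinc <- NULL
  if (is_nadd) {
    nadd_span <- hits[1L, , drop = FALSE]
    tr <- trace_match(pat, sequence, nadd_span$start, nadd_span$end)
    zinc <- tr$start[c(1L, 3L, 5L)]
  }
  box <- scan_prosite(nudix_box(), sequence, mode = "greedy",
                      sequence_id = sequence_id)
  sig <- scan_prosite(nadd_signature_core(), sequence, mode = "greedy",
                      sequence_id = sequence_id)
  structure(list(sequence_id = sequence_id,
                 is_nadd = is_nadd,
                 nadd_span = nadd_span,
                 zinc_positions = zinc,
                 nudix_box_span = if (nrow(box)) box[1L, , drop = FALSE] else NULL,
                 signature_core_span = if (nrow(sig)) sig[1L, , drop = FALSE] else NULL),
            class = "nadd_annotation")
}

#' @export
print.nadd_annotation <- function(x, ...) {
  cat(x$sequence_id, ": ", if (x$is_nadd) "NADD" else "not NADD", sep = "")
  if (x$is_nadd)
    cat(sprintf(" [%d-%d]; zinc positions %s",
                x$nadd_span$start, x$nadd_span$end,
                paste(x$zinc_positions, collapse = ", ")))
  cat("\n")
  invisible(x)
}

annotation_row <- function(a) {
  data.frame(sequence_id = a$sequence_id,
             is_nadd = a$is_nadd,
             nadd_start = if (a$is_nadd) a$nadd_span$start else NA_integer_,
             nadd_end = if (a$is_nadd) a$nadd_span$end else NA_integer_,
             zinc_pos1 = if (a$is_nadd) a$zinc_positions[1] else NA_integer_,
             zinc_pos2 = if (a$is_nadd) a$zinc_positions[2] else NA_integer_,
             zinc_pos3 = if (a$is_nadd) a$zinc_positions[3] else NA_integer_,
             nudix_box_start = if (!is.null(a$nudix_box_span)) a$nudix_box_span$start else NA_integer_,
             signature_start = if (!is.null(a$signature_core_span)) a$signature_core_span$start else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Classify every sequence of a FASTA file
#'
#' @param fasta Path to a FASTA file, or a named character vector of
#'   sequences.
#' @return A data frame (class `nadd_classification`) with one row per
#'   sequence: `sequence_id`, `is_nadd`, `nadd_start`, `nadd_end`,
#'   `zinc_pos1..3`, `nudix_box_start`, `signature_start`.  Attributes
#'   `n_total`, `n_matched` and `percent` (the matched rate, one decimal)
#'   summarise the run.
#' @export
batch_classify <- function(fasta) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && is.null(names(fasta)))
    read_fasta(fasta) else fasta
  if (!length(seqs)) stop("no sequences to classify")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  rows <- lapply(names(seqs), function(id)
    annotation_row(classify_nadd(seqs[[id]], sequence_id = id)))
  out <- do.call(rbind, rows)
  attr(out, "n_total") <- nrow(out)
  attr(out, "n_matched") <- sum(out$is_nadd)
  attr(out, "percent") <- summarize_rate(sum(out$is_nadd), nrow(out))
  class(out) <- c("nadd_classification", "data.frame")
  out
}

#' @export
print.nadd_classification <- function(x, ...) {
  cat(sprintf("NADD classification: %d/%d sequences matched (%.1f%%)\n",
              attr(x, "n_matched"), attr(x, "n_total"), attr(x, "percent")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Matched-sequence rate as a printed percentage
#'
#' `100 * n_matched / n_total`, rounded half away from zero to one decimal —
#' the reporting convention used for subfamily abundances (e.g. 7479 of
#' 234112 sequences is reported as 3.2).
#'
#' @param n_matched,n_total Non-negative counts, `n_total > 0`.
#' @return Numeric percentage with one decimal.
#' @examples
#' summarize_rate(7479, 234112)  # 3.2
#' summarize_rate(478, 7479)     # 6.4
#' @export
summarize_rate <- function(n_matched, n_total) {
  if (length(n_total) != 1L || is.na(n_total) || n_total <= 0)
    stop("n_total must be a positive count")
  if (any(n_matched < 0) || any(n_matched > n_total))
    stop("n_matched must lie in [0, n_total]")
  round_half_away(100 * n_matched / n_total, 1L)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
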