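# Seeded synthetic-data generators ---------------------------------------
#
# Every generator is deterministic under a fixed seed and leaves the
# caller's RNG state untouched.  Pattern positives/negatives verify
# themselves against the pattern engine before being returned.

# run code under a temporary RNG state; restores .Random.seed afterwards
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

sample_residue_for <- function(e) {
  pool <- switch(e$kind,
    exact    = e$residues,
    class    = e$residues,
    negated  = setdiff(AA20, e$residues),
    wildcard = AA20)
  if (length(pool) == 1L) pool else sample(pool, 1L)
}

# construct one conforming instance of a pattern; returns the string plus
# the per-element start positions (for targeted mutation)
build_pattern_instance <- function(pattern, minimal = FALSE) {
  starts <- integer(length(pattern))
  parts <- character(length(pattern))
  pos <- 1L
  for (k in seq_along(pattern)) {
    e <- pattern[[k]]
    r <- if (minimal || e$min == e$max) e$min else sample(e$min:e$max, 1L)
    starts[k] <- pos
    parts[k] <- paste(vapply(seq_len(r), function(i) sample_residue_for(e),
                             character(1)), collapse = "")
    pos <- pos + r
  }
  list(core = paste(parts, collapse = ""), starts = starts)
}

#' Generate a pattern-positive sequence
#'
#' Draws a conforming instance of a pattern (uniform choice within classes
#' and repeat ranges) embedded in random flanks, and verifies the match
#' before returning.
#'
#' @param pattern A `prosite_pattern` (or pattern text).
#' @param flank_length Residues of uniform-random flank on each side.
#' @param seed Integer seed.
#' @param id Sequence id.
#' @param minimal If `TRUE`, every repeat takes its minimum (for the NADD
#'   pattern this gives the 99-residue minimal instance).
#' @return Named length-1 character vector (name = id) with attribute
#'   `core_start` (position of the embedded instance).
#' @export
make_pattern_positive <- function(pattern, flank_length = 30L, seed = 1L,
                                  id = "positive", minimal = FALSE) {
  pattern <- resolve_pattern(pattern)
  with_seed(seed, {
    inst <- build_pattern_instance(pattern, minimal = minimal)
    flank <- function(n) if (n > 0L)
      paste(sample(AA20, n, replace = TRUE), collapse = "") else ""
    s <- paste0(flank(flank_length), inst$core, flank(flank_length))
    if (nrow(scan_prosite(pattern, s, mode = "greedy")) == 0L)
      stop("internal error: generated positive does not match")  # nocov
    out <- stats::setNames(s, id)
    attr(out, "core_start") <- flank_length + 1L
    out
  })
}

#' Generate a pattern-negative sequence
#'
#' Builds a positive instance, then mutates one fixed element — an exact
#' residue or a single-repeat class — to a residue outside its class, and
#' verifies that the whole sequence no longer matches anywhere (mutations
#' that still admit an alternative alignment of the variable-length gaps
#' are rejected and retried).
#'
#' @inheritParams make_pattern_positive
#' @param max_tries Attempts before giving up.
#' @return Named length-1 character vector guaranteed not to match.
#' @export
make_pattern_negative <- function(pattern, seed = 1L, id = "negative",
                                  flank_length = 0L, max_tries = 100L) {
  pattern <- resolve_pattern(pattern)
  fixed <- which(vapply(pattern, function(e)
    e$kind %in% c("exact", "class") && e$min == 1L && e$max == 1L, logical(1)))
  if (!length(fixed))
    stop("pattern has no fixed single-repeat element to mutate")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      inst <- build_pattern_instance(pattern)
      k <- if (length(fixed) == 1L) fixed else sample(fixed, 1L)
      off <- inst$starts[k]
      bad_pool <- setdiff(AA20, pattern[[k]]$residues)
      ch <- strsplit(inst$core, "", fixed = TRUE)[[1]]
      ch[off] <- sample(bad_pool, 1L)
      flank <- function(n) if (n > 0L)
        paste(sample(AA20, n, replace = TRUE), collapse = "") else ""
      s <- paste0(flank(flank_length), paste(ch, collapse = ""),
                  flank(flank_length))
      if (nrow(scan_prosite(pattern, s, mode = "greedy")) == 0L)
        return(stats::setNames(s, id))
    }
    stop("could not construct a verified negative in ", max_tries, " tries")
  })
}

#' Generate an alignment with planted covarying column pairs
#'
#' Each planted pair is drawn from a two-state paired alphabet: half the
#' sequences carry one residue pair, half the other, giving perfect
#' covariation between the two columns; all remaining columns are i.i.d.
#' uniform over the 20 residues (optionally some invariant columns).
#'
#' @param n_seqs,n_cols Alignment dimensions.
#' @param planted_pairs List of length-2 integer vectors of column indices.
#' @param seed Integer seed.
#' @param n_invariant Number of additional invariant columns (placed at the
#'   end of the column range, after the planted ones).
#' @return An [msa()]; attribute `planted_pairs` records the pairs.
#' @export
make_covarying_msa <- function(n_seqs = 64L, n_cols = 30L,
                               planted_pairs = list(c(1L, 2L)), seed = 1L,
                               n_invariant = 0L) {
  stopifnot(n_seqs >= 2L, n_cols >= 2L)
  planted <- unlist(planted_pairs)
  stopifnot(!anyDuplicated(planted), all(planted >= 1L), all(planted <= n_cols))
  with_seed(seed, {
    mat <- matrix(sample(AA20, n_seqs * n_cols, replace = TRUE),
                  nrow = n_seqs, ncol = n_cols)
    for (pair in planted_pairs) {
      res <- sample(AA20, 4L)             # (a1, b1) vs (a2, b2)
      state <- sample(rep(1:2, length.out = n_seqs))
      mat[, pair[1L]] <- ifelse(state == 1L, res[1L], res[3L])
      mat[, pair[2L]] <- ifelse(state == 1L, res[2L], res[4L])
    }
    if (n_invariant > 0L) {
      free <- setdiff(seq_len(n_cols), planted)
      inv_cols <- utils::tail(free, n_invariant)
      for (j in inv_cols) mat[, j] <- sample(AA20, 1L)
    }
    seqs <- apply(mat, 1L, paste, collapse = "")
    names(seqs) <- sprintf("seq%03d", seq_len(n_seqs))
    out <- msa(seqs)
    attr(out, "planted_pairs") <- planted_pairs
    out
  })
}

mutate_sequence <- function(chars, n_mut) {
  if (n_mut <= 0L) return(chars)
  pos <- sample(length(chars), min(n_mut, length(chars)))
  for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
  chars
}

#' Generate a clade-structured alignment
#'
#' Builds `n_clades` clades of `n_per_clade` leaves each from a common root
#' sequence: clade ancestors diverge so that between-clade leaf identity is
#' about `between_id`, and each leaf mutates from its ancestor at rate
#' `(1 - within_id) / 2`, so two leaves of the same clade share about
#' `within_id` identity.
#'
#' @param n_per_clade Leaves per clade.
#' @param n_cols Alignment columns.
#' @param within_id Target pairwise identity within a clade.
#' @param between_id Target pairwise identity between clades.
#' @param seed Integer seed.
#' @param n_clades Number of clades (default 2).
#' @return An [msa()] with ids `cladeA_1`, `cladeA_2`, ...; attribute
#'   `clades` maps ids to clades.
#' @export
make_clade_msa <- function(n_per_clade = 5L, n_cols = 200L, within_id = 0.95,
                           between_id = 0.60, seed = 1L, n_clades = 2L) {
  stopifnot(within_id > between_id || within_id == between_id)
  with_seed(seed, {
    root <- sample(AA20, n_cols, replace = TRUE)
    n_between <- round((1 - between_id) * n_cols)
    n_within <- round((1 - within_id) / 2 * n_cols)
    ancestors <- vector("list", n_clades)
    ancestors[[1L]] <- root
    for (c in seq_len(n_clades)[-1L])
      ancestors[[c]] <- mutate_sequence(root, n_between)
    seqs <- character(0)
    clade_of <- character(0)
    for (c in seq_len(n_clades)) {
      tag <- LETTERS[c]
      for (k in seq_len(n_per_clade)) {
        leaf <- mutate_sequence(ancestors[[c]], n_within)
        id <- sprintf("clade%s_%d", tag, k)
        seqs[id] <- paste(leaf, collapse = "")
        clade_of[id] <- tag
      }
    }
    out <- msa(seqs)
    attr(out, "clades") <- clade_of
    out
  })
}

#' Generate noisy Michaelis-Menten data
#'
#' Rates `v = kcat * E0 * S / (KM + S)` with multiplicative Gaussian noise
#' of coefficient of variation `cv`, replicated `n_rep` times per substrate
#' level; negative draws are truncated at zero.
#'
#' @param KM Michaelis constant (mM).
#' @param kcat Turnover number (1/s).
#' @param E0 Enzyme concentration (uM).
#' @param S_grid Substrate concentrations (mM).
#' @param cv Coefficient of variation of the noise (0 = noiseless).
#' @param n_rep Replicates per level.
#' @param seed Integer seed.
#' @return Data frame `substrate_mM`, `rate`, `replicate`, with `E0` and
#'   the generating truth as attributes.
#' @export
make_mm_data <- function(KM = 0.12, kcat = 10.7, E0 = 0.02,
                         S_grid = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5),
                         cv = 0.05, n_rep = 3L, seed = 1L) {
  stopifnot(KM > 0, kcat > 0, E0 > 0, all(S_grid > 0), cv >= 0, n_rep >= 1L)
  Vmax <- kcat * E0
  with_seed(seed, {
    S <- rep(S_grid, each = n_rep)
    mu <- Vmax * S / (KM + S)
    v <- if (cv > 0) pmax(mu * (1 + stats::rnorm(length(mu), sd = cv)), 0) else mu
    out <- data.frame(substrate_mM = S, rate = v,
                      replicate = rep(seq_len(n_rep), times = length(S_grid)))
    attr(out, "E0") <- E0
    attr(out, "truth") <- c(KM = KM, kcat = kcat, Vmax = Vmax)
    out
  })
}

#' Generate linked profiling tables
#'
#' Fabricates a classification table, a Pfam-style domain-hit table and a
#' lineage table consistent with a requested architecture distribution and
#' a nested lineage specification, for exercising the profilers end to end.
#'
#' @param architecture_spec Either a named integer vector (names are
#'   architecture strings joined with `"_"`) or a list of entries
#'   `list(domains = c(...), count = n)` for domain names that themselves
#'   contain underscores.
#' @param lineage_spec Nested named list of counts, e.g.
#'   `list(Fungi = list(Ascomycota = 3, Basidiomycota = 1), Metazoa = 2)`;
#'   leaf values are sequence counts.  Depth must not exceed
#'   `length(ranks)`.
#' @param seed Integer seed (domain coordinates are randomised).
#' @param ranks Rank names for the lineage table columns.
#' @return List of data frames: `classification`, `domains`, `lineages`.
#' @export
make_profiling_tables <- function(architecture_spec, lineage_spec, seed = 1L,
                                  ranks = c("kingdom", "phylum", "class")) {
  entries <- if (is.list(architecture_spec)) architecture_spec
  else lapply(seq_along(architecture_spec), function(i)
    list(domains = strsplit(names(architecture_spec)[i], "_", fixed = TRUE)[[1]],
         count = architecture_spec[[i]]))
  # flatten lineage spec to rows of (rank path, count)
  flatten <- function(spec, path = character(0)) {
    if (!is.list(spec)) return(list(list(path = path, count = spec)))
    do.call(c, lapply(names(spec), function(nm)
      flatten(spec[[nm]], c(path, nm))))
  }
  lin_rows <- flatten(lineage_spec)
  if (max(lengths(lapply(lin_rows, `[[`, "path"))) > length(ranks))
    stop("lineage specification deeper than the supplied ranks")
  n_lin <- sum(vapply(lin_rows, `[[`, numeric(1), "count"))
  n_arch <- sum(vapply(entries, `[[`, numeric(1), "count"))
  with_seed(seed, {
    # domain hits
    dom <- list(); arch_ids <- character(0); idx <- 0L
    for (e in entries) {
      for (r in seq_len(e$count)) {
        idx <- idx + 1L
        id <- sprintf("seq%04d", idx)
        arch_ids <- c(arch_ids, id)
        pos <- 1L
        for (dname in e$domains) {
          len <- sample(40:150, 1L)
          dom[[length(dom) + 1L]] <- data.frame(
            sequence_id = id, domain_name = dname,
            start = pos, end = pos + len - 1L,
            score = round(stats::runif(1, 20, 300), 1))
          pos <- pos + len + sample(5:30, 1L)
        }
      }
    }
    domains <- do.call(rbind, dom)
    # lineages (assigned to the first sequences, cycling if needed)
    all_ids <- sprintf("seq%04d", seq_len(max(n_arch, n_lin)))
    lin <- list(); li <- 0L
    for (row in lin_rows) {
      for (r in seq_len(row$count)) {
        li <- li + 1L
        path <- c(row$path, rep(NA_character_, length(ranks) - length(row$path)))
        lin[[li]] <- data.frame(sequence_id = all_ids[li],
                                t(stats::setNames(path, ranks)))
      }
    }
    lineages <- do.call(rbind, lin)
    classification <- data.frame(sequence_id = all_ids,
                                 is_nadd = TRUE)
    list(classification = classification, domains = domains,
         lineages = lineages)
  })
}
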