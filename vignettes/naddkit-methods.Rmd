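---
title: "naddkit: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{naddkit: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(naddkit)
```

`naddkit` is a toolkit for charting the NADH diphosphatase (NADD)
subfamily of Nudix hydrolases.  This vignette is the package's own account
of the methods it implements: the models and their assumptions, the
parameters that matter, the numerical choices, and what the synthetic
generators do and do not emulate.

## The detection pattern and its matcher

NADDs share the catalytic Nudix box (`GX5EX7REUXEEXGU`, with U a bulky
hydrophobic residue) with the whole superfamily; subfamily identity lies
in additional traits: a zinc-binding domain coordinated by cysteines, and
a conserved eight-residue array (`SQPWPFPXS`) downstream of the box.  The
bundled detection pattern strings these traits into one Prosite-syntax
motif of 33 elements spanning 99–147 residues, anchored at the first
zinc-coordinating position and ending at the conserved methionine of the
nicotinamide pocket:

```{r}
nadd_pattern()
```

**Grammar.**  `parse_prosite()` accepts both the canonical dash-separated
Prosite dialect (optional trailing period, `<`/`>` anchors) and the
compact spelling used when motifs are printed in running text; both parse
to the same element list, and a test asserts scan equivalence.  Classes
may contain only the 20 standard residues.

**Matching semantics.**  Coordinates are 1-based inclusive throughout
(the Prosite/UniProt convention), including in all TSV exports.
Variable repeats are matched by bounded backtracking over repeat counts
with memoisation of reachable positions, so a whole-sequence scan is
linear in sequence length times the number of reachable states; the
worst case is exponential only in the number of variable-repeat elements
(five in the NADD pattern), which is irrelevant at protein scale.  Three
scan modes are offered: `greedy` (default; per matching start position,
the longest valid end — one span per start, mirroring how ScanProsite
reports occurrences), `lazy` (shortest end) and `all` (every distinct
span).  Classification uses match existence only, so the mode cannot
change a verdict; the exact overlapping-match enumeration policy of the
ScanProsite server is not documented, and the greedy default is our
choice, not a claim about the server.

**Ambiguity codes.**  Sequences may contain X, B, Z, U, O.  The
conservative rule is: a wildcard element matches anything in the accepted
alphabet; classes, negated classes and exact residues match only standard
residues.  This avoids calling a sequence NADD on the strength of an
ambiguous position.  The regex translation (`prosite_to_regex()`)
encodes the same rule (negated classes also exclude the ambiguity
codes), which lets a brute-force regex enumeration serve as an
independent oracle for the native scanner: the test suite and the
acceptance script compare the two span-by-span over a seeded corpus.

**Feature tracing.**  For a positive sequence the classifier reports the
first greedy match and the positions consumed by pattern elements 1, 3
and 5 — the `[CS]`/`[CD]`/`[CN]` zinc-coordinating positions.  Among
repeat assignments realising the same span, the trace is leftmost-greedy
(earlier elements take as many residues as possible), which makes the
reported positions deterministic.  The fourth zinc-coordinating cysteine
of the EcNudC structure lies outside the pattern and is deliberately not
reported.  The full signature `SQPWPFPXS` is located for annotation only;
the verdict rests solely on the detection pattern.

## Profiling

Domain architectures are ordered concatenations of Pfam-style domain
names (`NUDIX-like_zf-NADH-PPase_NUDIX` is the canonical NADD
architecture).  Overlapping hits are resolved greedily: two hits conflict
when their overlap exceeds 30% of the shorter hit's length; the
higher-scoring hit wins, score ties go to the longer hit, remaining ties
to the smaller start.  No resolution rule is standard across databases;
this one mirrors common Pfam post-processing and is exposed as a
parameter.  Repeat-family names such as `Ank_2`/`Ank_5` are distinct
family identifiers, not repeat counts, and are never collapsed.

Taxonomy rollups count classified positives per lineage rank and report
each taxon's percentage of its parent and of the total; sequences without
a lineage are rolled up under `unassigned`, so child counts always sum to
parent counts.  Because published tables mix both denominator
conventions, both percentages are emitted, labelled.  Percentages are
rounded half away from zero to one decimal, with two decimals kept for
values below 1 (so 3.195 prints as 3.2 and 0.239 as 0.24, matching how
subfamily abundances are conventionally printed).

## Coevolution statistics

The analyzer reimplements the MISTIC family of alignment statistics in
natural-log units:

- **Sequence weighting.**  Sequences are clustered by single linkage at
  62% pairwise identity (identical positions over positions where both
  sequences are ungapped) and weighted `1/cluster size`, damping
  phylogenetic redundancy.  The threshold is configurable; 0.62 follows
  the published MISTIC protocol.
- **Frequencies.**  Per-column (and per-pair) frequencies are weighted
  and smoothed with a pseudocount mass `lambda = 0.05` spread uniformly;
  gaps and ambiguity codes carry no mass, and columns with weighted gap
  fraction above 0.5 are flagged and excluded from MI.  Pair marginals
  are derived from the joint table, i.e. over the pairwise-complete
  subset.
- **KL conservation** per column: `sum(p * log(p/q))` against a strictly
  positive background `q`, by default the BLOSUM62 marginal amino-acid
  frequencies (configurable).
- **MI z-scores.**  Raw MI uses the weighted, pseudocounted pair
  frequencies.  The null permutes each column's residues independently
  across sequences (`n_shuffles = 100` by default, seeded) and
  `z = (MI - null mean)/null sd`; degenerate pairs with zero null
  variance (e.g. invariant columns) get `z = 0`.  Before the null is
  drawn, rows are put in a canonical order, which makes the seeded
  pipeline bit-reproducible and invariant to the order sequences arrive
  in.  The published figures draw connections at MI score > 6.5 without
  stating the scale; we take the threshold on the z-score, which is the
  scale on which a fixed cutoff is transferable across alignments.
- **cMI and pMI.**  `cMI_i` sums the above-threshold z-scores incident
  to column i; `pMI_i` is the mean cMI of residues in spatial contact
  with i (contact list or distance table cut at a radius, in reference
  numbering when the alignment carries a reference sequence), and is
  absent without structural input.
- **Edge tiers.**  Among edges above the threshold, the top 5% by
  percentile rank are tier `top5`, the 70th–95th percentile band `mid`,
  and the rest `low` — the drawing convention of circos MI figures.

At `lambda = 0` the estimator satisfies the exact identities MI(X,X) =
H(X) and MI symmetry, which the tests assert to 1e-9; with a positive
pseudocount the identities hold only approximately, which is why the
identity checks disable smoothing.

## Phylogeny

Distances are p-distances (mismatches over pairwise-deletion sites) with
an optional Poisson correction `d = -log(1 - p)`.  Maximum-likelihood
JTT distances are deliberately not implemented: they add a full
rate-matrix machinery orthogonal to this toolkit's contribution, and at
the divergence levels involved the recovered topology is robust to the
distance choice.  This is the package's one prominent departure from the
web-server protocol that published NADD trees were built with.

Neighbor joining follows Saitou–Nei with the standard Q-criterion.
Taxa are put in lexicographic order first, and Q-ties are broken by the
lowest index pair in that canonical order, so the output is deterministic
and independent of input order.  Negative branch estimates are handled by
the Kuhner–Felsenstein convention: clamped to zero with the deficit
transferred to the sibling branch, preserving path lengths.  On additive
matrices the implementation recovers topology and branch lengths exactly
(asserted against path-length matrices and against `ape::nj` as an
independent cross-check).  Bootstrap support is the standard Felsenstein
column bootstrap: columns resampled with replacement, the NJ tree rebuilt,
and each internal bipartition of the full-data tree labelled with the
percentage of replicate trees containing it; degenerate replicates (a
pair with no comparable sites, or a saturated Poisson pair) are skipped
and counted.  The web server's exact support convention is not
reproducible from its description; standard column bootstrap is used.

## Kinetics

`fit_michaelis_menten()` fits `v = Vmax * S/(KM + S)` by nonlinear least
squares (Levenberg–Marquardt), with starting values from a Hanes–Woolf
linearisation (`S/v` regressed on `S`), which is well-conditioned
whenever the data span the hyperbola's bend.  The unit contract is: `S`
and `KM` in mM, enzyme concentration `E0` in µM, rates in µM product per
second; then `kcat = Vmax/E0` is in s⁻¹ and the catalytic efficiency
`kcat/KM` in mM⁻¹s⁻¹.  Standard errors of derived constants come from
the fit covariance by the delta method.  Reporting conventions follow
enzymological practice: efficiencies to 3 significant figures, preference
ratios (`efficiency(NAD+)/efficiency(NADH)`) to 2 decimals.  Only the
plain Michaelis–Menten model is offered — no substrate inhibition or
Hill variants — because NADDs display hyperbolic kinetics towards both
NAD⁺ and NADH.

## Synthetic generators and what passing tests mean

All generators are seeded, restore the caller's RNG state, and
self-verify where possible (pattern positives must match before being
returned; negatives mutate one fixed element of a positive to a residue
outside its class and are re-scanned to confirm no alternative alignment
of the variable gaps rescues the match).

- `make_covarying_msa()` plants perfectly covarying column pairs (a
  two-state paired alphabet, balanced across sequences) in i.i.d.
  uniform noise columns.  Real alignments have phylogenetic correlation,
  gaps and conservation gradients; recovery of planted pairs shows the
  MI machinery is correct, not that it separates structural contacts
  from phylogeny in real data.
- `make_clade_msa()` builds star-within-star clades: clade ancestors
  diverge to a target between-clade identity, and each leaf mutates at
  rate `(1 - within_id)/2` so two leaves of one clade share about
  `within_id` identity.  There is no rate heterogeneity and no indel
  process.
- `make_mm_data()` draws multiplicative Gaussian noise at a given CV
  around the true hyperbola, truncated at zero.  The default substrate
  grid is `c(0.05, 0.1, 0.2, 0.5, 1, 2, 5)` mM with triplicates — seven
  levels bracketing the Michaelis constants of characterized NADDs.
- Background residue frequencies default to uniform in the generators
  and BLOSUM62 marginals in the KL score; both are parameters.

**Problem sizes.**  The shipped tests and the acceptance script use
desk-scale sizes chosen to make the statistical assertions sharp while
keeping runs short: 1,000+ sequence/pattern oracle comparisons, 200
kinetics simulations at 5% CV, 100 random additive trees, 100-replicate
bootstraps, and 100 planted-pair alignments of 64 sequences by 30
columns with a 25-permutation null.  Database-wide counts printed in the
literature (e.g. 7,479 NADDs among 234,112 Nudix sequences) depend on a
specific UniProtKB release and are treated as worked inputs to the
reporting operations, not as quantities this package re-derives.

**A known statistical limit.**  At 5% CV with triplicates at seven
substrate levels, the KM estimator's sampling SD is about 4% of the true
value regardless of how the seven levels are placed.  The median
relative error across 200 simulations is therefore comfortably below 5%,
but the maximum of 200 draws is expected near 2.9 sigma (about 12%), so
occasional individual runs exceed 10% — visible in the acceptance
report's `km_max_rel_error_percent`.  Halving the noise or doubling the
replication would be needed to keep every run within 10%.

## Known limitations

- Prosite profiles (weight matrices) and fuzzy matching with mismatches
  are out of scope; the engine handles patterns only.
- The classifier is binary by design; no match scoring or ranking.
- Taxonomy lineages and domain hits are consumed as tables; there is no
  live database retrieval.
- Contacts for pMI must be supplied; the package does not model
  structures.
- JTT/ML distances and Bayesian or likelihood tree inference are not
  provided.
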