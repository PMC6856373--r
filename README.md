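# naddkit

Toolkit for discovering and characterizing **NADH diphosphatases (NADDs)**,
the Nudix-hydrolase subfamily that cleaves NAD(H) into (N)MN(H) and AMP.
NADDs are of practical interest as biocatalysts for producing the NAD⁺
precursor nicotinamide mononucleotide (NMN), but they are a small and
sparsely annotated corner of the Nudix superfamily, and finding them
requires more than the catalytic Nudix box shared by the whole superfamily.

`naddkit` implements the complete in-silico pipeline used to chart the
subfamily:

- **Prosite pattern engine** — parses Prosite-syntax motifs (classes
  `[..]`, exclusions `{..}`, wildcard `x`, repeats `(n,m)`, anchors) and
  scans protein sequences by bounded backtracking, with a documented
  regex translation used as an independent test oracle.  The bundled NADD
  detection pattern

  ```
  [CS]-x(2)-[CD]-x(12,15)-[CN]-x(5,35)-[YF]-P-x(3)-P-x(2)-I-x(25,32)-
  G-F-x(4)-E-x(7)-R-E-x(2)-E-E-x(13,14)-Q-[PQ]-W-[PA]-x-P-x(2,9)-[QLIMA]-M
  ```

  spans the region from the first zinc-coordinating cysteine to the
  conserved methionine of the nicotinamide pocket (33 elements, covering
  99–147 residues): the zinc-binding domain, the Nudix box
  `GX₅EX₇REUXEEXGU`, and the core of the NADD signature `Q[PQ]W[PA]xP`.
- **Classifier** — a sequence is called NADD iff the pattern matches;
  annotations report the matched span, the three pattern-traced
  zinc-coordinating positions, and independently located Nudix box and
  signature.
- **Profilers** — taxonomy rollups of classified sets (counts and
  percentages per lineage rank) and Pfam-style domain-architecture
  strings (`NUDIX-like_zf-NADH-PPase_NUDIX` is the canonical NADD
  architecture) with distribution tables.
- **Coevolution analyzer** — MISTIC-style statistics on a protein
  alignment: per-column Kullback–Leibler conservation against BLOSUM62
  background frequencies, pairwise mutual information z-scored against a
  column-shuffle null, cumulative MI (cMI) per column, proximity MI (pMI)
  against a contact set, and a tiered edge list (top 5% / 70–95% /
  remainder) ready for circos-style plotting.
- **Phylogeny** — p-distance and Poisson-corrected distances,
  neighbor-joining with deterministic tie-breaking and Kuhner–Felsenstein
  negative-branch handling (exact on additive matrices), and Felsenstein
  column-bootstrap support.
- **Kinetics** — Michaelis–Menten fitting by nonlinear least squares
  (`v = Vmax·S/(KM+S)`, Hanes-linearization starting values) returning a
  classed model object with `KM`, `Vmax`, `kcat = Vmax/E0`, catalytic
  efficiency `kcat/KM` and standard errors, plus the NAD⁺/NADH
  substrate-preference ratio.
- **Fixture generators** — seeded, self-verifying generators for
  pattern-positive/negative sequences, covarying and clade-structured
  alignments, noisy kinetics data and profiling tables, so every
  component is testable with no database downloads.

## Worked example

```r
library(naddkit)

## pattern engine + classifier
p <- nadd_pattern()
p
#> Prosite pattern: [CS]x(2)[CD]x(12,15)[CN]x(5,35)[YF]Px(3)Px(2)Ix(25,32)GFx(4)Ex(7)REx(2)EEx(13,14)Q[PQ]W[PA]xPx(2,9)[QLIMA]M
#>   elements: 33; span: 99-147 aa

pos <- make_pattern_positive(p, flank_length = 0, seed = 1, minimal = TRUE)
classify_nadd(pos)
#> positive: NADD [1-99]; zinc positions 1, 4, 17

summarize_rate(7479, 234112)   # NADDs among Nudix sequences, percent
#> [1] 3.2

## kinetics: NAD+ dataset at the TmNADD truth, noiseless
d <- make_mm_data(KM = 0.31, kcat = 2.9, E0 = 0.11, cv = 0, seed = 1)
fit <- fit_michaelis_menten(d)
fit
#> Michaelis-Menten fit
#>   KM   = 0.31 +/- 0 mM
#>   Vmax = 0.319 +/- 0 uM/s
#>   kcat = 2.9 +/- 0 1/s   (E0 = 0.11 uM)
#>   kcat/KM = 9.355 +/- 0 mM^-1 s^-1

catalytic_efficiency(10.7, 0.12)   # NADH efficiency from reported kcat, KM
#> [1] 89.2
efficiency_ratio(9.3, 89.2)        # NAD+/NADH preference ratio
#> [1] 0.1

## coevolution on a generated alignment with one planted covarying pair
aln <- make_covarying_msa(n_seqs = 64, n_cols = 30,
                          planted_pairs = list(c(5, 20)), seed = 42)
net <- coevolution(aln, n_shuffles = 50, seed = 1)
net
#> MI coevolution network: 30 columns, 1 edges above z > 6.5
#>   tiers: top5=1
head(net$edges)
#>     col_i col_j        z tier
#> row     5    20 67.18975 top5

## phylogeny with bootstrap
caln <- make_clade_msa(n_per_clade = 5, n_cols = 200, seed = 17)
tree <- bootstrap_support(caln, n_replicates = 100, seed = 4)
```

The kinetics output above means: with substrate in mM, rates in µM/s and
enzyme at `E0` µM, the enzyme turns over 2.9 substrate molecules per
second at saturation, is half-saturated at 0.31 mM, and its catalytic
efficiency is 9.35 mM⁻¹s⁻¹.  In the coevolution output the planted pair
(columns 5 and 20) is the only edge passing the z > 6.5 threshold and
lands in the top-5% tier.

A thin command-line wrapper over the same functions ships at
`inst/cli/naddkit.R` (subcommands `scan`, `classify`, `profile`,
`coevolve`, `tree`, `kinetics`, `simulate`).

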