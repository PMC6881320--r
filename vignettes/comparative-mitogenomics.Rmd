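---
title: "Comparative characterization of circular mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative characterization of circular mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## The problem

Animal mitochondrial genomes are small circular molecules (typically
14--17 kb) carrying a nearly fixed complement of 13 protein-coding genes
(PCGs), 22 tRNAs and 2 rRNAs. Characterizing a newly sequenced mitogenome
and comparing it to relatives is a standard exercise in molecular
systematics, and it decomposes into a handful of well-defined computations:

* **annotation geometry** — gene lengths, the signed intergenic spacers
  between neighbouring genes (negative values are overlaps), and the scan
  for non-coding regions, all on a circle whose last/first gene pair wraps
  across the replication origin;
* **nucleotide composition** — A+T content and the strand-asymmetry
  statistics AT skew $=(A-T)/(A+T)$ and GC skew $=(G-C)/(G+C)$, per genome,
  per gene and per gene class;
* **codon usage** — start/stop codon tabulation across genomes, relative
  synonymous codon usage (RSCU), and the usage ratio of A+T-rich to
  G+C-rich codons;
* **divergence** — Kimura 2-parameter (K2P) distances between aligned
  sequences;
* **gene order** — rotation- and strand-invariant comparison of signed
  circular gene arrangements, with breakpoint distances.

`mitocomp` implements these as composable functions over a single
annotation container, ships the full published organization tables of two
strombid gastropod mitogenomes (*Harpago chiragra*, 15,460 bp;
*Lambis lambis*, 15,481 bp) as worked fixtures, and includes a synthetic
mitogenome generator plus a K2P sequence-evolution simulator so that every
stage can be exercised against known ground truth.

## Coordinate model

Coordinates are 1-based inclusive, exactly as organization tables are
published; conversion to string offsets happens only inside sequence
slicing. A feature's length is `end - start + 1`. The spacer *before* a
gene is `start - previous_end - 1`, and the junction pair that closes the
circle contributes `(genome_length - last_end) + (first_start - 1)`. This
"spacer before" convention is the only reading of published intergenic
columns consistent with a first gene at position 1 carrying a non-zero
intergenic entry, which then measures the wrap-around gap. Two invariants
follow and are enforced in the tests:

* **tiling identity**: feature lengths plus signed spacers (junction
  included) sum to the genome length;
* **rotation invariance**: shifting all coordinates by a constant
  (mod genome length) changes no spacing.

Origin-spanning features are rejected rather than modeled; none occur in
the fixtures, and rejecting them keeps every downstream computation free of
modular-arithmetic corner cases. Structural problems are reported as
machine-readable findings by `validate_annotation()` rather than thrown, so
imperfect annotations can still be inspected.

```{r}
hc <- chiragra_annotation()
scan_spacers(hc)
protein_lengths(hc)$total
```

Amino-acid counts are `span/3 - 1`, excluding the terminator. One published
cell (atp6 of *L. lambis*, printed 232 aa over the same 696-nt span that is
printed 231 aa in the other genome) is inconsistent with its own span; the
formula value is used, which is why both bundled genomes total 3,744
encoded amino acids.

## Composition conventions

All skew statistics are computed on the (+)-strand text regardless of the
strand a gene is encoded on, matching the convention of published per-gene
skew tables; `strand = "gene"` switches to native-strand sequences for
exploration. IUPAC ambiguity codes are counted separately and excluded from
every denominator, and a skew whose denominator is zero is `NA`, never
coerced to 0. Multi-gene classes (all PCGs, all tRNAs) are concatenations
in annotation order; bases shared by overlapping genes count once per
region they fall in, since the table layout is per-gene. Report output is
rounded to 2 decimals; full precision is retained in memory.

## Codon analysis

The genetic code defaults to NCBI translation table 5 (invertebrate
mitochondrial), which has 62 sense codons — only TAA/TAG terminate; TGA is
tryptophan and AGA/AGG are serine. Codons are counted over all PCGs pooled,
excluding each gene's terminator, so the codon census equals the total
encoded amino acids. RSCU is a codon's count divided by its synonymous
family's mean count; within any used family the values sum to the family
size, and unused families are reported as undefined rather than zero.

"A+T-rich codon" is not a formally defined term; this package classifies a
codon as A+T-rich when at least 2 of its 3 positions are A or T (a majority
always exists), and the reported ratio counts codon *occurrences*, not
codon types. Both choices are deliberate resolutions of an informal term
and are documented on `at_rich_ratio()`.

## Divergence

`k2p_distance()` classifies each aligned site (transitions A↔G, C↔T; all
other substitutions transversions) after *pairwise deletion* of sites with
a gap or ambiguity code in either sequence — complete deletion is the other
common option, but pairwise deletion wastes no sites in pairwise work. The
correction is
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$.
Saturated pairs (either log argument $\le 0$) return `NA` with the P, Q
tallies retained, so a saturated entry is visible rather than silently
clamped. Inputs are assumed pre-aligned; synthetic pairs are indel-free and
therefore aligned by construction, and externally aligned gene blocks can
be supplied as named vectors or per-gene block lists to
`distance_matrix()`.

## The synthetic generator

`generate_genome()` emulates the statistical structure the analysis
assumes, not any particular real sequence:

* the 37-feature consensus layout at ~15.5 kb, with the published lengths
  and spacers as the default template (four overlaps; one larger 53-bp gap
  where a control region is suspected, between cox3 and trnF);
* A+T content 66.22% with AT skew −0.128 and GC skew +0.019 on the (+)
  strand — the values characteristic of the bundled genomes — implemented
  by strand-asymmetric base frequencies;
* PCG content written codon-wise in the gene's own frame: annotated start
  codon, sense codons drawn base-wise with stop codons rejected, annotated
  terminator. The third codon position is pulled toward A/T by
  `codon_bias_strength` (default 0.3, a moderate bias chosen to give
  realistic RSCU spreads around 0.5–1.5); because that bias would lift
  genome-wide A+T above target, the background frequencies are solved so
  the overall expectation still hits the configured A+T content.

One template adjustment: the real map's single PCG-over-PCG overlap
(nad4l/nad4, −7 bp) is relocated to a tRNA boundary (trnT/nad4l). tRNA and
rRNA spans carry unconstrained background sequence, so placing every
overlap against a non-coding partner lets protein-coding content remain
authoritative in overlap zones and guarantees generated PCGs contain no
internal stops. The overlap census (4) and all other spacers are kept.

What the generator does **not** emulate: real tRNA/rRNA secondary
structure, site-to-site rate variation, indels, rearrangements (beyond
user-supplied template permutations), and selection. Tests passing on
synthetic data therefore validate the *computations* — coordinate
arithmetic, counting, estimation — not the biological realism of any
particular genome.

`evolve_pair()` diverges two descendants from a common ancestor, each along
half the requested distance, under the exact K2P site channel
($P(b), Q(b)$ closed forms, so two half-branches compose to the full
distance by the Markov property). By default the six start/stop codon
positions of every PCG are protected from substitution so downstream codon
tabulation stays meaningful (≈0.5% of sites; a `preserve_codons = FALSE`
mode disables this, and the bias tests use it). Near-saturating distances
flag the truth record and warn.

All randomness flows from the seed in the configuration object via
`withr::with_seed()`; the global RNG state is never consumed or disturbed.

## Numerical and design choices

* Undefined statistics (zero-denominator skews, unused RSCU families,
  saturated distances, a ratio with empty denominator) are `NA` with a
  warning where actionable — never silently 0 or clamped.
* Gene-order comparison uses signed adjacencies normalized over the two
  reading directions of the circle, so equivalence and breakpoint counts
  are invariant to rotation and to a global strand flip; `cox1` anchors the
  canonical form, as in published linearizations. An unsigned mode is
  available for coarse comparison.
* tRNA isotype labels (trnL1/trnL2, trnS1/trnS2) are kept distinct; the
  GenBank reader resolves them from anticodon hints when present and by
  encounter order (with a finding) otherwise.
* The statistical test sizes used in the suite — 10 kb alignments with 12
  replicates for the K2P recovery check, 100 synthetic genomes for the
  tiling-identity sweep, exhaustive signed circular orders up to 6 genes
  for the breakpoint oracle — were chosen so each property has real power
  while the whole suite stays interactive.

## Known limitations

* Origin-spanning features and multi-exon locations (`join(...)`) are not
  modeled.
* The pipeline computes distance matrices only when shared PCGs have equal
  spans across genomes (true for simulated pairs and for the two bundled
  genomes); anything else needs external alignment first.
* The GenBank writer emits a minimal record (sufficient for round-trips
  and for re-reading by this package), not a full submission-grade file.
* No tree inference, no divergence dating, no rearrangement-scenario
  reconstruction — those are different tools' jobs.
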