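---
title: "Methods: gene-family characterization in ap2erf"
author: "ap2erf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterization in ap2erf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ap2erf)
```

This vignette is the package's own account of its methods: the models and
rules each stage implements, the tunable parameters and their defaults,
what the synthetic-genome generator does and does not emulate, and the
design choices made where the underlying survey recipe leaves room.

## Family identification

Membership in the AP2/ERF superfamily is decided from per-domain
profile-HMM hits against the AP2 (PF00847) and B3 (PF02362) profiles.  A
gene belongs to the family iff its representative protein carries at least
one AP2 hit with E-value at or below `ap2_evalue_max` (default `1e-5`,
the conventional cutoff for domain-based family surveys; unitless
E-value).  The representative is the longest isoform; length ties are
broken by the lexicographically smallest protein id so output never
depends on input order.

Two conventions are worth making explicit:

* **Hit merging.**  Overlapping AP2 hits whose alignment envelopes share
  at least half of the shorter envelope are merged and counted as one
  domain.  Profile matches are occasionally split in two by a poorly
  conserved stretch; counting raw hits would misclassify such single-domain
  proteins as two-domain AP2 members.
* **B3 scoping.**  B3 hits are only consulted for proteins that already
  qualify by AP2.  A B3 domain without an AP2 domain identifies a
  different family (ARF/B3 proteins) and must not create RAV calls.

Architecture then maps to subfamily: ≥ 2 AP2 domains → AP2; 1 AP2 + B3 →
RAV; 1 AP2 → ERF, *provisionally* — the tree stage may override it (below).

Systematic names are assigned per subfamily in genome order: chromosomes
sorted naturally (`2` before `10`; subgenome suffixes alphabetical;
unplaced contigs last, alphabetically), then start coordinate.  Published
surveys number genes the same general way but rarely state their exact
rule; this package's ordering is therefore its own documented convention,
chosen for reproducibility, and names should not be expected to match any
particular publication gene-for-gene.  ERF names are zero-padded to three
digits (`CaERF001`), the smaller subfamilies use dotted numbering
(`CaAP2.1`).

## Alignment layer

Pairwise global alignment is Needleman–Wunsch with affine gaps, delegated
to `Biostrings::pairwiseAlignment`: BLOSUM62, gap open 10, gap extension
0.5 per position (CLUSTALW-like defaults; a gap of length $L$ costs
$10 + 0.5L$).  The optimal score is unique and the traceback is
deterministic, so repeated runs agree exactly.  The test suite checks the
optimum against an exhaustive enumeration oracle on small strings.

Two statistics drive the duplication screen, and their operationalization
is the single most consequential definition in the package:

* **similarity** = percent identity over residue–residue columns only;
* **coverage** = the fraction of each sequence's residues sitting in
  residue–residue columns (computed for both genes).

A BLAST-style "positives" similarity is available via
`alignment_stats(..., similarity = "positives")` but identity is the
default: it is the stricter and more reproducible reading.

For trees, the package accepts a pre-computed aligned FASTA (e.g. MUSCLE
output) or builds one with `progressive_align()` — a deliberately simple
progressive aligner (most-similar-pair seed, gap propagation through a
representative).  It is *not* a MUSCLE reimplementation; it exists so the
pipeline and its tests are self-contained, and it aligns well-conserved
domain blocks reliably, which is all the downstream p-distance needs after
partial deletion.

## Distances and neighbor joining

`pdistance_matrix()` implements the p-distance model with partial
deletion: alignment columns with non-gap coverage below
`min_site_coverage` (default 0.9) are removed globally; per pair, columns
where either row is gapped are skipped; the distance is the proportion of
mismatches among compared sites (uniform rates across sites).

`nj_tree()` is a from-scratch Saitou–Nei implementation with two pinned
conventions: ties on the Q-criterion are broken by the smallest pair of
node-creation indices, and negative branch lengths are clamped to zero
without redistribution.  The test suite verifies exact topology recovery
on random additive matrices (where NJ is provably exact) and cross-checks
topologies against `ape::nj`, which serves as an independent oracle, never
as the implementation.

## Tree-based classification

**Single-domain overrides.**  Some genes carry one AP2 domain yet belong
with the two-domain AP2 subfamily; a few divergent single-domain genes
(Soloists) group with neither clade.  The survey literature resolves these
by inspecting the tree; this package replaces that manual judgement with a
deterministic, root-invariant rule.  An ancestor-walk rule ("first
ancestor containing k references") was considered and rejected: the final
join of an unrooted NJ tree places a trifurcation at an arbitrary
position, and genes adjacent to it inherit whatever clade happens to span
the join.  Instead, `resolve_single_domain_overrides()` works on patristic
distances, which do not depend on where the trifurcation lands:

* references are all other family genes labeled by architecture
  (two-domain → AP2, single-domain → ERF; RAV genes are not references);
* a provisional-ERF gene farther from *every* reference than the
  inter-clade scale — the median patristic distance between two-domain and
  single-domain genes — is a Soloist ("groups closely with neither");
* otherwise the gene takes the majority label among its `clade_k`
  (default 3) nearest references; AP2 majority overrides, ERF majority or
  a tie leaves the architecture call standing.

The inter-clade scale is data-driven, so no absolute distance threshold
has to be chosen; the rule's single tunable is `clade_k`.

**ERF subgroups.**  Subgroup assignment (I–X, V-L, VI-L) is two-step:
each ERF gene starts from the subgroup of its closest reference protein
(highest-identity global alignment, standing in for a BLASTP best hit),
and the tree confirms or refines it via `clade_context()` — walk from the
gene's leaf rootward and, at the first ancestor holding at least `clade_k`
reference leaves, take the majority subgroup (ties yield no context, so
the best-hit subgroup stands).  Here the ancestor walk is appropriate:
references from many subgroups are interleaved through the tree, so a
gene's first qualifying ancestor is local, and a root-spanning context
resolves to a tie.  The assignment is idempotent: re-running it on its
own output changes nothing.

## Duplication classification

Pairs with identity ≥ 80% and coverage > 80% of *both* genes are
duplicates.  On one chromosome and within 1 Mb they are tandem; in an
allotetraploid run (`subgenome_mode = TRUE`), pairs on homoeologous
partner chromosomes — identical leading number, differing subgenome
suffixes (default `c`/`e`) — are homoeologs, i.e. parental homologs
inherited at hybridization rather than true duplications; all remaining
pairs are segmental.  Summaries report segmental counts under both
conventions (with and without homoeologs folded in), since family surveys
publish the folded headline first and split it afterwards.

Pinned conventions: inter-gene distance is start-to-start
(`distance_anchor = "gap"` switches to end-to-start); the 1 Mb rule
applies only within a chromosome, so cross-chromosome pairs can never be
tandem; all qualifying pairs are reported without transitive reduction
(three mutual duplicates yield three pairs); tandem clusters are connected
components of the tandem-pair graph only — co-location alone never joins a
cluster.

## Ka/Ks (NG86 with Jukes–Cantor correction)

Codon alignments are obtained by back-translating the protein alignment
(protein gaps become `---`; the CDS must translate exactly to its protein,
with one terminal stop codon tolerated and stripped).  Columns containing
gaps, ambiguous bases or stop codons are skipped pairwise and counted.

Sites: each of a codon's nine single-nucleotide changes contributes ⅓ of
a site, synonymous if the encoded amino acid is unchanged (changes to
stop codons count as nonsynonymous), so every sense codon's counts sum to
exactly 3.  Pair totals average the two sequences' counts.  Differences:
codons differing at one position classify directly; at two or three
positions the synonymous/nonsynonymous steps are averaged over all 2 or 6
orderings, excluding orderings that pass through a stop codon (if every
ordering is blocked — not reachable for ordinary sense-codon pairs — all
are used, as a documented fallback).  Proportions are Jukes–Cantor
corrected, $K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; a proportion at or
beyond the $3/4$ saturation bound leaves that rate (and the ratio)
undefined and flags the pair `saturated` — undefined is reported as `NA`,
never silently propagated.

Significance is a two-sided Fisher's exact test on
$[[\,\mathrm{round}(S_d),\ \mathrm{round}(S-S_d)\,],
[\,\mathrm{round}(N_d),\ \mathrm{round}(N-N_d)\,]]$ — substitutions
versus unchanged sites, rounded because NG86 counts are fractional (the
convention of codon-based Ka/Ks significance testing).  The p-value sums
hypergeometric probabilities not exceeding the observed table's, with the
customary $1+10^{-7}$ relative tolerance for floating-point ties.  On
degenerate tables (rounded substitutions exceeding rounded sites, possible
only for very short or saturated alignments) the batch reports `NA`
rather than aborting.

This estimator deliberately replaces the model-averaging approach of
KaKs_calculator-style tools: averaging over many substitution models adds
a large machinery for a second-decimal refinement.  Replicated ratios on
real data will differ from model-averaged values at that level; the
qualitative conclusion such surveys draw — all duplicate-pair ratios well
below 1, indicating purifying selection — is robust to the choice, and the
package's parameter-recovery tests quantify the estimator's accuracy
directly (mean recovered ω within ±0.1 of the generating value at
ω ≤ 0.5 over 30 replicates of 300 codons).

## Expression

CPM is counts × 10⁶ / library size (column sum); the matrix is
log₂(CPM + pseudocount) transformed with pseudocount 1 (a zero count maps
to 0; configurable).  A gene is *expressed* iff CPM ≥ `min_cpm` (default
1) in at least one sample — upstream tools leave this criterion
unspecified, so the package fixes a conventional, permissive one and
echoes it into every report.  Clustering of genes and samples is
agglomerative (`stats::hclust`) on Euclidean distances with complete
linkage by default (average available); `hclust`'s leaf order is
deterministic with ties resolved by input index.

## The synthetic-genome generator

`generate_diploid()` emulates the statistical structure the pipeline
consumes, not biological sequence realism:

* **Proteins** are fixed canonical domain blocks (an AP2-like 60-mer, a
  B3-like 100-mer) embedded in random linkers.  Each subfamily uses its
  own fixed block variant 8% diverged from the canonical (so subfamilies
  are ~15% apart in the domain region), each Soloist-like gene a 35%
  diverged variant (far from both clades), and each gene ~2% private
  substitutions.  Linker lengths keep every class's conserved-domain
  fraction at or below about half the protein (two-domain 120/240, ERF
  60/150, RAV 160/340): with less than half the protein conserved,
  non-duplicate same-class pairs cannot simultaneously clear the
  duplicate screen's 80% identity *and* 80% coverage, because gapping the
  dissimilar linkers out raises identity only by sacrificing coverage.
* **Duplicates** (tandem within 50–900 kb on the same chromosome,
  segmental across chromosomes) and the sister subgenome are produced by
  evolving the CDS: uniform single-nucleotide proposals, stop codons
  rejected, synonymous changes accepted with probability min(1, 1/ω) and
  nonsynonymous with min(1, ω), until the protein reaches the target
  divergence (default 5%).  Proposals are uniform over positions and
  alternative bases — the same mutation-opportunity model NG86 assumes —
  so the realized Ka/Ks approximates ω; recovery is asserted in bands,
  not as equality.
* **The allotetraploid** merges two such diploids (the second derived
  from the first at the subgenome divergence, default 5%), suffixes
  chromosomes `c`/`e`, records every shared lineage as a homoeolog pair,
  and plants post-hybridization duplications using lineages private to
  one subgenome as sources, so each planted pair's similarity signal is
  confined to that pair and label precision/recall against truth is
  meaningful at 1.0.
* **Counts** give expressed family genes negative-binomial counts
  (dispersion 0.1, a typical RNA-seq overdispersion) at a target mean
  CPM, unexpressed genes all-zero, and fill each library to exactly one
  million reads through the background genes, so CPM equals the raw
  count.

What it does **not** emulate: real HMM score distributions (hit E-values
are planted at 10⁻³⁰, plus above-threshold decoys on background genes),
indels in duplicate divergence, rate heterogeneity across sites,
pseudogenization, or read-level noise.  Passing the closure tests
therefore demonstrates that the pipeline's logic is correct under its own
stated assumptions — clean domain hits, substitution-only divergence —
not that it is robust to annotation errors or borderline domain calls in
real genomes.

Default problem sizes — a 48-gene diploid (38 family members) for
end-to-end closure and a 200-gene allotetraploid for the
duplication-recovery scenario, with 300-codon pairs and 30 replicates per
ω for estimator calibration — are compact study conditions chosen so the
full suite re-runs quickly while every planted structure (all four
subfamilies, all three duplicate labels, both subgenomes) is represented.

## Reproducibility and numerical conventions

Every stochastic function takes an explicit seed and restores the
caller's RNG state; identical seeds give byte-identical genome bundles
and reports.  Determinism conventions collected in one place: isoform
ties → lexicographic protein id; NJ Q-ties → smallest creation-index
pair; alignment traceback → Biostrings' deterministic choice among
co-optima; clustering leaf order → `hclust` input-index ties; negative NJ
branch lengths → clamped to zero.

## Known limitations

* The progressive aligner degrades on sequences without a shared
  conserved block; supply an external MSA for publication trees.
* NG86 underestimates divergence at high saturation; pairs near the JC
  bound are flagged rather than corrected with a richer model.
* Bootstrap support is not computed.
* Homoeolog detection relies on the suffix convention for chromosome
  names; polyploids with other naming schemes need the suffixes remapped.
* The strand column is carried through but never used — all criteria in
  the pipeline are strand-agnostic.
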