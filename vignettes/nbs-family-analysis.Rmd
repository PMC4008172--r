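---
title: "Methods: genome-wide analysis of NBS-encoding resistance gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide analysis of NBS-encoding resistance gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsfam)
library(dplyr)
```

# The scientific problem

Plant disease-resistance (R) genes of the NBS-LRR superfamily carry a
nucleotide-binding site (NB-ARC) domain, usually combined with an N-terminal
TIR or coiled-coil (CC) domain and C-terminal leucine-rich repeats (LRR).
In crucifers, the *Brassica* ancestor underwent a whole-genome triplication
(WGT) after its split from the *Arabidopsis* lineage, so every ancestral R
gene could in principle leave up to three descendant copies per *Brassica*
genome. The questions this package operationalises are: how many
NBS-encoding genes does a genome carry and in which architectural classes;
how are they arranged physically (clusters, tandem arrays); how much of the
triplicated redundancy survived fractionation; and whether the retained
ortholog copies diverged in selective pressure (Ka/Ks) and in expression.

`nbsfam` implements that analysis chain as composable, tabular operations —
identification from domain evidence, architecture classification, cluster
and tandem-array calling, collinearity chaining with retention accounting,
NG86 Ka/Ks with a Mann-Whitney lineage contrast, and expression-divergence
scoring — together with a synthetic genome generator that plants all of the
structure the downstream stages are supposed to find.

# Identification and classification

## Two-pass domain search

Family members are recognised from per-protein domain evidence. The
built-in route scans each proteome with fixed amino-acid signatures (>= 15
residues per domain; see `domain_signatures()`), scoring every window by
identity fraction and keeping windows at or above 0.6. The threshold was
calibrated once against the generator: planted signatures score 1.0 at
their coordinates and moderately diverged copies remain above threshold,
while the best random 17-residue window in unrelated sequence has an
expected identity near 0.05 and essentially zero probability of reaching
0.6. A second pass rebuilds a genome-specific position-frequency profile
from the first-pass hits (`refine_profile()`), keeping "high-quality" seeds
— those at or above the median first-pass score, a deterministic and
scale-free reading of that otherwise loose notion — and rescans with the
threshold set to the weakest seed's own profile score, which guarantees the
second pass is a superset of the first. On noiseless input the procedure is
idempotent: a third pass reproduces the second exactly.

Externally computed evidence slots in through `read_domtblout()`
(HMMER3 per-domain table layout), so real profile-HMM searches can replace
the built-in scanner without touching anything downstream; the package
itself never shells out to external binaries.

## Coiled-coil consensus

CC motifs are accepted only by consensus of two predictors, mirroring the
practice of requiring agreement between a P-score predictor (cutoff 0.025,
lower is better) and a probability predictor (cutoff 0.90). The built-in
`builtin_cc_score()` slides a 28-residue window (four heptads) and scores
the best of the seven heptad frames as the fraction of strongly hydrophobic
residues (L, I, V, M, F) at the `a`/`d` positions minus the hydrophobic
fraction elsewhere; an ideal leucine zipper scores 1, random sequence near
0. Where several passing segments overlap, each overlapping pair
contributes the intersection interval — published protocols rarely say how
multiple overlapping segments should be merged, and
intersection-per-overlapping-pair is the reading adopted here. The
operation is symmetric in its two prediction arguments.

## Architecture and category

Ordered hits collapse to token strings over `T`, `C`, `N`, `L`
(`collapse_architecture()`), and `assign_category()` maps each string to
one of the seven census classes by *presence* rules with TIR-over-CC
precedence: TIR-only genes are TIR-X; among NBS-carrying genes, T+L gives
TNL, C+L (no T) CNL, L alone NBS-LRR, T alone TIR-NBS, C alone CC-NBS, and
bare N NBS. Presence-based assignment (rather than order-based) is a
deliberate choice so that complex strings such as TNNL, TCNL or NLTNL fall
into the class their domain content implies, while the full string is kept
for reporting; the one mixed T+C architecture observed in the reference
census sits inside a TNL tandem array, which motivates the precedence rule.
A gene whose evidence contains neither an N nor a T token is not a family
member and is refused. When CC detection is equivocal the consensus is
applied strictly: no consensus segment, no C token.

# Physical organisation

Clusters follow the classic 8-ORF rule: two or more NBS-encoding genes on
one chromosome with at most eight intervening ORFs between adjacent
members, read on consecutive gene ranks (0-based internally; GFF3 output is
1-based, closed). Cluster percentages use chromosome-anchored NBS genes as
the denominator and exclude TIR-X genes, matching how the published
percentages are framed ("NBS genes on chromosomes").

Tandem arrays require both physical adjacency — at most one unrelated gene
between consecutive members, applied per adjacent pair so the rule is
scale-free for long arrays — and sequence similarity: each member must link
to an earlier member of the same array in the similarity graph. Imported
12-column alignment tables (E <= 1e-20) take precedence; the built-in
fallback aligns candidate neighbour pairs globally (BLOSUM62) and uses
percent identity >= 50 as the similarity proxy, a level comfortably above
the ~25-35% global identity of unrelated proteins while tolerant of the
divergence an E <= 1e-20 hit would show at these protein lengths. An array
is `pre_split` when at least two members' ortholog counterparts are members
of one array in the outgroup genome, otherwise `species_specific`; with no
ortholog map arrays stay `unassigned`.

# Collinearity and retention accounting

Anchors are homolog pairs between two genomes (imported similarity at
E <= 1e-20, or the built-in k-mer-prefiltered alignment search) annotated
with gene ranks. `chain_blocks()` finds maximal-score monotone chains by
dynamic programming over rank-sorted anchors: each anchor scores 10, each
skipped rank costs 1 (the unit gap penalty), a run of more than 25
consecutive skipped ranks breaks the chain, and blocks need at least 5
anchors — the minimum-block-size and unit-gap settings of MCscan-style
collinearity detection, with the gap cutoff made explicit so the DP is
well-defined. Blocks are extracted greedily best-first; equal scores prefer
the chain with the smaller total rank span, then the lexicographically
first anchor, so results are deterministic. A counterpart gene that would
fall into two blocks keeps only the higher-scoring one, preventing
double-counting in the retention histograms. Blocks are chained over
all-gene anchors, not family genes only — with sparse NBS loci a
five-anchor minimum is only meaningful on the full gene set.

NBS-NBS anchors inside blocks become ortholog pairs, grouped by reference
gene (the non-triplicated genome) into retention records: the copy-count
histogram over {1, 2, 3} plus over-retention flags. Conservation is
asserted on every run: the histogram weights sum to the pair count and the
bins to the reference-gene count. `cross_comparison_sets()` intersects two
comparisons sharing the reference genome to report the overlap and union of
reference gene sets and each counterpart genome's retained fraction.

# Selection analysis

The built-in estimator is pairwise Nei-Gojobori (1986). Codon-aware
alignments come from a global protein alignment back-mapped to codons; gap
columns are excluded from counting. Site counts apportion each codon
position by the fraction of its three possible changes that are synonymous;
difference counts average over all shortest mutational pathways between two
codons with equal weights, excluding pathways through stop codons (the
standard NG86 convention; if every pathway is blocked, all are used).
Proportions are Jukes-Cantor corrected, `d = -(3/4) log(1 - (4/3) p)`, with
`p >= 0.75` reported as a saturation error. Pairs with `Ks = 0` have an
undefined ratio and are excluded from group means so infinities cannot skew
the rank test. The implementation uses a cached 61 x 61 codon-pair lookup
table for speed; the test suite checks it against an explicit
pathway-enumeration oracle on random codon pairs to 1e-9.

Branch-wise free-ratio maximum likelihood is out of scope as an
implementation; `read_branch_results()` parses externally produced
branch-model result rows (`parent..child t N S dN/dS dN dS`) so such
estimates are usable interchangeably with NG86 output downstream.

Lineage contrasts use the two-sided Mann-Whitney U test
(`compare_lineages()`): the exact null when both groups have at most 8
observations and no ties, the normal approximation with tie correction
otherwise, with the exact p verified against full enumeration for group
sizes up to 6. The summary reports group means and the relative excess
`(a - b) / a`; for the published CNL lineage means 0.497 and 0.235 this is
52.72%.

# Expression divergence

FPKM matrices are transformed as `log2(FPKM + 1)`. The pseudocount is not
stated in the source methodology (zeros exist in any FPKM table); 1 is the
default here and is configurable. Hierarchical clustering uses uncentered
correlation similarity with average linkage — the documented defaults of
the classic clustering tool whose output the heat maps mirror — with
all-zero profiles excluded (their uncentered correlation is undefined) and
heatmap export writing the transformed matrix exactly, no silent
re-scaling; the display colour scale clamps at +/-2 on the log2 scale.
Expression divergence of a pair is `1 - Pearson` on the transformed
profiles, a score in [0, 2]; comparative studies typically assert the
ortholog/paralog contrast without naming a statistic, so this
operationalisation is a design decision of the package and is labelled as
such in output. The group
comparison reuses the Mann-Whitney machinery one-sided (paralog > ortholog).

# The synthetic genome generator

`generate_genome_set()` builds an ancestral genome, triplicates it into two
descendant lineages with fractionation, diverges the coding sequences, and
simulates tissue expression, emitting FASTA/GFF3/TSV plus truth tables.
What it emulates, and what it does not:

- **Gene content.** Each background gene is a random protein (150-450
  amino acids by default); family genes are built from literal domain
  signatures joined by disordered spacers. Spacers exclude the strongly
  hydrophobic residues so the heptad CC scorer cannot fire on linker
  sequence — the positive CC signal comes only from the planted zipper.
  The default architecture mix follows the *B. oleracea* census
  proportions (TNL 0.17, CNL 0.03, NL 0.10, TN 0.12, CN 0.02, N 0.22,
  T 0.34), and the default NBS fraction of 0.12 yields family sizes in the
  dozens at default genome sizes.
- **Triplication and fractionation.** Each ancestral gene is lost with
  probability 0.65 or retained as 1-3 copies with probabilities
  (0.80, 0.15, 0.05), values chosen once to match the observed retention
  histograms (mostly single-copy survivors, triple retention rare) and the
  ~35% of reference NBS genes found on triplicated regions. Surviving
  copies preserve ancestral order within each of three subgenomes.
- **Divergence.** Codon evolution is proposal/acceptance per site:
  synonymous changes always accepted, nonsynonymous accepted with
  probability omega, stop-creating proposals rejected; proposals continue
  until the accepted synonymous count reaches `ks_target` times the
  sequence's synonymous site count. This matches the NG86 estimand by
  construction, which is the point: the estimator must recover the dial.
  Default lineage omegas are the published CNL means (0.497, 0.235);
  default Ks 0.45 is a crucifer-scale synonymous distance. Tandem
  duplicates are young, so they re-derive from their already-diverged seed
  copy with a small extra Ks (0.05 by default).
- **Expression.** Profiles are drawn on the log2 scale (mean 4, sd 2 per
  tissue across the six tissues root, stalk, leaf, flower, silique,
  callus); the second gene of each truth pair mixes the first profile with
  an orthogonalised random component so the noiseless within-pair
  `1 - Pearson` equals the dial exactly (ortholog 0.3, paralog 0.8 by
  default), then iid noise (sd 0.25) is added and profiles map to
  nonnegative FPKM. Pairs whose genes were both already constructed get
  emergent (larger) divergence rather than a dialled one.
- **Not emulated.** Intergenic sequence content, introns and exon
  structure, strand-aware regulation, read-level RNA-seq noise, unanchored
  scaffolds, and real hit-score distributions of profile-HMM searches.
  Passing tests on this generator therefore demonstrate correctness of the
  rules and estimators under their own assumptions — not robustness to
  annotation errors or alignment artefacts in real genome releases.

Determinism: every stage derives its own stream from the master seed and
the stage name, so a fixed configuration reproduces byte-identical outputs
and re-running a single stage reproduces that stage regardless of order.

# Numerical and degenerate-input choices

- Ranks are 0-based internally; GFF3 coordinates 1-based closed.
- `Ks = 0` ratios are undefined (NA), never infinite; `p >= 0.75` is a
  saturation error, not a clamped value.
- Cluster calling refuses duplicate ranks; similarity edges referencing
  unknown genes are input errors; empty hit lists are refused by
  classification (gene not in family).
- Chain-extraction ties prefer smaller rank span, then lexicographic order.
- All-zero expression profiles are excluded from clustering with a warning
  and flagged undefined in divergence scores.
- Identical-valued Mann-Whitney groups return p = 1 (the normal
  approximation would be 0/0).

# Problem sizes in the tests

The test and acceptance runs use deliberately small instances chosen to
exercise every rule while keeping the suite quick on one CPU: genomes of
2-4 chromosomes with 30-60 genes each for pipeline-level checks,
n = 2000 ancestral genes for fractionation recovery (binomial standard
errors small enough to separate the dials), 200 gene pairs of 100 codons
per lineage for the omega contrast, 100 pairs per group for the expression
ordering, and exhaustive oracles capped where enumeration is exact
(<= 12 anchors, <= 6 per Mann-Whitney group, 10-codon NG86 pairs).

# Known limitations

- The built-in scanner detects the generator's signatures and reasonable
  divergence from them; it is not a general profile-HMM and carries no
  E-value calibration. Real analyses should import HMMER results.
- The real genomes' published gene counts (157/206/167) depend on specific
  genome releases and Pfam 26.0 profiles and are represented here by the
  bundled printed tables, not recomputed from sequence.
- Subfamily labels (TNL-I..III, CNL-I..III) are phylogenetic-tree entities;
  only distance-based clustering stand-ins exist here.
- Ka/Ks is pairwise NG86, not branch-model ML; per-branch omegas must be
  imported if needed.
- Percent identity stands in for alignment E-values in the built-in
  similarity searches; imported tables with real E-values take precedence.

# A compact worked run

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1, sim = simulation_config(
  seed = 1, n_chromosomes = 2, n_genes_per_chromosome = 40,
  nbs_fraction = 0.2, protein_len_range = c(80, 150), loss_prob = 0.35))
report <- run_pipeline(cfg, "pipeline_out")
report
```

And the published worked examples, straight from the bundled tables:

```{r}
summarize_counts(load_census_counts()) %>%
  select(species, total_nbs, total_tir_nbs, total_cc_nbs, total)

rec_bo <- retention_accounting(load_ortholog_pairs("boleracea"))
rec_br <- retention_accounting(load_ortholog_pairs("brapa"))
glance(rec_bo)
cross_comparison_sets(rec_bo, rec_br, total_a = 157, total_b = 206)
```
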