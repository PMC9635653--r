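---
title: "Curating a NAC transcription-factor family in a polyploid genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating a NAC transcription-factor family in a polyploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polynac)
```

## The problem

NAC (NAM / ATAF1-2 / CUC2) transcription factors regulate plant
development and pathogen responses. In an allohexaploid genome such as
bread wheat, each gene may occur as a homoeolog triad on subgenomes A, B
and D, tandem duplication creates near-identical inparalogs, and a subset
of genes sits on unplaced ("U") scaffolds. Before expression and motif
patterns can be compared across studies, the family needs (i) reliable
membership calls, (ii) a phylogenetic subfamily classification, and
(iii) systematic names that encode ortholog anchoring, subgenome, group
and paralog structure. `polynac` implements this workflow end to end and
ships a synthetic-data generator with planted ground truth so that every
rule can be tested exactly.

## Domain identification

Membership is decided by similarity to the NAM domain. At desk scale the
package uses an ungapped position-specific log-odds profile built from a
training alignment: columns with at least 50% gaps are dropped and each
cell scores

$$ s(a, j) = \log_2 \frac{(c_{aj} + \pi)/(n_j + 20\pi)}{b_a}, $$

with per-column counts $c_{aj}$, pseudocount $\pi = 1$, and background
$b_a$ equal to the training alignment's own residue frequencies
(pseudocounted the same way). `scan_sequence()` scores every window and
reports maximal non-overlapping windows above a bit-score threshold
(default 30, a margin comfortably separating planted domains, which score
about 200 bits on the synthetic families, from shuffled sequences, which
score far below zero). A crude E-value, `E = n_windows * 2^-score`, is
attached so the retention rule — keep a protein iff some hit has
`E < 0.01`, strictly — can be exercised uniformly on internal scans and
on parsed HMMER3 per-domain tables (`read_domtbl()`; the Open Question of
whether the cutoff applies to the full-sequence or per-domain E-value is
resolved as full-sequence by default with `use = "domain"` as the
alternative). The scanner is deliberately ungapped; on real data a
profile-HMM search tool produces the domain table that `read_domtbl()`
consumes.

Each retained protein is split at the envelope end of its last qualifying
NAM domain: residues 1..end form the NT region (subdomains A–D), the
remainder is the C-terminal transcriptional activation region (TAR),
which may be empty. Subdomains A–E are located in synthetic proteins by
exact match against planted anchor motifs; for real data their
coordinates would be supplied as an annotation table, since subdomain
boundaries come from the literature rather than from an algorithm.

## Alignment completeness QC

`completeness()` scores an alignment before tree inference: `Cr` per
sequence, `Cc` per column, overall `Ca` (equal to both means — a
conservation identity the tests verify on random alignments), and the
pairwise matrix `Cij` = shared non-missing sites / total sites. Gaps and
`X` both count as missing, the simplest reading of completeness for
ambiguous residues. Sequences whose best pairwise score is below 0.5 are
removed; columns with `Cc < 0.6` are masked (removing low-completeness
columns can only raise the mean of the remaining ones, so `Ca` never
decreases). Identical sequences are collapsed to the lexicographically
smallest identifier — a deterministic choice — with a surplus map that
`reattach_surplus()` uses to restore the full gene universe after tree
inference. The `Cij` denominator is the total number of alignment sites
rather than the pairwise union of covered sites; this is the simplest
self-consistent definition and is stated here because completeness tools
differ on it.

## Subfamily classification

Bootstrap supports live on internal nodes in newick input; a missing
support is treated as 0 (conservative: it can never pass the threshold).
A query leaf receives subfamily `L` iff the smallest clade whose defining
node has support ≥ 70 (inclusive) and which contains the query plus at
least one reference leaf contains references of exactly one subfamily.
This operationalizes "clusters with" informally used when reading trees;
ties cannot arise because clades on one leaf's ancestor path are nested.
The procedure expects the tree to be rooted at a subfamily boundary — the
pipeline reroots on the subfamily-"b" clade first — and is then invariant
to rerooting on any other subfamily clade; rooting inside a subfamily
would distort the ancestor paths of that subfamily's genes, which is why
rerooting is part of the pipeline rather than left to the caller.

Enriched subclades are maximal clades with at least `min_size = 5`
members of which ≥ 60% (inclusive) are pathogen responsive; nested
qualifying clades are suppressed. The size floor is configurable; 5 keeps
single triads from qualifying on two responsive members.

## Nomenclature

Names follow `TaNAC<base>-<A|B|D|U><group>(-<paralog>)`.

* **Anchors.** Each gene's ortholog anchor comes from the ortholog table
  (the equivalent of a public ortholog download); a gene orthologous to
  several anchors is resolved to the first anchor by position when all
  candidates lie on one reference chromosome, else to the
  patristically closest anchor leaf in the tree.
* **Inparalogs.** Same-chromosome genes with global-alignment identity
  ≥ 80% (inclusive) are merged into one unit, ordered — and eventually
  numbered — by chromosome position rank, ties by identifier. Identity is
  computed by Needleman–Wunsch global alignment under BLOSUM62 with gap
  opening 10 and extension 0.5, terminal-gap columns excluded; the pair
  is ordered lexicographically before alignment so the measure is exactly
  symmetric even when tied-score alignments differ in gap placement.
* **Groups.** An orthologous cluster is partitioned into groups with at
  most one unit per subgenome. Conflicting units are separated along
  supported clades of the tree; where the deciding node falls below
  support 70 the partition falls back to a deterministic packing of the
  ortholog table's genes. Units are accepted into one group only if every
  cross-subgenome pair also reaches 80% identity — homoeologs are far
  more similar than that in practice, and the check prevents two adjacent
  single-gene groups from being fused merely because their subgenomes
  differ. For anchorless genes, which have no table entry at all, the
  same rule applied inside maximal all-anchorless supported clades is the
  only way to delimit groups, so it is load-bearing there.
* **Numbering.** Groups sharing an anchor are numbered 1..k in traversal
  order; anchorless groups receive consecutive bases starting at 153
  (configurable; the default continues an existing ortholog name series).
  Traversal order is the tree's stored (depicted) leaf order rotated so
  the first subfamily-"b" leaf comes first. A ladderized depth-first
  order was considered instead; the depicted order was chosen because it
  is what a reader of the published tree sees and it needs no tie-break
  cascade of its own.
* **Chromosome U.** A gene on an unplaced scaffold that clusters with
  putative homoeologs joins their group and keeps the letter U in its
  name.

Duplicate names are impossible by construction; `assign_names()` still
verifies uniqueness and treats a collision as an internal error.

## Expression analysis

A gene is responsive to a pathogen iff at least one condition (any
genotype and timepoint) has `|log2FC| > 1` and adjusted `p < 0.05`, both
strict — a fold change of exactly 1.0 or an adjusted p of exactly 0.05
never qualifies. Whether the significance column is an adjusted or raw p
differs between upstream differential-expression sources, so the column
is selectable (`p_col`), with adjusted as the default. Lifestyle
categories follow a declared pathogen panel (three fungal hemibiotrophs,
two biotrophs, one bacterial hemibiotroph by default), and "universal"
means responsive to at least two pathogens.

Baseline tpm values are averaged per gene and organ; a gene is expressed
in an organ at ≥ 0.1 tpm, and expressed values are binned low / moderate /
high at the 1st/3rd quartile edges — computed from the data
(`bin_edges = "auto"`, type-7 quantiles) or fixed at 0.3 / 3.7 tpm, the
published wheat values, which the pipeline uses as its default so bins
are comparable across runs. Grain-specific means expressed in grain and
in no other organ.

Statistics: subfamily enrichment uses the two-sided Fisher exact test per
subfamily with Benjamini–Hochberg adjustment across subfamilies (reported
raw and adjusted, since conventions differ); the family-vs-genome
comparison is a 2×2 Pearson chi-square without continuity correction
(df = 1), refusing zero expected cells; bit-score distributions across
subfamilies use a tie-corrected Kruskal–Wallis H with a greedy step-down
grouping — groups ordered by mean pooled rank, a subset extended while the
within-subset test stays non-significant at 0.05 — labeled as a greedy
partition because the legacy step-down procedure it emulates is
under-documented; and the Moses test of extreme reactions is implemented
exactly: the statistic is the span of the control ranks after trimming
`h = 1` extreme control observations per tail (ties broken by input
order, control first), and `P(span ≤ observed)` is computed from the
combinatorial null distribution, which the tests verify against full
enumeration for all pooled sizes up to 12. Heatmap ordering uses
agglomerative clustering with Euclidean distance and average linkage,
imputing 0 for untested conditions (logged).

## Motif analysis

Motif sites come either from MEME-style text output (`read_meme()`, with
a zero-or-one-site-per-sequence contract check for the CT discovery mode)
or from the deterministic exact-match scanner used on synthetic data.
Presence fractions per subfamily classify a motif as a signature
(> 90%), absent (< 10%) or present (otherwise — fractions of exactly
0.1 and 0.9 are both "present"); conserved means > 50% overall; specific
means reaching 10% presence in exactly one subfamily. The 10% specificity
floor is used even though observed subfamily-specific motifs can sit
slightly below it in real data; the class boundaries and the specificity
floor are the same parameter so they cannot drift apart. An occurrence
maps to a subdomain when at least half the motif length overlaps it
(largest overlap wins, otherwise "between-subdomain"), and the
motif-level label is the majority over occurrences — stated explicitly
because published subdomain comparisons are typically visual.
Motif–trait association (responsiveness, grain-specific expression) is a
per-motif two-sided Fisher test with BH q-values.

## The synthetic generator: what it emulates, and what it does not

`generate_family()` mutates a fixed planted NAM-consensus protein
(12-residue leader, 160-residue NAC core carrying five subdomain anchor
motifs, 100-residue tail) along a family → subfamily → group → homoeolog →
inparalog hierarchy. Substitution counts per branch are calibrated so
that the identities the downstream rules consume hit their configured
targets: inparalog pairs at `identity_inparalog` (default 90%, always
above the 80% rule), homoeologs near 92%, cross-group pairs near
`identity_cross_group` (default 60%, always below 80%). Anchor motifs
are never mutated, so subdomain location by exact match stays exact. A
small amount of `X` missing data exercises the completeness machinery.
Decoys are shuffled gene sequences — same composition, no domain — so
scanner specificity is tested without composition confounds. Group
structure (triad rate 0.6, inparalog rate 0.15, orphan rate 0.2,
chromosome-U rate 0.05, about 60 anchored groups giving families of
roughly 200 genes), responsiveness (rate 0.35 with hemibiotroph-skewed
pathogen weights), and grain specificity (rate 0.05) default to values
chosen to resemble a hexaploid NAC family and its published response
rates. The DE tables are generated at the table level: planted responders
get exactly one passing condition per pathogen
(`|log2FC| = effect + U(0, 0.5)` with `effect = 2.5`, adjusted p below
0.05) and every other row is drawn so it can never pass both thresholds —
the tables encode the planted truth with no leakage, because a
differential-expression table, not raw reads, is what the classifier
consumes. Adjusted p-values are planted directly rather than simulated
from counts for the same reason.

The tree implied by the truth is rebuilt deterministically (subfamily "b"
first, groups as caterpillar clades, one anchor leaf per anchored base,
one reference leaf per subfamily) with all supports at 100; support noise
degrades each internal node independently to a value below 70 with the
given probability, drawing per node regardless of the noise level so that
for a fixed seed the degraded set is nested as noise grows — which makes
the monotone-degradation property exactly testable rather than merely
statistical.

What the generator does **not** emulate: indels and alignment ambiguity
(sequences are equal length, so the MSA step is trivially complete),
read-level RNA-seq noise, codon-level evolution, paralog interleaving
across chromosomes, and genuinely discordant gene trees. Passing tests
therefore demonstrate that the decision rules are implemented exactly and
compose correctly — not that the pipeline is robust to alignment error or
tree estimation error on real proteomes, where the external aligner, tree
builder and HMM search carry that burden.

## Numerical choices and degenerate inputs

Thresholds are inclusive or strict exactly as documented: support ≥ 70,
identity ≥ 80, subclade fraction ≥ 0.6 and motif specificity ≥ 0.1 are
inclusive; `E < 0.01`, `|log2FC| > 1`, `p < 0.05`, signature > 0.9,
absent < 0.1 and conserved > 0.5 are strict. Degenerate inputs are
handled explicitly: empty CT regions are allowed; an all-gap row has
`Cr = 0` and is removed by the overlap filter; a subfamily with zero
members is skipped with a warning in enrichment; a single group is an
error for the Kruskal–Wallis test, as are samples too small for the Moses
trim; unknown pathogens and trait gaps are configuration errors, not
silent drops. All randomness in the package flows through explicit seeds
(`with_seed` restores the caller's RNG state), and a fixed seed makes
every artifact byte-identical across runs.

## Problem sizes

The test suite and the acceptance script run the full pipeline on
families of about 200 genes (the scale at which every structural feature
— triads, inparalog clusters, orphans, chromosome-U genes, all eight
subfamilies — occurs many times per seed), with ten independent seeds for
the truth-recovery suite and a five-level noise grid on two seeds for the
monotone-degradation property; exhaustive statistical oracles run at all
pooled sizes up to 12, where full enumeration is exact. These sizes were
chosen as the smallest at which each property is non-trivially exercised.

## Known limitations

The internal scanner is a log-odds window scorer, not a profile HMM: it
cannot model insertions in the domain, and its E-value is a crude
bit-score conversion meant only to make the retention rule uniformly
exercisable. Grouping quality under heavy support noise depends on the
deterministic fallback packing, which guarantees reproducibility, not
correctness. The step-down grouping is a greedy emulation and can differ
from other implementations near the significance boundary. The
completeness `Cij` uses the total-sites denominator. Real-data runs
require externally computed alignments, trees and domain tables in the
standard formats the package reads.
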