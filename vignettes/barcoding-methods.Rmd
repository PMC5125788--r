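---
title: "Methods: COI barcode identification of leptocephali"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COI barcode identification of leptocephali}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The identification problem

Anguilliform larvae are assigned to morphotypes from external characters
(body shape, myomere counts, pigmentation), but congeneric species can be
morphologically indistinguishable at the larval stage. The molecular route
compares a ~655 bp COI fragment from each specimen against a reference
library and reconciles the molecular verdict with the morphotype label.
`leptobarcode` implements that comparison as a pipeline of declared,
testable rules, with every tunable exposed.

## Distances and similarity

All distances are uncorrected p-distances: the proportion of differing
sites among compared positions. Comparison uses *pairwise deletion*: for
each pair, only columns in which both sequences carry an unambiguous base
(A/C/G/T) count; gaps and IUPAC ambiguity codes drop the column for that
pair only. This matches the common default of barcoding practice and keeps
per-pair information when queries are fragments of full-length references.
The similarity value is `SV = 100 * (1 - p)` on the same compared-site
support, so terminal overhang of a short query is missing data, never
mismatch. A pair with zero comparable sites has an *undefined* distance
(`NA`), never 0. A Kimura 2-parameter distance is provided for comparison
(`k2p_distance()`), but p-distance is the default throughout: at barcode
divergences the correction is small, and the uncorrected distance is the
scale on which the similarity thresholds are defined.

Unaligned pairs are aligned globally (Needleman–Wunsch via Biostrings) with
fixed scores — match +1, mismatch −1, a gap of length L costs 5 + 2L — and
deterministic traceback, so every run of the same inputs yields the same
alignment. Equal-length ungapped sets (simulator output, or any pre-aligned
set) are treated as positionally homologous and compared column-wise.

## The tier rule

The best similarity value against the library grants a rank:

| condition | rank |
|---|---|
| SV ≥ 98 | species |
| 92 ≤ SV < 98 | genus |
| 85 ≤ SV < 92 | family |
| SV < 85 | unassigned |

The intervals are half-open and cover [0, 100], so the rule is total and
deterministic; boundary values belong to the higher rank. The reported
taxon is the single best hit's lineage truncated to the granted rank (no
consensus over hits; a best-hit consensus mode is deliberately out of
scope). Thresholds are configurable (`pipeline_config(thresholds = ...)`)
but default to 98/92/85.

## Quality control

A functional mitochondrial COI fragment translates without internal stop
codons. QC screens each record under the vertebrate mitochondrial code
(translation table 2; stops TAA, TAG, AGA, AGG — note AGA/AGG, unlike the
standard code, and TGA = Trp):

- **Frame.** The reading frame is the one of 0/1/2 minimizing internal
  stops; the terminal codon, complete or partial, is never counted, since
  barcode fragments end mid-gene. If all three frames tie with more than
  zero stops the frame is *undetermined* (and the stop flag set); a
  two-way tie resolves to the lower frame.
- **Stops in reference coordinates.** When a reference is available
  (`qc_barcodes(records, references = ...)` screens each record against its
  best similarity hit), the record is first projected into the reference's
  coordinates — insertions dropped, deleted sites masked as N. Stop
  screening in the homologous frame is then robust to frameshifting
  indels, which would otherwise scramble the downstream codon structure and
  mask or fabricate stops.
- **Indels.** "Insertion or deletion" is only meaningful relative to
  something, so the primary criterion is an internal gap in the global
  alignment against the reference. Without a reference the fallback is the
  record's length mod 3 against the dataset's modal length class, and the
  report states which criterion was used (`indel_basis`).
- Ambiguity codes never count as stops and never break a frame; the report
  also carries length and the fraction of ambiguous sites.

QC failure flags a query prominently but never removes it from
identification: QC and similarity are independent evidence streams, and a
flagged record's assignment is still informative.

## Neighbour joining and bootstrap

Trees are built by the Saitou–Nei neighbour-joining algorithm from the
p-distance matrix, written here in full rather than delegated, so that
tie-breaking is pinned down: ties in the Q criterion resolve to the
lexicographically smallest pair of cluster representative labels, making
the tree a deterministic function of the matrix. Negative branch-length
estimates — expected occasionally from noisy small-sample distances — are
clamped to zero with the deficit moved to the sister branch, preserving
path lengths (the usual Kuhner–Felsenstein convention). On additive
matrices NJ is consistent; the test suite verifies exact topology recovery
on random additive matrices of 4–6 taxa against an exhaustive
least-squares topology oracle, and against `ape::nj` as an independent
implementation.

Bootstrap supports resample alignment columns with replacement, recompute
the distance matrix under the same pairwise-deletion rule, and rebuild the
NJ tree per replicate; an internal edge's support is the percentage of
replicates containing its bipartition. The pipeline default is 1000
replicates (the conventional choice); the analysis drivers and tests use
100, which is ample to saturate the clean splits they assert on. Trees are
rooted on the outgroup by placing the root at the midpoint of the
outgroup's pendant edge. Monophyly is evaluated on bipartitions for
unrooted trees (a set is monophyletic iff some edge separates exactly that
set), on clades for rooted ones.

## Diagnostic characters

The character classifier uses single-position pure diagnostics only: a
column/state pair is diagnostic for a species when every member carries
that unambiguous base and no non-member does, re-verified after
construction. A query is called as the unique species whose full
diagnostic set it matches; zero or several matches, or an N at a
diagnostic column, give a no-call — mirroring how character-based
classification tools return NA when reference coverage is thin. Species
with no diagnostic column are recorded and can never be called. Boolean
combinations of positions (as mined by dedicated character-based software)
are intentionally out of scope; this is the simplest defensible version of
the idea, not a clone of any tool.

## MOTU verdicts

For each group (reference species or query morphotype) the pipeline
summarizes within-group distances (mean, max) and distances to the nearest
other group (mean, min) and applies a declared, tunable rule with ratio
parameter R (default 5) and a zero-within cutoff of 0.02:

- within = 0 (or undefined, e.g. a singleton — flagged as a fallback):
  **distinct** iff mean-between ≥ 0.02, else **ambiguous**;
- **distinct** if min-between > max-within (a clean barcode gap) *and*
  mean-between ≥ R × mean-within;
- **merged-signal** if mean-between < R × mean-within;
- **ambiguous** otherwise.

The two calibration points are the qualitative situations the rule must
reproduce: a congeneric pair whose between-species distance (0.009) is the
same magnitude as the within-species distance (0.004) must not read as two
MOTUs (merged-signal), while a cluster with zero internal divergence
sitting 0.059–0.070 away from its nearest congeners must (distinct). Note
that under this rule exactly equal within and between means fall on the
merged-signal side, since R > 1.

## The synthetic data generator

The generator emulates the hierarchical structure the thresholds assume:
families ⊃ genera ⊃ species ⊃ specimens, realized on nested star
topologies — each taxon descends independently from its tier ancestor —
which gives direct control over tier means without birth–death machinery.
Substitutions are Jukes–Cantor-like (per-site, equal rates to the three
alternative bases); each branch's substitution proportion m solves the
two-lineage expectation `E[p] = 2m(1−m) + (2/3)m²` for its tier's target,
upper tiers incrementally over lower ones. Sequences are coding fragments:
a random stop-free codon sequence at the root, and any mutation creating an
in-frame stop is reverted, so clean simulated barcodes always pass QC.

Defaults: 5 families × 2 genera × 3 species × 4 specimens; fragment length
657 bp (the multiple of 3 nearest the ~655 bp COI barcode, keeping codon
structure clean); divergence tiers 0.005 (within species), 0.05 (within
genus), 0.10 (within family), 0.15 (between families). The tiers are
chosen to straddle the similarity thresholds — conspecific pairs at
SV ≈ 99.5, congeners ≈ 95, confamilials ≈ 90 — not to match any published
distance distribution. Realized tier means land within a few percent of
targets at this length (the tests allow ±30%).

Query simulation produces the three situations a survey meets. Conspecific
queries are simply additional specimens of a library species. Novel
lineages branch from a stored tier ancestor, never from a specimen, so
they attach *beside* existing species clusters rather than nesting inside
them (keeping reference species monophyletic, as real distinct species
are): a novel species branches from its genus ancestor targeting the
midpoint of the within-species and within-family tiers (≈ 0.05, the genus
band), a novel genus from its family ancestor targeting the midpoint of
the within- and between-family tiers (≈ 0.125, the family band). Branch
proportions invert the two-lineage expectation against the known
substitution depth of existing specimens, so realized similarities center
in their bands (observed: ≈ 99.7 / 95.6 / 88.8) with several standard
deviations of margin to the thresholds at 657 bp. For a library without
stored ancestors (external FASTA), novel lineages fall back to branching
from a sampled specimen at the tier target.

Artifact injection corrupts each record independently: with probability
`stop_rate`, one substitution converting an internal codon into a stop;
with probability `indel_rate`, a single 1-base internal insertion or
deletion (never a multiple of 3, hence always frameshifting). The two
artifacts are kept disjoint within a record — a deletion is never placed
inside the planted stop codon — so every truth flag remains independently
detectable, which is what the QC sensitivity tests assert. A single
integer seed drives every draw through one generator, and the caller's RNG
state is always restored; identical specs and seed give byte-identical
FASTA output.

**What the simulation does not emulate:** codon-usage bias, among-site
rate heterogeneity, transition/transversion bias, saturation at deep
divergences, coalescent population structure within species, incomplete
reference coverage, and length variation from real sequencing. Passing
tests therefore demonstrate the *logic* of the pipeline — thresholds,
flags, tree and verdict rules — under idealized divergence structure, not
its performance on real survey data, where reference gaps and uneven
divergences dominate the error budget.

## Numerical and design choices

- Distance/similarity edge cases: undefined (zero-overlap) distances are
  `NA` and propagate as such; matrices with `NA` entries are rejected by
  NJ rather than silently imputed.
- The within-group mean of a singleton group is undefined and reported
  `NA`, never 0; the MOTU rule's zero-within route then applies, flagged
  as a fallback.
- Alignment scoring constants are fixed (match +1, mismatch −1, gap
  5 + 2L) for bit-exact reproducibility rather than exposed as knobs; the
  SV scale, not the alignment score, is the quantity of record.
- The morphotype-vs-molecule congruence flag is `mismatch` only when both
  labels exist and disagree at the granted rank; a morphotype unknown to
  the reference library yields `indeterminate`, not `mismatch`.
- Problem sizes in the drivers and tests (120-reference library, 60
  queries, 100 bootstrap replicates, 200 additive matrices) were chosen as
  the smallest sizes at which every assertion is statistically comfortable;
  the pipeline itself has no size-dependent logic.

## Known limitations

Single-position diagnostics lose power as libraries grow (shared states
accumulate across species); the similarity search is exhaustive rather
than indexed, adequate for libraries of hundreds to a few thousand
records; multiple sequence alignment is out of scope (pairwise-to-reference
suffices for this pipeline's inputs); and the MOTU rule is a declared
heuristic for flagging, not a species-delimitation model — coalescent or
Bayesian delimitation is explicitly not attempted.
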