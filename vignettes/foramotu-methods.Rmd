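---
title: "Methods: amplicon inference and two-rank delimitation in foramotu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon inference and two-rank delimitation in foramotu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`foramotu` implements a complete inference chain for tag-multiplexed 18S
rDNA amplicon surveys of planktonic foraminifera, from raw reads to a
reference-anchored 4-rank taxonomy
(`Morphogroup;Genus;Morphospecies;GeneticType`) and an ecological
taxon-by-sample table.  This vignette records the models, the defaults and
the numerical decisions, in the order the pipeline applies them.

## The synthetic community generator

Because the chain is meant to be verifiable without external archives, the
package ships a generator (`generate_taxonomy()`, `evolve_references()`,
`simulate_reads()`) that emulates the structure of a size-fractionated
photic-zone survey and records full ground truth per read.

**What it emulates.**

* A hierarchical community: morphogroups (e.g. spinose, non-spinose,
  microperforate, basal, long-branch) containing genera, morphospecies and
  genetic types, with one reference sequence per genetic type.  Sequences
  evolve under Kimura's two-parameter (K80) substitution model with
  transition/transversion rate ratio κ = 2 (configurable): per site a
  Poisson number of events with mean equal to the branch length, each a
  transition with probability κ/(κ+2).  Branch lengths are chosen so the
  expected pairwise K80 distance is `divergence_between_types` (default
  0.05 substitutions/site) within a morphospecies and
  `divergence_between_species` (default 0.15) between morphospecies of one
  morphogroup.  The genus rank is nomenclatural and adds no divergence, so
  the between-morphospecies tier holds for every within-morphogroup pair.
* Rate heterogeneity: each morphogroup carries a `rate_multiplier` (≥ 1,
  default 3 for the long-branch group) scaling all its branches, emulating
  lineages with strongly elevated rDNA substitution rates.
* Reads: `tag + forward primer + insert [+ reverse-complemented reverse
  primer]`, with 8-nt tags designed by rejection sampling (pairwise
  Hamming distance ≥ 2, no homopolymer run over 2 nt).  Per-read
  within-genetic-type variation (expected pairwise K80 distance
  `divergence_within_type`, default 0.002) models intra-genomic rDNA
  polymorphism.  The survey grid defaults to 8 stations × 2 depths (SUR,
  DCM) × 3 size fractions, the full crossing of the strata of the
  motivating study design.
* 454-style noise: uniform substitution errors (default 10⁻³ per base) and
  indels confined to homopolymer runs of length ≥ 3 (default 2·10⁻³ per
  base of run), the characteristic pyrosequencing artefact.
* Chimeras: a fixed proportion of reads (default 5%) are two-parent
  concatenations with a single breakpoint, parents drawn
  abundance-weighted from two *distinct* genetic types of the same sample.
  The breakpoint is uniform in the middle 60% of the 300-bp region
  retained after trimming (positions 61–240): chimeric joints outside the
  analysed window are invisible to any detector by construction, so
  placing them inside it is what makes the generator a meaningful test of
  the screen.
* Length structure: an exact per-sample count, `round(fraction_full_length
  × n)` (default fraction 0.3222), of reads runs through to the reverse
  primer; the rest are truncated uniformly.
* Community structure: per-fraction clade weights bias small fractions
  towards the microperforate/basal/long-branch groups and the large
  fraction towards spinose/non-spinose groups (configurable via
  `clade_weights`); a configurable fraction of reads (default 10%) derives
  from non-foraminiferal outgroup taxa to exercise the non-target screen.

**What it does not emulate.** Flowgram-level 454 artefacts (quality
scores, SFF structure), PCR amplification bias between taxa, chimeras with
more than two parents, intergenic variation beyond the single barcode
region, and realistic biogeography.  Green tests therefore certify the
*inference machinery* under controlled noise, not field performance on any
particular instrument.

Per-sample depth defaults to 1,000 reads; the test-suite fixtures use
150–500 reads per sample and the acceptance script 300, sizes at which
every genetic type is still comfortably sampled.

## Read preparation

* Demultiplexing compares the leading 8 nt to the tag map; the default
  tolerance is 0 mismatches (configurable).  Reads matching no tag, or
  more than one within the tolerance, are rejected with a reason.
* Quality filtering retains reads containing the exact forward primer
  (S15rF, which has no degenerate bases) and no character outside ACGT.
* Trimming keeps the 300 bp immediately 3′ of the forward primer.  Reads
  with fewer than 300 bp after the primer are dropped: all downstream
  distances (edit distance at *d* = 2, K80, alignment identity) assume a
  shared region, and ragged lengths would conflate length with divergence.
  Trimming an already-trimmed read is a no-op.
* The reverse primer (S19F) carries two R ambiguities; its reverse
  complement is searched IUPAC-aware with ≤ 1 mismatch in the 3′ half of
  each read to report the fraction of full-length amplicons.

## Chimera screening

Dereplicated amplicons (deterministic order: total abundance descending,
then lexicographic) are screened de novo, most abundant first.  For a
query, candidate parents are amplicons at least `abskew` = 2 times more
abundant.  The best two-parent model — one breakpoint, evaluated by prefix
sums of per-column matches — is compared with the best single parent; a
query is flagged only if

1. the chimeric model's identity exceeds the best single-parent identity
   by ≥ `min_div` = 0.8 percentage points,
2. the vote score reaches `min_score` = 0.28, where each column at which
   the two parents disagree votes *yes* (query matches the model), *no*
   (matches the other parent) or *abstain* (matches neither), each side of
   the breakpoint scores `Y/(Y + 8·N + 1.4·A)`, and the final score is the
   smaller side — both parents must contribute signal, and
3. no single parent explains the query within `min_div` under *gapped*
   (edit-distance) identity.  This last guard exists because the columnar
   model cannot absorb frame shifts: a read carrying one homopolymer indel
   looks ~10 identity points away from its own template yet can be
   "explained" perfectly by a template plus an indel-sharing relative,
   which is an alignment artefact, not a chimera.

Thresholds and weights are the published UCHIME/USEARCH defaults and are
configurable.  With many amplicons, candidate parents are restricted to
the `top_k` = 64 best 6-mer matches collected per query chunk (8 chunks of
the query, top 8 each): chunked collection is essential because
whole-query ranking is dominated by relatives of the majority parent and
crowds out the minority-side parent; 6-mers (4,096 words) are used because
4-mer presence sets saturate on 300-bp amplicons and carry almost no
ranking signal.  Below 200 amplicons the search is exhaustive, and the
test suite checks verdict equality against a brute-force oracle over all
(parent A, parent B, breakpoint) triples.

## Clustering and MOTU filtering

MOTUs are the connected components of the graph joining amplicon pairs at
Levenshtein distance ≤ *d* (default 2; indels count, as in SWARM v1), grown
breadth-first from the most abundant unassigned amplicon.  A banded
dynamic program with early exit and a 6-mer prescreen (one edit changes at
most six distinct 6-mers) keeps the scan near-linear in practice; the test
suite asserts exact equality with brute-force connected components.  No
cluster-breaking refinement is applied: the cited clustering behaviour is
pure single linkage.

MOTUs are retained for delimitation when they occur in ≥ 3 samples with
≥ 10 total reads; the rare remainder re-enters at the reassignment stage.
Each retained MOTU receives a representative sequence: among untrimmed
reads whose post-primer prefix equals the MOTU seed, the longest, then the
most abundant, then the lexicographically smallest — preserving the
seed's identity while recovering the longest available stretch of the
amplicon for the meta-reference.

## Taxonomic assignment

Global–global (Needleman–Wunsch, affine gaps) alignment with match +5,
mismatch −4, gap open −12, gap extend −4; identity is matching columns
over *all* alignment columns, end gaps included.  The aligner is a small
C++ kernel cross-checked in the tests against `Biostrings::pairwiseAlignment`
under the same scoring.  An edit-distance prescreen aligns only references
within 6 edits of the closest one — only those can attain the best
identity, and exact ties are preserved.

Ties at the best identity with one taxonomy path are unambiguous; ties
with conflicting paths set the `ambiguous` flag.  For 4-rank paths the
deciding rank is the morphospecies (rank 3): equal-identity hits agreeing
there but differing in genetic type assign to the morphospecies with
genetic type `unresolved`, retaining resolvable cases instead of
discarding them.  MOTUs whose best hit does not carry `Foraminifera` at
level 3 of the reference path are discarded as non-target.

## Two-rank delimitation

Within each clade (crown group), pairwise K80 distances are computed on
the shared 300-bp region with pairwise deletion of gapped or ambiguous
sites; pairs sharing fewer than 100 comparable sites are flagged
unreliable, and saturated pairs (non-positive logarithm argument) are
errors for the scalar function and `NA` with a warning in the matrix.
Delimitation runs per clade precisely because cross-clade distances —
especially involving long-branch groups — approach saturation, where K80
is uninformative.  The module consumes *aligned* sequences; multiple
sequence alignment is out of scope, and indels present themselves as gap
columns handled by pairwise deletion.

The prior sweep evaluates 100 log-spaced priors *P* in [0.001, 0.2] (the
defaults of the original barcode-gap software).  At each prior the sorted
distance list is scanned for the first interval whose upper end exceeds
*P* and whose width exceeds 0.5 × the running mean of the distances below
it; sequences linked at distances at or below the gap's lower bound form
groups, and the scan recurses within groups (depth ≤ 10; groups of < 3
sequences are never split, as gap detection is undefined there).  Using
"at or below the lower bound" rather than "strictly below" keeps pairs
sitting exactly at the gap's lower edge together, which is the only
reading consistent with the intended behaviour on clean two-cluster data.
A degenerate matrix (all distances equal) yields a single group at every
prior, with no error.

Runs of consecutive priors with identical partitions form plateaus.  Rank
selection is anchored to the references: admissible plateaus for the
*morphospecies* level never co-cluster references of distinct
morphospecies; admissible plateaus for the *genetic-type* level never
co-cluster references of distinct genetic types of one morphospecies.
Among admissible plateaus the default rule picks the one with the fewest
groups ("coarsest admissible"): the literal alternative — the plateau at
the lowest prior — is vacuous, because the finest partition never merges
anything.  A `longest_span_admissible` rule is available.  The
genetic-type plateau is chosen among those refining the selected
morphospecies partition, which enforces the nesting invariant by
construction; if no admissible plateau exists the finest partition is used
with a warning.  Environmental sequences inherit labels from co-clustered
references; groups without references found new morphospecies
("<clade> A", "<clade> B", …) and new genetic types ("<species> Type I",
…).

A per-clade policy (`apply_clade_policy()`) can collapse genetic types to
the morphospecies label.  This is the conservative treatment for clades
whose reference material carries no molecular taxonomy and whose high
intragenomic rDNA variability could masquerade as diversity below the
morphospecies level — typical for basal, benthic-derived lineages.

Optional validation maps the delimitation onto a user-supplied
phylogenetic tree: patristic distances are classed as intra-genetic-type,
inter-genetic-type-within-species, or inter-species, and consecutive
classes are compared with two-sample Kolmogorov–Smirnov and Mann–Whitney
tests.

## Meta-reference and final table

The meta-reference concatenates the planktonic reference database, any
benthic references, and the delineated environmental representatives with
their new 4-rank paths.  Every MOTU — including the rare ones excluded
before delimitation — is reassigned against it on the shared 300-bp
region.  Retention requires identity strictly greater than 95%
("greater than 95%" is implemented strictly; an `inclusive` switch admits
the boundary) and unambiguous attribution at the morphospecies rank.
Retained MOTUs inherit the hit's path, and MOTUs sharing a path merge by
summing per-sample abundance vectors, so reads are conserved:
retained + excluded = all foraminiferal reads, an invariant asserted in
the tests.

## Ecology

Rarefaction uses the analytic hypergeometric expectation
`E[S_n] = Σ_i [1 − C(N−N_i, n)/C(N, n)]` (via `vegan::rarefy`), not
resampling: it is deterministic, exact, and the tests verify it against
exhaustive enumeration at small sizes and Monte-Carlo subsampling
elsewhere.  Curves are reported per station, depth, size fraction, sample
or for the pooled dataset; the module reports curves and leaves any
"saturation" judgement to the analyst, since no principled saturation
criterion exists for the expectation itself.  Composition summaries give
per-sample relative clade proportions grouped by size fraction, with an
optional user-supplied sediment census appended as a pseudo-fraction for
side-by-side comparison.  Displayed abundances in log scale use
log10(count + 1).

## Determinism and tie-breaking

Every stochastic step flows from a single integer seed (the generator
restores the caller's RNG state).  All orderings are total: amplicons by
abundance then sequence; MOTUs by seed order; representatives by length,
abundance, then sequence; assignment ties by reference order after path
comparison.  Identity ties are compared at 10⁻⁹ to absorb floating-point
noise.

## Known limitations

* The chimera scorer is a simplified, documented variant of the published
  UCHIME rule (per-side votes, no chunk-level voting within sides); it
  reproduces the decision behaviour on constructed cases but not the
  original's exact scores.
* The barcode-gap sweep uses the running-mean relative-gap criterion
  described above rather than the original software's slope-based
  inference; only the distance model (K80), the relative gap (0.5) and
  the number of steps (100) are pinned to the published procedure.
* K80 with pairwise deletion assumes a fixed shared region; it does not
  model among-site rate variation, and saturated pairs are unusable
  rather than corrected.
* Manual curation steps of real studies (exclusion of short or suspect
  representatives) are supported only via an explicit `exclusion_list`.
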