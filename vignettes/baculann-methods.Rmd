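---
title: "Methods and design notes for baculann"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for baculann}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baculann)
```

`baculann` packages the standard analytical workflow of a baculovirus genome
report: ORF calling on a circular genome, promoter-motif classification,
homologous-region (hr) detection, pairwise comparative genomics, and qPCR
replication kinetics. This vignette records the models behind each stage,
the conventions and tunable parameters, why the defaults are what they are,
and what the synthetic-data generator does and does not emulate.

## Coordinates and containers

All coordinates are 1-based and inclusive. Position 1 is the adenine of the
polyhedrin start codon — the conventional zero point of an NPV physical map —
so the polyhedrin gene is ORF 1 and needs no coordinate shift on export.
Features crossing the origin of a circular genome are stored with
`start > end` plus a `wrap` flag; their span is
`end - start + 1 + genome_length`. In GFF3 output a wrapping feature becomes
two `CDS` part lines sharing one `ID`.

Two length conventions coexist in the field and both are reported: the
*genomic span* of an ORF includes its stop codon (span = 3·aa + 3), while
the *nominal length* in "bp" is 3·aa, the convention under which a 50-aa ORF
is "150 bp". `summarize_genome()` reports both, along with two coding
totals: the plain span sum and the overlap-collapsed union, because the two
differ exactly by the pairwise overlaps and published totals rarely say
which convention they used.

`N` is accepted in sequences (draft-genome tolerance) but excluded from GC
and AT percentages, never matches in palindrome scans, and disqualifies any
ORF candidate with an `N` in a codon.

## ORF calling

`find_candidate_orfs()` applies the classic NPV annotation criterion: an ORF
starts at ATG, ends at a stop codon, and encodes at least `min_aa = 50`
amino acids, counting the initiator Met and excluding the stop — so the
50-aa threshold corresponds to a 153-nt genomic span. Each stop-to-stop
interval of each strand and frame contributes at most one candidate,
anchored at its *first* ATG (the longest ORF of the interval), matching the
default behaviour of the interval-based ORF finders genome reports rely on.
If the first ATG of an interval would yield an ORF longer than the circle
itself, the anchor advances to the first ATG whose span fits — an ORF cannot
be longer than the genome it sits on.

Circularity is handled exactly rather than approximately. On a circle whose
length is not a multiple of 3, the three reading frames of a strand merge
into a single cyclic orbit of L codons with period 3L nt (for L divisible by
3, each frame is its own orbit of period L). The scanner walks a linear
extension of the sequence covering two full orbit periods plus two
nucleotides, which guarantees that every stop-to-stop arc — including an arc
bounded by a single stop codon spanning the whole circle — appears
contiguously, with a genuine left-bounding stop, in at least one linear
frame. Coordinates are mapped modulo L and deduplicated. The unit tests hold
this equal to a brute-force oracle (try every position and strand, walk
codons cyclically) across 1,000 random genomes.

`resolve_minimal_overlap()` makes "minimal overlap" concrete: candidates are
processed in decreasing protein length (ties by position, so the result is
independent of input order), and a candidate is kept iff its inclusive-span
intersection with every kept ORF is at most `max_overlap_nt` and it is not
fully nested inside a kept ORF. The default cap of 250 nt was chosen because
curated NPV tables retain overlapping pairs up to the ~245-nt range while
rejecting longer conflicts; the cap is a parameter, not a constant.

## Promoter classification

Baculovirus transcription uses two consensus signals. The *early* (host RNA
polymerase II) signal is modelled as a TATA box with a CAGT or CATT
initiator whose first base lies 20–40 nt downstream of the TATA's first
base. The *late* signal is the viral-polymerase initiator (A/T/G)TAAG.
`classify_promoters()` scans the `window = 180` nt immediately upstream of —
and not including — the A of the ATG, on the ORF's coding strand, wrapping
the origin on circular genomes. Classes are: `both` if at least one early
pair and one late hit, `early`/`late` if only one kind, `none` otherwise;
the four tallies always sum to the ORF count.

Conventions that had to be fixed:

- The TATA box is the literal 4-mer `TATA` by default. Published screens
  rarely state their box definition; the loosest literal reading is the only
  defensible default, and `tata_pattern` accepts simple IUPAC codes (e.g.
  `"TATAWA"`) for stricter screens.
- The spacer is measured first-base-of-TATA to first-base-of-initiator,
  a common promoter-annotation convention; both bounds are parameters.
- Motifs must lie wholly inside the window: a motif overlapping the ATG is
  not "upstream" and does not count.
- The window is taken from raw sequence even where it overlaps an adjacent
  ORF; no exclusion rule is applied, since any such rule would be an
  invention with no principled setting.

Classification is invariant under reverse-complementing the genome (with
ORF coordinates and strands mirrored), which the tests assert.

## hr detection

hrs are modelled directly as what they are described to be: clusters of
~40-bp perfect or near-perfect palindromes (type A) with 31-bp direct-repeat
flanks (type B) in AT-rich intergenic sequence.

*Type A* — `find_palindromes()` slides a `unit_len = 40` window and counts
mismatches between the left arm and the reverse complement of the right arm;
units pass at `max_arm_mismatch = 3` ("near-perfect"). The reported
`mismatches` field is the Hamming distance of the unit to its own reverse
complement, i.e. twice the arm count. Overlapping windows within
`unit_len/2` are merged, keeping the fewest-mismatch window with ties broken
by closeness to the cluster centre and then by position. The centre rule
makes the merge reversal-symmetric in all but one degenerate case: when a
cluster holds two equally good windows placed symmetrically about its
centre, no positional rule can be direction-invariant, and the reported
representative may shift within the cluster between a genome and its
reverse complement. Detection itself (cluster count and mismatch profile) is
strictly invariant.

*Type B* — `find_flank_repeats()` searches within `search_radius = 100` nt
of each A unit for 31-nt segments matching a genome-wide consensus with at
most `max_mismatch = 4` mismatches, at most one B unit per side per A unit.
The consensus is built greedily: candidate windows are all admissible 31-mers
in the flank regions — a window overlapping *any* palindromic unit is
excluded, since neighbouring A units fall inside the radius and the
palindrome sequence itself must not masquerade as a flank repeat. The most
frequent candidate k-mer seeds the consensus; among equally frequent seeds
the one accepting the most flanks wins, with remaining ties broken by the
smallest total mismatch over accepted flanks (this keeps the consensus in
phase with the repeat rather than one column off). One round of per-column
majority voting over the accepted flanks refines it. A consensus supported
by fewer than two flanks is discarded: a lone self-match is not a repeat.

*Regions* — `call_hrs()` single-links units with inter-unit gaps up to
`max_gap = 500` nt; clusters with at least `min_units = 2` type-A units
become regions named `hr1`, `hr2`, … in genome order. Defaults were chosen
so that hr regions of the size range seen in NPV genomes (~0.7–1.8 kb) each
form a single cluster. AT content is reported per region, not gated —
"AT-rich" is a qualitative observation, so the caller only drops a cluster
when an annotation is supplied and the cluster overlaps an ORF by more than
half its length.

`diff_hr_architecture()` pairs regions by rank and computes a minimal
insert/delete edit script over unit tokens (type + orientation) by LCS-style
dynamic programming, reporting runs with their nucleotide extents — the
repeat-unit-level comparison used when hr architectures diverge between
related genomes.

## Comparative genomics

`align_global_identity()` is a Needleman–Wunsch global aligner (Rcpp) under
identity scoring: match +1, mismatch 0, gap −1 per column, with a
deterministic traceback (diagonal, then up, then left). Percent identity
uses the full alignment length including gap columns; the denominator is a
declared convention, not a claim. Tests pin the score to an exhaustive
enumeration over all non-crossing matchings on tiny instances and to an
independent aligner under the equivalent scoring scheme.

`map_homologs()` pairs proteomes by reciprocal best hit on percent identity
(ties by score, then lower index), dropping pairs below `min_pct = 15` —
low enough that genuine but diverged homologs in curated tables (identities
down to ~17%) are never discarded. Reciprocal best hit was chosen over
E-value searches because it is deterministic, dependency-free, and adequate
at the scale of viral proteomes; curated homolog columns can always be
supplied directly instead.

`gene_parity()` produces the identity–gene-parity data: shared ORFs as
points at (rank in A, rank in B) with identity bins (default cut points
30/50/70), unpaired ORFs listed as unique to their genome. A duplicate
pairing on the A side is an integrity error; duplicated partners on the B
side are tolerated because curated tables occasionally map two query ORFs
onto one subject ORF. `collinearity_stats()` adds the Spearman rank
correlation and the fraction of consecutive-in-A point pairs that are also
consecutive in B. `detect_segmental_indels()` reports maximal runs of at
least `min_run = 2` consecutive ORFs with no partner, flanked by paired ORFs
(a missing flank at a genome end is flagged "terminal").

`scan_transposon_signature()` finds the classic TTAA-family insertion
signature: perfect inverted terminal repeats of `itr_len = 13` nt whose
element is bracketed by the `TTAA` target-site duplication immediately
outside both ITRs. ITRs must be exact — the signature is defined by perfect
repeats — and the scanner equals an exhaustive pair enumeration on every
tested sequence.

## qPCR kinetics

`fit_standard_curve()` regresses Ct on log10(copies) by OLS (triplicates
averaged on the Ct scale, the common practice) and derives the
amplification efficiency 10^(−1/slope) − 1, warning outside [0.8, 1.1];
r² is computed directly from the residuals so that an exactly collinear
dilution series does not trip the perfect-fit warning in `summary.lm`.
`quantify()` inverts the curve; `normalize_copies()` reports viral copies
per 10⁵ host actin copies and is invariant under common rescaling of both
inputs.

`annotate_phases()` labels each between-timepoint interval from its log₂
rate r: `exponential` at r ≥ 0.5 log₂/h, `decreasing` at r < −0.05,
`stationary` for 0 < r < 0.5 after the last exponential interval, `latent`
otherwise. The two thresholds are invented, configurable knobs — published
phase boundaries are read off growth curves by eye, so the defaults were set
to reproduce the canonical four-phase trajectory (a drop to 4 h, a flat
latent stretch to 12 h, a doubling every ~1.25 h to 48 h, then a slow rise)
and are not claimed to be biologically calibrated. `kinetics_summary()`
reports fold change, doublings = log₂(fold), doubling time =
window/doublings, plus the rounded doubling count and its doubling time,
because published summaries round to whole genome duplications. A fold of 1
leaves the doubling time undefined (reported as NA).

## The synthetic-data generator

`generate_annotated_genome()` exists so that every pipeline stage can be
tested against known truth without downloads. Its central design decision is
an invariant, not a probability: outside planted features the emitted
sequence never contains the dinucleotide `AT`. Both spellings of a start
codon — ATG on the plus strand and CAT (the plus-strand image of a
reverse-strand ATG) — contain `AT`, so the only start codons in the genome
are the planted ones, and ORF recovery is exact by construction. The
generator asserts this after assembly by counting ATG/CAT occurrences
against the planted strand totals.

Consequences and ingredients:

- Gene bodies are drawn from the codon alphabet without `AT`, which also
  excludes internal Met and all Ile codons. Synthetic proteins therefore
  lack I and internal M — a deliberate unrealism, traded for provable
  recovery.
- Spacers are token streams over plus- and minus-strand stop codons and
  GC-balanced fillers, none containing `AT`, with junction rules (and
  single-base repairs at block boundaries) preserving the invariant.
- Promoter windows are exactly the 180 nt upstream of each ORF, built as
  token streams with motifs spliced in at sampled offsets (TATA first base
  at 60–170 nt, spacer 20–40 nt, late initiator at 10–170 nt), then scrubbed:
  windows whose class must lack a signal have every TATA and/or (A/T/G)TAAG
  destroyed by single C/G substitutions, re-scanned until clean. Promoter
  recovery is thus exact for all four classes.
- hr cassettes interleave B and A units (B A B A … B) around one
  genome-wide B consensus and one palindrome template, with configurable
  per-unit noise (default one substitution) and AT bias 0.7, separated by
  short token gaps. Default A-unit counts (3–7 per cassette) and four
  cassettes give regions in the realistic 0.3–0.7 kb range.
- `diverge_genome()` derives a partner genome: substitutions at the
  configured rate (synonymous-biased inside ORFs — 70% synonymous swaps —
  and suppressed inside promoter windows and hr units so motif and repeat
  tests stay orthogonal to divergence), one contiguous multi-gene deletion,
  and optionally one gene relocated (with its promoter window) to a new
  locus near the end of the genome.
- `simulate_qpcr_experiment()` draws the four-phase trajectory anchored at
  the canonical endpoint values (452 per 10⁵ actin at 12 h, 2.02 × 10¹¹ at
  48 h, 1.17 × 10¹² at 96 h), inverts configured standard curves to Ct, and
  emits noisy triplicates (default Ct sd 0.3). With zero noise the analysis
  pipeline reproduces the true normalised values exactly.

What the generator does *not* emulate: realistic codon usage or base
composition, indel evolution beyond the single planted deletion, rate
heterogeneity across sites, overlapping genes, promoter windows shared
between convergent gene pairs, or hr sequence turnover. Passing recovery
tests therefore demonstrate algorithmic correctness under clean conditions,
not performance on messy real genomes; the packaged HearMNPV table provides
the real-data anchor for the table-level statistics.

## Problem sizes and numerical conventions

The test and acceptance workloads are sized for a desk machine: oracle
equivalence suites run 1,000 random instances of 60–160 nt against
brute-force re-implementations; recovery tests use genomes of ~9–15 kb with
12–18 genes and four hr cassettes; the qPCR recovery study runs 200 noisy
simulations. Exhaustive alignment enumeration is limited to sequences of
length ≤ 7, where the full matching space is tractable.

Fixed tie-breaks keep every result deterministic: alignment traceback
diagonal > up > left; overlap resolution longest-first then leftmost;
palindrome merge fewest-mismatch then centre-closest then leftmost; homolog
ties by score then lower index; flank-consensus seeds by frequency, then
flank acceptance, then total mismatch, then lexicographic order. Degenerate
inputs follow one rule: impossible requests error with a message (empty
annotation tables, two-point standard curves, zero actin copies,
out-of-range deletion blocks), while legitimately empty results (no ORFs on
a poly-A genome, no palindromes longer than the genome) return empty
containers.

## Known limitations

- The promoter screen is literal-motif matching; no position-weight
  matrices, so counts are sensitive to the (configurable) TATA definition.
- The hr flank consensus is greedy; pathological repeat landscapes could
  anchor it off-phase, though the tie-break rules make this rare and the
  planted-cassette recall stays above 95% at 5% per-unit noise.
- Reciprocal best hit cannot represent many-to-one homology (gene splits
  or fusions); such cases must be supplied via curated tables.
- `detect_segmental_indels()` works at gene-order resolution; it does not
  align intergenic sequence across the indel boundary.
- The qPCR model assumes constant host actin copy number per extract and a
  single global efficiency per target.
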