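---
title: "Pruning fungal ITS2 metabarcoding reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pruning fungal ITS2 metabarcoding reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fungits)
```

# The problem

Soil and other environmental samples are routinely profiled for fungi by
amplifying the ITS2 region of the rRNA operon and sequencing the amplicons
as paired-end Illumina MiSeq reads. Between the sequencer and an ecological
analysis stands a long chain of read-pruning decisions: low-quality pairs,
unmergeable pairs, PCR artifacts carrying extra primer copies, reads in
mixed orientation, reads whose multiplexing labels cannot be trusted, the
conserved rRNA flanks that inflate similarity between unrelated sequences,
PCR chimeras, and co-amplified non-fungal organisms. `fungits` implements
that chain as a set of small, independently runnable stages, each of which
accounts for every read it receives and writes its intermediate output so
that any two stages can be cross-checked by hand. The design premise is
that users should be able to understand, modify and error-check every
pruning step rather than trust a black box.

The amplicon model throughout is a dual-tagged molecule:

```
tag (8 bp) + forward primer + 5.8S flank + ITS2 + LSU flank +
  revcomp(reverse primer) + revcomp(tag)
```

with the *same* tag on both ends. Double labelling is what makes tag
switching detectable: a molecule that acquired a foreign label during
library preparation will carry inconsistent tags at its two ends and can
be rejected outright.

# Stages and their models

## Paired quality filtering

A pair is kept only when *both* mates have mean phred quality at or above
`mean_q_min` (default 26) and length at or above `len_min` (default 150
bases). Judging the pair jointly preserves the positional synchronization
of the two FASTQ files, which the assembler depends on. Quality encoding
is fixed to phred+33; other offsets are rejected rather than auto-detected
because silent auto-detection can mask corrupted input.

## Paired-end assembly

Overlap-based merging considers every candidate overlap length L from
`min(len1, len2)` down to `min_overlap` (default 5) between the 3' end of
R1 and the 5' end of the reverse-complemented R2, scoring each as matches
minus mismatches. The best score wins; ties go to the longest overlap
(more evidence). Consensus bases where the mates agree get quality
`min(q1 + q2, 41)`; disagreements take the higher-quality base with
quality `|q1 - q2|`, and an exact quality tie keeps R1's base at quality 2
so the uncertainty stays visible downstream. Pairs are rejected (a
categorized outcome, not an error) when no candidate overlap exists, when
the best overlap's mismatch fraction exceeds `max_overlap_mismatch_frac`
(default 0.25), or when the merged sequence contains an N. This is a
transparent, oracle-checkable rule set rather than a probabilistic
assembler: the unit tests re-derive every merge with a brute-force oracle
that scores all overlaps explicitly.

## Multi-primer artifact removal

Some library molecules carry extra internal primer copies at plausible
insert lengths, so they pass electrophoresis and chip-based QC and surface
only in the reads. A merged read is kept only if each primer occurs at
most once, counting exact occurrences on both strands. Primers with
ambiguity codes are rejected here because occurrence counting is exact.

## Reorientation and demultiplexing

Roughly half of all merged amplicons are reverse complements of the other
half. A read containing the forward primer (with up to `mismatches`
substitutions, default 1) anywhere is kept as-is; one whose reverse
complement contains it is flipped; reads with evidence in both
orientations, or neither, are discarded with a reason. The operation is
idempotent.

Demultiplexing then requires a *perfect* match of `tag + forward primer`
at the very start of the read and `revcomp(tag + reverse primer)` at its
very end, for the same sample. Anchoring the patterns to the read ends is
stricter than grep-style matching anywhere (which remains available via
`anchored = FALSE`); strictness here is deliberate, since label errors
reassign reads *between samples*, the most damaging failure mode in a
multiplexed design. After assignment, sample names are folded into the
headers (`sample=NAME;`), samples are pooled, and the constant 26-bp
tag+primer head and tail are trimmed.

## ITS2 extraction

The ITS2 is delimited by conserved rRNA regions (the 5.8S 3' end upstream,
the LSU 5' start downstream). Leaving those flanks attached biases both
clustering and homology searches because they raise the apparent
similarity of unrelated sequences. Extraction searches a window (default
80 bases) from each read end for the best match of a configurable IUPAC
motif list — fewest mismatches first (default at most 1), then the
outermost position — and keeps only the sequence strictly between the two
motifs, requiring at least 30 extracted bases, below which a fragment is
uninformative at a 97% clustering radius. The motif model is data, not
code: it ships as `inst/extdata/its2_anchors.yml` and the simulator uses
the same motifs, so the tests are independent of any particular motif
choice. Both flanks are required; reads failing the structural model go to
a discard stream with per-reason counts.

## Dereplication, abundance sorting, greedy OTU clustering

Identical full-length sequences (case-insensitive) collapse to unique
sequences annotated `;size=N;`. Uniques are sorted by decreasing size
(ties broken lexicographically, for determinism) and sizes below
`min_size` (default 2, i.e. singleton removal) are dropped: a sequence
observed once is more likely a sequencing error than a taxon.

Greedy centroid clustering then processes uniques in order: a unique joins
the first existing centroid within the identity radius (default 0.97);
otherwise it is screened as a potential bimera (below); otherwise it
founds a new centroid. Because processing is in descending abundance,
centroids are always at least as abundant as their members, and summed
sizes are conserved across centroid members plus flagged chimeras — an
invariant asserted in the tests.

## The pairwise identity definition

All thresholds share one alignment definition: match +1, mismatch −1, gap
open −2, gap extension −1 (a length-L gap costs `open + L*ext`), with
every terminal gap run free — the alignment may start and end anywhere in
either sequence; only its interior is global. Identity is

```
matches / (alignment columns + min(unaligned bases of a, unaligned bases of b))
```

Two deliberate choices deserve explanation.

*Fully free ends.* A dovetail-only formulation (alignment forced to reach
the end of one sequence) cannot represent a prefix-to-prefix overlap. That
case matters for chimera detection: the shorter parental segment of a
bimera matches a *prefix* of its parent, and under dovetail semantics that
segment would be forced to pay for the unrelated remainder, hiding the
parent signal. With all four terminal gap runs free, the score equals an
affine-gap local alignment score, which the tests verify against an
independent aligner.

*The min-overhang denominator.* Counting only aligned columns makes
identity degenerate: two random sequences almost always share some short
perfect overlap, which would score identity 1.0. Counting the smaller
side's unaligned bases in the denominator penalises such spurious
overlaps, while a pure length surplus of the *longer* sequence
(containment; ragged extraction ends) still does not depress identity —
`ACGT` against `ACGTACGT` is 1.0, and a truncated ITS2 still matches its
full-length sibling at 1.0. Identity is defined on the unordered pair: it
is computed on the lexicographically sorted pair so that tie-breaking
among co-optimal alignments cannot make it asymmetric.

## Chimera screening, de novo and against a reference

Both filters use the same explicit bimera rule. Each parent is projected
onto the query through a pairwise alignment, giving per-position match
indicators; every crossover position is scanned for the best two-segment
model (left from one parent, right from the other). A query is bimeric iff
some crossover achieves model identity ≥ 0.97, an improvement of at least
0.02 over the best single parent, and at least 3 diagnostic differences on
each side (positions where the segment's own parent matches and the other
does not). The de-novo filter takes candidate parents from already-formed
centroids whose sizes are at least twice the query's — a chimera arises
after its parents in PCR, so it cannot out-amplify them two-fold. The
reference filter takes candidates from a trusted sequence collection,
pre-ranked per query chunk by shared 8-mers (4 chunks, top 4 per chunk);
references carry no abundances, so the skew rule is waived there. The
k-mer pre-ranking only limits which parent pairs are *considered*; the
verdict always comes from the full alignment rule, so candidate-set misses
can only lose chimeras, never invent them — the tests assert exactly this
asymmetry, and plus-strand-only searching means reverse-complemented
chimeras are knowingly not detected.

Published practice with much larger data puts combined chimera losses
around 12% of clustered OTUs; the package's `chimera_accounting()`
reproduces that arithmetic from per-stage counts.

## Taxonomy gating and the OTU table

Homology searches against general nucleotide databases are external to the
package; their tabular results (query, lineage, bitscore, e-value) feed a
lowest-common-ancestor assignment: hits below bitscore 170 are dropped,
hits within 5% of the best bitscore are retained, and the assignment is
the longest common lineage prefix. "Upper percentage" is interpreted as
percent of the best bitscore; the alternative (a raw score window) is not
derivable from the published parameterization, so the choice is documented
here. `min_support` (default 1 = no-op) trims each assignment to its
deepest node supported by at least that many queries, counting queries at
or below the node. OTUs whose lineage contains `Fungi` are retained;
everything else is tallied by top-level group.

Finally, the *unclustered* ITS2 reads (including singletons that never
entered clustering) are mapped back against the relabelled fungal OTUs at
97% identity, plus strand only, ties to the lower OTU index; the table's
column sums therefore equal per-sample mapped reads, and totals can exceed
the summed centroid sizes — deliberately, following the practice of
mapping all extracted reads. The mapper reports `below_threshold` and
`no_candidate` (no shared 8-mer) reads separately.

# The simulator as the testing instrument

`simulate_reads()` generates the study conditions end to end: random ITS2
cores (160–220 bp) at pairwise divergence verified with the same identity
function used for clustering; the dual-tag amplicon structure above with
8-bp tags and 18-bp primers (26-bp tag+primer ends); 2 × 250 bp paired
reads with ~50/50 random orientation; per-base substitution errors with
constant quality `round(-10*log10(e))` capped to [2, 40]; single-crossover
bimeras between same-sample amplicons with breakpoints uniform in the
middle 60% of the ITS2 (matching the bimera model the detectors assume);
length-preserving internal extra-primer insertions; and optional
one-substitution tag corruption and cross-sample tag switching, all
recorded per read in a ground-truth table together with the expected
OTU × sample table of intact reads.

The default per-base error rate is 0.002. Under the constant-quality
model, rates above ~0.0025 encode below Q26 and such a run is — correctly
— removed wholesale by the default quality filter; 0.002 (≈Q27) keeps the
default conditions self-consistent while remaining in the range of
MiSeq-scale substitution error.

What the simulator does *not* emulate: position-dependent quality decay
and indel errors, PhiX carry-over, variable-length tag sets, and
length-heterogeneous real ITS2 secondary structure. Passing tests
therefore demonstrate the pipeline's logic — accounting, orientation,
label handling, extraction coordinates, clustering and chimera rules — on
an idealized error process, not its robustness to every real-world MiSeq
artifact.

# Numerical and design choices

- **Problem sizes.** The packaged test and acceptance runs use 10 species
  × 5 samples × 2,000 read pairs per sample for ground-truth recovery,
  1,000/500/200 cases for the merge/identity/bimera oracle comparisons,
  and 12 species × 2 × 400 pairs at 5% chimera rate for filter
  sensitivity. These sizes exercise every code path while keeping a full
  run on one CPU in minutes.
- **Determinism.** Every stage is deterministic given its input; the
  simulator is deterministic given its seed; ties (overlap length, equal
  quality disagreements, equal-size uniques, equal-identity OTUs) all have
  fixed documented resolutions. Two runs of `run_all()` on the same input
  produce byte-identical outputs.
- **Degenerate inputs.** Empty FASTQ files, empty record sets, sequences
  shorter than the k-mer size, and reads too short to trim are either
  handled (empty outputs with zeroed reports) or rejected with stage-tagged
  errors before any partial output is written.
- **Conservation.** `n_in == n_kept + n_discarded`, with per-reason counts
  summing to the discard total, is enforced in the report constructor
  itself, so a non-conserving stage cannot even build its report.
- **Pipeline order.** Assembly precedes artifact removal and orientation so
  that mate-order synchronization is needed only once, at the start; the
  reference chimera filter runs on centroids (cheap) rather than reads;
  taxonomy gating is optional in `run_all()` because the homology search
  is external, and the reference filter is likewise skipped when no
  trusted reference set is supplied.

# Known limitations

- The merger is an explicit score-based rule, not a probabilistic model;
  at very low qualities its behaviour differs from likelihood-based
  assemblers.
- Chimera screening considers bimeras only; multi-parent chimeras are
  flagged only if they happen to fit a two-segment model.
- Reference chimera filtering is plus-strand only, by design.
- LCA gating interprets "upper percentage" as percent of best bitscore.
- The OTU radius, skew factor, model gain and diagnostic-difference floor
  are configurable but interact; the defaults (0.97, 2×, 0.02, 3) are a
  conservative, internally consistent set and changing one in isolation
  shifts the sensitivity/false-positive balance measured in the tests.
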