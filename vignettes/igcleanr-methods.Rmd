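---
title: "Cleaning Ig amplicon reads and screening homopolymer indel artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning Ig amplicon reads and screening homopolymer indel artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igcleanr)
```

## The problem

Immunoglobulin (Ig) gene amplicons resist the generic read-cleaning
toolchain. The genes are rearranged and somatically hypermutated, so there
is no reference to align against, no consensus adapter to learn from the
data, and highly similar-but-distinct sequences are signal, not noise.
Multiplexed amplicon runs mark each sample with a pair of 10-nt MID
(molecular identifier) barcodes, one at each end of the template, and the
templates carry degenerate PCR primers inward of the MIDs. Sequencing can
start from either strand, errors concentrate near the read boundaries, and
pyrosequencing chemistry miscounts homopolymer tracts (HPTs, runs of one
nucleotide), producing insertion/deletion artifacts that corrupt downstream
mutation analysis.

`igcleanr` implements two independent rule-based pipelines for this
setting, plus the simulators needed to validate them without access to any
particular sequencing run.

## The read cleaner

A raw read is modelled as

```
adapter | FW MID | FW primer | gene | rc(RV primer) | rc(RV MID) | adapter
```

possibly reverse-complemented as a whole. Cleaning applies five checks in a
fixed order, and a read stops at the first failure:

1. **Raw length (L1).** The delivered read length must lie within
   `[minL1, maxL1]` (defaults 200-400 nt). Bounds are inclusive; the
   boundary reading is ambiguous in general usage and the inclusive form
   is the one adopted here.
2. **MID identification.** Each end window (`search_range` bases, default
   50) is scanned for a perfect match of any MID or its reverse
   complement. If no full tag matches, the scan falls back to a perfect
   match of the `min_mid_len` gene-proximal bases (default 5) — the outer
   tag end is the part sequencing tends to truncate. A full match always
   beats a partial one; among competing hits the one closest to the read
   end wins, then the lower MID index (the tie rules are this package's
   choice; competing full matches essentially never co-occur with a
   well-separated tag set). A legitimate read shows a sense-oriented tag
   at the 5' end and an antisense tag at the 3' end — true for both read
   orientations — and the index pair must appear in the sample table.
3. **Primer identification.** On the MID-trimmed core, both end windows
   are scanned for perfect IUPAC matches of every forward and reverse
   primer and their reverse complements (`R` matches `A` or `G`, and so
   on; an `N` base call matches only the primer code `N`, so low-quality
   calls cannot fake a match). An end with no perfect hit falls back to a
   bounded-edit search: each primer is trimmed to its gene-proximal
   `primer_fraction` (default 75%) and located by IUPAC-aware semi-global
   (pattern-infix) Levenshtein dynamic programming; a hit is accepted when
   its edit count is at most `max_mismatches` (default 2). The acceptance
   criterion is an explicit edit budget rather than an alignment score:
   it is directly testable against a brute-force all-substrings oracle,
   which the test suite and the acceptance script both do. Two hits on
   the same strand orientation indicate a template-switching chimera and
   fail the read.
4. **Gene length (L2).** The region strictly between the primer spans
   must lie within `[minL2, maxL2]` (defaults 150-360 nt). When a primer
   was matched partially, trimming uses the optimal alignment span.
5. **Average quality.** The mean of the gene-region base scores (0-40)
   must be strictly greater than `quality_threshold` (default 20); a read
   sitting exactly on the threshold fails.

Passing reads are written per sample, sense-normalised (gene and scores
reverse-complemented/reversed when the read was antisense), so downstream
alignment sees one orientation. Failure files keep the original untrimmed
reads for forensics. Raw-length (L1) failures are written to the same
length-failure file as L2 failures: both are length rejections, and no
sample can be attributed to either. Reads failing MID identification are
counted only globally, since without a tag pair no sample attribution
exists. When primers fail, the read's orientation is unknown; the
per-sample accounting then uses the (5' tag, 3' tag) order if it is in the
table, else the flipped order. If, after the primers fix the orientation,
the oriented key is absent from the table, the read is treated as a MID
failure — the combination did not match the table.

### MID-set diagnostics

Two quantities describe how robust a tag set is: the minimum pairwise
Hamming distance, and the minimal distinguishing inner length — the
smallest `k` such that the `2n` strings {length-`k` gene-proximal suffix
of each MID} together with their reverse complements are pairwise
distinct, so a `k`-base inner fragment pins down both the tag and its
orientation. For the standard nine-tag basic MID set shipped with the
package these are 6 and 5, which is why `min_mid_len = 5` is a safe
default for that set. The reverse-complement closure is part of the
contract because tags are matched on both strands; a `k` that separates
suffixes only within one orientation could still collide across
orientations.

## The indel identifier

Input is a set of clone alignments: clonally related sequences aligned
together with a germline/consensus row (PIR files as produced by classic
multiple aligners; the germline row is recognised by a `GL` name prefix,
else the first row is taken — the format itself does not mark it). Each
member row is compared to the germline position by position. A maximal gap
run is one indel event: gap in the germline row means insertion, gap in
the member row means deletion; columns where both rows have gaps belong to
other members' insertions and are transparent. Aligned non-gap mismatches
are point mutations.

The screening rules, applied to each member's events in alignment order:

* An indel **away from any HPT** is legitimate. "Near" means the event's
  germline locus is inside a tract of at least `min_hpt_len` bases
  (default 2), or immediately adjacent on either flank — the minimal
  reading of 5'/3' proximity, consistent with how polymerase slippage
  errors localise.
* A near-HPT indel **shared** by at least `min_share` members (carrier
  included; default 2, i.e. "at least one other member") is legitimate.
  Sharing compares the indel kind and the exact alignment-column
  interval; the same columns deleted at a different length are a
  different event.
* A near-HPT, under-shared indel is a sequencing **artifact** when the
  clone has other members — the sequence is discarded. In a singleton
  clone sharing cannot be assessed, and the sequence is set aside as
  **uncertain** rather than discarded, preserving scarce material (e.g.
  archival tissue) for analyses that can tolerate it.
* With `min_qual >= 0`, a point mutation scoring below `min_qual` that
  lies outside the AID hotspot motifs (`AACA`/`TGTT`) and is under-shared
  in a multi-member clone discards the sequence as a low-quality
  mutation. Mutations inside the motifs are kept regardless of score —
  AID targets them, so a low-confidence call there is plausibly
  biological. Singleton clones are never discarded on mutation evidence.
  `min_qual = -1` disables mutation screening entirely.

A sequence's final class is the first terminal verdict reached
(artifact or low-quality mutation), else uncertain if any indel was marked
so, else "with legitimate indels" or "without indels". The four output
files partition the input: legitimate-indel sequences ship together with
indel-free ones, uncertain singletons separately, and the two discard
classes each in their own file.

Raising `min_share` makes the sharing requirement harder to meet, so the
artifact count can only grow; raising `min_hpt_len` disqualifies short
tracts, so it can only shrink. Both monotonicities are asserted over a
4x12 parameter grid in the tests and recomputed by the acceptance script.

## Simulators and what they do (and do not) show

**Read generator.** `generate_clean_fixture()` assembles reads with the
full anatomy above — MIDs from the configured table, IUPAC primer codes
realised randomly, random genes at lengths keeping both L1 and L2 in
range, high-quality scores — and reverse-complements about half. Each
requested failure mode plants exactly one defect: raw length pushed past
`maxL1`; the 5' MID replaced by random bases (verified free of full-tag
and inner-fragment decoys); the forward primer replaced by random bases
verified to exceed the edit budget for every trimmed primer; the gene cut
10 nt below `minL2` with the raw length padded back into range; or
gene-region scores drawn from 5-15 against a threshold of 20. Assembly is
redrawn whenever an end window does not contain exactly one full-MID
occurrence, because a junction between planted parts can otherwise spell a
second tag and legitimately out-compete the planted one in the
closest-to-the-end tie-break. The generator therefore provides exact
per-read truth, which is what the conservation suite checks read by read.
What it does not emulate: flowgram-style error processes, quality-score
correlation along the read, chimeras, or adapter read-through; passing the
conservation suite shows the routing logic is exact, not that real 454
error modes are all caught.

**Deletion injector.** `inject_deletions()` follows the benchmark recipe:
per member, with probability `p_del` (default 0.5; only the decision
itself is prescribed, not its rate), draw a tract length uniformly from
2-10, redrawing until the member has a maximal run of exactly that length
(implemented as a single uniform draw over the lengths present, which is
the same distribution with a termination guarantee; members with no
drawable tract are recorded as not injected), pick one such tract and one
position among its interior plus two flanks — never the first or last
sequence position — replace that base with `-`, and append 0-10 uniform
duplicate copies. All draws come from one seeded stream, so output is
reproducible byte for byte.

**Clone generator.** `generate_clonal_fixture()` builds random germlines
(default 300 nt, 85 clones, sizes 1-12 — around 500 members, the scale of
the benchmark dataset) and members that differ only by point mutations
placed at positions neither inside nor adjacent to any germline run of two
or more, with the substituted base differing from both neighbours. This
preserves the run structure exactly, so every member tract of length >= 2
is a germline tract at the same coordinates. That property is what makes
the round-trip exact: an injected deletion is always near a germline HPT
of length >= 2, so with `min_hpt_len = 2` and `min_share` above any
attainable sharing count, every injection in a multi-member clone is
classified artifact — 100% by construction, not approximately. One caveat
is inherent to the rules: two members of a large clone can independently
receive the same deletion, and with their duplicates the event can become
genuinely shared beyond `min_share`, at which point the classifier — by
design — calls it legitimate. The round-trip is therefore stated over
injections whose true sharing count is below the threshold, and the
exceptions are asserted to be exactly the over-shared ones.

## Numerical and interface choices

* Quality comparison is strict (`>`); length bounds are inclusive.
* Consensus ties (`build_consensus()`) resolve by the fixed order
  `A < C < G < T < -`, so a nucleotide always beats the gap.
* The semi-global DP breaks span ties toward the window's outer edge,
  then the shorter span; when several primers match one side, fewer edits
  wins, then the lower primer index.
* Degenerate codes are permitted in primers only; MIDs and reads are
  plain `A/C/G/T(/N)`.
* The configuration dialect is parsed case-insensitively with `#`
  terminated lists; `parse_clean_config()` and `format_clean_config()`
  round-trip exactly, and the structured `clean_config()` constructor is
  equivalent for programmatic use.
* Problem sizes used by the validation suites: 1000 generated reads for
  conservation; 500 window/pattern pairs and 1000 random strings for the
  oracle-equivalence checks; about 500 simulated sequences (85 clones)
  for the round-trip and the 4x12 monotonicity grid. These sizes give
  exact, not sampled, agreement checks at each scale.

## Limitations

Chimera detection is limited to the primer-orientation rule; V(D)J
segment assignment, clonal clustering and lineage reconstruction are out
of scope and expected from dedicated tools, whose clone alignments this
package consumes. The indel rules flag artifacts rather than correcting
them, and offer no probabilistic error model; sequences with real indels
inside homopolymer tracts that no clone-mate shares are indistinguishable
from artifacts by design.
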