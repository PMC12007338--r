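---
title: "Reference-comparative error detection and correction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-comparative error detection and correction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refpolish)
```

## The problem

Long-read (nanopore) assemblies of small genomes are contiguous but carry
residual 1–2 nt indel errors, concentrated in homopolymers, that frameshift
otherwise intact genes and inflate pseudogene counts. Raw-read polishers
share the basecaller's systematic homopolymer bias, so read consensus alone
cannot resolve these sites. `refpolish` takes an orthogonal evidence source:
a curated set of related genomes (ideally ~10, roughly equidistant, ~94–98%
identity) locally aligned to the draft. Where *every* aligned reference
disagrees with the draft in the same way, the draft base is far more likely
to be a sequencing artifact than a genuine strain variant; raw reads are
then consulted to keep strain-specific variation and to place indels at
their read-supported positions.

All error types are defined from the draft's perspective:

* **insertion error** — the draft carries spurious bases (references show a
  deletion relative to the draft); the correction removes them;
* **deletion error** — the draft is missing bases (references show an
  insertion); the correction inserts them after the anchor base;
* **substitution** — the draft base is replaced.

## Module one: candidate detection

The unit of evidence is the **alignment difference probability (ADP)**: the
fraction of sources covering a column whose alignment reports a difference
of a given type there. Indels attach to the draft base immediately
preceding the event (the mpileup convention) and indels longer than
`max_indel_len` (default 2 nt) are ignored entirely — longer events are
taken as genuine variants, not assembly errors. Lengths 1 and 2 are tallied
independently. Reference `N` observations count toward depth but never
toward a numerator; columns whose draft base is `N` are excluded (no
correction can be defined).

Scanning proceeds in passes over each contig. A column is only considered
when at least `min_ref_coverage` (default 5) references cover it. A column
*triggers* when its best positional ADP reaches `regional_trigger`
(default 0.25). The pass then evaluates a window around the trigger:

| pass | window |
|------|--------|
| 1    | the trigger column itself |
| 2    | the maximal homopolymer run containing the column |
| 3    | 11 nt centred on the column |
| 4, 5, … | grows by 5 nt per side per pass |

The total number of passes is 2 mandatory plus `elective_passes` (default
4). The two published direct-detection and multi-pass descriptions are
unified here: pass 1 *is* direct detection, since a one-column window makes
the regional ADP equal the positional ADP. Easy, isolated errors are
claimed in early passes; wider windows in later passes disambiguate
clustered differences. On every second elective pass two extra strategies
switch on: **window shifting** (the window is also anchored to end at, and
to start at, the trigger column, and the best regional ADP wins) and
**alternative-length merging** (1-nt and 2-nt evidence for the same indel
type is pooled, for sites where references disagree about length rather
than presence).

The **regional ADP** over a window counts each reference at most once, no
matter how many differences it shows there, so one divergent reference can
never masquerade as several. Its denominator is the number of references
covering the *trigger column* — reference blocks may end mid-window, and
the trigger column is the site actually under test.

When the regional ADP reaches `error_threshold` (default 0.99 — with 15 or
fewer references that means every covering reference), the window is
scored. Every in-window location with a same-type difference is a
candidate; locations in the same homopolymer run with the same correction
type are merged first (support pooled per reference, deduplicated), because
positions within a run are alignment-equivalent for an indel of the run
base. Each merged site scores

```
score = (reference support fraction at the site) x (homopolymer length)
```

halved when the implied correction would place a non-matching base strictly
inside a run of length ≥ 2 (splitting a homopolymer is the least likely
explanation of a basecalling artifact). The highest-scoring site is the
emitted candidate (ties go leftmost), and a candidate is only emitted when
its own merged support fraction also reaches `error_threshold` — the
references must report the *same* difference, not merely some difference of
the same type. Without this site-level consensus, independently divergent
references would pass wide-window regional gates by chance: at ~95%
identity each reference has some substitution in almost every 41-nt window.
Columns inside an emitted candidate's window are claimed and skipped in
later passes; candidates are never revised once emitted.

A combined substitution + deletion at one site surfaces as two adjacent
candidates in the mandatory passes, since the two types are evaluated
independently at the trigger.

When a **secondary reference set** is supplied, columns that fail the
primary coverage gate are re-evaluated against it with identical logic —
the more divergent secondary set supplements detection only where the
curated set has no say.

## Module two: read adjustment

Indel candidates are never discarded: the systematic homopolymer bias of
nanopore reads means true indel corrections often have weak read support,
and reference consensus has already vouched for them. Instead, a 21-nt
window (`adjust_window`) centred on the candidate is profiled: a read ADP
of the candidate's type and length is computed for every position,
positions within one draft homopolymer run collapse to a single
representative site (leftmost, per-read deduplicated), and an event that
would break a run (inserting a non-run base) stays its own site. Then, in
order:

1. support for the *initial* site at or above `adjust_threshold_indel`
   (default 0.25) confirms the candidate in place — no alternatives are
   even considered;
2. otherwise the best-supported same-type, same-length site replaces it
   (status `adjusted`, original position retained, correction re-derived
   from the reads at the new site);
3. a 2-nt indel with no same-length support may split into two supported
   1-nt indels (both must clear the threshold);
4. failing all of that, the candidate is retained unadjusted
   (`retained_unsupported`).

Substitutions are the mirror image: all three alternative bases are scored
from raw, unfiltered reads at the site, the best alternative at or above
`adjust_threshold_sub` (default 0.10) becomes the correction (it may differ
from the reference-suggested base), and lacking that, the substitution is
*removed* — a reference-only substitution signal is indistinguishable from
strain divergence. Consequently, when no read pileup is available at all,
every substitution candidate is dropped and every indel passes through
unadjusted.

All threshold comparisons in both modules are inclusive (≥): the published
boundaries are stated without strictness, and one convention is used
everywhere. Ties between equal-ADP sites go leftmost.

## Module three: correction

The finalized list is applied per contig in descending coordinate order, so
all positions refer to original draft coordinates and never shift.
Validation is strict: recorded draft bases must still match (a stale list
aborts), and overlapping or duplicate edits are rejected rather than merged
— detection's window claiming cannot produce them, so their presence
signals a corrupt table. The TSV written by `write_error_table()` is a
complete, re-applicable record: `reapply_from_table()` reproduces the
corrected FASTA byte-for-byte without re-running detection.

## Coordinates and formats

All coordinates, internal and external, are 1-based and inclusive — the
native convention of both R string handling and the mpileup dialect, and
the one reported in the TSV. The pileup parser consumes the standard
samtools text encoding (`.`/`,`, `ACGT`, `+N`/`-N`, `*`, `^X`/`$`) in its
all-positions form; source identity is reconstructed positionally across
columns via the segment markers, and files violating slot consistency are
rejected, never guessed around. Base and mapping qualities are consumed
and discarded — the method is a counting procedure, not a quality-weighted
one. Upstream pileup generation must disable depth capping, or read depth
(and hence read ADPs) would be understated.

Alignment blocks feeding the pileup should be pre-filtered with
`filter_alignment_blocks()` (identity ≥ 0.80, length ≥ 1000 nt, both
inclusive) to keep spurious mappings from diluting the per-column
consensus.

## The synthetic world generator

`simulate_world()` builds seeded test worlds in which every alignment is
*exact*, derived from known edit coordinates — no aligner, no heuristics,
no downloads. A truth genome is drawn at the requested length and GC
content; a draft is derived by injecting a recorded error list
(`error_mix()` defaults to 50 errors dominated by homopolymer-associated
1–2 nt deletions, the regime observed in nanopore assemblies); references
are the truth plus independent per-reference strain divergence; reads are
truth-derived spans with a substitution rate and a homopolymer-escalated
indel rate (per-base rate × run length). Divergence events never coincide
with injected sites, keeping ground truth unambiguous. Injected indels are
left-aligned to their homopolymer run so that every module agrees on the
canonical anchor.

Default study conditions: 100 kb genome, 10 references, 50 well-separated
injected errors, 30× reads of 6 kb; divergence defaults to zero and is
raised to ~95% identity (substitution rate 0.04, indel rate 0.005) for
precision testing — realistic strain divergence is substitution-dominated.
Error placements `after_kmer` and `in_homopolymer` give profiling tests
exact expected tallies.

What the generator does *not* emulate — and what passing tests therefore do
not show — includes: alignment ambiguity and mapping error near repeats,
reference assembly gaps and misassemblies, coverage fluctuation beyond read
tiling, chimeric reads, and correlated (phylogenetically structured)
divergence between references. Results on real data depend on reference-set
curation in a way no synthetic test can certify.

## Numerical and degenerate-input choices

* Windows truncate at contig ends; candidates within `max_indel_len` of an
  end are allowed, but an insertion in a source before the first draft base
  of its block cannot be expressed in the pileup encoding and is ignored.
* Correction sequences resolve disagreements by plurality with
  lexicographic tie-break (deterministic output is a design requirement;
  byte-identical reruns are tested).
* Zero-depth columns have undefined ADP and are unreachable behind the
  coverage gate.
* The analysis path consumes no randomness at all; only the world generator
  takes a seed.

## Known limitations

* Indels longer than 2 nt and structural differences are out of scope by
  design.
* Memory holds whole-genome pileups in data frames; the tool targets small
  (microbial-scale) genomes.
* Regions covered by fewer than `min_ref_coverage` references are
  invisible to detection unless a secondary set covers them.
* The site-consensus emission rule trades a little sensitivity in genuinely
  ambiguous multi-error windows for precision under reference divergence;
  the window-shifting and length-merging passes recover part of that.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` rebuilds the default
worlds from the seed and recomputes, end to end: zero-noise sensitivity and
false-candidate count with byte-level truth recovery; sensitivity and false
candidates under ~95%-identity references; the relocation rate for
deliberately mis-positioned homopolymer indels at 30×; and the
no-reads exclusion/retention percentages. Problem sizes match the defaults
above (100 kb; 50 kb for the relocation world with 30 shifted candidates).
```
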