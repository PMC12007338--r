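# refpolish

Reference-comparative detection and correction of gene-fragmenting errors
in small-genome long-read draft assemblies.

Nanopore-only assemblies of bacterial (and other small) genomes are
contiguous but retain 1–2 nt indel errors concentrated in homopolymers.
These frameshift otherwise intact genes and pseudogenize annotations, and
read-based polishers inherit the basecaller's homopolymer bias, so the
errors survive standard polishing. `refpolish` uses an orthogonal evidence
source: a curated set of ~10 related genomes (ideally roughly equidistant,
~94–98% identity) locally aligned to the draft. Where every covering
reference reports the same difference with the draft, the draft state is
far more likely a sequencing artifact than a shared variant; raw reads are
then used to confirm, reposition or discard each candidate so that
strain-specific variation is preserved.

## The statistic

For each draft column and error type, the **alignment difference
probability (ADP)** is the fraction of covering sources whose alignment
disagrees with the draft there:

* substitution error — fraction of references with a mismatching base;
* insertion error (spurious draft bases) — fraction of references *missing*
  sequence at the column (a deletion in the reference);
* deletion error (missing draft bases) — fraction of references carrying
  extra sequence after the column.

A multi-pass scan (window of 1, then the containing homopolymer, then 11 nt
growing by 5 nt per side) triggers on columns with positional ADP ≥ 0.25,
requires a per-reference-deduplicated regional ADP ≥ 0.99 (all covering
references, for sets of ≤ 15), and scores each candidate site as

```
score = reference support fraction × homopolymer length
```

(halved if the correction would split a homopolymer). Indels longer than
2 nt are treated as genuine variants and ignored. Read adjustment then
works over a 21-nt window: indel candidates are confirmed in place at
≥ 25% read support, else relocated to the best-supported equivalent site,
possibly split 2 → 1+1, and never dropped; substitutions need ≥ 10% read
support for a single replacement base or they are removed (all of them,
when no reads are provided). The finalized list is applied to the FASTA
and written as a TSV that reproduces the correction exactly via
`reapply_from_table()`.

## Worked example

Everything is testable without an aligner: `simulate_world()` builds a
seeded world — truth genome, error-injected draft, divergent references,
simulated reads — with all alignments serialized as FASTA + all-positions
mpileup.

```r
library(refpolish)

spec <- simulation_spec(genome_length = 50000L, seed = 42L)   # 50 injected errors
w <- simulate_world(spec, dir = "demo")
res <- polish_assembly(w$paths$draft, w$paths$ref_pileup, w$paths$read_pileup,
                       outdir = "demo/out")
#> draft: 1 contig(s), 49990 nt total
#> detected 50 candidate error(s): deletion=25 insertion=15 substitution=10
#> after adjustment 50 error(s): deletion=25 insertion=15 substitution=10 | status: adjusted=1 confirmed=49

head(res$errors[c("position", "error_type", "length", "draft_seq",
                  "correction_seq", "reference_adp", "read_adp", "status")])
#>   position error_type length draft_seq correction_seq reference_adp read_adp    status
#> 1     1658  insertion      2        CG                            1        1 confirmed
#> 2     1837  insertion      1         T                            1        1 confirmed
#> 3     1919   deletion      1                        A             1        1 confirmed
#> 4     2445   deletion      1                        G             1        1 confirmed
#> 5     2654   deletion      1                        A             1        1 confirmed
#> 6     4810  insertion      1         T                            1        1 confirmed

identical(unname(res$corrected), unname(w$truth))
#> [1] TRUE
```

Each row is one error in original draft coordinates: an `insertion` row
deletes `length` draft bases, a `deletion` row inserts `correction_seq`
after `position`, and `reference_adp` / `read_adp` record the fraction of
references and reads supporting the correction. The corrected assembly
here recovers the truth genome byte-for-byte, and
`demo/out/errors.tsv` + `demo/out/corrected.fasta` are reproducible from
the TSV alone:

```sh
inst/exec/refpolish correct --draft demo/draft.fasta \
    --errors demo/out/errors.tsv --out corrected.fasta
```

Error-context profiling (`upstream_kmer_profile()`,
`homopolymer_length_distribution()`) tabulates the upstream 4-mer and
homopolymer length for each detected error, the standard diagnostic of
systematic nanopore miscalls.

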