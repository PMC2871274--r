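---
title: "Mapping bisulfite reads by three-letter alignment: methods and design"
author: "methylMapR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping bisulfite reads by three-letter alignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylMapR)
```

## The problem

Sodium bisulfite converts unmethylated cytosines to uracil while leaving
5-methylcytosine untouched; after PCR, an unmethylated genomic C is read as
T and a methylated one as C. Sequencing a bisulfite-converted library
therefore measures methylation at single-base resolution — but it also
breaks ordinary read mapping, because a read T over a genomic C is not an
error, while the reverse (read C over genomic T) is. An aligner that treats
both as mismatches both loses coverage and biases the recovered methylation
levels towards heavily methylated (less-converted, hence easier to map)
fragments.

Depending on library chemistry, a bisulfite fragment can reach the sequencer
in four forms: the forward read of a Watson-strand fragment (+FW), its
reverse complement (+RC), the forward read of a Crick-strand fragment (−FW),
and its reverse complement (−RC). Non-directional, tagged libraries produce
all four, and mark direction with a 5-nt adapter-derived tag at the read
start; directional libraries (premethylated adapters) produce only +FW and
−FW and carry no tag.

## The mapping model

methylMapR removes conversion-induced differences by collapsing both sides
to three letters:

* FW-form reads have every C replaced by T; the genome's Watson and Crick
  strands are converted the same way, giving spaces `W_CT` and `C_CT`.
* RC-form reads have every G replaced by A; the reverse complements of the
  two strands are G→A converted, giving `RCW_GA` and `RCC_GA`.

A converted read is then aligned, ungapped, against the spaces its form can
occupy: FW reads against `W_CT`/`C_CT`, RC reads against `RCW_GA`/`RCC_GA`,
and reads whose tag matched neither pattern against all four (they could be
either). A directional run needs only the two C/T passes.

Complementation swaps C↔G, so `RCW_GA` is exactly the reverse complement of
`W_CT` (and `RCC_GA` of `C_CT`), character for character. The package
therefore builds only the two C/T seed indexes and searches the reverse
complement of a G/A-converted read in them, reflecting hit offsets back into
the logical G/A space. Results are provably identical and index memory
halves; the four-space contract remains visible in `alignRead()`. The
identity is verified exhaustively for all sequences up to length 8 in the
test suite.

### The internal aligner

Candidate placements come from a plain k-mer occurrence index over each
converted space and are verified by an early-exit Hamming count. Seeding is
pigeonhole-complete: a read is seeded with `m + 1` non-overlapping segments,
so any placement with at most `m` mismatches must contain at least one exact
seed. Completeness matters here more than in ordinary mapping, because the
uniqueness rule below is only correct if no qualifying hit was missed. A
read too short to carry `m + 1` seeds of length `k` is aligned by a full
sliding-window scan instead (counted in the run statistics) — sensitivity is
never silently reduced. The aligner is deliberately ungapped: the mismatch
accounting that drives uniqueness and quality filtering is defined over
positionwise substitutions, and indels are out of scope.

An equivalent external aligner could substitute for this step provided it
honours the same contract (every placement with ≤ m three-letter mismatches
reported); the internal aligner is the tested default, and an independent
brute-force oracle (`alignBruteForce()`) pins its behaviour on thousands of
randomized instances.

### Uniqueness and quality filtering

Per read, hits from all searched spaces are pooled and the read is kept only
if exactly one hit attains the minimum three-letter mismatch count. A
strictly worse hit does not break uniqueness; a tie at the best count
discards the read as ambiguous. Ambiguous reads are never assigned at
random — random placement of multi-mapping reads is known to bias inferred
methylation rates.

The surviving hit is transformed to Watson coordinates (1-based position of
the leftmost base, plus the form label), and mismatches are recounted in the
original alphabet under the asymmetric bisulfite rule: read T over genomic C
matches (FW forms), read A over genomic G matches (RC forms), and the
converse substitutions count as mismatches. Reads whose recounted count
exceeds `maxMM` are discarded as low quality; the threshold itself is kept
("larger than" semantics). Every unmapped read carries a reason code
(`no_hit`, `ambiguous`, `low_quality`, `too_short`) so that mapability
percentages are auditable.

### Methylation calling

For every read position whose origin-strand genome base is C, a read C is a
methylated observation and a read T an unmethylated one; any other base is
no call. Sites are keyed by (chromosome, Watson position, strand) — the two
Cs of a CG dinucleotide are two distinct sites. Context (CG, CHG, CHH; H ∈
{A, C, T}) is classified from the reference on the C's strand, never from
the read, so sequencing errors cannot shift context; bases past a chromosome
end are treated as H. Genome-wide rates are pooled
(`sum nMeth / sum nTotal`) rather than averaged over sites, i.e. they are
read-level rates, which is what a read-level simulation should reproduce. No
smoothing and no per-site testing is applied; the output is raw counts and
rates. The per-read methylation string uses one character per read base:
`M` (methylated C), `U` (unmethylated C), `.` (no call over a genomic C),
`-` (not a genomic C position).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` (seed length, bp) | 12 | k-mer length of the seed index. For full-sensitivity seeding choose `k ≤ floor(readLen/(m3+1))` after tag trimming: 9 for 36-mers, 7 for tagged 36-mers (31 bp payload). Larger k is faster, smaller k admits shorter reads. |
| `m3` | 3 | Mismatch ceiling of the three-letter alignment phase. |
| `maxMM` | 2 | Ceiling on recounted original-alphabet mismatches (asymmetric rule). Kept independent of `m3`: the two counts live in different spaces and need not coincide. |
| `cap` | 500 | Per-space hit-enumeration cap. A read exceeding it is discarded as ambiguous, which is already forced by ≥ 2 minimal hits, so the decision is unaffected; the cap only bounds repeat-region blowup. |
| `minAlignable` | 20 bp | Reads with a shorter (post-trim) sequence are discarded as `too_short`. |
| `tagLength`, tag patterns | 5 bp; `GATCT`/`GATCA` | Tag chemistry is configuration. The shipped defaults are synthetic patterns used by the simulator and examples; real tagged libraries should supply their own (`readTagConfig()`). |

The `m3 = 3` / `maxMM = 2` defaults are free choices: the alignment-phase
ceiling and the post-hoc threshold are exposed independently precisely
because no single pair is canonical.

## The simulator

`simulateGenome()` draws an i.i.d. background at 41% GC and plants pairs of
near-identical repeats (defaults: 20% of the genome in 1 kb units at 2%
divergence). The repeats are the point: real chromosomes owe sub-100%
mapability — and error-induced mismapping between repeat copies — to repeat
structure, and an i.i.d. genome would make both phenomena vanishingly rare.

`simulateMethylome()` methylates every genomic C on both strands
independently with its context's probability. The package default is
`pCG = 0.72`, `pCHG = pCHH = 0`: a CG-only methylome whose read-level CG
rate is 72%, matching the structure of the synthetic experiments the
evaluator is designed around. `simulateReads()` samples origins uniformly
over (chromosome, form, start), applies the bisulfite rule on the origin
strand under the fixed methylome, reverse-complements RC forms, prepends
form-appropriate tags (tagged protocol; total read length stays `readLen`,
so a 36-mer carries a 31 bp genomic payload), and finally injects per-cycle
substitution errors. Everything is deterministic given the seed, to the
byte.

The error model is a configurable per-cycle substitution probability vector;
the shipped default rises linearly from 0.1% to 2.3% across cycles (mean
≈ 1.2%), the characteristic 3'-end deterioration of short-read base calls.
No attempt is made to reproduce any specific instrument's empirical error
distribution — the shape is enough to reproduce the qualitative effects
(accuracy slightly below 100%, spurious non-CG signal of a few tenths of a
percent).

What the simulator does **not** emulate: indels, quality-score structure
(qualities are a constant placeholder), PCR duplicates, fragment-length
variation (reads are the fragments), bisulfite non-conversion, and the
specific repeat families of any real chromosome. Passing tests on this
synthetic data therefore demonstrate the correctness of the mapping and
calling logic under the stated model — not performance on any particular
real genome, whose mapability depends on its own repeat structure.

### Truth and evaluation

Truth records, per read, the post-trim leftmost Watson coordinate and form —
exactly the mapper's output convention — so `evaluateMapping()` is a pure
equality join. Mapability is unique reads over total; accuracy is correct
placements over unique reads. With no errors, accuracy is exactly 100% by
construction: the true origin always yields a 0-mismatch three-letter hit,
so a read is either placed there or discarded as ambiguous; it can never be
uniquely placed elsewhere. The test suite asserts this at a scale of 50,000
reads × 2 Mb under both protocols, and checks rate recovery against a
3-standard-error band of the coverage-weighted site-state estimator.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; writers emit 1-based
  inclusive Watson positions.
* N is never indexed in seeds, and N on either side of a column always
  counts as a mismatch (read N, genomic N, or both).
* Ties in the uniqueness rule discard the read; there is no tie-break.
* Reads shorter than the seeding requirement fall back to a full scan;
  reads shorter than `minAlignable` are discarded with a reason, not
  errors.
* Transformed coordinates that would leave the chromosome are asserted
  against, not clipped — they are impossible by construction, so reaching
  them is a bug, not data.
* Mismatch recounting applies to the tag-trimmed read only: the tag is
  adapter-derived and has no genomic counterpart, so any other choice would
  count chemistry against the alignment.
* The problem sizes used by the shipped verification (2 Mb genomes, 50,000
  reads for the study-scale checks; 1 Mb / 20,000 reads for the
  error-injection check; 1,000 randomized instances for oracle equivalence)
  were chosen as the smallest scales at which the binomial error bands and
  repeat-collision counts are decisively informative.

## Known limitations

Single-end, ungapped, substitution-only alignment; no mapping-quality
model (SAM MAPQ is 255); no duplicate marking; no differential methylation
or DMR calling; no correction for incomplete bisulfite conversion. Genomes
are held in memory; the k-mer index is sized for desk-scale genomes (up to
roughly 10^8 bp at `k = 12`), not for multi-gigabase references.
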