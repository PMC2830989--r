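---
title: "Designing Southern blot probes with blotprobe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing Southern blot probes with blotprobe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Southern blotting detects a specific locus in restriction-digested genomic
DNA by hybridizing a labelled DNA probe to the blotted fragments. It remains
the standard way to confirm homologous recombination in gene-targeting
experiments: a correctly targeted allele shifts the size of the restriction
fragment seen by a probe placed in the flanking sequence. For the method to
work the probe — typically a 500–1300 bp fragment — must hybridize to a
single genomic locus and contain essentially no repetitive or low-complexity
DNA, otherwise the blot shows extra bands or an uninterpretable smear.
Oligonucleotide probe designers built for microarrays do not help here:
their probes are under 100 bp.

`blotprobe` automates the search for such probes. Given a soft-masked genome
assembly (lowercase = RepeatMasker/DUST-masked bases) and a design window —
usually ~3 kb of sequence flanking a targeting construct — it enumerates
candidate probes by brute-force tiling, aligns every candidate back to the
whole genome, scores each one for uniqueness and repeat content, bins and
ranks them, and picks PCR primers to recover the chosen probe from genomic
DNA.

## The procedure

### Tiling

Candidates are enumerated from the maximum allowed probe length downwards.
At each length $p$ the window is tiled left to right with a step of
$\max(1, \lfloor f \cdot p \rfloor)$ bases, where $f$ is the step fraction
(default 0.05, i.e. 5% of the probe length); then $p$ is reduced by the
length decrement (default 50 bp) and the window re-tiled, until the minimum
length is passed. With the defaults (500–1300 bp) a 3 kb window yields 907
candidates; the count grows essentially linearly with window size. Flooring
the fractional step and omitting a flush-right terminal tile are the
package's conventions; any consistent choice gives counts within a few
candidates of each other.

### Genome search

Every candidate is aligned against the full genome on both strands with an
affine-gap local aligner (match +5, mismatch −4, gap open −12, gap extend
−4 — the conventional DNA defaults of the `affine:local` model, under which
a perfect 800-mer scores 4000). Alignments scoring at least `min_score`
(default 150) are reported. Hits are extracted greedily: the best local
alignment is taken, its genomic span masked, and the scan repeated, so
reported hits on a strand never overlap. Alignment is case-insensitive —
soft-masking does not alter scores; it is consumed only by the
repeat-content statistic. `N` bases never match, not even each other.

Two search modes share this contract. The exhaustive mode scans every
target position (Smith–Waterman/Gotoh). The default seeded mode first finds
exact 12-mer matches between probe and genome and restricts the scan to
windows padded by one probe length around them. The seeded mode is
guaranteed to recover alignments containing at least one exact 12-mer within
that window — in practice every alignment above roughly 80% identity; a
~75%-identity copy with no shared 12-mer can be missed, which is the
documented sensitivity bound. Results from an external aligner can be
substituted through a line-oriented adapter (`parse_external_alignments()`),
with 0-based coordinates shifted to the package's 1-based inclusive
convention on import.

### Uniqueness and repeat content

Each search must reproduce an on-target ("self") hit — the plus-strand hit
reciprocally overlapping the candidate's own coordinates by ≥ 95%. A search
without one fails quality assurance. The uniqueness statistic is the **score
ratio**: self-hit score divided by the best off-target score, anywhere in
the genome (including elsewhere in the design window). A candidate with no
off-target hit at all is *unique* — the ideal single-locus probe. Repeat
content is the percentage of soft-masked (lowercase) bases in the
candidate, with `n` counting as masked and `N` as unmasked.

### Binning, relaxation, ranking

Acceptance uses two inclusive cut-offs, calibrated against a set of eight
manually designed, experimentally validated probes (bundled as
`calibration_probes()`): score ratio ≥ 10 and masked content ≤ 5%.
Candidates are binned *unique* (no off-target hit, masked content within
bound), *passed* (both cut-offs met), or *failed*. A unique but
repeat-saturated candidate fails: repetitive probes smear on hybridization
regardless of their uniqueness, which is the reason the repeat criterion
exists. Accepted candidates completely contained in a longer, better-ranked
accepted candidate are moved to a *redundant* bin.

If nothing is accepted — typical of windows inside segmental duplications —
the cut-offs are relaxed automatically so the least-bad probes can still be
reported: the score-ratio cut-off is multiplied by 0.75 (floored at 1),
then, if still empty, the masked ceiling is raised by 5 percentage points
(capped at 100), alternating until at least one candidate passes. The
schedule itself is this package's choice (only the existence of relaxation
is prescribed by practice); it is configurable and the full trail is
recorded in the result and the report. Survivors are ranked by bin (unique
first), then score ratio descending, length descending, start ascending.

### Recovery primers

For the top-ranked probes a PCR primer pair is picked so the amplicon is
the probe itself: primer length 18–27 nt, GC 40–60%, melting temperature
57–63 °C with pair difference ≤ 3 °C, no single-base run longer than 4, the
3′ base never on a soft-masked position, and product ≥ 80% of the probe
length. Among feasible pairs the smallest Tm difference wins, ties broken
by the longest product. Melting temperatures use unified nearest-neighbor
thermodynamics (SantaLucia 1998) with the entropy salt correction
$0.368\,(N-1)\ln[\mathrm{Na}^+]$ at 50 mM monovalent salt and 250 nM total
oligo with the conventional $C/4$ term. Keeping primers inside the probe is
an interpretation — the alternative of extending into flanking sequence
would amplify more than the probe; records from an external primer-design
tool can be imported instead (`import_external_primers()`, boulder-IO
format).

## The synthetic genome generator

Real probe design runs against a multi-megabase masked assembly; tests and
examples cannot. `generate_genome()` builds a deterministic stand-in with
known ground truth: i.i.d. background at a chosen GC content, planted
segmental duplications derived from their source by per-base substitution
at rate $1-\mathrm{identity}$ (uppercase — duplications are paralogy, not
masked repeats), divergent copies of repeat-family consensus sequences, and
homopolymer/dinucleotide low-complexity tracts (both lowercase, emulating
RepeatMasker/DUST soft-masking). Substitution-only mutation keeps realized
identity analytically checkable (binomially concentrated within ±3 points
for ≥ 300 bp features); an indel-free model is a simplification of real
duplication divergence. What the generator does *not* emulate: a realistic
mammalian repeat landscape (nested, truncated, strand-mixed elements),
GC-content structure, or assembly gaps. Passing the end-to-end tests on
such genomes demonstrates the pipeline's logic — self-hit recovery,
ratio-1 detection of exact duplications, unique-bin recovery in clean
background — not performance on a real assembly.

## Numerical and degenerate-input choices

* Coordinates are 1-based fully inclusive everywhere in the interface; BED
  export converts to 0-based half-open on write.
* Tie-breaks: equal-scoring hits order by (target, start); the DP itself
  resolves ties toward the smallest target end. Ranking ties resolve by
  length then start.
* Score ratios print at 3 significant figures, percentages and base-pair
  means at 1 decimal; `Inf` prints as `"unique"`. Internally nothing is
  rounded.
* Summary statistics use the sample standard deviation over $\sqrt{n}$ with
  pairwise-complete $n$ per metric; unique-sentinel ratios are excluded as
  non-numeric; $n < 2$ reports no SE.
* A probe of all `N` is unalignable and rejected; an empty sequence has no
  masked fraction; out-of-range slices are errors, never clamped.
* Candidates whose masked content is unknown cannot satisfy the repeat
  criterion and fail.

## Scale and reproducibility

The in-process aligner is written for desk-scale genomes (up to a few Mb);
there is deliberately no FM-index or suffix-array machinery. The bundled
tests run the full pipeline on 12–30 kb synthetic genomes with coarsened
tiling (500–700 bp probes, 25% step, 200 bp decrement, giving 21–64
candidates per window) so the whole suite completes in well under a minute;
the tiling statistics themselves are always exercised at the full default
granularity. For larger runs the on-disk store (`store_create()`,
`store_search()`, `store_analyse()`) persists candidates and per-batch hit
tables as JSON/TSV, resumes interrupted searches, and accepts any
`lapply`-compatible parallel map over batches — a deliberate file-based
replacement for the database-and-cluster infrastructure such pipelines
historically used.

## Known limitations

* Score-ratio values depend on the substitution and gap parameters; other
  aligners or other scoring matrices give ratios on a different scale, so
  cut-offs calibrated here do not transfer verbatim.
* The seeded search can miss highly diverged (< ~80% identity) off-target
  copies; use `method = "full"` where that risk matters.
* Primer picking checks primer-level feasibility and mask state but not
  cross-dimers, hairpins, or polymorphisms under the primer — the
  historical workflow checked the latter manually against dbSNP.
* The generator's duplications are substitution-only; real segmental
  duplications accumulate indels, which shift alignment scores slightly.
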