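# blotprobe

Automated design of Southern blot probes from a soft-masked genome
assembly.

Southern blots remain the definitive confirmation of homologous
recombination in gene-targeting experiments: a probe placed in the sequence
flanking a targeting construct reveals the band shift that distinguishes a
correctly targeted allele from wild type. The probe has to be long
(500–1300 bp), effectively single-copy in the genome, and nearly free of
repetitive or low-complexity DNA — otherwise the blot shows extra bands or
smears. Microarray-style oligo designers cannot produce such probes, and
picking them by eye from a genome browser is slow and error-prone.

`blotprobe` automates the whole search for anyone doing gene targeting,
locus validation, or any hybridization assay needing long unique probes:

1. **Tiling** — candidates are enumerated across the design window from the
   maximum probe length down (default 1300 → 500 bp in 50 bp decrements),
   stepping by 5% of the current probe length; a 3 kb window yields ~900
   candidates.
2. **Genome search** — every candidate is aligned to the full genome on
   both strands with an affine-gap local aligner (+5/−4/−12/−4, hits
   reported at score ≥ 150), exhaustively or k-mer seeded.
3. **Scoring** — each candidate's *score ratio* = self-hit score / best
   off-target score measures uniqueness; the fraction of soft-masked
   (lowercase) bases measures repeat content.
4. **Binning** — *unique* (no off-target hit at all), *passed* (score
   ratio ≥ 10 and masked ≤ 5%), *failed*; accepted probes contained in a
   longer, better-ranked one become *redundant*. If nothing passes, the
   cut-offs relax automatically and the relaxation trail is reported.
5. **Recovery primers** — a PCR pair amplifying the probe itself, picked by
   nearest-neighbor thermodynamics (18–27 nt, GC 40–60%, Tm 57–63 °C,
   ΔTm ≤ 3 °C, 3′ ends off masked bases).

A deterministic synthetic-genome generator with ground truth
(duplications of controlled identity, divergent repeat families,
low-complexity tracts) makes the full pipeline testable without any genome
download, and an on-disk store turns the three classic steps
(create → search → analyse) into a resumable, batch-parallel command-line
workflow.

## Worked example

```r
library(blotprobe)

# a 30 kb soft-masked test genome with known ground truth
cfg <- synthetic_genome_config(
  length = 30000, seed = 42,
  duplications    = list(list(length = 2000, identity = 0.9, count = 1)),
  repeat_families = list(list(length = 250, copies = 4, divergence = 0.08)),
  low_complexity  = list(list(length = 60, count = 3)))
gen <- generate_genome(cfg)
gen$genome
#> <masked_seq> synth1: 30000 bp, 3.9% masked
#>   AAGATTTCTTGTAGGAACGTACAACTGAGATAGTCACCATGGCAGAATATGGGACTTCGT...

design <- design_probes(gen$genome, window_start = 12001, window_end = 15000,
                        min_len = 500, max_len = 900,
                        step_fraction = 0.1, length_decrement = 100,
                        n_primers = 2)
design
#> Southern blot probe design: synth1:12001-15000
#>   177 candidates (500-900 bp)   QA passed
#>   unique    26/177
#>   passed    1/177
#>   failed    17/177
#>   redundant 133/177
#>   criteria: score ratio >= 10, masked <= 5%
#>   best probe: probe_2 synth1:12091-12990 (900 bp, ratio unique, masked 0.0%)
```

All 177 candidates produced their on-target self hit (the QA check). 26
survivors are *unique* — a single perfect genomic match and ≤ 5% masked
bases, the ideal Southern probe; 17 *failed* (they overlap the planted
repeat copies or the masked tracts inside the window); 133 accepted
candidates were dropped as *redundant* because a longer, better-ranked
probe completely contains them. The best probe and its recovery primers:

```r
head(design$ranked[, c("candidate_id", "start", "end", "length",
                       "score_ratio", "masked_pct", "bin")], 3)
#>   candidate_id start   end length score_ratio masked_pct    bin
#> 1            2 12091 12990    900         Inf          0 unique
#> 2            3 12181 13080    900         Inf          0 unique
#> 3            4 12271 13170    900         Inf          0 unique

design$primers[[1]]
#> <primer_pair> product 820 bp
#>   left  ACTGAACTGGCCTACGATCGT  12150-12170  Tm 57.5  GC 52.4%
#>   right TACTCCCGAGCCAGTGAAGTC  12949-12969  Tm 57.5  GC 57.1%
```

(`score_ratio = Inf` is the *unique* sentinel: no off-target alignment
reached the search threshold at all; it prints as `"unique"` in reports.)

`plot(design)` draws the per-base coverage of the window by unique, passed
and failed candidates; `render_report(design, "outdir")` writes the full
static report (bin counts in `n/total` form, criteria and relaxation trail,
ranked probe and primer tables, profile TSV, FASTA/BED of accepted probes).

The same run works from the shell against a FASTA on disk, resumably and in
batches:

```sh
inst/scripts/blotprobe run --config design.ini
```

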