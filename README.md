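# circassess

Rotation-invariant quality assessment for long-read assemblies of circular
prokaryote replicons (chromosomes and plasmids), aimed at anyone
benchmarking assemblers or checking whether a bacterial assembly really
circularised cleanly.

## The metric

Most prokaryote replicons are circular, so a perfectly assembled contig is
a *rotation* of the reference with an arbitrary start point, and the
classic failure modes sit at the contig junction: missing bases (gapped
circularisation) or duplicated bases (start-end overlap). The package's
headline metric, **contiguity**, is

```
contiguity = 100 × (length of the longest single alignment, on the reference) / L
```

where `L` is the reference replicon length and the alignment is made
against the reference concatenated **three** times, so one unbroken
alignment exists for every rotation even when the contig carries start-end
overlap (a doubled reference provably fails for some rotations).
Contiguity of exactly 100% means clean circularisation; 99.9% a small
junction gap; 101% start-end overlap; ~70% an incomplete assembly; ~200% a
fully doubled (typically plasmid) contig. Per-replicon contiguities feed a
four-way completeness status — `fully_complete`, `complete_chromosome`,
`incomplete`, `empty` — thresholded inclusively at 99%. From the longest
alignment's CIGAR the package also reports BLAST-style identity and the
largest single indel.

Alignments come from an external `minimap2` (asm20 preset, 10 kbp chaining
and banding, Z-drop 1000/500), from a compiled built-in affine-gap aligner
suitable up to a few tens of kbp, or from any precomputed PAF. A fixture
generator fabricates genomes and defective assemblies in each of the six
circularisation states with exact ground-truth alignments, and companion
modules implement reference-genome QC filters, panel selection,
read-simulation parameter sampling and depth-targeted read subsampling.

## Worked example

```r
library(circassess)
g <- generate_random_genome(10000, 2000, seed = 1, label = "demo")
defects <- list(demo_chromosome = defect_spec("gapped", 10, rotation = 137),
                demo_plasmid_1  = defect_spec("gapped", 150, rotation = 55))
asm <- make_defective_assembly(g, defects)
assess_assembly(asm$contigs, g, aligner_paf(asm$truth))
#> <assembly_assessment> assembly: 2 contig(s), status complete_chromosome
#>         replicon       role length contiguity  identity max_indel
#>  demo_chromosome chromosome  10000      99.9% 100.0000%         0
#>   demo_plasmid_1    plasmid   2000      92.5% 100.0000%         0
```

The chromosome lost 10 bp at its junction: 9,990 of 10,000 reference bases
in one alignment gives 99.9%, which clears the inclusive 99% threshold.
The plasmid's 150 bp gap leaves 92.5% — incomplete — so the assembly as a
whole is `complete_chromosome`. Identity is 100% and the largest indel 0
because the contigs contain no internal errors, only junction defects.

File-level wrappers (`assess_files()`, `summarise_assessments()`) write
per-replicon and per-assembly TSV reports; `fixture_battery()`
materialises all six defect states to disk; `sample_read_params()`,
`sample_plasmid_depth()` and `subsample_fastq()` cover the simulation
side. `inst/cli/circassess.R` exposes the same operations as `assess`,
`summarise`, `fixtures`, `params` and `subsample` subcommands.

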