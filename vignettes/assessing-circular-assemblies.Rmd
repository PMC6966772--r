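---
title: "Assessing assemblies of circular replicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing assemblies of circular replicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circassess)
```

## The problem

Most prokaryote replicons — chromosomes and plasmids — are circular, with
no defined start or end. A long-read assembler that reconstructs such a
replicon perfectly will still emit a linear contig whose start position is
arbitrary, and common assembler artefacts concentrate at the contig
junction: a few bases may be lost (gapped circularisation) or the start of
the sequence may be duplicated at the end (start-end overlap). Standard
assembly metrics such as NG50 or per-event misassembly calls say little
about whether circularisation was clean. This package implements a single
metric that does, together with everything needed to compute and test it.

## Contiguity and the tripled reference

**Contiguity** is defined as the length of the longest single alignment
between the assembly and a reference replicon, expressed as a percentage of
the replicon length. Its interpretation:

* exactly 100%: the replicon is complete and cleanly circularised;
* slightly under 100% (e.g. 99.9%): complete but with bases missing at the
  junction;
* slightly over 100% (e.g. 101%): complete with start-end overlap;
* far below 100% (e.g. 70%): incomplete — fragmented or missing sequence;
* around 200%: the whole replicon was duplicated within one contig, a
  failure mode seen with small plasmids.

Because the contig's start position is arbitrary, aligning it against the
linearised reference would almost always split the alignment in two. The
reference is therefore concatenated **three** times before alignment. A
doubled reference suffices only for contigs without start-end overlap: a
contig of length $L + o$ (overlap $o > 0$) starting at rotation $k$ needs
positions $k$ through $k + L + o$ of the repeated reference, which exceeds
$2L$ whenever $k > L - o$. Three copies accommodate every rotation of every
contig with $o \le L$ (up to a fully doubled replicon). The test suite
demonstrates both facts by exhaustive substring search on toy replicons.

A contig that is an exact rotation of the replicon aligns in one unbroken
block of exactly $L$ target bases, giving contiguity exactly 100 — the
arithmetic is exact, not approximate, which is why the package's worked
examples ($100$, $99.9$, $101$, $70$, $200$) are asserted with no
tolerance.

## Completeness classification

Each reference replicon gets one contiguity value; an assembly of a genome
with two plasmids has three. The four-way status:

* **fully_complete** — every replicon at or above the threshold (99%);
* **complete_chromosome** — chromosome at/above, some plasmid below;
* **incomplete** — chromosome below;
* **empty** — the assembly has no contigs (e.g. the assembler crashed).

The threshold is inclusive: exactly 99% counts as complete. It is a
parameter (`threshold`) everywhere it is used.

## Identity and maximum indel

From the CIGAR of the longest alignment the package reports BLAST-style
**identity** — matches over all alignment columns, counting every inserted
and deleted base — and the **maximum indel**, the largest single I or D
operation, a proxy for the worst localised consensus error.
Gap-compressed identity (each indel run counted once) is available as an
option but is not the default, since indel errors dominate long-read
consensus quality and should be penalised per base. Assembly-level
identity and maximum indel are taken from the chromosome's longest
alignment. When a CIGAR uses `M` rather than `=`/`X`, the match count
falls back to the alignment's residue-match field.

## Aligner backends

Alignments can come from three interchangeable sources:

1. **External minimap2** (`aligner_minimap2()`), run with the asm20
   preset, chain-elongation and banding thresholds of 10 kbp, Z-drop 1000
   and inversion Z-drop 500, plus `--eqx`. This is the backend for
   genome-scale work.
2. **Builtin affine-gap aligner** (`aligner_builtin()`), a compiled
   Smith-Waterman/Gotoh local aligner (match +1, mismatch −4, gap open 4,
   gap extend 2) that reports the best local alignment, masks the aligned
   query interval, and repeats. An R-level post-pass splits any alignment
   whose running score falls more than a Z-drop (default 1000) below its
   running maximum, mirroring minimap2's chain breaking so that long
   low-identity stretches — such as an inverted segment — break the
   alignment instead of being bridged. Quadratic time and memory limit it
   to sequences of a few tens of kbp; within that envelope it makes the
   whole pipeline testable with no external binary.
3. **Precomputed PAF** (`aligner_paf()`), serving alignments from any
   source, including the fixture generator's exact ground truth.

Numerical edges worth knowing: the builtin aligner breaks score ties by
the first-encountered DP cell (row-major), so placements among the three
identical reference copies are deterministic; "longest" alignment ties are
broken by match count, then contig name. Inversions much shorter than
Z-drop/(per-base mismatch cost) — roughly 250 bp at these scores — may be
absorbed into a bridged alignment as mismatches and small gaps rather than
split; minimap2 behaves analogously, which is why small inversions
depress identity rather than contiguity under either backend.

## Synthetic fixtures and what they do (not) show

`make_defective_assembly()` derives an assembly from a genome in any of
the six states of a circular-replicon assembly — perfect, gapped,
overlapping, fragmented, missing, misassembled (implemented as an internal
segment inversion, one reasonable choice among several) — and emits exact
ground-truth alignments with pure-match CIGARs against the tripled
reference. Fixture genomes are uniform-random sequences. They validate the
assessment arithmetic exactly, and the builtin aligner reproduces the
ground truth exactly whenever each contig (or fragment) is an exact
substring of the tripled reference. They do **not** contain repeats,
biased composition, or homology between replicons, so passing tests here
says nothing about an aligner's behaviour on repeat-rich real genomes —
that is precisely why the external-aligner backend exists.

Defect positions are drawn from a single seed; every generator in the
package is deterministic per seed.

## Genome QC, panel selection and read-set parameters

For building benchmarking panels the package implements the
reference-genome selection machinery: five quality-control filters
(chromosome ≤ 10 Mbp and ≥ 500 kbp; every plasmid ≤ 300 kbp and ≤ 25% of
the chromosome; at most 9 plasmids — all configurable so desk-scale
genomes can exercise each rule), and rejection-sampled panel selection
that redraws the plasmid-bearing subset until it contains exactly the
target number of plasmids.

Read-set parameters are sampled per set: uniform mean depth 5–200×, mean
length 100–20,000 bp, length SD 100 to twice the mean length, mean
identity 80–99%, max identity from mean+1 to 100%, identity SD 1 to
(max − mean); junk, random and chimera rates exponential with mean 2%;
adapter length exponential with mean 50 bp (exponentials unbounded above,
accepted as drawn); a shared glitch size/skip uniform on 0–100, with the
glitch rate (mean bp between glitches) derived as
$100000 / 1.6986^{s/10}$. Size and skip are sampled as a single shared
value — the rate formula consumes one "size/skip" number, so a joint draw
is the parsimonious reading.

Plasmid read depth relative to the chromosome is drawn log-uniformly:
$\log_2$ relative depth uniform on $\pm W$, with $W$ interpolating
log-linearly in plasmid length from 0.1 at 300 kbp (within ~7% of
chromosome depth) to 2.0 at 1 kbp (0.25×–4×). The qualitative design —
large plasmids near chromosome depth, small plasmids spanning a wide
range — is the modelled phenomenon; this particular envelope and its
endpoints are this package's own parameterisation, chosen so the extreme
sizes behave as just described, and both endpoints are arguments.

Depth-targeted subsampling adds whole reads in seeded random order until
the target depth is first reached, so the result never falls below target
and removing the last read would.

## Problem sizes and runtime

The test suite and the reproduction script run everything at desk scale:
replicons of 0.2–10 kbp, panels of 70 genomes, $10^4$ parameter draws.
These sizes keep the quadratic builtin aligner comfortable (a 10 kbp
contig against its 30 kbp tripled reference is the largest alignment
computed) while still exercising every rule and boundary; all of the
package's arithmetic is size-independent, and genome-scale inputs simply
route through the minimap2 backend instead.

## Worked example

```{r example, eval = FALSE}
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

The chromosome's 10 bp junction gap yields contiguity 99.9% — above the
inclusive 99% threshold, so the chromosome counts as complete — while the
plasmid's 150 bp gap leaves it at 92.5%, short of the threshold, hence the
`complete_chromosome` status.

## Known limitations

* The builtin aligner is quadratic; use minimap2 beyond ~50 kbp.
* Small inversions (≲ 250 bp) are reported as identity loss, not broken
  contiguity, under both backends.
* No minimum alignment length or mapping-quality filter is applied before
  selecting the longest alignment.
* Linear replicons are assessed against the untripled reference; the
  fixture generator only models circular replicons.
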