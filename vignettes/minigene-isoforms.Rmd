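---
title: "Assembling and annotating minigene splicing-assay isoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling and annotating minigene splicing-assay isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minigeneiso)
```

## The assay and its coordinate system

A minigene splicing reporter clones a genomic fragment — one or several
exons with their flanking introns — between two constitutive exons of an
expression vector (pCAS2 and derivatives). After transfection, RT-PCR
with primers in the constitutive exons amplifies every mature transcript
the construct produced. Sequencing those amplicons, especially with long
reads, characterizes each isoform completely; but the reads derive from
a plasmid, so the first step is building the reference they actually
come from.

`minigeneiso` delineates the **amplified splicing vector** inside the
full construct sequence: the amplicon runs from the first base of the
upstream constitutive exon to the last base of the downstream one, and
all coordinates are expressed relative to it. The two constitutive
exons are recorded as `UTR` features (they are assay plumbing, always
present, and anchor the amplicon ends); the cloned exons are `exon`
features labelled with their exon numbers in the source transcript.

Two conventions are fixed here and used consistently:

* internally all intervals are 0-based half-open; the GTF is emitted
  1-based inclusive, per the GTF standard;
* the construct is assumed supplied in the transcription orientation,
  and every feature is written on the `+` strand. A reverse-orientation
  construct must be reverse-complemented by the user first.

Exon placement uses exact, case-insensitive string matching of the
declared sequences, with overlapping occurrences counted: zero or
multiple matches abort with the match positions. Constructs are
user-designed sequences, so an ambiguous or absent exon indicates a
design or transcription error that fuzzy matching would hide. `N` is
accepted in the construct backbone but not in declared exon sequences,
where it would make matching ambiguous. Exon numbers need not be
contiguous (a construct may span exons 2–9) but must increase along the
construct — the skipping nomenclature assumes collinearity, so a
violation is an error rather than a warning. A construct with zero
cloned exons (empty-vector control) is legal and yields a two-UTR
annotation. GenBank input contributes only its ORIGIN sequence; feature
tables are ignored because exon declarations are supplied explicitly.

## From alignments to isoform models

Spliced alignments (SAM/BAM, e.g. from minimap2 against the artificial
genome) are reduced to their block structure: match/insertion/deletion
CIGAR operations merge into aligned blocks, `N` gaps become introns.
Only primary alignments passing a MAPQ threshold (default 1) are kept.

Long-read basecalling and alignment place splice boundaries imprecisely
by a few nucleotides. Each intron boundary within a **wobble** window
(default 8 nt; 0 for short reads) of an annotated feature boundary is
snapped onto the nearest such site, ties resolving to the lower
coordinate; a snap that would create a non-positive block or intron
flags the read unsnappable and leaves it unchanged. Snapping is
idempotent.

Isoform identity is the **exact intron chain** after snapping. Terminal
block endpoints do not differentiate isoforms because the amplicon ends
are fixed by the RT-PCR primers, not by splicing. Reads covering less
than half of either terminal (constitutive) feature are discarded as
incomplete amplicons — the assay amplifies full-length molecules, so a
partial read is an artifact, not a short isoform. An unspliced read is
a legitimate chain (the full intron-retention product). The threshold
(`min_end_overlap = 0.5`) and all other knobs are exposed; setting it
to 0 disables the filter, which is appropriate for short-read tiling
data where single reads never span the amplicon.

Externally assembled transcript models (StringTie-style GTF) can be
imported instead of raw alignments; their `cov` attribute then serves
as the expression value, in place of supporting-read counts.

## Event nomenclature

Each isoform is described relative to the cloned exon structure. A
cloned exon counts as present if at least one of its bases is covered;
a fully absent exon is skipped, and maximal runs of consecutive skipped
exons merge into one event. Partial coverage at an edge becomes a
partial deletion with the missing size in nt on the acceptor (5', `p`)
or donor (3', `q`) side. A block covering a whole reference intron is a
retention; spilling over an exon edge, a partial retention; a block
touching no feature, a novel exon assigned to its flanking pair.
Interior gaps (both exon edges present, middle absent) fall outside
this grammar and are reported as a partial deletion on the larger
missing side, with a warning.

The string grammar joins events 5'→3' with commas: `FL`, `Δ(4-5)`,
`Δ(3p_12)`, `▼(6-7)`, `▼(6q_12)`, `▼(4-5,30)`. Ranges use the ASCII
hyphen so annotations are machine-safe identifiers;
`format_annotation(..., unicode = FALSE)` degrades Δ/▼ to `del`/`ins`
for fully ASCII pipelines. Event sizes are given in nucleotides rather
than genomic positions so that annotations are comparable across
constructs. `parse_annotation()` inverts the grammar exactly, which the
tests exploit as a round-trip property. Introns flanked by a
constitutive exon carry the labels `UTR5`/`UTR3` in retention events
(they have no exon number); constitutive exons themselves never
generate skip events — their absence means a non-full-length read,
which the upstream filter already removed.

## Quantification

Per sample, each isoform's expression (supporting reads, or imported
coverage) is divided by the total over all isoforms of the construct;
an all-zero sample yields zeros rather than NaN. `occurrence` counts
the samples where the proportion exceeds a presence threshold, default
0 (report everything: minor isoforms near background level are often
exactly what a diagnostic assay needs to see). The final table has one
row per isoform — `transcript_id` (construction name plus rank by total
expression), `construction`, `gene`, `annot_ref` (the cloned span, e.g.
`ex2_ex9`), `annot_find`, one expression column per sample,
`occurrence`, and one `P_`-prefixed proportion column per sample — as
TSV and as a one-sheet xlsx workbook (written through Python's
openpyxl, the only step not done in R).

## What the simulator emulates — and what it does not

`random_construct()` draws a pCAS2-style construct: two 120-nt
constitutive exons, cloned exons of 60–150 nt separated by 80–200 nt
introns with GT..AG contexts, 50 nt of vector padding outside the
amplicon, and all declared sequences unique by rejection sampling.
Cloned exons are numbered from 2 by default, since the first exon of a
gene is rarely part of a cloned genomic fragment; an 8-exon construct
therefore spans exons 2–9, matching the multi-exonic assays this
package targets. `example_rad51d_truth()` fixes the configuration used
throughout the documentation: four isoforms — full length and the
skipping products Δ(4-5), Δ(3-5), Δ(4-9) — at weights
0.55/0.25/0.15/0.05, the minor species sitting at background level as
seen in practice.

`simulate_reads()` draws isoform membership multinomially, jitters each
splice boundary uniformly by up to ±4 nt (within the default snapping
window of 8 nt, so junction correction is exercised but recoverable),
and applies substitution errors at rate 0.02. The error model is
substitution-only: CIGARs stay block-structured, so alignment itself is
exact by construction. Real nanopore data additionally contains indels,
basecaller-specific error profiles, PCR chimeras and template switching
— none of which are modelled. Passing tests therefore demonstrate that
the reference construction, junction correction, chain clustering,
annotation and quantification logic are correct, not that any aligner
will resolve every real read; alignment quality remains minimap2's
responsibility upstream.

Simulation problem sizes in the test suite were chosen to keep the
statistical checks sharp while staying desk-scale: 2,000 reads suffice
to recover a 5% isoform essentially always, and 10,000 reads put the
expected absolute error of each proportion below 0.01, where the
proportion–weight correlation of a four-isoform mixture is reliably
above 0.999.

## Numerical and design notes

* Junction snapping uses nearest-site with ties to the lower
  coordinate, making results independent of feature enumeration order.
* Isoform ordering is by descending total count with lexicographic
  intron-chain tie-break, so reports are byte-deterministic.
* All random generation goes through a single seed and restores the
  caller's RNG state; identical seeds give identical SAM/FASTQ bytes.
* The spliced-read clusterer is an internal stand-in for guided
  StringTie assembly at amplicon scale, where exact chain identity is
  both simpler and stricter than a general-purpose assembler; external
  assembler output remains a first-class entry point.
* Orchestration is plain sequential R (`run_pipeline()`), not a
  workflow engine: a single construct with a handful of samples
  finishes in seconds, and determinism is easier to guarantee.

## Known limitations

Interior exon gaps are approximated (see above). Annotation of events
inside UTR-adjacent introns uses UTR labels rather than exon numbers.
The simulator does not model indel errors or chimeric reads. One
construct per run: multi-construct pools must be demultiplexed
upstream, and each construct gets its own artificial genome.
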