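---
title: "Assessing transgene integration and genome-wide variation in resequenced transgenic lines"
author: "tgintegrity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing transgene integration and genome-wide variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgintegrity)
```

## The problem

When a crop line is produced by *Agrobacterium*-mediated transformation,
two questions dominate its molecular characterization. First, where and
how did the T-DNA integrate: on which contig, with what deletion at the
integration site, in how many copies, and was vector backbone carried
along? Second, did the transformation (and the tissue-culture
regeneration it requires) change the rest of the genome, and if so, how
much, of what kind, and where? Both questions are answered from
paired-end resequencing of the transgenic line against the parent
reference genome. This package implements that analysis as a tested,
reusable pipeline, and pairs it with a seeded synthetic-data generator
so every stage can be exercised end to end without any external data.

## Insertion-site detection

Reads are mapped against a *combined* reference: the genome contigs plus
the transformation vector as one extra contig. Two kinds of chimeric
evidence then mark an integration site:

* **Discordant pairs** — one mate on a genomic contig, the other on the
  vector. A forward genomic mate anchors the *left* flank of the insert;
  a reverse one anchors the *right* flank.
* **Split reads** — genomic reads soft-clipped at the junction whose
  clipped tail exactly matches a T-DNA border window. These give the
  junction at single-base resolution.

Evidence is clustered per contig and side (clusters separated by more
than `cluster_gap`, default 1000 bases, about twice the fragment
length), clusters below `min_support` (default 3) are discarded, and
each left cluster is paired with the nearest right cluster downstream.
The junction convention is: `left_junction` is the last retained
reference base before the insert, `right_junction` the first retained
base after it, so `deletion_len = right_junction - left_junction - 1`.
When split reads are present the junctions are exact; otherwise the
innermost anchor ends are reported and the event is flagged
approximate. Split-read matching is an exact comparison of at least 12
clipped bases against a 40-base border window — deterministic and
sufficient at fixture scale; no local alignment is attempted.

Copy number is inferred from relative depth: the median depth over the
T-DNA interval of the vector contig divided by the median genomic depth,
rounded and floored at 1. The insert structure is called
`TDNA_BACKBONE_TDNA` when the copy estimate is 2 *and* at least half of
the backbone positions (vector minus T-DNA) are covered at depth 3 or
more; otherwise `TDNA_ONLY`. For the backbone structure the generator
integrates the T-DNA, then the full plasmid arc between the borders,
then the T-DNA again — every vector base is integrated while the T-DNA
is present in exactly two copies, which is what the depth rule
recovers.

Finally the site is classified against gene models: `GENIC_DISRUPTING`
if the deleted interval or the insertion point falls inside any
transcript span (deleted CDS bases are counted per gene on the
canonical transcript), else `PROMOTER` if within 1500 bases upstream of
a transcription start site (strand-aware), else `INTERGENIC`. When
several classes apply across overlapping genes — the classic case being
an insertion in one gene's promoter that simultaneously truncates an
antisense gene — all genes are listed and the summary label follows the
precedence disrupting > promoter > intergenic.

## Dual-caller consensus

Small variants are taken as the intersection of two callsets produced by
independent callers, after a fixed filter cascade:

1. **Low-complexity exclusion.** A from-scratch symmetric DUST masker:
   an interval of length $L$ with triplet counts $c_t$ scores
   $S = \sum_t c_t(c_t-1)/2$, and is masked when $10\,S/(L-2)$ exceeds
   the threshold (default 20) for some interval no longer than the
   window (default 64). The mask is the union of qualifying intervals.
   Triplets containing N are invalid. These defaults mask homopolymers
   and short-period repeats while leaving typical random sequence
   unmasked, matching the behavior of the classic masker.
2. **Quality**: Phred variant quality at least 30.
3. **Depth**: read depth strictly greater than 10 and strictly less
   than 29 (both configurable).
4. **Strand balance**: at least one alt-supporting read on each strand.
   This is our concrete reading of "unbiased double-strand coverage";
   the minimum per strand is configurable.

Removals are tallied against the first failing filter in that fixed
order, so tallies are reproducible.

Because the two callers represent the same haplotype differently (one
joins adjacent substitutions into MNPs, the other emits per-base
primitives), intersection happens in *primitive space*: indels are
parsimony-trimmed and left-aligned, MNPs are decomposed into per-base
SNPs tagged with their source record, and a record of callset A is kept
iff every primitive derived from it occurs among B's primitives. The
output keeps A's representation. Complex records (alleles differing in
both content and length) are never decomposed and match only exactly —
a deliberate trade of recall for determinism. Exact-representation
matching is also available (`mode = "exact"`).

## Effect annotation

Each consensus variant is assigned one summary region class over the
canonical transcripts (longest CDS, ties broken lexicographically by
transcript id) with the precedence CDS exon > UTR > non-coding exon >
intron > upstream > downstream > intergenic, using strand-aware
1500-base flanks. Coding effects are evaluated codon-wise on the
mutated CDS: indels changing the frame (net inserted/deleted CDS bases
not divisible by 3) are `frameshift_variant`, otherwise
`inframe_indel`; substitutions are `start_lost`, `stop_gained`,
`stop_lost`, `missense_variant` or `synonymous_variant`. A deletion
spanning an exon boundary counts only its deleted *CDS* bases toward
the frame rule. Substitutions spanning the CDS edge are split at the
boundary and the most severe part reported. Impact tiers are a fixed
function of the effect term: frameshift and start/stop changes are
HIGH, missense and in-frame indels MODERATE, synonymous LOW, and all
non-coding terms MODIFIER. Because the generator also produces lincRNA
genes, whose exons none of the classic region labels fit, we add a
region class `EXON_NC` (effect `noncoding_exon_variant`, MODIFIER); it
ranks between the UTRs and introns in the precedence.

There is no splice-region effect class, and canonical-transcript
selection by longest CDS is a convention — both choices mirror the
standard annotator configuration this module replaces.

## Summary statistics

The report computes: the variation rate (variants per base, also at 3
significant figures); the type spectrum over SNP/MNP/INS/DEL/COMPLEX;
transition/transversion counts and ratio (MNPs contribute their
decomposed substitutions); the substitution spectrum both as 12 ordered
changes and strand-collapsed into 6 classes; indel length histograms
with the deletion/insertion ratio and 1-bp shares; variant density per
Mb of each region class, with class lengths taken as collapsed union
lengths under the same precedence as assignment, so they partition the
genome; variant counts in half-open 10-kb bins (projected onto
chromosomes through the contig placement map when present); hotspot
contigs (share of all variants at or above a threshold, default 20%);
the high-impact effect table with percentages at two decimals; NS/S
tallies (NS = missense + stop gained/lost + start lost, S = synonymous;
the ratio is reported as undefined when S = 0); and verification
precision as a rounded integer percentage. Rounding conventions are
fixed per statistic so printed numbers are exactly reproducible.

## The synthetic-data generator

The generator is first-class, tested code. It emulates the study design
the pipeline targets:

* **Genomes**: multi-contig references (default 2 x 50 kb for fixture
  work) with protein-coding and lincRNA genes on both strands. Coding
  genes carry real ORFs written into the sequence (ATG, no internal
  stop, terminal stop, CDS length divisible by 3), so effect calls
  translate. One antisense overlapping pair is planted with exact
  geometry: a minus-strand gene whose first coding exon (142 bases)
  lies just upstream of a plus-strand gene's TSS — a 361-base deletion
  ending 1 base before that TSS removes exactly those 142 CDS bases.
  The contig tails are kept gene-free so intergenic fixtures exist.
* **Constructs and insertions**: a parameterized plasmid (9 kb with a
  3-kb T-DNA by default; real border coordinates vary by construct,
  so they are parameters, not constants) inserted with a configurable
  junction deletion, copy count and structure. The three built-in line
  fixtures use junction deletions of 1304, 361 and 95 nt, with one,
  one and two T-DNA copies, the last carrying the vector backbone —
  the published integration parameters.
* **Variants**: planted with the published type spectrum (62%
  deletions, 27% SNPs, 7% insertions, 2% MNPs, 2% complex), a
  transition weight of 0.63 (Ts/Tv about 1.7), and 1-bp-dominant indel
  lengths (97.5% of deletions and 88.5% of insertions are 1 bp).
  Variants are non-overlapping with a 12-base guard and avoid the
  insertion locus. An optional hotspot contig takes a fixed share
  (30% in the acceptance fixtures) of all variants.
* **Reads**: 100-bp paired-end fragments at 35x coverage with a Normal
  fragment-length law, substitution-only sequencing errors, and *truth
  alignments* against the combined reference: junction-straddling reads
  are soft-clipped exactly at the junction, insert reads map to the
  vector contig, mates and template lengths follow the SAM standard.
* **Callers**: emulated callsets in the two allele representations
  (MNP-joining vs primitive-decomposed) with independent
  false-negative dropout, uniform false-positive SNPs outside truth
  loci, and simple quality/depth/strand laws.

What the generator does *not* emulate — and therefore what passing
tests do not establish about real data — includes realistic error
profiles and quality strings, indel sequencing errors, PCR duplicates,
repeat-induced mis-mapping (reads come with their true alignments), and
structural variation beyond the single transgene insertion. Variant
calling itself is emulated from truth sets rather than re-derived from
pileups, which is also why read errors are substitutions only.

## Numerical and design choices

* Internal coordinates are 1-based closed intervals throughout (the
  native convention of the interval and annotation libraries used);
  only BED output converts to 0-based half-open, giving a single
  conversion boundary.
* The junction convention (last retained / first retained base) is
  documented rather than inferred; published junction tables rarely
  state their convention.
* Depth bounds are exclusive on both sides, per the published filter
  ("greater than 10", "less than 29"); the upper bound is configurable
  because it is tied to mean coverage.
* Degenerate inputs have defined answers: Ts/Tv and deletion/insertion
  ratios are undefined (NA) without transversions/insertions; NS/S is
  undefined at S = 0; zero-length region classes give NA densities; a
  zero-length junction deletion still disrupts a gene it lands in, with
  zero deleted CDS bases.
* Cluster tie-breaks: split-read junctions take the modal value;
  left/right cluster pairing is nearest-downstream; event tables are
  sorted by contig and coordinate so output files are deterministic.
* A reference CDS that fails to translate cleanly flags the annotation
  with a warning and is still evaluated on the raw frame.

## Scale of the shipped fixtures

The built-in fixtures run on 2 x 50 kb (fixture work and the pipeline
default), 1 x 20 kb (randomized insertion sweeps) and 6 x 100 kb
(spectrum recovery at n = 10 000 planted variants) genomes at 35x
coverage. These sizes were chosen so the complete suite — including 30
seeded read simulations and 200-string masker cross-checks — runs
comfortably on a laptop while every statistical check retains enough
events for 3-standard-error bounds.

## Running the pipeline

```{r, eval = FALSE}
cfg <- default_config(seed = 7, outdir = "line212", line = "212")
run_pipeline(cfg)                 # simulate -> scan -> consensus ->
                                  # annotate -> summarize + manifest
events <- stage_scan(cfg)         # any stage can be rerun standalone
report <- stage_summarize(cfg)
```

The same orchestration is available from a shell through the thin
wrapper in `inst/scripts/tgintegrity`; the exported functions are the
tested surface.
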