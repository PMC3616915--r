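---
title: "Mapping and classifying bacterial transcription start sites with tssmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and classifying bacterial transcription start sites with tssmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tssmap)
```

## The problem

Differential 5'-end RNA sequencing of a bacterium yields, after mapping,
millions of read 5' ends. A small fraction of these mark genuine
transcription start sites (TSS); the rest are processing products and noise.
`tssmap` turns a table of mapped read 5' ends plus a genome and its gene
annotation into (i) a set of called TSS, (ii) a six-way classification of
each TSS by genomic context, (iii) merged antisense-RNA and small-RNA
features, (iv) TSS-guided open-reading-frame (ORF) calls, (v) sigma-factor
promoter predictions, and (vi) transcription-factor binding-site scans. A
synthetic-genome generator plants ground truth for every one of these
layers so the whole pipeline can be validated end to end.

## TSS calling

Reads are first filtered: at least 18 nt long, uniquely mapped, and without
mismatches in the first three 5' bases (a mismatched 5' base usually means
the true transcript end is elsewhere). Reads sharing a common 5' position
form a *TSS contig*: its 5'-most position is the TSS, the 3' end of the
longest member read is the contig end. A contig requires at least 30
supporting reads; positions below that threshold are kept in a separate
sub-threshold channel rather than silently discarded, because known TSS can
fail a global coverage cutoff. TSS whose positions differ by **less than
3 nt** (strict) are merged; merging is transitive, since the pairwise rule
is naturally closed under chaining. The merged contig keeps the coordinate
of the member with the most reads (ties go to the 5'-most member — the
"prominent 5' end"), sums the read counts, and extends to the furthest 3'
end. All thresholds are `tss_call_config()` parameters.

## The minimal-transcription-unit model and the six TSS classes

Classification is anchored on a *minimal transcription unit* (MTU) per
annotated gene: the CDS extended by fixed minimal UTRs — 14 nt of 5'-UTR
(the shortest useful ribosome binding site) and 20 nt of 3'-UTR (a minimal
terminator hairpin) — with a 40-nt promoter region immediately upstream.
The 14 + 40 = 54 nt upstream of the start codon form the "mRNA window":
a TSS contig overlapping it in sense orientation is most plausibly the 5'
end of that gene's mRNA.

Each TSS receives exactly one class, applying the rules in fixed
precedence:

1. **lmTSS** — the TSS coincides with the first nucleotide of a
   same-strand ATG start codon (leaderless mRNA). The genomic triplet is
   checked, not assumed from the annotation.
2. **mTSS** — the contig overlaps the 54-nt window of a gene in sense;
   the target is the gene with the nearest downstream start codon among
   qualifying windows, which minimises the implied 5'-UTR length. A prior
   mRNA-leader contig covering a gene's MTU can also rescue a more distant
   TSS into this class.
3. **seTSS** — the TSS position lies inside a same-strand MTU (internal
   sense transcript).
4. **asTSS** — the contig overlaps an MTU on the opposite strand
   (cis-antisense RNA).
5. **pmTSS** — the contig overlaps no MTU on either strand and the TSS is
   at most 300 nt upstream, in sense, of a start codon (mRNA with a long
   5'-UTR, or an sRNA — genuinely ambiguous).
6. **sTSS** — everything else: a trans-encoded sRNA in an intergenic
   region.

The precedence order itself is a design choice. mTSS must precede seTSS,
otherwise every TSS inside the 14-nt minimal 5'-UTR would be absorbed by
the "inside an MTU" rule; asTSS must precede pmTSS because pmTSS requires
the absence of antisense overlap. We evaluate seTSS on the TSS *point*
(not the whole contig), which matches the definition of an internal
transcript; the whole-contig alternative would reclassify borderline cases
that the boundary-case generator flag exercises deliberately.

Overlapping sTSS contigs merge into sRNA features; overlapping asTSS
contigs with a common target gene merge into asRNA features annotated with
the region of the target they cover (5'-UTR, CDS or 3'-UTR; the region
with the largest overlap wins, ties resolved towards the 5'-UTR).

Coordinates are 1-based inclusive throughout, with BED half-open input
converted at the boundary. Circular replicons are carried as metadata but
interval arithmetic is linear: an MTU is truncated at replicon ends rather
than wrapped across the origin. This is a known limitation; genes spanning
the origin of a circular replicon should be split by the caller.

## ORF discovery and the ribosome-binding-site energy model

For each mRNA-like TSS the downstream strand (3 kb by default) is scanned
for ORFs (start codon, in-frame stop, at least 60 nt). A candidate
starting exactly at the TSS with an ATG is *leaderless*; one whose start
codon lies at least 14 nt downstream is a *Shine-Dalgarno* (SD) candidate
whose leader must contain a ribosome binding site. SD candidates may use
ATG/GTG/TTG starts; leaderless ORFs are ATG-only.

The RBS test asks whether the leader can hybridise with the 3' tail of the
16S rRNA (supplied as `anti_sd_tail`; there is no universal cross-species
default). We score every ungapped antiparallel alignment of leader and
tail: each contiguous stretch of Watson-Crick or G:U pairs of at least 3
base pairs is a candidate helix, scored as the sum of nearest-neighbour
stack free energies plus a duplex-initiation penalty of +4.09 kcal/mol and
a +0.45 kcal/mol terminal penalty per helix end closed by an A:U or G:U
pair. Watson-Crick stacks use the standard RNA nearest-neighbour values;
all G:U-containing stacks are scored with a single flat -0.50 kcal/mol.
Bulges, internal loops and dangling ends are not modelled — the model is a
documented simplification of a full secondary-structure energy, adequate
because the decision is a threshold test, not a structure prediction. A
leader is an RBS when its minimum energy is at or below
**-3.4535 kcal/mol** (the cutoff is part of the interface contract and
configurable). The implementation is checked against a brute-force
enumeration of all (offset, helix) pairs.

An ORF sharing its start or stop codon position with an annotated gene is
*reannotated*; one overlapping no annotated gene by more than a start/stop
codon (3 nt) is *new* (named `<replicon>_ORF_n`); the rest are discarded.
Protein-homology evidence enters only as an optional external keep-filter
table — the package never runs similarity searches itself.

## Promoter discovery

Two strategies, chosen per sigma factor:

**Consensus string search** (for ECF sigma factors with a known motif,
e.g. `GAAT-N18-GTCT`): all placements on either strand with at most one
mismatch across both boxes, the configured spacer, and the last promoter
nucleotide 5-12 nt upstream of a TSS.

**Iterative two-phase profile search** (when aligned example promoters
exist): -35 and -10 elements of the seed promoters are stacked into
separate position-specific scoring matrices (pseudocount 1) against the
genome's zero-order background composition — a uniform background would
distort P-values on a GC-rich genome. Element P-values are *exact*: the
score distribution under the background model is built by dynamic
programming over the attained score sums (no discretisation grid), so a
word's P-value is the exact tail probability, verified against full
enumeration up to width 8. Before phase 1 the seed set is extended by
genomic occurrences *identical* to a seed's element pair near a TSS
(`extended_model`). Phase 1 scans both strands, chains collinear -35/-10
pairs whose spacer (nucleotides strictly between the elements) is in the
model's range, keeps pairs whose -10 element ends 5-12 nt upstream of a
TSS or prior-contig 5' end, and retains candidates with both element
P-values at most 0.005 that are not associated *exclusively* with seTSS
(`new_initial`). Phase 2 rebuilds the matrices from the enlarged seed set
and repeats with the cutoff relaxed to 0.02 and all TSS classes admitted
(`second_search`). The scan itself always uses the phase-2 cutoff, so
phase 2 never needs a rescan; the phase-specific filters are applied to
the candidate list. The final output is the de-duplicated union (key:
sigma, strand, element coordinates) with provenance labels, and is by
construction a superset of the phase-1 result.

The gap to the TSS is measured from the final -10 nucleotide, exclusive:
an element ending at position *t* − 5 has gap 5. Spacer ranges and element
widths are per-model configuration; the shipped examples (6/6 elements,
spacer 16-18 for housekeeping-type factors) are illustrative defaults, not
species constants.

## TFBS scanning and upstream extraction

Gapped two-box motifs (e.g. the CtrA box TAA-N7-TTAAC) are scored with a
PSSM over the informative box columns only, smoothed with pseudo-frequency
0.01, scanned along the sense strand of each gene's upstream window
(300 nt, truncated at the nearest annotated gene); hits need a positive
log-odds score, exact P-value at most 1e-4, and no overlap with any
annotated gene. Sites are then positioned relative to TSS: a site ending
22-25 nt upstream of a TSS occupies the -35 element and is a strong
direct-regulation candidate; sites further upstream are reported
separately. For de novo motif discovery, the 40-nt windows upstream of
mTSS/lmTSS with at least 300 reads and no promoter assignment are exported
as FASTA for an external tool such as MEME
(`-dna -mod anr -minw 18 -maxw 40 -minsites 10`).

## The synthetic-data generator

`synth_config()` defaults define the simulated study: two replicons
(300 kb + 200 kb), 200 genes in transcription units separated by 1 kb
(80 nt within operons, at most 25% of genes as non-lead operon members),
GC content 0.60 as in a GC-rich soil alphaproteobacterium, planted TSS of
all six classes (40/10/15/30/35/10 for mTSS/lmTSS/pmTSS/seTSS/asTSS/sTSS —
proportions loosely mirroring a real bacterial primary transcriptome,
scaled to the genome), read depth negative-binomial with mean 100 and
dispersion 0.5 (variance mu + 0.5 mu², so roughly 12% of plants fall below
the 30-read threshold and the cutoff is genuinely exercised), 5% satellite
reads within ±2 nt, 0.5 spurious read-start positions per kb per strand
(a fifth of them flagged non-unique or 5'-mismatched to exercise the read
filters), and read lengths uniform on 87-108 nt, the observed contig
length range. Setting the dispersion, jitter and noise to zero gives the
idealised no-noise condition under which every plant must be recovered at
its exact coordinate with its exact class; "noise off" is interpreted as
all stochastic corruption off, including depth dispersion (Poisson depth
at mean 100 never drops below 30 in practice).

Class geometries are planted with at least 10 nt of slack from every rule
boundary: mTSS 20-54 nt upstream of a start codon, lmTSS on the ATG,
pmTSS 170-290 nt upstream with the contig clear of all MTUs, seTSS/asTSS
150 nt into the CDS in sense/antisense, sTSS 450 nt upstream of the
nearest same-strand start codon. The `boundary_cases` flag additionally
plants deliberately ambiguous TSS inside operons whose contig spans the
gap and the next member's mRNA window, exercising the precedence order.

Promoters are written into the genome sequence, not merely recorded: seed
promoters carry one mismatch per element (so that exact-consensus plants
are discovered by the profile search rather than swallowed by the exact
extension step), exact-consensus instances test phase-1 recovery, and
PSSM-sampled instances (accepted at ≥ 80% of the seed matrix's maximal
score) test generalisation. Shine-Dalgarno leaders are the reverse
complement of the anti-SD tail written 8 nt before the start codon, and
the rest of the leader is written pyrimidine-rich (G-poor): around real
ribosome binding sites, G/A-rich stretches complementary to the anti-SD
core are selected against because they would create competing ribosome
entry sites — and, for the generator, a G/A-rich leader background would
make the planted RBS ambiguous as ground truth. TF binding sites are
planted in the upstream windows of genes that carry no other feature.

What the generator does *not* emulate: sequencing errors and quality
scores, fragment-length structure beyond the read length, processing-site
5' ends (the caller treats all surviving read starts equally, since
enrichment for primary 5' ends is never complete in real libraries),
origin-spanning features on circular replicons, and expression-level
heterogeneity beyond the negative-binomial depth. Passing the planted
recovery tests therefore demonstrates correctness of the rule logic and
robustness to count noise — not performance on the harder ambiguities of
real transcriptomes.

## Numerical and scale choices

The exact P-value convolution aggregates equal score sums without any
rounding; floating-point comparisons in the scanner use a 1e-9 guard so a
word equal to the threshold is always reported. Acceptance-scale checks
run at the sizes they are specified for — 100 replicons of up to 10 kb for
the caller oracle, 1,000 random TSS over a 50-gene genome for the
classifier oracle, a 0.5 Mb two-replicon fixture for the end-to-end runs —
sizes at which every oracle is exhaustive and a full run takes well under
five minutes on one CPU. All randomness flows from a single integer seed;
two runs at one seed are byte-identical, including written outputs (the
run report omits wall-clock timing for exactly this reason).

## Known limitations

- Linear interval arithmetic on circular replicons (above).
- The RBS energy model is a threshold test, not a structure prediction;
  absolute energies should not be compared with full secondary-structure
  tools.
- The paper-derived promoter element widths and spacer ranges for specific
  sigma factors are species knowledge the user must supply; the shipped
  values are illustrative.
- The seTSS rule uses the TSS point; a whole-contig variant would be a
  one-line change but alters borderline classifications.
- Promoter discovery reports every (sigma, element-pair) candidate that
  survives its phase's filters; it does not attempt to pick a single best
  promoter per TSS, and one TSS may carry several predictions, as in real
  overlapping regulons.
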