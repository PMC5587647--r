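---
title: "Methods: repeat-level analysis of WD40 proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-level analysis of WD40 proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscope)
```

## The scientific problem

WD40 proteins fold into beta-propellers of roughly seven blades, each blade
built from a ~40–60 residue sequence repeat (four strands Sa–Sd joined by
loops Lda, Lab, Lbc, Lcd; the sequence repeat is offset from the structural
blade by one strand, the "Velcro" closure). Because the repeats arise by
internal duplication and then diverge, the *similarity between a protein's
own repeats* carries a signal about how recently that duplication happened,
and the DH[S/T]W hydrogen-bond tetrad carried by some blades is a proxy for
thermal stability. repeatscope implements the full analysis chain around
these two observables: cataloguing WD40 candidates and their abundance
across taxa, measuring internal repetitiveness, calling tetrads, examining
the genomic neighbourhoods of prokaryotic WD40 genes, and dating repeat
duplications with synonymous substitution rates.

The package consumes WDSP-style repeat annotations (boundaries, per-residue
strand/loop labels, per-repeat scores) rather than predicting repeats
itself; repeat prediction is out of scope.

## Candidate filtering and abundance statistics

A protein enters the WD40 catalogue when it has at least 6 annotated
repeats and a mean repeat score of at least 48 (`filter_wd40_candidates()`,
both thresholds configurable). Retained proteins with mean score in
[48, 60) are additionally *review-flagged*: with real annotations this band
is where manual double-checking against domain databases is advisable. The
flagged set is kept by default because the package cannot replay a manual
review; `strict = TRUE` drops it instead. Per-gene redundancy is removed by
keeping the longest protein per (organism, gene), ties broken by the
lexicographically smallest accession (`dedupe_longest_per_gene()`).

Abundance of WD40 proteins in a proteome is the simple percentage
100·n_wd40/n_proteins. Category summaries use the *unweighted* mean over
proteomes, which is the natural reading of "average percentage per
proteome"; an overall prokaryote-vs-eukaryote fold change is deliberately
not computed because it depends on averaging weights that are not part of
the per-category definition. Differences between categories are tested
with a one-sided Wilcoxon rank-sum test (`rank_sum_test()`), exact (via
the rank-sum null distribution) when the combined sample size is at most
12 and there are no ties, otherwise the normal approximation with tie and
continuity correction. The switch point of 12 keeps the exact branch where
an enumeration oracle is cheap to verify against; whether a continuity
correction is applied in the approximate branch is a documented choice,
not an inference.

## The internal-sequence-identity statistic

Repeat pairs are aligned globally (Needleman–Wunsch through
`Biostrings::pairwiseAlignment`; BLOSUM62, gap open 10, gap extend 0.5 in
the positive-penalty convention, all configurable — alignment parameters
for this statistic are a convention, and outputs echo them). Pairwise
identity divides identical aligned pairs by the length of the *shorter*
repeat.

The per-protein statistic (`internal_identity()`) is the continuous form
of a windowed clique criterion:

> max over windows of 8 contiguous repeats, of the max over 6-repeat
> subsets of the window, of the minimum pairwise identity inside the
> subset.

For proteins of 6 or 7 repeats the window constraint is dropped. The value
v returned satisfies "some 8-window contains 6 repeats all mutually
identical at level X" exactly when v ≥ X, with the threshold read
inclusively — that reading makes the class cutoffs ("at least 0.7")
consistent and only differs from a strict reading on exact ties.
Highly-Repetitive (HR) means v ≥ 0.7, Moderately-Repetitive (MR) means
0.4 ≤ v < 0.7. Proteins with fewer than 6 repeats get an *undefined*
statistic, never 0: absence of evidence for repetitiveness is not low
repetitiveness. Reports on a 0.1-wide level grid are obtained by flooring
v. The implementation enumerates windows and subsets directly (C(8,6) = 28
subsets per window); the test suite checks it against an independent
enumeration over all span-constrained 6-subsets.

## Canonical template, tetrad calls and logos

Because the geometry of the source repeat predictor is not reproduced
here, the package defines its own 48-residue canonical blade
(`wd40_template()`): blocks Lda(6) Sa(7) Lab(5) Sb(7) Lbc(3) Sc(9) Lcd(4)
Sd(7). Loop block widths equal the conventional numbers of conserved loop
sites kept for logos (6/5/3/4 for Lda/Lab/Lbc/Lcd), and the template
carries a complete tetrad at explicit positions: His on Lda (position 2),
the Asp of the SPDG motif on Lab (position 16), Ser at the last Sb site
(position 25) and Trp at the last Sc site (position 37). The D and W
anchors follow the two positions that are well established for WD40
repeats (the SPDG aspartate; the Sc tryptophan); the H and S/T sites are
this package's template choices and, like all four, are plain
configuration of `call_tetrad()`.

`map_repeats_to_template()` places strand residues positionally
(left-anchored; a missing or overflowing strand run flags the repeat) and
aligns loop residues across all same-loop segments of the protein. The
loop alignment is positional when all segments share one length and
otherwise a star alignment around the longest segment using the package's
global aligner — loops here are 3–10 residues, for which a star alignment
and a progressive multiple alignment coincide in practice. Aligned loop
columns are ranked by non-gap occupancy, then by the highest
single-residue frequency, then leftmost, and the top-k kept in original
order. Ranking by occupancy-then-frequency operationalises "top conserved
sites", for which no metric is standard.

A tetrad is called complete when the four configured sites carry D, H,
S-or-T and W respectively; one repeat can hold at most one tetrad, so
tetrad density (#complete / #repeats) lies in [0, 1]. Logo matrices are
plain residue counts per template position; information content is Shannon
information against the uniform 20-letter background with no small-sample
correction (counts are emitted alongside bits so corrected renderings
remain possible).

## Gene neighbourhoods

Prokaryotic gene clusters — operon proxies — are maximal runs of genes on
one contig and strand whose intergenic distances are below 300 bp
(`cluster_genes()`). The distance convention is the number of bases
strictly between consecutive genes (`next_start − prev_end − 1`), so a
299-bp gap joins and a 300-bp gap splits; overlapping genes (negative
distance) cluster, as is common in operons. The alternative end-to-start
convention is available as an option.

Orthology between two genomes uses bidirectional best hits
(`bbh_pairs()`). Scores come from the package's global aligner rather than
an external BLAST binary — at the scale of per-genome WD40 complements the
BBH relation depends only on the score ordering — and ties are broken by
higher identity, then lexicographic id, making the relation deterministic.
Two clusters are a conserved neighbourhood when they share a BBH pair of
WD40 genes and every remaining member of the smaller cluster has a BBH
partner of identity ≥ 0.3 inside the other cluster
(`match_conserved_clusters()`); 0.3 is a deliberately permissive
remote-homology default and is configurable. The WD40 gene itself must be
a cluster member for a conservation call. WD40 clusters without a partner
are reported lineage/species-specific. Annotation term counts
(`term_frequencies()`) drop uninformative phrases ("hypothetical protein",
"WD40 repeat", …) before counting; drawing word clouds from the counts is
out of scope.

## Dating repeat duplications: NG86 dS and omega

For each unordered pair of repeats in one gene, the amino-acid alignment
is threaded onto the repeat CDS segments (codon i..j for residues i..j —
repeats must come from one reading frame) and the Nei–Gojobori counting
estimator is applied (`ng86()`): per-codon synonymous site fractions from
the nine single-nucleotide neighbours with mutations to stops excluded
from the denominator, site counts averaged over the two sequences,
observed differences averaged over all minimal mutation paths with
stop-traversing paths discarded, and Jukes–Cantor correction
d = −(3/4)·ln(1 − (4/3)p). Saturated pairs (non-positive log argument)
carry no rates and are *excluded* downstream, never clamped — the same
treatment as undefined estimates in the source pipelines. omega = dN/dS
when dS > 0 and is absent when dS = 0 (a 0/0 ratio is meaningless, and at
dS = 0 there has been no time for selection to leave a synonymous
yardstick).

A counting estimator was chosen over maximum-likelihood codon models
because it is exactly specified, fast, and verifiable against a
brute-force site/path enumerator (the test suite does exactly that on
short alignments); the per-pair interface leaves room for other
estimators. The genetic code is a parameter (`code = "11"` by default for
the bacteria-focused pipeline). Note that NCBI translation tables 1 and
11 assign identical amino acids — they differ only in initiation codons —
so dS/dN are identical under the two; codes that genuinely reassign
codons (e.g. table 2) do change site counts, which the tests demonstrate.

Per protein, the median of non-saturated pairwise dS summarises the age of
its duplications; proteins with median dS in [1.0, 2.0) — old enough to
measure, young enough to estimate reliably — form the purifying-selection
subset whose median omega is reported (`purifying_subset()`).

## The synthetic-data generator

`simulate_wd40_gene()` operationalises the duplication–divergence model
the analyses assume: an ancestral blade CDS is built by back-translating
the canonical template with uniform synonymous codon usage, duplicated
n_repeats times, and each copy evolves independently — a *star* phylogeny,
matching the pairwise (non-phylogenetic) statistics computed downstream.
Candidate point mutations arrive as Poisson(t × 3 × codons) per repeat,
targets drawn with transition weight kappa (default 2) against 1 per
transversion; mutations creating stops are rejected; nonsynonymous changes
are accepted with probability omega_sim (default 0.1, emulating purifying
selection), synonymous changes always. The truth log records every
accepted mutation, which is sufficient to rebuild the evolved CDS and to
compute planted divergences without re-running the generator; true
pairwise synonymous divergence is defined as accepted synonymous events on
both lineages per ancestral NG86 synonymous site.

`pairwise_syn_rate()` converts analytically between the candidate rate t
and the expected pairwise synonymous divergence (from the template's codon
composition and kappa; no simulation or fitting), so study conditions can
be stated on the dS scale. Validation uses synonymous divergences of
0.05, 0.2 and 0.5 — the regime the counting estimator is designed for —
with 50 independent genes of 8 repeats each (28 repeat pairs × 48 codons
= 1344 codons per gene), asserting mean estimated dS within 15% of the
truth log. Beyond pairwise synonymous divergence ≈ 1 the Jukes–Cantor
correction increasingly overshoots the true event count (two-fold
degenerate sites saturate faster than the JC model assumes; with kappa = 2
the overshoot reaches roughly 15–20% at divergence ~1.1). This is a known
property of the estimator, consistent with treating dS ≥ 2 as unreliable
and with excluding saturated pairs.

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real data: insertions and deletions within repeats
(real repeats vary in length; the aligner handles indels but recovery is
only tested indel-free), codon usage bias, tree-structured duplication
histories (a ladder of nested duplications changes the pairwise identity
spectrum), among-site rate variation, and the zero-inflation of WD40
presence in prokaryotic proteomes (`simulate_proteomes()` draws plain
binomial counts at the configured abundance, so the *fraction of proteomes
containing* WD40s is an outcome, not a control). The "ancient but
conserved" regime — high dS with amino-acid identity held high by strong
purifying selection — is only partially reproducible with a single global
omega_sim.

Other generator defaults: proteome collections follow the six cellular
taxonomic categories with their published proteome counts and mean
abundances (100/27/198/55/134/1679 proteomes; 0.98/0.77/1.21/1.08/
0.08/0.06%), with round per-category proteome sizes (15000/25000/9000/
12000/2400/3500 proteins) typical of each group. Planted gene clusters
are laid down with exact requested intergenic gaps; decoys are separated
by at least 400 bp, safely beyond the 300-bp clustering threshold.

## Numerical and degenerate-input conventions

* All thresholds stated as "at least" are inclusive (score ≥ 48, identity
  ≥ 0.7/0.4, dS ≥ 1.0); "less than" bounds are exclusive (gap < 300 bp,
  dS < 2.0).
* Deterministic tie-breaks everywhere: dedup ties by accession; BBH ties
  by identity then id; loop-column ties by frequency then position;
  cluster ids from the leftmost member.
* Empty inputs return empty results with a warning where the operation is
  a summary (empty FASTA, empty distribution), and errors where the result
  would be meaningless (abundance of an empty proteome, identity of empty
  sequences, tetrad density of zero repeats).
* Unknown residue X aligns with score 0 against everything.
* All generators are byte-deterministic under a fixed seed.

## Validation problem sizes

The shipped test-suite and acceptance-script runs use: 200 random identity
matrices of 6–12 repeats against the enumeration oracle; the full battery
of rank-sum splits up to combined size 10; all ≤3-codon NG86 cases against
the site/path enumerator; 50 genes per divergence level for dS recovery;
30 seeds per divergence level for identity monotonicity; and two planted
genomes for neighbourhood recovery. These sizes give the oracles full
coverage of the small regime and keep stochastic checks well inside their
tolerance at desk scale.
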