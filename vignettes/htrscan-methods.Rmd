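---
title: "Methods: detecting and analysing horizontally transferred regions"
author: "htrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and analysing horizontally transferred regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`htrscan` targets a specific comparative-genomics signature: genomic
regions transferred horizontally between distantly related fungal
species in very recent (human) time. Such regions are expected to be

1. nearly identical between species whose genomic background diverged by
   10–15% per site;
2. long — far longer than the near-identical stretches that survive by
   chance between species at that distance;
3. enriched in, and often delimited by, transposable elements;
4. patchily distributed across strains and species, contributing
   directly to genome-size differences.

The package implements the detection machinery, the panel scan that maps
presence and identity of each region across a genome collection, the
within-species population statistics used to establish the demographic
context (clonality, diversity, mating-type composition), and gene-level
selection inference. It deliberately consumes standard interchange
formats at every boundary (FASTA, PAF, GFF3/BED, VCF, Newick), so each
stage can also be driven by external tools.

## Threshold calibration

Vertical descent alone produces some long, highly similar segments
between related species. To bound that null, matches between a *control*
species pair — at the same phylogenetic distance as the focal pair but
with no suspicion of recent gene flow — are examined: among control
matches of at least `minMatch` (default 1000 bp), the identity threshold
is the *floor* of the maximum identity, and the length threshold is the
*second-longest* qualifying match rounded *up* to the nearest 100 bp.
Using the second-longest treats the single longest match as a one-off
that may itself reflect undetected transfer; the rounding rules encode a
conservative integer-percent / round-hundred policy and can be
overridden. With fewer than two qualifying matches the longest is used
and the result is flagged under-powered.

## Matching and candidate detection

The built-in matcher is a seed-and-extend k-mer anchor chain: exact
k-mers (default k = 15) shared between query and target are grouped by
diagonal, chained when separated by at most `maxGap` (500 bp), and each
chain is scored by exact column comparison over its full span, so the
identity of a block is literally its fraction of matching columns.
The matcher is gapless: an indel splits a match into two blocks on
different diagonals. This is a deliberate simplification — the
synthetic genomes evolve by substitution only, keeping coordinate truth
exact, and real-data users are expected to feed PAF from a whole-genome
aligner (`minimap2 -cx asm20`) through the same `MatchBlocks` container.
Alternative chains of the same region pair (same strand, nearby
diagonal, mutually overlapping) are resolved by most matched bases, ties
to the leftmost query start; matches of one query region to distinct
loci are all kept, since repeat-induced multi-matches carry information
the panel scan needs.

Detection keeps matches passing both calibrated thresholds, projects
them onto one designated reference strain per species, and single-linkage
merges any overlapping projected intervals. Projection through a
non-reference strain uses that strain's own matches to its reference,
mapped gaplessly by offset within the covering block; matches that no
block covers by at least half are counted and excluded. The projection
rule is our design choice — with near-clonal strains the lift is almost
always the identity map, and counting unliftable matches makes the rare
failures visible. Candidate identity is the matched-bases-weighted mean
over member matches; IDs are assigned by descending length with
coordinate tie-breaks, so output order is deterministic.

Whether candidates should be defined per strain pair and then
de-duplicated, rather than on reference projections, is genuinely open;
we chose reference projection because it yields a single coordinate
system for masking, consensus extraction and the panel scan. Similarly,
physically clustered candidates that plausibly represent one transfer
event are *not* merged at detection time; only the plotting stage
(`mergeForPlotting`, 35 kbp floor) merges overlapping regions.

## TE masking and extremities

Each candidate is intersected with the TE annotation; the unmasked
length is the candidate length minus the width of the TE union, and
candidates with less than 500 bp unmasked are discarded — regions that
are essentially pure repeat cannot be distinguished from TE mobility.
The consensus sequence of a retained region is the reference strain's
subsequence, not a column-wise majority: member copies are near-identical
by construction, and the choice keeps output deterministic. The
extremity report asks, for the very first and last base of each region,
whether it falls in a TE and how far the nearest TE is (0 inside,
`Inf` when the contig has none) — a TE-rich edge profile is the expected
signature of element-mediated transfer.

## Panel scan

Presence of an HTR in a panel genome is quantified from kept matches
only, where a match is kept iff it (1) covers ≥ 95% of the HTR span,
(2) covers ≥ 95% of a contig with at least 1 kbp of matched bases, or
(3) exceeds 10 kbp and lies within 1 kbp of the end of a contig longer
than the HTR, with at most the two longest such edge matches per HTR.
The 95% softening of "entire" tolerates aligner end-trimming and is
configurable back to 100%. "Larger contig" in rule 3 is defined as
longer than the HTR (the natural reading, though not the only one).
The fraction present is the union of kept match intervals over the HTR
length; identity is matched bases over the union, counting overlapping
portions once and attributing them to the higher-identity match
(pro-rata, since per-base identities are not retained). Positions hit by
more than one kept match can optionally be excluded from both numerator
and denominator (`excludeAmbiguous`), which is our operationalization of
"non-ambiguous matches" — multiply-hit positions are almost always
repetitive sequence.

An ordinary least-squares regression of genome size on total HTR
content (`genomeSizeRegression`) reports the adjusted R², quantifying
how much of the size variation between strains HTRs explain.

## Population genetics

Hard filters follow standard haploid GATK practice: QD < 2, MQ < 40,
FS > 60, rank-sum bounds, ≤ 10% missing calls, indels and
non-biallelic sites removed, with per-filter removal tallies. The two
rank-sum thresholds are sometimes printed unsigned in pipelines
(`MQRankSum < 12.5`); the GATK convention makes them −12.5 and −8.0, and
those negative bounds are the defaults here, overridable.

π is computed per site as 2·n₀·n₁ / (n·(n−1)) over non-missing calls
(equivalent to pairwise-complete averaging) and scaled by the *total*
reference length — callable length would be the alternative, and a
`genomeLength` override is provided. θ_W is S/(a₁·L) with S counting
sites where at least two non-missing calls disagree. Tajima's D uses the
standard constants; with S = 0 it is undefined and reported as `NA`.

The 95% null interval for D is obtained by fixed-S coalescent
resampling: neutral genealogies for n samples are simulated, exactly S
mutations are dropped with probability proportional to branch length,
and the 2.5/97.5 empirical quantiles of the resulting D sample form the
interval. Conditioning on S removes the nuisance dependence on θ; the
interval is seeded and memoized per (n, S).

LD is summarized as the squared allelic correlation r² between haploid
site pairs, binned by distance within 15 kbp windows at MAF ≥ 0.2 — a
flat profile near 1 indicates clonal propagation. Pruning for
structure-type analyses drops a site when r² ≥ 0.2 with any retained
site within 1 kbp upstream, after requiring MAF ≥ 0.05 with the minor
allele in ≥ 2 individuals; the greedy scan is a fixed point (pruning a
pruned set changes nothing).

Mating types are called by six-frame translated similarity against the
two reference idiomorphs — the fraction of the idiomorph's translated
k-mers (k = 8 aa, best frame) found in the six-frame translation of the
assembly. The idiomorphs are non-homologous, so scores separate cleanly;
0.25 is a permissive default threshold, and a double call is flagged as
an anomaly rather than silently resolved.

## Selection inference

Per-gene McDonald–Kreitman tables are built by a codon walk over the
in-group alignment plus outgroup: a codon where the in-group varies
contributes polymorphic counts (outgroup state ignored), a monomorphic
codon differing from the outgroup consensus contributes fixed counts.
Multi-position codons are resolved by averaging over mutational paths,
preferring stop-free paths and splitting ties equally; polymorphic
codons with more than two states are decomposed as a star from the
in-group consensus. When the outgroup sample is itself polymorphic, its
consensus (majority, deterministic tie-break) is used. Synonymous and
replacement site totals are NG86 per-codon counts averaged over
sequences, weighted by each sequence's non-missing codon count.

The classifier is a hierarchical Poisson log-linear model: counts
y ∈ {P_S, P_R, D_S, D_R} have

log E[y] = log L + β₀ + β_R·R + β_D·D + β_RD·R·D + u_g + d_g·D + s_g·R·D

with offsets log L_syn / log L_rep, gene random effects u_g (mutation
rate), d_g (lineage-specific divergence) and the *selection effect* s_g
on the replacement×divergence interaction. s_g > 0 means more
nonsynonymous divergence than the gene's own polymorphism predicts —
positive selection; s_g < 0, purifying. Classification uses the 95%
credible interval of s_g. Because the model conditions on the gene's own
synonymous and polymorphism rates, it makes no assumption about
demography or reproductive mode, which is what makes it usable for
clonal, bottlenecked industrial populations where sweep scans are
meaningless. Priors are weakly informative (normal(0, 10) fixed effects,
half-normal(0, 2.5) scales) — the approach's original description leaves
priors unstated, and these are standard choices that let the data
dominate at the count sizes involved. Sampling is by MCMC (JAGS),
default 25,000 iterations, 10,000 burn-in, thinning 4, two chains, with
split-chain R̂ reported per parameter and a warning above 1.1. The exact
conditional 2×2 test (`mkFisher`) is retained as the classical base
case; its discrete p-values are valid (conservative) rather than exactly
uniform under the null, which the test suite checks at several levels.

COG-category enrichment uses two-sided exact tests of focal-class
membership against the rest of the mapped genes; both raw p and
Benjamini–Hochberg q are reported, since whether a correction should be
applied at this stage is a matter of taste.

## The synthetic generator

The generator emulates the data regime the pipeline is built for, and
its defaults are the study conditions used throughout the tests:
two focal species at 12% background divergence (i.i.d. composition,
configurable GC), a handful of near-clonal strains per species carrying
coalescent SNPs at θ ≈ 0.005/bp (between the observed high- and
low-diversity regimes of the motivating system), planted HTR insertions
at ≥ 99% identity and 10–50 kbp, 5% TE density with optional TE
intervals across every HTR terminus, and two planted mating-type
idiomorphs. Divergence is applied as per-site substitution with no
indels, so planted coordinates remain exact — the price is that the
generator cannot exercise gap handling, structural variation, or
repeat-driven misalignment, and panel fractions on real data will be
noisier than the near-perfect recoveries seen on synthetic panels.
Passing tests therefore demonstrate correctness of the arithmetic and
the decision rules, not robustness to assembly artefacts.

Each HTR copy is mutated away from a fresh donor segment at rate
(1−identity)/2 so the *pairwise* identity between recipient copies
matches the configured value (two independent mutation processes
compound). Within-species variation comes from an in-package Kingman
coalescent sampler (genealogy simulation with exponential waiting times,
mutations dropped proportionally to branch length), which also backs the
fixed-S null intervals; E[S] = θ·L·a₁ by construction. A two-lineage
"clonal" variant plants every SNP on the same strain bipartition,
reproducing the flat r² ≈ 1 LD profile of purely asexual populations.
The MK-count generator draws from exactly the model the classifier fits,
with baseline rates chosen to give realistic counts (tens of synonymous
polymorphisms per ~400-codon gene).

## Numerical and design choices

- Coordinates are 0-based half-open internally (PAF convention); 1-based
  closed only inside GRanges/IRanges containers and GFF3 output.
- All stochastic functions take or derive from a single integer seed;
  identical seed + configuration gives byte-identical outputs.
- Problem sizes used by the test-suite and the acceptance script —
  300 kbp genomes, 20-seed detection panels, 200 simulated genes,
  200 null replicates with 4000-replicate fixed-S intervals — were
  chosen as the smallest sizes at which the quantities of interest are
  statistically stable; all scale up via configuration.
- Degenerate inputs are contracts, not crashes: empty match sets give
  empty (typed) results, S = 0 gives `NA` D, a zero-variance predictor
  or an all-zero expected count is an error naming the cause.
- `fisher.test`, `lm`, `p.adjust`, vcfR, Biostrings, GenomicRanges,
  rtracklayer, ape and rjags provide the standard statistical and format
  machinery; the contribution-specific logic (calibration rule, merge
  and masking rules, panel rules, the coalescent sampler, the MK codon
  walk, the hierarchical selection model) is implemented in-package.

## Known limitations

- The matcher is gapless and k-mer anchored; highly diverged or
  indel-rich homology is under-detected by design (external PAF is the
  intended route for real data).
- π scaling uses total reference length, slightly deflating diversity
  when callable fraction is low.
- The mating-type caller assumes the provided idiomorphs are
  representative; distant idiomorph variants may fall below the
  translated k-mer threshold.
- Fixed-S null intervals are conditional on the observed S; they are
  not simultaneous bands over the genome.
- The selection model shares one random-effect scale per effect type
  across genes; strongly heteroskedastic gene families are shrunk
  accordingly.
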