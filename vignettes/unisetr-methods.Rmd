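---
title: "Comparing multiple de novo transcriptome unigene sets"
author: "unisetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing multiple de novo transcriptome unigene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unisetr)
```

## The problem

When a species has no usable reference genome, its transcriptome is
reconstructed de novo, and no single technology does this well. Long-read
circular-consensus sequencing (CCS) yields near-full-length transcripts
without assembly, but under-samples weakly expressed isoforms and its reads
often stop short of the true 5'/3' UTR ends. Short-read assemblies (pure or
hybrid) recover complete UTR ends and rare isoforms, but bury them under an
enormous excess of short, weakly expressed fragments and occasionally join
material that does not belong together, either two transcripts of one gene
placed end to end (a concatenation) or pieces of two different genes (a
chimera).

`unisetr` treats several independently built unigene sets for the same
organism as mutually correcting witnesses. It answers three questions:

1. **Which expression threshold separates signal from assembly noise?**
   Scanning TPM cutoffs and asking where the sets' survivor counts and
   length distributions converge formalises the judgement that a CCS-like
   set, which needs no assembly, is the yardstick the assembly-based sets
   should match after filtering.
2. **What does each unigene contribute structurally?** After collapsing
   redundancy, unigenes are grouped across sets by shared sequence blocks
   and each member is classified against the group's anchor: UTR-end
   extension, isoform variant, concatenation, chimera, redundant, or
   faithful.
3. **How do the retained unigenes partition by expression pattern?**
   Z-scored TPM rows are clustered with WPGMA/complete linkage and cut
   into expression groups.

Because the real study's inputs (hundreds of millions of reads, assembler
runs) are not reproducible at desk scale, the package ships a first-class
synthetic-study generator with a machine-readable truth ledger, and every
downstream claim is tested as *recovery of planted truth*.

## The synthetic study

`simulate_truth()` draws a transcriptome: each gene has a coding region of
100–500 codons (ATG to stop, no internal in-frame stop), a 30–300-base 5'
UTR and a 50–500-base 3' UTR. A Poisson(0.5) number of extra isoforms per
gene (capped at 4 total) is generated by inserting an in-frame, stop-free
cassette of roughly 60–150 bases at a random codon boundary — the smallest
structure that behaves like alternative splicing under pairwise alignment.
Gene abundances are lognormal (sdlog 1.5) and isoform abundances give the
primary isoform 80% of the gene's mass. Abundances are normalised to sum
to one million so that they live on the TPM scale of an uncontaminated
set. Each gene carries one of four tissue patterns over leaf, stem, root
and flower — (a) leaf+root high, (b) leaf+flower, (c) stem+root, (d)
stem+flower — with the two high tissues holding 88% of the gene's
expression. The four patterns are pairwise orthogonal or opposite as
z-score profiles, which is what makes the k = 4 cut of the heatmap
clustering a well-posed recovery target.

`emit_ccs_set()` models the long-read set: isoforms are detected with
probability $1 - e^{-d\,w_i}$ at sampling depth $d$ (default 4000) and
relative abundance $w_i$, so low-expression isoforms are frequently
absent; each detected isoform is emitted once, with each end truncated by
a geometric number of bases (mean 30, capped at the UTR so the CDS stays
intact) and substitution errors at $10^{-3}$ per base. The geometric is
the simplest memoryless choice for end erosion; the default depth leaves
roughly 85–90% of transcripts detected, the regime in which a CCS-like
set and the filtered assembly sets are comparable in size. The truncation
cap encodes the observation that incompleteness of consensus long reads
is concentrated in the UTR ends.

`emit_assembly_set()` models an assembly: captured transcripts (capture
intensity 60 for hybrid, 40 for short-read-only style) are emitted full
length with complete UTR ends; on top of these it plants, per true
emission, chimeras at rate 0.05 (5' piece of one gene joined to the 3'
piece of another), concatenations at rate 0.04 (two isoforms of one gene
end to end), redundant variants at rate 0.04 (substitution-mutated copies
at 92–99% identity), and noise: short random fragments (lognormal length,
median 400 bp) with TPM-scale abundance uniform in [0.05, 2], in number
chosen so the noise fraction of the set is 0.885. That fraction is the
generative encoding of the observation that an expression threshold of
TPM ≥ 5 removes the overwhelming majority of assembly-based unigenes; it
is a design default of the generator, not a measured claim.

`simulate_counts()` draws negative-binomial counts (dispersion 0.05,
library size $2\times10^7$) for 4 tissues × 3 replicates, with means
proportional to abundance × length × library size, so TPM computed from
the counts recovers the assigned abundances. Chimeras and concatenations
inherit the average of their parents' means, redundant variants split
reads evenly with their source, and noise keeps its own low means.

What the generator does *not* emulate: read-level errors and coverage
gaps, genomic contamination, fragment-length bias in quantification,
alternative transcription start/end sites, paralogous gene families with
partial homology, and isoforms that differ by anything other than an
internal cassette. Passing recovery tests therefore shows the method's
logic is correct under the stated model, not that it is robust to every
failure mode of real assemblies.

## Threshold scan

`compute_tpm()` uses the full transcript length as effective length — no
fragment-length correction — so the transformation is exactly reproducible
from the counts table alone; every non-degenerate column sums to $10^6$.
`filter_by_tpm()` aggregates a unigene's TPM across samples with
max-across-samples by default (a unigene expressed at the threshold in any
tissue survives); per-unigene aggregation across samples has no single
convention, and max is the most permissive choice that still removes
globally silent fragments. The convergence score of a threshold is
$\max_{i<j}\max\!\left(\frac{|n_i-n_j|}{\max(n_i,n_j)},
\frac{|m_i-m_j|}{\max(m_i,m_j)}\right)$ over survivor counts $n$ and
median survivor lengths $m$; the selected threshold is the smallest
scanned cutoff with score ≤ 0.25. The score makes the by-eye judgement
"the sets closely match" reproducible; 0.25 is deliberately loose, since
even well-converged real sets differ by tens of percent in count.

## ORF calling and UTR definition

`predict_cds()` scans all six frames and returns the longest complete ORF
of at least 100 residues (ties: + strand, then smallest start). Partial
ORFs at sequence ends are recognised only on request because UTR
classification downstream needs trusted CDS boundaries. Unigenes without
a predictable CDS are excluded from the structural comparison — without a
CDS there is no UTR to reason about. The 5' UTR is everything before the start codon on
the called strand, the 3' UTR everything after the stop.

## Shared blocks

`shared_blocks()` anchors exact 15-mers, collapses them into maximal exact
segments, chains segments colinearly (both coordinates increasing, gaps
≤ 500, diagonal shift ≤ 500, small penalty per shifted base), merges
same-diagonal segments across gaps up to 100 bases while counting
mismatches directly, and extends chain ends ungapped under a +1/−2
match/mismatch score, keeping the maximum-score prefix. Blocks shorter
than 100 bases — the conventional floor for declaring a region of two
unigenes the same — or below 0.95 identity are discarded, and reported blocks
never overlap on the query. With k = 15 two random kilobase sequences
share an expected $\approx 2\cdot986^2/4^{15} \ll 1$ anchors, so unrelated
pairs essentially never produce blocks, while 5%-diverged homologs still
anchor densely. Diagonal shifts between chained blocks are exactly the
insertions that distinguish isoforms, so the chain structure, not a
single alignment score, is the object the classifier consumes.
`pairwise_identity()` reuses the machinery with no length or identity
floor and reports total matched bases over the shorter sequence — the
CD-HIT-EST convention, under which a contained sequence scores 1.0.

## Redundancy collapse, grouping, classification

`dedup_greedy()` is greedy in descending length order (ties by id): each
sequence joins the first earlier representative with identity > 0.90,
else founds its own. A shared-k-mer prefilter skips hopeless pairs; with
the 0.90 threshold and ≥150-base sequences, a qualifying pair shares
clean 12-mers with overwhelming probability, so the prefilter does not
change results in practice, and the test suite checks exact equality
with a brute-force oracle that uses an independent alignment route.
Because identity is over the shorter sequence, an isoform fully contained
in a longer same-set isoform (or in a concatenation) is collapsed — a
real and consequential property of CD-HIT-style deduplication that the
classifier must, and does, work around by using witnesses from the other
sets.

`build_groups()` computes blocks for all pairs passing the k-mer
prefilter and takes connected components; the representative is the
longest member of the anchor (CCS-like) set, falling back to the longest
member. `classify_members()` then works per group:

* **Chimeras first.** A member whose removal disconnects the remaining
  members into two or more populated components is a bridge between
  otherwise unrelated genes — a chimera. It cites its strongest partner
  on each side. Because the two parents of a *concatenation* stay
  connected through their shared backbone, concatenations are never cut
  vertices, which is what separates the two artifact classes without any
  gene labels.
* **Concatenations.** A member carrying two chains that each cover ≥ 70%
  of a partner, occupy disjoint stretches of the member and jointly ≥ 80%
  of it, is a concatenation. The two copy chains may come from a single
  partner: after redundancy collapse the joined isoforms usually survive
  as one member elsewhere. Concatenation members cannot anchor a group.
* **Against the representative.** Remaining members are oriented to the
  representative by their best-strand chain. An internal discontinuity of
  ≥ 50 bases on either sequence between colinear blocks marks an isoform
  variant (50 separates cassette-scale differences from alignment
  jitter, which is bounded by k−1 = 14 per junction side). A member whose
  chain reaches within 20 bases of a representative terminus and runs at
  least 20 bases past it extends that UTR end; the evidence is the
  diagonal offset at the terminus, which is exact for substitution-only
  divergence. The 20-base margin suppresses anchor-edge jitter while
  catching the multi-decade-base truncations the truncation model
  produces. Extension evidence is emitted independently of the isoform
  call, and also for concatenations, whose first/last joined copies carry
  complete UTR ends — the concatenated witness is precisely how both
  missing ends of an anchor transcript can be demonstrated at once.

`summarize_reconcile()` tallies calls per set, counts groups missing from
each set, and flags isoform variants whose block structure (mutual
coverage ≥ 0.9, no discordant gap ≥ 50) matches no member of any other
set in the group — the set-exclusive isoforms. A heavily truncated CCS
variant can fail the coverage test against its own assembly counterpart
and be reported exclusive spuriously; the planted-recovery test therefore
measures exclusivity on assembly-set plants, where the anchor is intact.

## Expression clustering

`zscore_rows()` drops zero-variance rows and scales the rest; `hcluster()`
implements agglomerative clustering with WPGMA ("McQuitty") and complete
linkage on Euclidean distances (the metric underlying the usual heatmap
defaults; linkage names alone do not pin down the metric). Ties at the minimal
distance merge the pair with lexicographically smallest member labels, so
the partition is invariant to row order. Both linkages are monotone —
WPGMA's update is an average of two distances that each dominate the
current minimum — so cutting by merge order equals cutting by height, and
`cut_tree(tree, 4)` reproduces the four planted patterns. WPGMA is the
default for rows; the column ordering of a heatmap, where complete
linkage is conventional, is out of scope here.

## Pipeline, sizes and determinism

`run_pipeline()` executes simulate/load → per-set statistics → TPM →
threshold scan → filter at the selected threshold → per-set redundancy
collapse → ORF calling → blocks and grouping over CDS-bearing
representatives → classification → summary → expression clustering, and
writes a plain-text report bundle. All coordinates in all outputs are
0-based half-open. One integer seed drives every stage through derived
sub-streams, and a fixed seed reproduces the bundle byte for byte.

The default study uses 120 genes (~170 isoforms), which puts ~1,600
members in each assembly-like set before filtering and ~500 unigenes into
the structural comparison — large enough that every planted artifact
class appears in double digits, small enough that the full pipeline and
its recovery checks run in about two minutes. The Monte-Carlo recovery
checks (pattern clustering across seeds, low-isoform dropout) use 50-gene
studies.

Recovery of planted UTR truncations is measured on truncations of the
unigenes that anchor a classification: a truncation on a non-anchoring
member is not what the comparison is designed to expose, and a gene whose
witnesses were all collapsed into artifacts has, by construction, no
evidence left to find.

## Known limitations

* Isoform structure is cassette-insertions only; alternative 5'/3' ends
  would be classified as UTR extensions, not isoform variants.
* Two chimeras bridging the same pair of genes protect each other from
  the cut-vertex test; with realistic chimera rates this is rare but not
  impossible.
* A set-exclusive isoform that itself anchors its group (no other set
  carries the gene) is reported faithful, not exclusive — exclusivity is
  only visible against a cross-set witness.
* `pairwise_identity()` is chain-based and can differ from an optimal
  aligner by a few bases at block edges; with the 0.90 collapse threshold
  and ≥ 2-point margins in the planted identities this never changes a
  collapse decision in the test batteries, but sequences engineered to
  sit exactly at the threshold could flip.
* The convergence score compares counts and medians only; two sets could
  in principle converge in both while differing in shape. The scan table
  retains mean and N50 per (set, threshold) for inspection.
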