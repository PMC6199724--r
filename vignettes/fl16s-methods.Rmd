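---
title: "Profiling microbial communities from full-length 16S CCS reads"
author: "fl16s"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling microbial communities from full-length 16S CCS reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Short-read 16S rRNA surveys interrogate at most three of the nine
hypervariable regions (V1--V9), which usually limits taxonomic resolution
to family or genus and, because sequencing errors are large relative to
the number of informative sites, inflates the number of apparent taxa.
Circular consensus sequencing (CCS) of the full-length gene (~1.5 kb)
changes both constraints: each molecule is read many times ("passes") and
a per-molecule consensus is produced, so per-read accuracy rises steeply
with pass count, and the full V1--V9 span carries enough signal for
species-level work.

`fl16s` implements the complete desk-side analysis for such data: quality
and artifact filtering of CCS reads, de novo OTU clustering with chimera
removal, a species-level classifier with per-rank confidence values,
sub-OTU variant (ASV) detection by minimum entropy decomposition,
abundance and diversity statistics, and a read simulator that generates
mock communities with ground truth so every stage can be validated
end-to-end without external data.

## Pre-clustering filters

Reads flow through a fixed cascade, each stage tagging its casualties so
that every input read ends in exactly one terminal bin:

1. **Demultiplexing** (optional): terminal asymmetric barcode pairs,
   matched IUPAC-aware within a configurable mismatch budget on both
   orientations. A read matching more than one sample at equal distance
   is left unassigned rather than risking cross-sample bleed.
2. **Pass-count filter**: reads with fewer than 5 passes are removed;
   their consensus quality is far below the rest. Reads with no pass
   annotation fail too (fail-closed).
3. **Length filter**: 0.5--2 kb retained. The prominent artifact above
   the window is the ~3 kb head-to-tail amplicon dimer formed during
   library ligation.
4. **Host screen**: a deterministic canonical 21-mer containment index of
   the host/background genome; a read is host when at least half of its
   k-mers occur in the index. This is this package's realization of the
   usual "align against the host genome and discard hits" step: it is
   exact on verbatim host fragments, insensitive to the k-mer-poor
   divergence of true 16S reads, and has no external-aligner dependency.
   Both `k` and the fraction are configurable.
5. **Primer matching**: the forward primer and the reverse complement of
   the reverse primer must each occur exactly once, on the same strand,
   in the right order (defaults F27/R1492, degenerate bases honored, 2
   mismatches allowed per primer, indels not allowed in a hit). Reads
   whose reverse primer comes first are reverse complemented, then both
   primers are trimmed, leaving the read oriented 5'->3' with respect to
   transcription.

The cumulative expected error EE = sum(10^(-Q/10)) is deliberately *not*
part of this cascade. The EE gate (default EE <= 1, inclusive; the
comparator is exposed because the boundary is a convention) applies only
to the reads used for *clustering*; abundances are later counted over the
full filtered read set. This asymmetry is the reason the pipeline is
split into two phases.

## OTU clustering and chimera removal

Clustering follows the greedy abundance-sorted centroid scheme: reads are
dereplicated exactly (ties in size broken lexicographically so runs are
bit-reproducible), then processed from most to least abundant. Each
sequence joins the highest-identity existing centroid if that identity is
at least 97%; ties go to the earliest-created centroid. Otherwise it is
checked for being a chimera of existing centroids (CHIM1) and, if clean,
founds a new OTU. A second pass (CHIM2) applies the same test against a
curated reference set and removes flagged centroids before
classification.

Identity is computed from an end-free global alignment (match +1,
mismatch -2, gap open -4, gap extend -1, terminal gaps free) as
matches / (matches + mismatches + internal gap columns). Terminal gaps
are excluded because amplicons legitimately differ a little in length;
the scoring scheme is stated explicitly because tools differ and the
definition moves the 3% boundary. The aligner is a banded affine dynamic
program (C++); the band (default 50 columns plus the length difference)
is far wider than the indel drift of <= 3%-divergent amplicons, and
short sequences are aligned unbanded. For speed, candidate centroids are
ranked by shared 8-mer counts and only the top 16 are aligned per query;
with 16 or fewer centroids this is exactly "compare to every centroid",
and the tests that assert oracle equivalence run in that regime.

The chimera test is a two-parent crossover model: the candidate is
aligned to its top 8 most similar parents, per-column match vectors are
formed in candidate coordinates, and the breakpoint maximizing
left-parent plus right-parent matches is found for every ordered parent
pair. A candidate is chimeric when the two-parent model explains at least
99.5% of its columns *and* beats the best single parent by at least one
percentage point. The reference tools' internal scores are not published;
these two thresholds are our documented equivalents and are exposed as
arguments. Only single-crossover chimeras are modeled — the dominant PCR
mode; multi-breakpoint hybrids are out of scope.

Abundance quantification maps **all** primary-filtered reads (no EE
cutoff) to the final centroids at the same 97% rule; reads matching no
centroid are counted as unassigned, so mapped + unassigned partitions the
read set exactly.

## Taxonomic classification

The species-level database is a set of full-length sequences with 7-rank
lineages, serialized in the utax header dialect
(`;tax=d:...,p:...,...,s:...`). The classifier is an RDP-style bootstrap
word classifier presented through a per-rank-confidence interface: the
query's distinct 8-mers are collected (W of them), and each of 100
bootstrap rounds samples ceiling(W/8) k-mers with replacement and scores
every reference by shared sampled k-mers. The round's winner is the top
reference (ties to the lowest accession, for determinism); the name
assigned at each rank is the most frequent winner's name there, with
confidence equal to its frequency.

One mechanism matters for host and other off-target reads: a bootstrap
round only votes when its winner shares at least 1/8 of the sampled
k-mers; otherwise the round abstains. Without this, any query — even
random sequence — would receive domain confidence 1.0 against an
all-bacterial database, because some reference always scores highest.
With it, random host-like queries are reported at domain confidence well
below 0.1 while genuine 16S queries, even 10% divergent from their best
reference, vote normally (their k-mer survival rate is far above the
floor). The floor is an argument (`minHitFrac`).

Because distinctly named species are often indistinguishable at
full-length 16S resolution, the database itself is clustered into dbOTUs:
all-vs-all alignment distances (1 - identity), average-linkage
agglomeration, applying every merge with linkage distance <= 0.03
(boundary merges are applied; 3% separates clusters only when exceeded
— the boundary convention is stated because the alternative is equally
defensible). A centroid's species call can then be cross-referenced to
its dbOTU to list the "nearly best hits" that a low species confidence
typically signals.

## ASV detection by minimum entropy decomposition

Within an OTU (or any taxon bin), reads are projected into a common
coordinate frame. The default frame is centroid-anchored: each member is
globally aligned to the centroid, bases over centroid columns are kept,
deletions become gaps and insertions relative to the centroid are dropped
(with counts recorded). This is deterministic and linear-cost, and for
members within 3% of a centroid it discards very little; an externally
computed multiple alignment in the same rectangular shape is accepted as
a drop-in.

Decomposition is recursive: while a node's maximum per-column Shannon
entropy (nats, over {A, C, G, T, -}) exceeds 0.2, members are split by
their joint residues at up to 4 top-entropy columns. Afterwards, nodes
smaller than max(2, 0.1% of reads) are dissolved and their members
reassigned to the surviving node with the most similar representative
(fewest matrix-row differences) — the usual treatment of stray error
reads. The thresholds mirror the reference implementation of the method
and are exposed; every input read ends in exactly one final node, and
the per-node representative is the most abundant exact member sequence
(ties lexicographic).

Full-length frames separate haplotypes whose differences lie anywhere in
the gene; frames truncated to a short-read window (e.g. V3--V5) cannot
separate haplotypes whose differences fall outside it — the package's
tests demonstrate exactly this collapse.

## Abundance, detection and diversity statistics

Expected 16S relative abundances combine DNA mass fractions m, genome
sizes g and per-genome 16S copy numbers c as p_i proportional to
(m_i / g_i) c_i. Copy numbers come from an rrnDB-style table; a species
missing from the table walks up the lineage and takes the mean over all
species under the first matching rank. The probability that a taxon of
expected abundance p yields zero of n reads is the exact binomial mass
(1 - p)^n — not a Poisson approximation. Observed-versus-expected
agreement is summarized by ordinary least squares on the relative
abundance scale (the count scale is available via an argument, since the
choice is a convention).

Per-read error rates against a multi-copy reference (e.g. the seven
E. coli 16S operons) are estimated by aligning each read to every copy,
keeping the best, and reporting substitutions and gap columns separately,
stratified into EE <= 1 and EE > 1 — the comparison that shows what the
EE gate buys.

Diversity per sample: richness, Shannon entropy H = -sum q ln q and the
effective species number e^H (e^H <= richness, equality only for uniform
compositions). Count tables can be filtered with the conventional minima
(samples < 500 reads first, then OTUs < 50 reads overall, both
inclusive), converted to relative abundances, and log-transformed with a
1/(sample total) pseudocount. Core taxa are those present in at least
one sample of every subject.

## The simulator and what passing tests mean

`makeReferenceSet()` builds species references with conserved
primer-binding termini and internal V3/V5 anchor blocks, mutating only
the variable blocks, so primer matching and in-silico truncation work as
on real amplicons. Divergence plans are verified by alignment after
generation: designated pairs hit their target within 0.2 percentage
points (e.g. one pair at 1.4%, below the 3% OTU threshold — the classic
two-staphylococci situation), all other pairs at least 5% apart.

`simulateReads()` draws each read's species proportional to weight times
copy number, draws a pass count (5--25 by default, centered near 12),
scales the per-base substitution/insertion/deletion rates by 10/passes
(fewer passes, more errors), and writes a quality string whose Phred
value encodes exactly the planted per-base error probability. EE is
therefore consistent with the realized error count in expectation, which
makes the EE filter's behavior analytically predictable. Default rates
(2e-4 substitution, 5e-5 indel at 10 passes; EE around 0.5 per
full-length read) represent the high-quality CCS regime; tests that need
degraded data raise them explicitly. Chimeras join two parents at a
uniform breakpoint in the middle 80% (end-proximal crossovers are
indistinguishable from their parents and would poison sensitivity
metrics); host reads are verbatim host-genome substrings; dimers
concatenate two amplicons.

What the simulator does *not* model: miscalibrated quality strings
(real CCS qualities are optimistic — realized errors exceed EE),
per-pass subread structure, homopolymer-biased indels, position-dependent
error rates, and PCR abundance biases. Consequences worth stating
plainly: with calibrated qualities, an EE <= 1 gate keeps clustering
exact almost by construction, so the package demonstrates the *ordering*
of effects on real data (truncation inflates OTU counts at a matched EE
cutoff; full length stays at the true count) rather than their empirical
magnitudes, and error-driven OTU inflation is exercised at generous EE
cutoffs where the heavy low-pass tail supplies genuinely bad reads.

## Numerical and design choices

* Alignment scores (+1/-2, open -4, extend -1, free ends) are fixed
  package-wide; the upstream tools' internal parameters are unpublished,
  so ours are stated and tested against exhaustive enumeration on short
  sequences.
* All tie-breaks are deterministic and documented: dereplication size
  ties lexicographic; equal-identity centroid ties to the earliest
  centroid; classifier score ties to the lowest accession; dbOTU ids
  ordered by lowest member accession. Same inputs, same seed, same
  output bytes.
* Joining by best identity (not first-above-threshold) makes clustering
  order-robust; it can differ from heuristic-order implementations on
  contrived ties, which is why the straight-line oracle in the tests is
  the contract.
* Degenerate inputs: empty FASTQ yields an empty read set; an all-zero
  sample is an error for diversity but an empty *filtered table* is only
  flagged; a single database entry is its own dbOTU; MED on identical
  reads returns one node.
* Problem sizes in the tests (4,000-read mock community for the 19-OTU
  check, 1,200 reads for the truncation-inflation comparison, 3,000 for
  EE calibration) were chosen as the smallest sizes at which the
  binomial/Poisson noise terms are far from the asserted boundaries.

## Known limitations

Single-crossover chimera model; k-mer host screen requires the host
reference (it does not discover unknown contaminants); the classifier's
confidence is a bootstrap frequency, not a calibrated posterior; MED
here operates on a centroid-anchored frame, so insertions relative to
the centroid cannot define ASVs; tree building and monophyly scoring are
intentionally left to external tools, for which the node-representative
FASTA is the interface.
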