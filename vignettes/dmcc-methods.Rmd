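---
title: "Methods: in-silico DmCC haplotyping of the honey bee COI-COII region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico DmCC haplotyping of the honey bee COI-COII region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmcc)
```

## The biological problem

The mitochondrial region between the cytochrome *c* oxidase I and II genes of
*Apis mellifera* is non-coding and structurally variable: it contains the
tRNA-Leu gene followed by a combination of the repeat elements P0 (68 bp),
P (54 bp) and Q (in *x* tandem copies). The element combination is
lineage-diagnostic — African (A) colonies carry P0, West-Mediterranean (M)
colonies carry the shorter P, and North-Mediterranean (C) colonies carry only
Q — and the combination of structure, amplicon length and DraI restriction
fragment profile (the "DmCC test") identifies individual maternal haplotypes.
`dmcc` implements this test fully in silico, together with the population
summaries that normally accompany it: exact-identity sequence grouping,
haplotype and nucleotide diversity, Tajima's D, and minimum-spanning
haplotype networks.

Because real surveys hinge on manual sequence inspection, every stage here is
exercised against a synthetic amplicon generator with known planted truth;
the `analysis/` scripts run the pipeline end to end on a simulated 15-sample
survey patterned on a published study design (13 haplotypes among 15
samples, three carriers of an 18 bp P0 deletion, a 5-entry reference
catalog).

## Structure annotation

`annotate_structure()` performs greedy left-to-right semi-global matching of
canonical element strings against the amplicon:

1. the tRNA-Leu stub is located by a pattern-global/subject-local alignment;
2. the Q tandem run is seeded by the best downstream Q match and extended
   copy by copy in both directions — an adjacent copy is accepted when it
   aligns at identity at or above `min_identity` and starts within 5 bp of
   the current run boundary (tandem copies are adjacent by definition at
   this locus, so a larger gap terminates the run);
3. the span between the tRNA end and the first Q copy is classified as P0 or
   P by global alignment against both canonical strings, taking the higher
   identity and breaking exact ties toward the longer element (P0).

Identity is computed over aligned (non-gap) columns, so an element carrying
an internal deletion — the classic 18 bp P0 deletion of East-African
populations — still matches its canonical string at full identity and keeps
its lineage call (A). Deletions are then read off the alignment as maximal
gap runs, reported as (offset, length) in canonical-element coordinates.

All alignments use unit match/mismatch scores with an affine gap cost
(opening 5, extension 1). The opening penalty matters: with per-column gap
costs alone, an optimal alignment may split one biological deletion into
several smaller gaps interleaved with chance matches, and the reported
deletion offsets become meaningless. With the affine cost the planted 18 bp
event is recovered as a single block at its exact canonical offset in every
simulated case.

`min_identity` defaults to 0.80 per element. Surveyed amplicons diverge from
their references by about 1% or less, so 0.80 tolerates realistic divergence
with a wide margin while rejecting random sequence (random DNA aligns to an
unrelated element at roughly 0.6 identity under these scores). Coordinates
are 0-based half-open everywhere internally; only SNP report positions are
1-based, matching how substitutions are quoted in the field ("a SNP at
155 bp").

Lineage is a pure function of the elements found: A if P0 is present
(deletions included), M if P without P0, C if only Q. Sub-lineage labels
such as Z are catalog vocabulary, not structure-derived calls, and lineage O
is never called from structure because no structural rule distinguishes it.

## The in-silico DraI test

`digest()` scans for every (possibly overlapping) occurrence of the
recognition site — DraI's TTTAAA by default, cut bluntly after the third
base — and cuts once per occurrence. Fragment lengths always sum to the
amplicon length; this conservation is asserted on every call. The scanner is
written for general sites even though TTTAAA cannot overlap itself.

`assign_haplotype()` equates "known" with exact full-length identity
(case-insensitive) against a catalog entry, mirroring the field's convention
that a known haplotype is a 100% match to a published reference; anything
less is a novel haplotype reported with its nearest reference and identity
(matches over aligned columns of an end-free global alignment, normalised by
the longer sequence so truncated queries cannot reach 1.0). A reverse
complement is tried when the forward identity falls below 0.5, since
mixed-strand FASTA submissions are common.

Novel haplotypes are named `{lineage}{serial}-{length}-{fragments}-{country}`
(e.g. `A1-838-6-OMN`). Serial numbers restart per (lineage letter, country)
and follow first appearance in input order — the interpretation that
reproduces the per-country A1/A2/A3 progressions seen in published tables.
Whether the third field is exactly the DraI fragment count is an
interpretation of the same tables; it is computed from the digest here.
`classify_dataset()` guarantees that byte-identical samples share one name,
and that appending the novel assignments to the catalog and re-classifying
turns every sample into a known haplotype with its name unchanged.

## Diversity statistics

Haplotype diversity uses the unbiased estimator
$H = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$ over haplotype class
frequencies. For the canonical 15-sample design (two doubletons, eleven
singletons) this gives 0.98095…, printed as 0.980 after 3-decimal
truncation; the full precision is retained internally.

Nucleotide diversity is the mean over sequence pairs of per-site differences,
with pairwise deletion: a column where either member of the pair carries a
gap or ambiguity code is excluded from both the numerator and the
denominator of that pair, so indels never count as substitutions. Tajima's D
uses the standard constants $a_1 \dots e_2$ with
$D = (\hat\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$, where $\hat\pi$ is the
mean pairwise difference *count* computed over columns in which every
sequence is unambiguous (complete deletion). Two p-values are reported: a
two-sided normal approximation and the rescaled beta approximation over
$[D_{\min}, D_{\max}]$ from the statistic's original derivation. With no
segregating sites D is undefined and returned flagged with p = 1.

The test suite checks D against a second, independently written
implementation (built on `ape`'s distance and segregating-site machinery) to
1e-9 on random alignments, and checks calibration on 500 neutral-coalescent
simulations (n = 15, infinite sites, θ = 5 per locus): the replicate mean of
D must sit within three standard errors of zero and significant values must
be rare. The coalescent simulator (`simulate_neutral_alignment()`) exists
precisely for this check.

## Haplotype networks

`pairwise_changes()` counts substitution columns plus one change per
contiguous block of columns in which exactly one sequence is gapped — an
indel block is a single mutational event regardless of its length.
`build_network()` then builds a minimum spanning tree by Kruskal's algorithm
with fully deterministic tie-breaking (candidate edges sorted by weight,
then lexicographically by the sorted label pair), so the exported edge list
is byte-identical across runs and input orderings.

Secondary ("dotted") links — the equally parsimonious alternative
connections drawn in haplotype network figures — are defined here as
non-tree pairs whose direct distance equals the tree-path distance between
them: a direct edge costing exactly as many changes as the route through the
network is an equally parsimonious alternative. This is a design choice
where published figures give no algorithm; the classical MST cycle rule
(direct weight equals the maximum edge weight on the tree path, i.e. the
edge could swap into a co-optimal tree) is available via
`secondary_rule = "path-max"`, and `"none"` yields a plain MST. The central
haplotype is the node of minimum weighted eccentricity on the primary tree,
ties broken lexicographically.

## The synthetic data generator

`build_element_library()` derives all canonical strings pseudo-randomly from
a seed. They are internally consistent, not biological: P0 is 68 bp and P is
54 bp (the two diagnostic lengths), P is a suffix of P0 carrying six
substitutions so that P0-vs-P discrimination is non-trivial but
unambiguous, and DraI sites are planted at fixed offsets (two in the 5'
flank, one in P0 downstream of the deletion window, one per Q copy) and
scrubbed everywhere else, so a full P0Q2 amplicon digests into 6 fragments —
the modal fragment count of African P0Q2 surveys. Q's length is not fixed by
the locus literature consulted here; it is set to 196 bp so that the default
P0Q2 amplicon totals 838 bp, the modal length of the published envelope
(818–839 bp), with flank stubs of 193/120 bp and a 65 bp tRNA stub standing
in for the primer-captured gene ends whose exact extent is
publication-dependent.

`simulate_dataset()` builds each haplotype class as the canonical
concatenation for its structure label, plants a class-specific substitution
set (binomial per site at `snp_rate`, default 0.005 — about 4 substitutions
per amplicon, matching the ≤1% divergence seen between surveyed amplicons
and their references), optionally excises an 18 bp block from P0 at
canonical offset 20 (fixed for reproducibility; uniform placement is a
flag), and replicates classes according to a haplotype frequency spectrum.
Within-class noise defaults to zero so haplotype counts are exact; a
`within_class_snp_rate` knob exists for robustness experiments. Everything —
FASTA bytes included — is reproducible from the seed.

What the generator does *not* emulate: coalescent genealogy between classes
(class substitution sets are independent), sequencing error, heteroplasmy,
Q-copy sequence divergence within an amplicon, and real element sequences.
Passing tests therefore demonstrate that the pipeline's logic is correct on
data satisfying its structural assumptions, not that the annotator would
segment any real amplicon; real use requires a library of real canonical
element strings (`read_element_library()`), and `run_accession_reproduction()`
documents the expected layout for re-analysing user-downloaded GenBank
records.

## Problem sizes and numerical choices

The shipped checks use the study's own scales: 15-sample amplicon sets for
classification and diversity; 200 simulated amplicons across the six
structure labels (substitution rate 0.005, 30% of P0 classes carrying the
deletion) for structure recovery; 1,000 random sequences for digest/oracle
equivalence; 100 random alignments for the Tajima dual-implementation check
and 500 coalescent replicates for its calibration; and exhaustive
spanning-tree enumeration (Prüfer sequences) on networks of up to 7 nodes,
100 instances. These sizes keep each property at the scale the corresponding
claim is made while running comfortably on a laptop.

Degenerate inputs are handled explicitly: empty FASTA, duplicate
identifiers and non-IUPAC characters are errors with positions; a sequence
with no recognisable Q element is rejected as "not a recognizable COI-COII
intergenic amplicon"; monomorphic alignments yield H = 0 and an undefined,
flagged D; single-node networks have no edges.

## Known limitations

- The annotator assumes the element order tRNA → (P0|P) → Q…Q; rearranged or
  partially sequenced amplicons are out of scope.
- C-lineage Q-variant sub-labels beyond the copy count *x* are not modelled.
- Diversity statistics require a caller-supplied alignment for
  unequal-length sets; the package deliberately does not auto-align, and the
  analysis workflow restores alignment from the simulation truth instead.
- The secondary-link rule is an interpretation (documented above), not a
  published algorithm.
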