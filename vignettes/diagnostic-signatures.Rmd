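---
title: "Diagnostic nucleotide signatures and DNA-based taxon delimitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic nucleotide signatures and DNA-based taxon delimitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigtax)
```

## The problem

Environmental sequencing recovers large numbers of fungal lineages that have
never been formally described: monophyletic groups of rRNA-operon reads with
no cultured representative, no morphology, and no name. Describing such taxa
from DNA alone requires molecular characters that can stand in a formal
Diagnosis the way morphological characters traditionally do. `sigtax`
implements that workflow over an annotated multiple sequence alignment of
rRNA-operon long reads (SSU–ITS1–5.8S–ITS2–LSU):

1. **Diagnostic nucleotide signatures** — short degenerate motifs, typically
   20 bases, unique to a target taxon within a stated mismatch budget;
2. **Barcode-gap analysis** — per-region maximum intraspecific versus
   minimum interspecific p-distances;
3. **Reference coordinates** — signature positions expressed on the
   ungapped bases of the holotype-derived (legitype) sequence and/or an
   external reference sequence;
4. **Tree-side delimitation** — monophyly, least-inclusive-clade membership
   and bootstrap support (> 95, strict) for a tip set;
5. **Richness estimation** — single-linkage clustering of region distances
   at a threshold calibrated on the type species' intraspecific variation;
6. **Reporting** — rendering of formal Diagnosis paragraphs and tallies of
   newly proposed taxa per rank from a ledger table.

A synthetic-data generator with known truth underpins the test suite, since
real environmental reads are deposited in external archives and are not
required for validating any of the algorithms.

## The mismatch model

All sequence comparison is IUPAC-ambiguity aware. Each symbol expands to a
base set (`r` = \{a, g\}, `n` = \{a, c, g, t\}, ...); two symbols *match*
when their expansions intersect, so a degenerate consensus code never counts
against the taxon that generated it. The gap `-` has an empty expansion and
never matches anything.

For distances (the `p-distance`), sites where either sequence has a gap or
an `n` are dropped from numerator and denominator; the distance is the
fraction of remaining comparable sites whose symbols are incompatible. A
distance is reported as undefined when fewer than `min_overlap` (default 50)
comparable sites remain. Gap exclusion is the default because extreme
intraspecific values in ITS regions typically arise from length polymorphism
in homopolymers and microsatellite-like repeats, which indel-containing
comparisons would otherwise dominate; a `gap_handling = "difference"` policy
is available for analyses where length variation is itself the signal.

For signatures, the motif is the per-column union (degenerate consensus) of
the target members over a window that is gap-free in all target members —
signatures print as contiguous barcodes, so windows interrupted by a gap in
any target member are not considered. Against non-targets, a gap column
counts as a mismatch. The allowed-mismatch budget is derived as
$m = d_{\min} - 1$, where $d_{\min}$ is the minimum mismatch count over all
non-target sequences; a motif is a valid signature iff $d_{\min} \ge 1$,
equivalently iff its *margin* $d_{\min} - m \ge 1$. The derivation and the
validation are deliberately separate contracts: `verify_signature()` will
also validate an externally stated record whose published $m$ is more
conservative than $d_{\min} - 1$.

## Signature search

`find_signatures()` enumerates every gap-free target window of each length
in `[min_len, max_len]` (default 20/20; useful range roughly 8–33) within
each region in priority order — ITS2 first, because it combines high
divergence with dense read coverage and few homopolymers, then LSU, 5.8S,
SSU, ITS1. Windows are kept when the consensus carries at most
`max_ambiguous` degenerate symbols (default 2, matching the observation
that usable signatures carry 0–2) and $d_{\min} \ge 1$. Ranking is fully
specified so output is reproducible: $d_{\min}$ descending, ambiguity
ascending, region priority, leftmost start column, then length. There is no
randomness anywhere in the search.

Where a target is too heterogeneous for one low-ambiguity motif,
`find_disjunctive_signature()` searches OR-disjunctions: target members are
partitioned by complete-linkage clustering of window-restricted mismatch
distances into up to `max_alternatives` groups (default 3), one consensus
motif per group. The signature is valid when every non-target exceeds $m$
against **all** alternatives while every target member matches at least one
alternative within $m$. The search is greedy over windows in
region-priority/leftmost order with the smallest feasible group count;
identical alternatives are deduplicated, so a homogeneous target degenerates
cleanly to the single-motif case.

Two implementation notes. The scan is vectorised: sequences are encoded as
4-bit base masks, compatibility is a bitwise AND, and per-window mismatch
counts come from prefix sums, so the search is linear in alignment width per
non-target. The non-target universe defaults to every non-member in the
alignment; restricting the contrast to a sibling taxon set reproduces
scoped claims of the form "distinguishable from other members of X".

## Coordinates

Signature positions are communicated on reference sequences, not alignment
columns: region-local, 1-based on the reference's ungapped bases, with the
holotype-derived legitype as the reference for ITS and an external reference
(supplied as an ordinary alignment member flagged `role=reference`) for
SSU/5.8S/LSU. Positions upstream of a region start are negative and there is
**no zero**: a boundary-spanning 20-base window renders as "−2–18",
which is exactly 20 positions (−2, −1, 1, ..., 18). This no-zero
convention is inferred from that span arithmetic; an `include_zero` switch
is provided for conventions that do use a zero. The printed form uses
U+2212 for the minus and an en-dash for the range separator.

## Tree checks and richness

`least_inclusive_clade()` reports the leaf set under the MRCA of a query tip
set, monophyly (MRCA leaf set equals the query), and the MRCA's bootstrap
support; unrooted trees must be rooted by naming an outgroup tip, and
supports supplied on a 0–1 scale are rescaled to 0–100 on read.
`check_taxon_criteria()` applies the delimitation rule for proposing higher
taxa: monophyly **and** support strictly greater than 95 — a support of
exactly 95 fails.

`cluster_species()` performs single-linkage threshold clustering: clusters
are connected components of the graph joining pairs at distance ≤ threshold,
and richness is the component count. Single linkage was chosen (over
complete/average) as the standard OTU-style convention that is robust to
within-species chaining; the linkage is a deliberate design choice and the
distance matrix interface accepts any symmetric matrix if another convention
is wanted upstream. `estimate_richness(threshold = "auto")` calibrates the
threshold on the maximum intraspecific ITS2 distance of a designated type
species, the convention of transferring the type species' observed
variability to its relatives. Richness is non-increasing in the threshold.

## The synthetic generator

`simulate_taxon_set()` emulates the divergence structure that the analyses
assume, with every quantity controlled:

* **Species ancestors** are drawn by mutating a shared root (Jukes–Cantor
  style uniform substitutions) under rejection until every pair differs by
  at least `d_inter` plus an intraspecific allowance in *every* region.
  Defaults: `d_inter = 0.10`, in the range of reported ITS2 interspecific
  minima.
* **Reads** (3–6 per species by default) are mutated from their ancestor and
  accepted only within 0.4 × `d_intra_max` of it per region, so any read
  pair is within 0.8 × `d_intra_max` by the triangle inequality; the 20%
  headroom absorbs the denominator shrinkage caused by later gap noise, and
  the realized per-region maxima stay below `d_intra_max` (default 0.02,
  below typical reported ITS2 intraspecific maxima of ~0.038).
* **Ambiguity recoding** replaces a fraction (`ambiguity_rate = 0.005`) of
  read sites with a two-base degenerate code containing the original base —
  under the compatible-as-match rule this can only shrink distances, which
  is why the interspecific floor check allows a 10% tolerance.
* **Indels** appear as shared gap columns over a random species subset
  (`indel_rate = 0.002` per column). Insertions and deletions are not
  distinguished: in a fixed-width alignment an insertion restricted to some
  species *is* a deletion in the complement.
* **Repeat noise** plants homopolymer (≥ 6 nt) and dinucleotide-repeat (≥ 4
  unit) loci in ITS1/ITS2 and shortens them per read by 1–3 units, realized
  as gaps — mimicking the repeat-length polymorphism that inflates apparent
  intraspecific ITS variation.
* **Planted signatures** overwrite a window in all target reads with a known
  motif (after all noise, so targets carry it exactly) and force at least
  `k` mismatches in every non-target read.

The whole simulation is deterministic in a single integer seed through one
RNG stream. What the generator does **not** model: platform-specific
sequencing error profiles, chimeras, alignment error, rate heterogeneity
across lineages, or phylogenetic structure above the species level (species
ancestors are drawn independently, so higher-rank groupings in the synthetic
taxonomy carry labels but no tree signal — which is why the bundled analysis
checks monophyly at species level). Passing tests on synthetic data
therefore validate the algorithms' contracts, not the biological realism of
any particular dataset.

## Numerical and degenerate-input choices

* Distances are exact rational fractions of site counts; percent values are
  rounded to one decimal only at rendering.
* A single-member taxon has `max_intra = 0` with a `single_member` flag
  rather than an undefined value.
* `NA` distances (overlap below `min_overlap`) propagate: they are skipped
  in max/min summaries, join nothing in clustering, and raise an error when
  no comparable pair remains.
* Ties in signature ranking are broken deterministically (region priority,
  leftmost, shortest); ties in clustering are irrelevant because connected
  components are order-independent.
* The mismatch budget renders as number-words up to "three" (the observed
  maximum in published Diagnoses) and as digits with a warning beyond.
* Rejection sampling caps at 1000 attempts and then reports the divergence
  demand as infeasible; a demand beyond substitution saturation
  (`d_inter + d_intra_max > 0.75`) fails immediately.

## Problem sizes used in validation

The test suite validates each stage against an independent oracle at the
scale where exhaustive checking is feasible: signature search against brute
force on 200 random alignments of up to 12 sequences × 200 columns;
p-distances against a naive per-site loop on 10^4 random gapped pairs; the
column↔position bijection on 10^3 random gapped references; clade calls
against clade enumeration on 500 random 7-tip trees; and 100 seeded
replicates each for planted-signature recovery and richness recovery at the
generator defaults (six species, 3–6 reads each, full-length ~3.8 kb
operon). These sizes were chosen so that the oracles are exact and the whole
suite stays comfortably reproducible on a laptop.

## Known limitations

* Signature mining assumes the input alignment is correct; misalignment can
  both create and destroy apparent signatures. Upstream alignment and
  trimming are out of scope.
* The disjunctive search is greedy (first feasible window in deterministic
  order), not globally optimal across windows.
* Distances are raw proportions; no model correction (K2P etc.) is offered,
  matching the convention the Diagnoses use.
* Published per-taxon values can reflect either gap convention; both are
  implemented but the default (exclusion) is an interpretive choice.
* The species-richness estimate is a clustering count at one threshold; no
  extrapolation to unsampled species is attempted.
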