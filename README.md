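# sigtax — diagnostic nucleotide signatures and DNA-based taxon delimitation

`sigtax` is an R toolkit for describing taxa from DNA alone. It is aimed at
molecular systematists working with environmental rRNA-operon long reads
(SSU–ITS1–5.8S–ITS2–LSU) who need the quantitative ingredients of a formal,
sequence-based Diagnosis for lineages that have no cultures, no specimens
and no names:

* **Diagnostic nucleotide signatures** — short IUPAC-degenerate motifs,
  typically 20 nt, unique to a target taxon. For a candidate window the
  motif is the per-column consensus of the target members; with
  $d_{\min}$ the minimum mismatch count over all non-target sequences, the
  allowed-mismatch budget is $m = d_{\min} - 1$ and the signature is valid
  iff $d_{\min} \ge 1$. Two symbols match when their IUPAC expansions
  intersect; a gap never matches. OR-disjunctions of up to three
  alternative motifs handle heterogeneous targets.
* **Barcode-gap analysis** — per region, the maximum intraspecific
  p-distance $\max d_{\text{intra}}$ against the minimum interspecific
  p-distance $\min d_{\text{inter}}$; a barcode gap exists when
  $\min d_{\text{inter}} > \max d_{\text{intra}}$. p-distances are raw
  proportions of differing comparable sites (gap and `n` sites excluded
  pairwise).
* **Reference coordinates** — signature positions on the ungapped bases of
  the holotype-derived (legitype) sequence and/or an external reference,
  region-locally, with negative positions and no zero upstream of a region
  start (a boundary-spanning 20-mer reads "−2–18").
* **Tree-side delimitation** — monophyly, least-inclusive-clade membership
  and bootstrap support (strictly > 95) for any tip set on a
  support-annotated tree.
* **Richness estimation** — single-linkage clustering of region distances
  at a threshold calibrated on the type species' intraspecific maximum.
* **Reporting** — Diagnosis paragraphs in the conventional wording
  (round-trippable through a parser) and per-rank tallies of newly proposed
  taxa from a ledger table.

A seeded synthetic-data generator (`simulate_taxon_set()`) produces
alignments with known truth — controlled inter/intraspecific divergence,
ambiguity recoding, shared-gap indels, homopolymer/microsatellite length
noise, planted signatures — so every stage is validated without access to
archived environmental reads.

## Worked example

The `analysis/` directory is a five-step narrative pipeline; each script
prints what it found and writes tables under `results/`.

```sh
Rscript analysis/01_simulate.R     # synthetic dataset with known truth
Rscript analysis/02_distances.R    # barcode-gap report
Rscript analysis/03_signatures.R   # signature mining + verification
Rscript analysis/04_delimitation.R # tree checks + richness
Rscript analysis/05_diagnoses.R    # Diagnosis text + taxon tallies
```

Step 1 simulates 23 reads over 3810 columns for 6 species (interspecific
p-distance ≥ 0.10 per region, intraspecific ≤ 0.02) and plants a 20-base
signature for `Species_01` in ITS2. Step 2 then reports, for every species,
rows like:

```
     taxon region max_intra min_inter nearest_other barcode_gap
Species_01   ITS2   0.01365     0.167    Species_03        TRUE
Species_01    LSU   0.00858     0.192    Species_03        TRUE
```

— `max_intra` is the largest distance between two reads of the species,
`min_inter` the smallest distance to any read of a congener, so every
species shows a clean barcode gap here by construction. Step 3 recovers the
planted window as the top-ranked signature and verifies it (margin ≥ 1
against all non-targets); step 4 finds every species monophyletic with
bootstrap support 100 on a neighbour-joining read tree and recovers exactly
6 clusters at the auto-calibrated threshold; step 5 renders the Diagnosis:

```
Separation from other species of *Genus_01* based on ITS2 (positions
175–194 in type species tgctaaaccgagtacgaggt; 13 mismatches allowed).
Intraspecific variation up to 1.4% in ITS2 and up to 0.9% in LSU.
Interspecific distance at least 16.7% in ITS2 and at least 19.2% in LSU.
Forms a monophyletic, least inclusive clade in Genus_01, covering sequences
Species_01_r01, Species_01_r02, Species_01_r03, Species_01_r04, and
Species_01_r05.
```

Positions are legitype coordinates, not alignment columns; the unusually
generous budget of 13 mismatches reflects the planted motif's distance to
all non-targets. Step 5 also tallies the packaged ledger of newly proposed
taxa: 8 phyla, 27 classes, 31 orders, 31 families, 31 genera and 30
distinct highest-rank novel lineages (the class count exercises both
deduplication — one class spans two rows — and the exclusion of previously
described names).

## Layout

```
R/                  package code: IUPAC algebra, alignment model, simulator,
                    distances, signatures, coordinates, delimitation, reporting
analysis/           numbered narrative drivers (the worked pipeline)
inst/extdata/       packaged taxon ledger (plain TSV)
tests/testthat/     unit, property and acceptance tests with independent oracles
scripts/            acceptance script
vignettes/          methods vignette (model, assumptions, design choices)
```
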