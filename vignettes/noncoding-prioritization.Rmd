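---
title: "Prioritizing noncoding variants in trio genomes with a tissue regulome"
author: "trioregulome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing noncoding variants in trio genomes with a tissue regulome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioregulome)
```

## The model

Most clinically relevant noncoding variation is thought to act through
*cis*-regulatory elements: conserved sequences, marked by active-enhancer
chromatin, that contact their target genes within a topologically
associating domain (TAD). `trioregulome` operationalizes this as an
interval mask — the **regulome** — and treats membership in the mask as
the first, strongest filter on noncoding calls.

The mask is

$$R \;=\; \bigl(C(t) \,\cap\, T_{\mathrm{limb}} \,\cap\, P\bigr)\;\cup\; E,$$

with `C(t)` the maximal runs of per-base conservation score strictly
above `t`, `T_limb` the TADs overlapping a limb-gene body, `P` the
H3K27ac-like peak intervals, and `E` the validated enhancer elements.

Two structural readings of the three core conditions are conceivable —
intersection or union. The package intersects them. A union of
genome-wide conserved positions with whole TADs would cover a large
fraction of any genome; only the intersection produces the sub-percent
footprint that makes the mask a usable filter, and the enhancer set is
an explicit add-on (`include_vista`, optionally restricted by
`vista_tissue_filter`). A **site** is defined as one maximal merged
interval of `R`; because the core term is dominated by short conserved
runs clipped by peak boundaries, sites average a few base pairs, and
`site_count`, `bp_covered` and `genome_fraction` are reported together
by `regulome_stats()`.

Downstream, the SNV side applies, in fixed order: coding-context
classification, the rarity filter, regulome intersection, then the
trio-aware analyses (de novo, hemizygous X, cross-case proximity,
double hits, in-trans, LoF double-hit genes). The order matters only
for the reported funnel counts; each stage is a pure function that can
be invoked alone.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `phylop_threshold` | 1.3 | score | conservation cutoff; strictly greater-than |
| `rare_af_noncoding` | 0.001 | fraction | rarity for the regulome analysis (strict `<`) |
| `rare_af_reported` | 0.01 | fraction | looser rarity used for descriptive counts |
| `proximity_bp` | 300 | bp | cross-case pairing distance (strict `<`; inclusive mode by flag) |
| `trans_maf` | 0.03 | fraction | MAF ceiling for the in-trans noncoding partner (strict `<`) |
| `cadd_lof` | 20 | score | CADD above which a non-truncating call counts as probable LoF (strict `>`) |
| `pli_min` | 0.9 | fraction | LoF-intolerance floor for the double-hit gene screen (strict `>`) |
| `coding_flank_bp` | 10 | bp | exon flank within which a variant is coding-proximal |
| `min_size_bp` | 1500 | bp | SV size floor (`>=` passes; BND exempt) |
| `min_support` / `escalated_support` | 2 / 5 | reads | SV read support, escalated when > `escalation_trigger` (30) SVs pass |

Two rarity thresholds coexist deliberately: the stringent one drives
the regulome filtering itself, while the looser one reproduces the kind
of descriptive cohort count usually quoted against gnomAD. Both are
plain config fields; nothing in the code privileges one number.

Every inequality above is strict or non-strict exactly as listed, and
the boundary behaviour is pinned by tests (a score of exactly 1.3 is
out; an AF of exactly 0.001 is out; a 1499 bp deletion is out and a
1500 bp one is in; 30 passing SVs do not escalate, 31 do).

## Coordinates

Internally every interval is a `GRanges` in the Bioconductor 1-based
closed convention. BED and bedGraph files are converted on read/write
by `rtracklayer`, and VCF positions are used natively, so no coordinate
arithmetic appears in user code. Printed-style 1-based inclusive
breakpoints are accepted directly by `sv_length(..., "one_based_inclusive")`;
`end − start + 1` is the length under that convention, and the 105 kb
worked example in the README follows from its printed endpoints.
Indel positions are the leftmost reference base; an indel is inside the
mask if any affected reference base overlaps it.

## What the synthetic-data module emulates

`make_genome()` draws a toy genome of (by default) three 2 Mb
chromosomes, the last named `chrX`; abutting TADs of 150–350 kb; genes
of 5–30 kb with one to three exons, 35 % limb-flagged, a subset of
those flagged with a recessive limb phenotype; a piecewise-constant
conservation track with geometric segment lengths (mean 40 bp, 12 %
of segments conserved) so that conserved *runs* of realistic width
exist rather than i.i.d. per-base noise; H3K27ac-like peaks at 25 per
Mb; and a dozen enhancer elements with tissue labels. pLI is drawn from
a symmetric bimodal beta, mirroring the U-shape of real catalogs, and
the generator guarantees at least one limb gene, one recessive-limb
gene and one pLI > 0.9 gene whenever the counts allow, so the planted
event classes are always constructible.

`make_cohort()` plants, per event class, the configuration the
analysis is designed to recover — de novo SNVs inside and outside the
mask, cross-case pairs at a controlled distance (250 bp by default) and
pairs sharing one enhancer at 500 bp, identical rare calls in two
cases, an in-trans coding/noncoding pair with opposite parental
origins, a LoF double-hit gene, hemizygous-X candidates, an SV slate
spanning every cascade outcome, and polyalanine alleles at +8 and +1
codons — and writes an exhaustive truth ledger. Background variants
(6000 over 12 trios by default) get AFs from a singleton-plus-beta
mixture so both rare and common strata exist, and genotypes that are
always inheritance-consistent.

Three generator properties make the ledger *exhaustive* rather than
merely a lower bound, which is what turns recall/precision checks into
exact set comparisons:

* a global spacing registry keeps any two variants (of different
  plants, or background) at least 400 bp apart, so no accidental
  cross-case pair can arise below the 300 bp rule;
* enhancer bodies are excluded from background and generic plant
  placement, so the only co-located-in-one-enhancer pairs are the
  planted ones;
* TADs used by in-trans plants are blocked for everything else, and
  X-chromosome background is assigned only to female-index trios, so
  the trans and hemizygous screens cannot pick up bystanders.

What the generator does **not** emulate: linkage disequilibrium,
mutation-rate heterogeneity, sequencing/genotyping error, caller
artifacts, multi-allelic sites, or realistic gene/TAD size
distributions. Passing tests therefore demonstrate that the *logic* of
every filter is exact on data satisfying its stated assumptions — not
that the pipeline's yield on real genomes would match any published
cohort. The headline numbers of a real cohort additionally depend on
proprietary annotation tracks and patient genomes that cannot be
shipped, which is why validation here is property-based.

## Numerical and degenerate-input choices

* Missing allele frequency is treated as rare (an allele never observed
  in a population database), and missing parental genotypes make a call
  *unevaluable* for de novo status — excluded and counted, never
  silently dropped. Unphaseable in-trans pairs go to a separate
  `phase_unknown` list for the same reason.
* Phase for the trans screen is inferred from parental transmission
  only (allele present in exactly one parent); statistical phasing is
  out of scope, and "unrelated cases" means distinct case identifiers.
* `proximity_pairs()` maps the strict `< 300 bp` rule onto
  `findOverlaps(maxgap = proximity_bp - 2)` for single-base positions
  (gap `g` pairs positions with `|Δpos| ≤ g + 1`); the inclusive mode
  uses `maxgap = proximity_bp - 1`. The all-pairs brute-force scan in
  the test suite is the independent check of this arithmetic.
* Pairs are reported once, in canonical member order (by position,
  then case id), so input order never changes the output.
* A TAD boundary is the junction point between two abutting TADs; an
  SV disrupts it if that point lies strictly inside the SV span or if
  the two breakpoints fall in different TADs. Deletions/duplications
  change dosage; inversions and breakends are flagged copy-number
  neutral.
* BND records have no defined length: exempt from the SV size filter,
  and `sv_length()` refuses them.
* The ACMG combiner resolves a simultaneous pathogenic-side and
  benign-side rule match to *Uncertain significance* (the guideline
  default for contradictory evidence), and `PVS1` alone does not
  classify. The test suite checks the combiner against an independently
  coded flat rule table on every criteria subset of size up to four.
* The polyalanine measure anchors the tract by one exact flanking
  match (ambiguous or absent anchors are errors, fuzzy matching is
  deliberately omitted), reads codons in the anchored frame, and stops
  at the first non-alanine codon; synonymous mixtures of
  GCA/GCC/GCG/GCT are equivalent by construction. It measures an
  assembled allele sequence — read-level repeat genotyping is out of
  scope, and the reference tract length is a required input rather
  than a built-in constant.
* De novo calling uses genotypes only; a minimum genotype-quality hook
  (`min_gq`) exists but defaults to off, since quality modeling is a
  property of the upstream caller, not of this filter.

## Problem sizes

The default simulation — 12 trios, ~6000 background variants over a
6 Mb genome — keeps a full end-to-end run in the tens of seconds while
leaving every analysis with a non-trivial search space (a run's rare
noncoding set is ~1100 calls, the scale at which the all-pairs oracle
is still exact and fast). The exhaustive per-base membership check runs
on a 100 kb genome, where every position of every chromosome is
evaluated against the raw defining condition.

## Known limitations

* The regulome is only as good as its input tracks; with synthetic
  tracks the mask is a geometry, not biology.
* The pipeline starts from variant calls. Alignment, SNV/SV calling,
  caller quality models and manual curation are upstream and out of
  scope (a per-record `poor_quality` flag is honoured, nothing more).
* The in-trans screen requires transmission-resolvable phase; both-
  parent-heterozygous configurations end up phase-unknown by design.
* No attempt is made to model neo-TAD formation or enhancer rewiring
  beyond the boundary-disruption flag; mechanistic 3D-genome modeling
  is a different problem.
* ACMG criteria are combined, not assigned: deriving PS/PM/PP codes
  from evidence is expert work the package does not automate.
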