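---
title: "The expanded ZFN design grammar: model, conventions, and readouts"
author: "zfndesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The expanded ZFN design grammar: model, conventions, and readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfndesign)
```

## The problem

Zinc-finger nucleases (ZFNs) cleave DNA as dimers: two designed zinc-finger
proteins (ZFPs) bind half-sites flanking a short spacer gap, and the FokI
cleavage domains fused to them dimerize over the gap and cut. Each finger
reads roughly one DNA triplet, and practical ZFPs are assembled by modular
assembly from archives of pre-characterized one- and two-finger modules.
Therapeutic applications often need the double-strand break placed within a
window of a few base pairs, so the design question is not "can we cut this
gene" but "can we center a cut on *this* base step" — the boundary between
two adjacent bases, which is the unit at which cleavage centering is scored
throughout this package.

Under the classical, canonical architecture the two half-sites must lie on
opposite strands converging on the gap, with no gaps between adjacent
fingers' triplets. That leaves exactly one dimer configuration per cleavage
position and archive, and for many base steps no assemblable design at all.
The grammar implemented here relaxes both constraints:

* **Architectures.** FokI may be fused at the carboxy (C) or amino (N)
  terminus of each ZFP. An amino-terminal fusion reverses which strand the
  ZFP must bind, yielding four dimer architectures: CC (canonical), NC and
  CN (both half-sites on the same strand; top for NC, bottom for CN), and
  NN (the strand-inverse of canonical). NC and CN are structurally the same
  protein pair, but at a fixed locus they impose different sequence
  requirements, so the grammar counts them as distinct configurations.
* **Base skipping.** Specialized inter-finger linkers enforce skipping
  exactly one unread base between the triplets of otherwise-adjacent
  fingers. Skips are allowed at two junctions per array (J2-3 and J4-5 of a
  six-finger ZFP; J2-3 and J3-4 of a five-finger ZFP), giving
  `2^2 = 4` skip plans per ZFP. The skipped base is unconstrained: it
  matches any base.

The multiplicity accounting is `configuration_multiplicity()`: with all
four architectures and skips on both sides of the dimer, the number of
configurations per cleavage site is `4 x 4 x 4 = 64` times the canonical
no-skip baseline — 4-fold from architectures alone and a further 16-fold
from skip plans across the dimer.

```{r}
configuration_multiplicity(zfn_architectures(), 6, skips_enabled = TRUE)
```

## Coordinate and orientation conventions

All coordinates are 0-based and half-open. Because a finger array runs
antiparallel to its target, the carboxy-terminal finger binds the 5'-most
triplet; archive triplets are therefore stored 5'→3' in *target-site*
orientation, and module lists in scanner output read 5'→3' along the site.
Five-finger arrays default to the composition one-finger + two-finger +
two-finger in site order (the single finger carboxy-terminal); this is
configurable via `composition`, and a skip falling *inside* a two-finger
module (junction J3-4 of that composition) is only taken by modules flagged
`skip_capable_internal`, since inter-module linkers are where skipping
linkers were demonstrated.

The cleavage center of a gap `[b, c)` is `(b + c)/2`. Even gaps give an
integer base step; odd gaps give a half-integer, assigned deterministically
to `floor(center)` so that every dimer maps to exactly one base step — a
requirement for unambiguous density accounting. A window of length L is
scored at L base steps (one per base position), matching the 28-position
accounting of a 28-bp window.

## Gap sets

Allowed spacer lengths are architecture-specific (`default_gap_sets()`,
all configurable):

* NC/CN: 6-7 bp — 6 bp is about the minimal spacing that lets the cleavage
  domains dimerize with an amino-terminal linker.
* NN: 7-9 bp by default, the range with a high hit rate and high activity;
  widenable to 5-9 bp, the full range explored.
* CC: 5-6 bp. No authoritative canonical gap set exists in the source
  material for this grammar; 5-6 bp is the conventional spacing of the
  standard carboxy-terminal linker era and is the package's own default,
  deliberately configurable because design practice varies.

## Scanning and pairing

`find_zfp_sites()` reports every (position, strand, skip plan, module
triple) whose concatenated triplets match the sequence, with one
unconstrained base at each skipped junction. Matching is IUPAC-aware on
both sides via 4-bit masks (two codes are compatible iff their base sets
intersect), so degenerate archive triplets from other design platforms are
supported. `pair_dimers()` then joins sites whose strands, intervals and
skip plans realize an allowed configuration; designs identical in layout
and module choice are reported once, while the same layout with different
modules counts as a distinct design (it is a distinct protein pair).
Overlapping half-sites are impossible by construction since all gap sets
are positive. Output order is fixed (base step, architecture, left start,
design id) and independent of input order.

The built-in GNN archive (`build_gnn_archive()`) is the reconstructible
reference set: 16 one-finger modules (one per GNN triplet) and all
`16^2 = 256` ordered two-finger combinations.

## Targeting density

`targeting_density()` reduces a design table to the fraction of base steps
in a region covered by at least one design's cleavage center. The test bed
inverts this: `plant_design()` writes strand-correct matchable sequence for
a chosen configuration into a genome, and `scan_planted_steps()` plants one
design per base step of a window — each into a fresh copy of the genome —
scans each copy, and pools the recovered designs. Planting is done per step
rather than cumulatively into one genome because a dimer's footprint spans
roughly 42 bp around its center: designs planted at consecutive base steps
of a single 28-bp window would overwrite each other's half-sites. The
per-step construction mirrors how a real tiling experiment proceeds (one
pair designed and assayed per base step) and makes density 1.0 achievable
and exactly checkable.

## Amplicon indel quantification

`call_alleles()` aligns each read to the amplicon reference with
`Biostrings::pairwiseAlignment` (global in the read, free reference ends),
scored match +1, mismatch −1, affine gaps with a 1-bp gap costing 8 and 1
per additional base. The aligner's tie-breaking between equivalent gap
placements is unspecified, so every indel operation is post-normalized by a
left shift (the VCF convention) before keying; allele identity is the
left-normalized edit description, which makes treated/control comparisons
exact. A read is an indel allele iff it carries an insertion or deletion
overlapping the cut window — by default ±20 bp around the annotated
cleavage center, standard amplicon practice to exclude distal PCR and
sequencing artifacts; substitutions never count as indels. Reads shorter
than half the reference are discarded into a QC tally.

`background_correct()` implements treated-vs-control correction: indel
alleles whose edit key also occurs in the untreated control are
reclassified as non-indels. Totals are unchanged, the indel fraction can
only decrease, and the operation is idempotent. `indel_significance()`
uses a two-sided Fisher exact test on the (indel × arm) 2×2 table with a
Bonferroni correction `min(1, p × n_tests)` over the loci tested; a locus
is called significant only when the adjusted p falls below 0.05 *and* the
treated indel fraction exceeds the control's. Fisher's exact test is the
package's stated choice where the upstream statistic is not otherwise
pinned down.

## Off-target candidate calling

The duplex-capture pipeline consumes *mapped* integration events (BED-like
tables: chromosome, position, strand, equally-best-hit count, replicate,
arm) — adapter trimming and genome alignment belong to standard external
tools. Per replicate:

1. `dedupe_events()` keeps one event per (chromosome, position, strand,
   replicate, arm); opposite strands are distinct integrations.
2. `cluster_events()` single-links unique events within 100 bp along each
   chromosome; the result is a partition, invariant under input order.
3. `apply_filters()` flags each cluster: at least fivefold more unique
   integrations than the same locus in control (control events matched
   within the cluster interval padded by the clustering window; a control
   count of zero passes, since any positive count is ≥ 5×0; the comparison
   is ≥, so treated = 5 × control passes exactly); every member read
   mapping equally well to fewer than three loci; chromosome on a
   configurable known-region whitelist (the "known region" notion is not
   algorithmically defined, so a primary-assembly chromosome list is the
   operationalization); and at least 10 kb from the intended target.
4. `replicate_consensus()` merges per-replicate candidates by ≥ 1 bp
   interval overlap and keeps loci supported in at least two replicates
   (the full design is quadruplicate), summing capture events and ranking
   them in descending order, the on-target locus first when captured.

The consensus rule is applied after the filter cascade, and replicate
matching of control events is used when the control arm carries the same
replicate labels; both choices are configurable because the upstream
description fixes neither.

## What the simulators emulate — and what they do not

* `random_genome()` draws i.i.d. bases at a target GC; real genomes have
  repeats, homopolymers and composition structure that make both spurious
  ZFP matches and ambiguous alignments more common than in the test bed.
* `simulate_amplicon_reads()` draws alleles multinomially and applies
  substitution errors only (default 0.1% per base, a MiSeq-like rate).
  Indel sequencing errors are deliberately excluded so the planted allele
  counts are the exact truth for the caller; consequently the suite
  demonstrates estimator exactness, not robustness to indel-rich error
  profiles, PCR chimeras or quality-dependent errors.
* `simulate_capture_events()` plants Poisson event counts per locus and
  replicate with uniform positions; real capture libraries carry mapping
  noise, duplicated breakpoints and chromatin-dependent capture bias.

Every generator is a deterministic function of (parameters, seed) and
restores the caller's RNG state.

## Problem sizes and numerical choices

The test suite verifies the scanner and pairing against brute-force
enumeration on 200 random sequences of up to 200 bp with small random
archives; indel recovery on 60 simulations of 10^4 reads (planted fractions
0.05/0.30/0.85, recovery judged at 3 binomial standard errors with the
band's own nominal exceedance allowance, plus exact agreement with the
realized planted counts); Fisher p-values against direct hypergeometric
enumeration for all 2×2 tables with totals ≤ 50 (evaluated per
row/column/transpose symmetry class after verifying the enumeration is
constant within each class); and the off-target cascade on quadruplicate
simulations with planted true loci and shared-with-control, multimapping
and near-target decoys. These sizes were chosen to make the checks exact or
statistically sharp while keeping the suite quick to run.

## Known limitations

* Activity is not modeled: the scanner enumerates *assemblable* designs;
  which of them cut efficiently in cells is a wet-lab question.
* Binding affinity/specificity scores per finger, and context dependence
  between adjacent fingers, are out of scope; archives carry triplets only.
* The indel caller consumes merged single-end reads; paired-end merging,
  UMI handling and HDR quantification are not implemented.
* The off-target caller starts from mapped events; it cannot compensate
  for upstream mapping errors beyond the equally-best-hit filter.
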