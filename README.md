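# zfndesign

Zinc-finger nucleases (ZFNs) cut DNA as dimers: two designed zinc-finger
proteins (ZFPs), each assembled from pre-characterized one- and two-finger
modules and fused to the FokI cleavage domain, bind half-sites flanking a
short spacer gap where FokI dimerizes and cleaves. Therapeutic editing often
requires centering the cut on a specific **base step** (the boundary between
two adjacent bases), and under the canonical architecture — both FokI domains
carboxy-terminal, half-sites on opposite strands, no gaps between adjacent
fingers' triplets — many base steps simply have no assemblable design.

`zfndesign` implements an expanded design grammar and its readouts, for
people who design ZFNs or analyze ZFN editing experiments:

* **Architecture grammar** — four dimer architectures from the two FokI
  attachment points (CC, NC, CN, NN; amino-terminal attachment flips the
  required strand) combined with single-base skipping between adjacent
  fingers at two junctions per array. Per cleavage site this multiplies the
  available configurations by

  `|architectures| x (skip plans per ZFN)^2 = 4 x 4 x 4 = 64`

  over the canonical no-skip baseline (4-fold from architectures, 16-fold
  from skips across the dimer).
* **Site scanning** — find every ZFP binding site assemblable from a module
  archive (IUPAC-aware, both strands, all skip plans), pair sites into dimer
  designs under architecture-specific gap sets, and score per-base-step
  targeting density of a region. A built-in GNN archive (16 one-finger +
  256 two-finger modules) makes everything runnable out of the box.
* **Indel quantification** — align amplicon reads (affine gaps,
  left-normalized indel keys), classify indel alleles within a cut window,
  apply treated-vs-control background correction, and test significance
  with Fisher's exact test plus Bonferroni correction.
* **Off-target candidate calling** — cluster mapped duplex-capture
  integration events (single linkage, 100 bp), then apply the filter
  cascade: >= 5-fold over the same locus in control, reads mapping equally
  well to < 3 loci, known-region whitelist, >= 10 kb from the intended
  target, and consensus across >= 2 of 4 replicates.
* **Simulators** — deterministic generators for genomes with planted
  designs, amplicon reads with planted indel spectra, and capture-event
  tables with planted off-targets; they are the test bed for every module.

See `vignettes/zfn-design-grammar.Rmd` for the model, conventions
(0-based half-open coordinates, 5'→3' target-site triplet orientation,
cleavage-center assignment) and design decisions.

## Worked example

Plant an NN dimer (8-bp gap) into a random 160-bp genome, recover it by
scanning, and profile a window:

```r
library(zfndesign)
gnn    <- build_gnn_archive()
cfg    <- dimer_configuration("NN", 8)
genome <- random_genome(160, 0.5, seed = 12)
planted <- plant_design(genome, center = 80, cfg, gnn, seed = 1)
res <- scan_designs(planted$genome, gnn, cfg)
res$designs[, c("base_step", "arch", "gap_bp", "left_start", "left_end",
                "left_strand", "right_start", "right_end", "right_strand")]
#>   base_step arch gap_bp left_start left_end left_strand right_start right_end right_strand
#> 1        80   NN      8         58       76           +          84       102            -
targeting_density(res$designs, c(70, 90))
#> density_profile over [70,90): 1/20 base steps covered, density 0.05
```

The design's cleavage center sits exactly on the planted base step 80: the
gap `[76, 84)` lies between an 18-bp half-site on the top strand (left,
amino-terminal FokI) and one on the bottom strand (right) — the
strand-inverse of a canonical dimer. One design in a 20-step window gives
density 1/20.

Quantify editing from simulated amplicon reads (30% planted 4-bp deletion,
0.1% per-base error, 5000 reads):

```r
ref <- amplicon_ref("demo", random_genome(120, 0.5, 7), cut_site = 60)
sim <- simulate_amplicon_reads(ref, list(list(type = "del", at = 58, len = 4,
                                              fraction = 0.30)),
                               n_reads = 5000, error_rate = 0.001, seed = 2)
at <- call_alleles(sim$reads, ref)
at
#> allele_table 'demo': 4 alleles, 5000 reads (0 discarded), %indels 29.4
head(at$alleles, 3)
#>   allele count is_indel frequency
#> 1     WT  3530    FALSE    0.7060
#> 2 D@58:4  1468     TRUE    0.2936
#> 3 D@59:4     1     TRUE    0.0002
```

`%indels` (29.4) matches the realized multinomial draw of the planted 30%
fraction exactly; the allele key `D@58:4` is the left-normalized 4-bp
deletion at 0-based position 58.

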