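Package: zfndesign
Title: Zinc-Finger Nuclease Design Grammar, Targeting Density, and
    Editing Readouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing zinc-finger nucleases (ZFNs) by modular
    assembly under an expanded dimer-architecture grammar: canonical and
    amino-terminal FokI attachment points (CC/NC/CN/NN dimers) combined
    with single-base skipping between adjacent fingers. Provides archives
    of one- and two-finger modules (including a built-in GNN archive),
    genome scanning for assemblable binding sites, dimer pairing and
    per-base-step targeting-density profiles, amplicon deep-sequencing
    indel quantification with treated-vs-control background correction
    and exact-test significance, and candidate off-target calling from
    duplex-capture integration events via a filter cascade with
    replicate consensus. Ships deterministic simulators for genomes with
    planted targets, amplicon read sets with planted indel spectra, and
    capture-event tables, which form the test bed for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
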