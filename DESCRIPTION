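Package: CPcompare
Title: Comparative Structural Analysis of Heterodimeric Capping Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the comparative structural analysis of homologous
    heterodimeric actin capping-protein (CP) structures: correspondence-based
    least-squares (Kabsch) C-alpha superposition with explicit fit/report
    residue selections, per-region r.m.s.d. and B-factor flexibility
    statistics, detection of disordered (unmodeled) segments, crystal packing
    calculations (unit-cell volume, Matthews coefficient, solvent content),
    and pairwise sequence-identity matrices with gap-aware denominators plus
    per-column conservation (sequence-logo data) over large multiple sequence
    alignments. A synthetic-data module generates structure pairs related by
    known rigid transforms with region-localized perturbations, painted
    B-factor profiles, disorder masks, star-evolved alignments and crystal
    fixtures with full ground truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Proteomics, Alignment, Software
RoxygenNote: 7.3.3
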