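Package: its2cbc
Title: ITS-2 Barcode Species Delimitation and V4 Haplotype Networks for
    Coccoid Green Algae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular species delimitation for unicellular green algae
    from ribosomal marker sequences. Translates conserved base pairs of
    ITS-2 secondary structures into an eight-state number-code barcode,
    detects compensatory base changes (CBCs) and hemi-CBCs between
    strains, and delimits species by combining barcode evidence with
    lineage support from distance trees with bootstrap. Annotates the
    hypervariable V4 region of the SSU rRNA against an E23 helix
    template, detects clade-diagnostic characters (non-homoplasious
    synapomorphies, CBCs, hemi-CBCs), builds statistical-parsimony
    haplotype networks with habitat and geography annotation, and
    assigns environmental query sequences by identity and coverage
    thresholds. Includes a synthetic-data generator that plants known
    barcode differences, diagnostic characters, and haplotype graphs so
    every pipeline stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    phangorn,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
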