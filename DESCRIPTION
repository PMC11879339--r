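Package: seepecol
Title: Community Assembly, Relative Activity and Diversity Analysis for
    Paired DNA/RNA Metabarcoding of Cold-Seep Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the community-ecology inference chain used on paired
    DNA/RNA (cDNA) metabarcoding ASV tables from cold-seep and reference
    sediments: alpha, beta and gamma diversity with ASV accumulation curves
    and ANOSIM; abundance-weighted beta mean nearest taxon distance (bMNTD)
    with a tip-shuffle null model and the beta nearest taxon index (bNTI)
    for ecological process classification; a phylogenetic-signal
    (Mantel correlogram) prerequisite check; Levins' niche breadth;
    per-ASV relative activity (RNA:DNA ratio) with phantom-taxon handling;
    and seep-active group identification. Includes a synthetic metacommunity
    generator with phylogenetically conserved niches, selection versus
    neutral assembly, and planted RNA activity structure, so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    picante,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
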