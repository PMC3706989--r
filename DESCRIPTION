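Package: introgmap
Title: Introgression Mapping for Backcross Conversion Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrospective mapping of donor introgressions in backcross
    conversion lines genotyped with sparse, high-missingness SNP data
    (for example genotyping-by-sequencing). Implements trio-based
    introgression calling between a donor consensus, converted lines and
    their exotic progenitors; unexpected-genotype quality control;
    distance-weighted imputation of introgression scores; genome-wide
    introgression-frequency and Hudson Fst scans; a subpopulation
    permutation test for differential introgression; and linkage
    disequilibrium based anchoring of SNPs on unplaced contigs. A
    meiosis simulator of the backcross conversion scheme generates
    synthetic donor/progenitor/converted trios with known ground truth
    so every stage of the pipeline can be validated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
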