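Package: sexlinkr
Title: Sex-Linked Marker Discovery from Reduced-Representation Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers sex-linked SNP and presence-absence markers in species
    with homomorphic sex chromosomes from DArTseq/RADseq-style genotype
    matrices. Provides sex-stratified genotype-proportion filters for XX-XY
    and ZZ-ZW systems, Cochran-Armitage trend tests of sex-by-genotype
    association, Hamming-distance concordance analysis with majority-vote
    genotypic-sex calling for sex-reversal surveys, a closed-form model of
    chance sex-linkage for sample-size planning, and a sex-chromosome
    genotype simulator with recombination leakage, sex reversal and missing
    data for power and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
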