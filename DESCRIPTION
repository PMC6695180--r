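Package: strpopkit
Title: Forensic STR Population Statistics, Equilibrium Testing and
    Inter-Population Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for autosomal short-tandem-repeat (STR)
    population studies in forensic genetics. Computes per-locus allele
    frequencies and the standard forensic efficiency panel (observed and
    expected heterozygosity, polymorphism information content, random match
    probability, power of discrimination, power of exclusion, typical
    paternity index, combined match probability), runs Monte-Carlo exact
    tests of Hardy-Weinberg equilibrium and permutation tests of linkage
    disequilibrium with Bonferroni correction, and compares populations from
    allele-frequency tables via pairwise FST, Nei genetic distances,
    neighbor-joining trees and nonmetric multidimensional scaling. Includes
    a synthetic genotype generator (Hardy-Weinberg with inbreeding, and
    Balding-Nichols multi-population structure) with microvariant,
    off-ladder and tri-allelic anomaly injection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
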