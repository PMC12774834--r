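Package: arborelate
Title: Genetic Relatedness on Ancestral Recombination Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified toolkit for genetic relatedness computed from
    ancestral recombination graphs (ARGs) encoded as succinct tree
    sequences. Provides dense branch, genotype, divergence, shared-area,
    eGRM and pedigree relatedness matrices; a matrix-free branch
    GRM-vector product with operation-count instrumentation; randomized
    principal component analysis of the branch GRM via the matrix-free
    product; pedigree kinship by tabular recursion with a Monte Carlo
    gene-dropping oracle; and the simulators (coalescent with
    recombination, random pedigrees, chromosomal gene dropping,
    recapitation, infinite-sites mutation dropping) needed to validate
    the identities connecting these notions of relatedness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
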