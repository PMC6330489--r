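Package: goleaf
Title: Most Specific Shared Gene Ontology Terms for Gene Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds the Gene Ontology (GO) terms shared by at least a
    threshold number of genes from one gene list ("within" mode) or two
    gene lists ("between" mode), prunes every shared term that has a more
    specific shared descendant, and ranks the surviving most-specific
    terms by a negative-log specificity score based on background
    annotation counts, score(t) = -log2(2 / g(t)).  Ingests the ontology
    from an OBO 1.2/1.4 flat file and annotations from GAF 2.x, with
    evidence-code filtering, NOT-qualifier handling, and true-path-rule
    propagation of annotations to ancestor terms.  Includes a seeded
    synthetic fixture generator (OBO + GAF + gene lists with planted
    ground truth) and an independent brute-force oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    optparse,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
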