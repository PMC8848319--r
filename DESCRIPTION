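Package: netepi
Title: Network-Guided Epistasis Detection at the Gene Level
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-step protocol for detecting statistical epistasis along
    the edges of a gene-gene co-function network. Candidate SNP pairs are
    enumerated from gene-pair ("gene model") hypotheses via many-to-many
    SNP-to-gene mappings (positional, eQTL, chromatin), tested with a linear
    interaction regression on covariate-adjusted phenotypes, thresholded at a
    permutation-derived family-wise error rate, and aggregated to gene-pair
    significance with the adaptive truncated product method. Includes
    polygenic-score-conditioned re-testing of significant pairs, a
    shortest-path neighborhood pathway enrichment stage, PLINK 1 binary
    input/output, and a self-contained synthetic-data generator with LD-block
    genotypes and planted interaction effects for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
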