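Package: proteowidth
Title: Proteoform Diversity and Aging-Gene Ortholog Overlap from
    Swiss-Prot Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the proteome width (the number of distinct
    proteoforms a genome can encode) of a species from its reviewed
    UniProtKB/Swiss-Prot annotations. Parses Swiss-Prot flat-file (DAT)
    records, counts per-gene alternative-splicing isoforms,
    single-amino-acid polymorphisms and post-translational modification
    sites, derives the 13-parameter proteome vector and evaluates three
    nested information models of proteoform formation. Also computes
    genome annotation coverage (reviewed genes versus Ensembl gene
    predictions) and the orthogroup-overlap statistic between a human
    aging-gene list and model-organism proteomes, with a reciprocal
    best-hit orthogroup inferrer for self-contained analyses. Includes
    seeded generators of synthetic Swiss-Prot records and ortholog
    families with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
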