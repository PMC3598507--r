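Package: evorate
Title: Evolutionary-Rate Screening of Antibacterial Drug Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counting-based estimation of per-gene evolutionary rate from
    codon alignments of closely related bacterial strains (pN/pS polymorphism
    statistics and Nei-Gojobori dN/dS with Jukes-Cantor correction), three-way
    comparison of drug-target, essential and background gene sets with
    Mann-Whitney U tests under Benjamini-Yekutieli false-discovery-rate
    control, genome-wide percentile ranking and orthology-group summaries,
    and hypergeometric Gene Ontology over-representation of the slowest
    evolving genes. Includes a ground-truthed codon-evolution simulator so
    the whole pipeline is testable end to end without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
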