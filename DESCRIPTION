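Package: methnet
Title: Promoter Methylation and Gene Regulatory Network Rewiring Across Tumor Stages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative analysis linking promoter DNA-methylation change to
    gene-regulatory-network rewiring across tumor stages. Assigns methylation
    array probes to target genes by promoter location and confirmed negative
    methylation-expression correlation, classifies the methylation landscape,
    identifies differentially methylated probes with trimmed rank-sum tests,
    scans promoter windows against a motif library with exact discretized
    log-odds p-values, infers motif-restricted regulatory networks per
    phenotype with guided tree ensembles, and ranks regulation gain or loss
    between tumor and normal networks under a methylation-consistency filter.
    Includes a synthetic multi-phenotype cohort generator with planted ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
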