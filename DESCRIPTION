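Package: txevents
Title: Alternative Promoter, Internal Exon and 3' End Events from Transcript
    Annotations, with Transcript Usage QTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies reference transcript annotations (Ensembl-dialect GTF)
    into independent alternative promoter, internal exon and 3' end events
    built on a scaffold of exons shared between transcripts. Truncated
    transcripts (cds_start_NF/cds_end_NF tags or truncation-marking biotypes)
    are first repaired by copying exons from the longest GENCODE-basic
    transcript of the gene. Event-level abundance estimates are converted to
    relative usage phenotypes, and usage QTLs are mapped with a permutation
    pass with group-best correction and Benjamini-Hochberg FDR. Response
    (condition-specific) QTLs are classified with a linear mixed model
    interaction test and a random-effects variance decomposition, and
    colocalisation results can be filtered with standard posterior-probability
    rules. Simulators for gene structures, usage QTLs and multi-condition
    phenotypes support fully synthetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
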