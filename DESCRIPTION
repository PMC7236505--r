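Package: isofit
Title: Functional Iso-Transcriptomics Analysis of Isoform-Resolved Annotations
Version: 0.1.0
Authors@R:
    person("isofit", "developers", email = "isofit@example.org", role = c("aut", "cre"))
Description: Isoform-level functional analysis of two-group transcriptome
    experiments. Given a gff3-like isoform-resolved functional annotation, a
    transcript-by-sample count matrix and a two-condition design, isofit
    computes functional diversity of genes and features (presence and
    positional variation, alternative polyadenylation, UTR and CDS structural
    variation), differential gene expression, differential isoform and CDS
    usage with total usage change and major-isoform switching, differential
    feature inclusion (FI, delta-FI, favored condition, co-inclusion),
    differential polyadenylation (DPAU) from a clustered polyA-site library,
    expression-weighted UTR lengthening analysis (UTRw), and Fisher-based
    functional enrichment. Count models use negative-binomial log-linear
    likelihood-ratio tests of unit-by-condition interactions; a synthetic-data
    generator with planted effects supports end-to-end statistical validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
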