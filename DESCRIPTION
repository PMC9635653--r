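Package: polynac
Title: Curation of the NAC Transcription-Factor Family in a Polyploid Genome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico workflow for curating the NAC (NAM/ATAF1-2/CUC2)
    transcription-factor family in hexaploid wheat and related genomes:
    profile-based NAM-domain identification, alignment completeness QC,
    tree-based subfamily classification, systematic homoeolog-aware gene
    nomenclature, pathogen-responsiveness classification from differential
    expression tables, baseline-expression binning, enrichment statistics,
    and protein-motif specificity and subdomain analysis. A synthetic-data
    generator produces hexaploid-style gene families with planted ground
    truth so every stage of the pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
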