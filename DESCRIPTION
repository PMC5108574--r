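Package: kirhap
Title: KIR Gene-Content Haplotyping and HLA Ligand Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Deconvolves killer-cell immunoglobulin-like receptor (KIR)
    gene copy numbers into centromeric/telomeric gene-content haplotypes,
    classifies HLA class I alleles into KIR ligand groups (Bw4, C1, C2),
    scores activating and inhibitory HLA:KIR engagements, and performs
    case-control and family-based association statistics (exact 2x2 tests,
    Woolf confidence intervals, binomial transmission disequilibrium test,
    and non-transmitted-allele AFBAC comparisons). Includes a synthetic
    trio-cohort generator so the full analysis runs without restricted
    subject data, plus drivers that reproduce the derivable statistics of
    a published autism family study from its printed count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
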