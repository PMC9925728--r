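Package: antioxscan
Title: Comparative Genomic Annotation of H2O2-Targeting Antioxidant Enzyme Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation pipeline for the three major hydrogen-peroxide-scavenging
    antioxidant enzyme families in animal proteomes - monofunctional catalase
    (CAT), peroxiredoxin (PRX) and glutathione peroxidase (GPX) - plus the
    sulfiredoxin (SRX) reductant. Candidates are nominated from Pfam domain
    architectures parsed out of HMMER3 per-domain tables, filtered on
    catalytic-site motifs (the peroxidatic-cysteine motif PXXX[TS]XXC, the
    sulfiredoxin binding motif F[SG]GCHR, the phospholipase A2 triad and
    GXSXG, the hyperoxidation-sensitivity motifs GGLG and YF), typed for
    selenocysteine- versus cysteine-dependent catalysis, classified into
    subfamilies by active-site profiles and by placement inside labelled
    reference clades of neighbor-joining trees, and summarised as a
    per-species gene census. A seeded synthetic-proteome generator with a
    truth ledger makes every stage testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
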