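Package: ecpdx
Title: Genomic Characterization of Endometrial Cancer PDX Models
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Burden metrics (tumor mutation burden, microsatellite
    instability score, copy-number alteration burden), 96-channel
    mutational-signature refitting with minimum-contribution and
    dominance rules, homologous-recombination-deficiency genomic-scar
    scoring (NtAI, LST, HRD-LOH), four-way molecular subtype
    classification (POLE, MMRd, CN-high, CN-low), lineage heterogeneity
    and clonality analysis across patient-derived xenograft panels, and
    in vivo treatment-response quantification. Includes a synthetic
    cohort generator emulating the four molecular subtypes and
    multi-lineage xenograft panels so every stage is testable without
    access to controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
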