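Package: hmesmap
Title: Homozygosity-Enrichment Mapping of Causative Mutations from Bulk
    Segregant Sequencing on Fragmented Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fine-maps causative mutations from bulked segregant sequencing
    experiments against unordered, contig-sized genome fragments. Per-site
    allele evidence from samtools mpileup text or VCF is turned into
    zygosity-classified variants, background and parental homozygous calls
    are subtracted, and each fragment receives a homozygosity-enrichment
    score HMES = (alpha + rho) / (beta + rho), the ratio of its homozygous
    to heterozygous variant counts with a small ratio adjustment.
    Fragments are arranged centre-out by score and candidate variants in
    the top score percentile are reported with flanking sequence for
    marker design. A simulation framework provides log-normal genome
    fragmentation and a gamete-level generator of backcross and outcross
    F2 bulks for a recessive allele, so the whole pipeline is testable
    from synthetic data alone.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
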