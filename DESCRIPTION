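Package: landracepopgen
Title: Population Genomics of Crop Landrace Range Expansion
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for population-genomic analysis of crop landrace panels
    genotyped on SNP arrays: genotype filtering and ancestral-allele
    polarization, LD pruning, per-population expected heterozygosity and
    inbreeding, pairwise Hudson F_ST with block-jackknife standard errors
    and Slatkin linearization, isolation-by-distance tests against
    geographic and environmental distance, EHH/iHS selection scans for
    doubled-haploid haplotype panels, redundancy-analysis variance
    partitioning of genotypes against climate, geography and neutral
    structure, and GERP-based genetic load accounting. Includes a
    serial-founder range-expansion simulator that emits the same file
    formats the pipeline reads, together with a truth table for
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
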