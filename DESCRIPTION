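Package: rrqtl
Title: QTL Mapping, Variance Components and Fine-Mapping for Round-Robin
    Multiparental Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical genetics for panels of haploid recombinant progeny
    from a round-robin cross of inbred parents. Provides a synthetic-data
    generator emulating a population panel with a realistic site-frequency
    spectrum, round-robin cross designs and Poisson-crossover meiosis;
    permutation-calibrated forward stepwise QTL mapping with the ForwardStop
    false-discovery stopping rule; restricted maximum likelihood (REML)
    variance-component models with Gower-centered kinship and Hadamard
    epistasis kernels, including allele-frequency-partitioned heritability;
    joint cross-panel QTL mapping with leave-one-chromosome-out polygenic
    residualization and pooled t statistics; simulation-based (PICS-style)
    fine-mapping of QTL to genes with gene-level FDR; and derived-allele and
    rare/common frequency analyses of QTL effects.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
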