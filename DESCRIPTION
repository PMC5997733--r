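Package: clonescape
Title: Clonal Evolution Analysis of Drug-Resistant Cancer Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reconstructs the subclonal architecture of drug-resistant cancer
    cell populations from paired parental/resistant variant tables. Provides
    somatic mutation catalogues by parental subtraction, depth-ratio gene copy
    number from exome target regions, cellular-prevalence estimation and 1-D
    density clustering into subclonal populations, recursive subset-containment
    clone-tree reconstruction with Newick export, droplet digital PCR
    quantification with Poisson-based 95% confidence intervals and
    mixed-population detection for single-cell dilution clones, and small
    preclinical computations (tumour volume, randomisation validity, TOP/FOP
    reporter ratio). A synthetic-data module generates ground-truth clonal
    structures, read counts, depth profiles and droplet counts so that every
    inference stage can be validated end to end without external sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    ape,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
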