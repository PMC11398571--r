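Package: rbapower
Title: Power Evaluation of Relief-Based Feature Selection for Epistasis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates case-control SNP datasets with known genetic
    architectures (clean k-way XOR epistasis, noisy penetrance-table
    interaction models with target heritability, heterogeneous subgroups,
    and main/additive effects), scores features with from-scratch
    implementations of ReliefF, MultiSURF and MultiSURF* plus a
    mutual-information baseline and a random-shuffle negative control,
    ranks feature scores under standard and absolute-value schemes, and
    evaluates detection power with the weakest-link statistic and
    per-rank-position power curves assembled into heatmap matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
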