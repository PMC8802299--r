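Package: buddorm
Title: Thermal Time, Phenology and Candidate-Gene Expression Analysis of
    Apple Bud Dormancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing winter bud dormancy in temperate fruit
    trees from hourly ambient temperature, forcing-assay phenology and
    high-throughput qPCR expression data. Implements chilling-hour,
    dynamic-model chill-portion and ASYMCUR growing-degree-hour
    accumulation; estimation of the endodormancy-to-ecodormancy
    transition date and of cultivar chilling and heat requirements from
    scion forcing assays; quality filtering, reference-gene stability
    ranking and 2^-ddCt relative quantification of qPCR cycle-threshold
    tables; best-of-n k-means clustering of expression trajectories; and
    Pearson correlation of expression with windowed temperature
    covariates. A coupled synthetic-data generator emulating a
    cool-temperate winter with two cultivars sampled weekly makes every
    stage of the pipeline testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
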