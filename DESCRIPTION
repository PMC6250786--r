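Package: rilTRD
Title: Forward Simulation and Transmission Ratio Distortion Analysis of
    Recombinant Inbred Lines
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Forward-in-time simulation of advanced-intercross (AI-RIL) and
    F2 recombinant inbred line breeding designs in a selfing hermaphrodite
    species with X0 males and maternally inherited mitochondria, including a
    single-obligate-crossover meiosis model and configurable mito-nuclear
    incompatibility (viability) selection.  Companion statistics detect
    transmission ratio distortion in genotyped hybrid lines: allele-fraction
    estimates against design-specific null expectations (0.5 for autosomes,
    1/3 paternal and 2/3 maternal for the X), Pearson chi-square tests with
    Bonferroni correction, drift fixation probabilities, linkage
    disequilibrium (D, D', r-squared) including mitotype-nuclear pairs, and
    reciprocal-cross asymmetry tests.  Includes a synthetic genotype-table
    generator for null and distorted fixtures, plain-text genotype table and
    marker panel input/output, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
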