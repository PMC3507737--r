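Package: chemopop
Title: Population Genetics and Phylogenetics of a Plant Chemotype
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing natural variation in a secondary-metabolite
    chemotype across plant populations, developed around the diterpenoid
    oridonin in Isodon. Covers parsimony mapping of a binary chemotype on a
    phylogeny with soft-polytomy step counts, consistency/retention indices
    and a character-reshuffle null test; parent-offspring regression
    estimates of narrow-sense heritability; microsatellite summary
    statistics, Hardy-Weinberg tests with Dunn-Sidak correction and a
    parent/offspring pooling check; Smouse-Peakall genotypic distances,
    principal coordinate analysis and Mantel tests of isolation by distance;
    mixed-mating-system EM estimation of outcrossing rates from maternal
    progeny arrays; a Bayesian admixture Gibbs sampler with DIC-based choice
    of the number of clusters and greedy label alignment across runs; and
    LC/MS standard-curve quantification of compound yield as percent dry
    weight. A seeded synthetic-data generator reproduces the study design
    (nine populations, eleven loci, maternal families) so the full pipeline
    runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    phangorn,
    vegan,
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
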