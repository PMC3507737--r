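#!/usr/bin/env Rscript
# Generate one synthetic dataset with the study's design and write it to
# results/data/ in the package's file dialects: nine populations of 10-15
# genotyped parents at 11 microsatellite loci on a geographic transect,
# maternal progeny arrays (6 offspring/family, outcrossing rate 0.9), an
# oridonin yield trait (within-population h2 = 0.76 plus a population-level
# yield gradient), a 60-tip phylogeny carrying a presence/absence chemotype,
# and LC/MS standards + peak areas for every sampled plant.

library(chemopop)

seed <- 20260921L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
parents <- simulate_island_populations(cfg)
families <- simulate_progeny_arrays(parents, t_true = cfg$t_true,
                                    offspring_per_family =
                                      cfg$offspring_per_family,
                                    seed = seed + 1L)
traits <- simulate_parent_offspring_trait(
  families, h2_true = cfg$h2_true, env_sd = cfg$env_sd,
  trait_mean = cfg$trait_mean, pop_effect_sd = cfg$trait_pop_sd,
  seed = seed + 2L)

tree <- ape::rcoal(60)
tree$tip.label <- sprintf("taxon%02d", 1:60)
chemotype <- simulate_binary_character_on_tree(tree, 0.3, 0.3,
                                               seed = seed + 3L)
lcms <- simulate_lcms(traits, seed = seed + 4L)

write_genotype_table(families, "results/data/genotypes.csv")
write_trait_table(traits, "results/data/traits.csv")
write_newick(tree, "results/data/tree.nwk")
write.csv(data.frame(taxon = names(chemotype),
                     state = as.integer(chemotype)),
          "results/data/chemotype.csv", row.names = FALSE)
write.csv(lcms$standards, "results/data/lcms_standards.csv",
          row.names = FALSE)
write.csv(lcms$areas, "results/data/lcms_areas.csv", row.names = FALSE)

cat(sprintf(
  "simulated %d parents + %d offspring in %d populations; %d tree tips (%d chemotype changes); %d LC/MS samples\n",
  sum(families$generation == "parent"),
  sum(families$generation == "offspring"),
  length(unique(families$population)), length(tree$tip.label),
  attr(chemotype, "true_changes"), nrow(lcms$areas)))
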