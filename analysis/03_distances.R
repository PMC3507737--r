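#!/usr/bin/env Rscript
# Individual-level Smouse-Peakall genotypic distances among parents,
# principal coordinate analysis, and Mantel tests of isolation by distance
# (genetic vs Euclidean and log-Euclidean geographic distance) and of the
# genetic-chemical association (genetic vs absolute oridonin difference).

library(chemopop)

seed <- 303L
gt <- load_genotype_table("results/data/genotypes.csv")
traits <- load_trait_table("results/data/traits.csv")

parents <- subset_genotypes(gt, gt$generation == "parent")
dgen <- genotypic_distance(parents)
write_distance_matrix(dgen, "results/genotypic_distance.csv")

pc <- pcoa(dgen)
write.csv(data.frame(sample = rownames(pc$coordinates),
                     population = parents$population,
                     pc$coordinates[, 1:2]),
          "results/pcoa_coordinates.csv", row.names = FALSE)
cat(sprintf("PCoA: axes 1-2 carry %.1f%% and %.1f%% of the variation\n",
            pc$percent[1], pc$percent[2]))

dgeo <- scalar_distance_matrix(cbind(parents$lon, parents$lat),
                               labels = parents$samples)
dgeo_log <- scalar_distance_matrix(cbind(parents$lon, parents$lat),
                                   transform = "log",
                                   labels = parents$samples)
val <- setNames(traits$oridonin_pct, traits$sample)[parents$samples]
dchem <- scalar_distance_matrix(val, labels = parents$samples)

tests <- list(
  geographic = mantel_test(dgen, dgeo, 999, seed = seed),
  log_geographic = mantel_test(dgen, dgeo_log, 999, seed = seed + 1L),
  chemical_parents = mantel_test(dgen, dchem, 999, seed = seed + 2L))
tab <- do.call(rbind, Map(function(m, nm)
  data.frame(comparison = nm, n = m$n_samples, r = m$r, p = m$p),
  tests, names(tests)))
write.csv(tab, "results/mantel.csv", row.names = FALSE)
for (i in seq_len(nrow(tab)))
  cat(sprintf("Mantel %-18s N = %d, r_xy = %.3f, p = %.3g\n",
              tab$comparison[i], tab$n[i], tab$r[i], tab$p[i]))
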