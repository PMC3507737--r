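#!/usr/bin/env Rscript
# Narrow-sense heritability of oridonin yield from the regression of mean
# offspring value on the maternal parent's value (h2 = 2b), over all
# populations and within a restricted population subset, mirroring the
# study's all-species vs single-species contrast.

library(chemopop)

gt <- load_genotype_table("results/data/genotypes.csv")
traits <- load_trait_table("results/data/traits.csv")

pairs_all <- family_means(traits, gt)
fit_all <- suppressWarnings(parent_offspring_regression(pairs_all))
print(fit_all)

# high-yield end of the transect only: within-group heritability, without
# the between-population divergence that inflates the pooled estimate
subset_pops <- sort(unique(gt$population))[6:9]
pairs_sub <- family_means(traits, gt, populations = subset_pops)
fit_sub <- suppressWarnings(parent_offspring_regression(pairs_sub))
cat(sprintf(
  "subset (%s): n = %d, b = %.3f (SE %.3f), p = %.3g, h2 = %.3f\n",
  paste(subset_pops, collapse = ","), fit_sub$n_families, fit_sub$slope,
  fit_sub$se, fit_sub$p, fit_sub$h2))

write.csv(rbind(
  data.frame(scope = "all", n = fit_all$n_families, slope = fit_all$slope,
             se = fit_all$se, t = fit_all$t, p = fit_all$p,
             h2 = fit_all$h2),
  data.frame(scope = "subset", n = fit_sub$n_families,
             slope = fit_sub$slope, se = fit_sub$se, t = fit_sub$t,
             p = fit_sub$p, h2 = fit_sub$h2)),
  "results/heritability.csv", row.names = FALSE)
write.csv(pairs_all, "results/family_means.csv", row.names = FALSE)
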