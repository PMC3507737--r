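# chemopop

Population genetics and phylogenetics of a plant chemotype, built around
the question of where to source a valuable secondary metabolite: the
anti-cancer diterpenoid **oridonin** from *Isodon* (Lamiaceae). Given
wild-collected parents, greenhouse-grown maternal progeny arrays,
codominant microsatellite genotypes, a phylogeny carrying a
presence/absence chemotype, and LC/MS assays of compound yield, the
package answers, with tested code for every step:

* **Is production evolutionarily labile or conserved?** Parsimony steps of
  the binary chemotype on a tree (hard polytomies via unit-cost Sankoff;
  *soft* polytomies as the exact minimum Fitch length over all binary
  resolutions, computed by a closed-form node recursion), consistency and
  retention indices `CI = m/s`, `RI = (g − s)/(g − m)`, and a
  character-reshuffle null: permute the observed states among the tips
  1000 times and report `p = (1 + #{s_null ≤ s_obs})/(n + 1)` for the
  "fewer steps than random" (phylogenetic inertia) alternative.
* **Is yield heritable?** One-parent regression of mean offspring yield on
  the maternal value; `h² = 2b` (Falconer), with a two-sided t-test on
  `n − 2` df.
* **How is genetic variation structured?** Per-locus/per-population `N_A`,
  `H_O`, `H_E = 1 − Σp²`, `F = 1 − H_O/H_E`; chi-square HWE tests
  (`df = k(k−1)/2`, no pooling of rare classes) at the Dunn–Šidák level
  `1 − (1 − α)^{1/n}`; Smouse–Peakall genotypic distances
  (`d² = ½‖Δ allele counts‖²` per locus, so AA–AB = 1, AB–CD = 2,
  AA–BC = 3, AA–BB = 4); Gower-centred PCoA; one-tailed Mantel tests of
  genetic vs (log-)geographic and vs chemical distance.
* **How much selfing?** A mixed-mating EM over maternal progeny arrays:
  multilocus and single-locus outcrossing rates `t_m`, `t_s`, biparental
  inbreeding `t_m − t_s`, maternal inbreeding `F_mat`, with
  family-bootstrap standard errors.
* **How many genetic clusters?** A non-spatial admixture Gibbs sampler
  (latent cluster origin per allele copy, Dirichlet updates for `Q` and
  `P`), `DIC = D̄ + (D̄ − D(θ̄))` per k, an asymptote rule for choosing k,
  and CLUMPP-style greedy/exhaustive label alignment across replicate
  runs.
* **How much compound?** Seven-point LC/MS standard curves, conversion of
  peak areas to percent dry weight (`conc × extract volume / sample
  mass`), classification against the 0.25 % dry-wt pharmacopoeia
  threshold, and replicate repeatability.

Because the original genotype and chemistry tables are not deposited
anywhere, the package ships a seeded synthetic-data generator
(`sim_config()`, `simulate_*()`) that reproduces the study design — nine
populations of 10–15 genotyped parents on a geographic transect, 11
microsatellite loci, ~6 offspring per maternal family, yields spanning
0–1.5 % dry wt around the 0.25 % threshold — so the full workflow runs end
to end and every estimator is validated by recovery of known truths.

## Worked example

```r
library(chemopop)

cfg     <- sim_config(n_pops = 4, parents_per_pop = 12, seed = 7)
parents <- simulate_island_populations(cfg)
fams    <- simulate_progeny_arrays(parents, t_true = 0.9,
                                   offspring_per_family = 6, seed = 8)
traits  <- simulate_parent_offspring_trait(fams, h2_true = 0.76,
                                           env_sd = 0.12, seed = 9)

parent_offspring_regression(family_means(traits, fams))
#> Parent-offspring regression: n = 48 families
#>   b = 0.346 (SE 0.061), t = 5.64, p = 1.01e-06
#>   h2 = 2b = 0.693

em_mating_system(subset_genotypes(fams, fams$population == "pop01"))
#> Mating system (12 families, 72 offspring):
#>   tm = 0.847  ts = 0.863  tm - ts = -0.016  F_mat = 0.016
#>   logL = -1247.90 after 7 EM iterations (converged)

set.seed(12)
tree <- ape::rcoal(40)
chem <- simulate_binary_character_on_tree(tree, 0.6, 0.6, seed = 13)
character_reshuffle_test(tree, chem, n_reshuffles = 999, seed = 11)
#> Chemotype lability (soft polytomies)
#>   steps = 5 (min 1, max 15)  CI = 0.200  RI = 0.714
#>   reshuffle null: mean = 12.323, sd = 1.395 (n = 999)
#>   one-sided p (fewer steps than random) = 0.001
```

The regression recovers the simulated heritability (0.76) within its
standard error and doubles the slope exactly; the EM recovers the
simulated outcrossing rate 0.9 within its bootstrap error with
`t_m − t_s ≈ 0` (no biparental inbreeding was simulated); the simulated
chemotype needs far fewer steps (5) than reshuffled characters
(12.3 ± 1.4), so the test reports strong phylogenetic inertia.

## Analysis workflow

`analysis/01_simulate.R` … `analysis/08_chemistry.R` are numbered drivers
that run the whole study on one synthetic dataset and write their tables
under `results/`: genotype/trait/tree/LC-MS inputs (01), the
Table-2-style population summary with HWE and the parent/offspring
pooling check (02), PCoA and Mantel tests (03), per-population
mating-system estimates with bootstrap SEs (04), the DIC-vs-k curve and
aligned consensus Q (05), pooled and subset heritability (06), chemotype
lability (07), and calibration/quantification/repeatability (08). Each
script states what it found on stdout; all are seeded and reproducible.

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

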