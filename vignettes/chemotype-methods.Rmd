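---
title: "Models and methods behind chemopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chemopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`chemopop` packages the statistical machinery needed to characterise
natural variation in a plant secondary metabolite — developed around
oridonin production in *Isodon* — from four kinds of evidence: a
phylogeny carrying a presence/absence chemotype, maternal progeny arrays
scored at codominant microsatellites, a quantitative yield trait measured
in parents and offspring, and LC/MS assays. This vignette explains each
model, its assumptions, the tunable parameters, the numerical choices,
and what the synthetic-data generator does and does not emulate.

## 1. Chemotype lability on a phylogeny

**Model.** The chemotype is a two-state character on the tips of a rooted
tree. Its lability is summarised by the minimum number of state changes
(parsimony steps) needed to explain the tip pattern, compared against a
null distribution obtained by reshuffling the observed states among the
tips.

**Polytomy treatment.** Consensus trees contain multifurcations. In
`hard` mode a multifurcation is treated as a true simultaneous
divergence and the step count is the unit-cost Sankoff length of the tree
as given (exact on multifurcating trees). In `soft` mode — the
conservative choice for detecting gains and losses, and the default — a
multifurcation represents uncertainty, and the step count is the minimum
Fitch length over *all* binary resolutions of *every* polytomy. For a
binary character this minimum does not require enumeration: at a
polytomy, children preferring the opposite state can always be grouped
into one clade served by a single stem change, so the per-state cost is
`sum of child minima + 1` unless some state is optimal in every child.
The recursion is exact; the test suite verifies it against exhaustive
enumeration of all resolutions on trees of up to 8 tips, where the
enumeration is still feasible.

**Homoplasy indices.** `CI = m/s` and `RI = (g − s)/(g − m)` with `m = 1`
for a binary character with both states present. `g` is defined here as
the maximum step count any permutation of the observed state multiset can
require *on this tree under the same polytomy mode*, computed exactly by
a dynamic programme over (number of derived tips in the subtree,
preferred root state); on a fully resolved tree this reduces to the
familiar `min(n_present, n_absent)`. The DP is validated against brute
force over all tip arrangements on small trees.

**Reshuffle test.** Each of `n_reshuffles` (default 1000) permutations
preserves the state multiset exactly. The p-value uses the add-one
convention `p = (1 + #{s_null ≤ s_obs})/(n + 1)` — it can never be 0 —
and is one-sided for *fewer* steps than random, since the scientific
question is phylogenetic inertia. Because the step count is discrete, the
reported p is conservative under ties; the suite checks calibration by
comparing the randomised-tie version against the uniform distribution.
Monomorphic characters are rejected with a named error: no test is
possible.

## 2. Heritability from one-parent regression

Mean offspring yield per maternal family is regressed on the maternal
value by ordinary least squares; `h² = 2b` because one parent transmits
half the additive value. Families are unweighted regardless of sibling
count (the plain reading of a regression on family means), offspring with
missing values are excluded from sibling means, and families with
unmeasured mothers are dropped and counted. The slope t-test is
two-sided on `n − 2` df. Estimates outside `[0, 1]` are returned with a
warning flag rather than truncated: in structured samples the pooled
regression legitimately exceeds the within-population heritability
because maternal and paternal population effects are shared, and the
package's own simulations reproduce that inflation (see §7). A
`populations` filter supports within-group re-fits, which is how the
inflation is diagnosed in practice.

Assumptions: purely additive inheritance, no genotype–environment
interaction, no shared environment between wild mothers and
greenhouse-grown offspring.

## 3. Microsatellite summaries and HWE

Per (population, locus): `H_E = 1 − Σp̂²` from sample allele frequencies
with no small-sample correction, `H_O` the observed heterozygote
fraction, `F = 1 − H_O/H_E` (undefined when `H_E = 0`). Population
summaries average across loci and report `SE = sd/√n_loci`; the
population `F` is the mean of per-locus `F` values, not a ratio of means
— the convention that matches how such tables are printed. The HWE
chi-square uses expected counts `np̂ᵢ²` and `2np̂ᵢp̂ⱼ` over all
`k(k+1)/2` genotype classes with `df = k(k−1)/2`; rare classes are not
pooled (whether the original analyses pooled them is undocumented; this
convention is fixed and stated). Multiplicity is handled by the
Dunn–Šidák level `1 − (1 − α)^{1/n}` over the testable cells. The
parent/offspring pooling check recomputes mean `F` with and without
progeny arrays: arrays are family samples, so pooling inflates `F`
whenever selfing or family structure is present, which is the reason
population statistics are computed from parents only.

## 4. Distances, ordination, Mantel tests

The individual genotypic distance is the Smouse–Peakall codominant
metric: per locus, half the squared Euclidean distance between
allele-count vectors (0/1/2/3/4 for the canonical genotype-pair types),
summed over loci where both individuals are genotyped; pairs sharing no
locus get a flagged missing distance. PCoA Gower-centres `−d²/2`,
eigendecomposes, and scales eigenvectors by the square roots of positive
eigenvalues; negative eigenvalues are reported but excluded from
percent-of-variation denominators. The exact standardisation used by the
original desktop tool is undocumented, so plain Gower-centred PCoA on the
genotypic distance is the package's stated choice.

Mantel tests correlate upper-triangle entries (diagonal excluded) and
permute rows and columns of one matrix simultaneously; `p` is one-tailed
(greater), add-one convention — the conventional direction for isolation
by distance. Geographic distance is Euclidean on planar coordinates (a
flag records whether coordinates are planar or lat/lon); the log
transform applies `log` to off-diagonal distances and refuses zero
distances rather than guessing a jitter, and log-distance matrices are
treated as dissimilarities (negative entries allowed) rather than metric
distances. Chemical distance is the absolute yield difference with
pairwise deletion of missing values.

## 5. Mating system from progeny arrays

The mixed-mating model: each offspring is selfed with probability
`1 − t` (both gametes Mendelian from its known mother) or outcrossed
(one maternal gamete, one pollen allele from pollen-pool frequencies).
The EM treats selfing status as latent; the M-step mixture-weight update
is a closed-form mean of posterior outcross probabilities, which stays in
`[0, 1]` by construction, so no reparameterisation of `t` is needed.
Pollen frequencies are estimated jointly: the E-step attributes each
outcrossed offspring's non-maternal allele to the pollen pool (summing
over maternal gametes at ½ each for heterozygous mothers), the M-step
renormalises posterior-weighted counts with additive smoothing
`ε = 10⁻⁶`. The log-likelihood is asserted non-decreasing at every
iteration; convergence is `|Δlog L| < 10⁻⁶` within 500 iterations, with
a flagged, returned last estimate otherwise. Single-locus rates run the
same EM per locus and average unweighted into `t_s`; `t_m − t_s`
estimates biparental inbreeding. `F_mat` is maximised separately from
the maternal genotypes under `P(hom) = p² + Fp(1−p)`,
`P(het) = 2pq(1−F)`, over `F ∈ (−1, 1)` with probabilities floored at
`10⁻¹²`.

Two practical policies: offspring carrying no maternal allele at some
locus are impossible under *both* mixture components (a genotyping
error, not a mating event) and are dropped with a warning rather than
allowed to corrupt the likelihood; and estimation is per population
(`mating_system_by_population()`), because each population has its own
pollen pool — pooling populations misstates the outcross likelihood and
biases both rates downward, most visibly `t_s`. Standard errors come
from resampling maternal families with replacement.

## 6. Admixture clustering and DIC

The sampler implements the standard non-spatial admixture model with
uncorrelated allele frequencies: latent cluster origin per allele copy,
`P | z ~ Dirichlet(1 + counts)`, `Q_i | z ~ Dirichlet(α + counts)`, with
`α = 1` fixed by default (user-settable, not sampled). This deliberately
replaces the spatially correlated prior of the original analysis — a
non-spatial model can over-predict k when sampling is geographically
gapped, so the DIC-vs-k curve is reproduced conceptually, not
numerically. Missing allele copies contribute nothing to the likelihood.
The deviance `−2 log L` is recorded every post-burn-in sweep;
`DIC = D̄ + pD` with `pD = D̄ − D(posterior means)`. Desk-scale defaults
(hundreds of sweeps) replace the original half-million-sweep regimen;
both are available through the configuration. `select_k()` encodes the
"approach an asymptote" reading of a DIC plot: the smallest k whose
improvement at the next k falls below 5 % of the DIC range, with all
values returned for inspection. Label switching across replicate runs is
resolved by maximising the summed Q-row dot products against the first
run — exhaustively over `k!` permutations for `k ≤ 8`, greedily beyond —
and averaging the aligned runs into a consensus.

## 7. The synthetic-data generator

The generator defines the study conditions under which everything is
tested: nine populations of 10–15 genotyped parents (drawn per
population), 11 loci with up to 10 alleles, ~6 offspring per maternal
family, outcrossing rate 0.9 (selfing detectable but not dominant),
within-population heritability 0.76, yields centred on 0.25 % dry wt so
the pharmacopoeia threshold splits the sample.

Allele frequencies follow a mean-reverting Dirichlet chain along a 1-D
transect: population j draws from
`Dirichlet(c · ((1 − ρ)·base + ρ·p_{j−1}))` with `c = (1 − θ)/θ`,
`θ = 0.15`, `ρ = 0.7`. The pull toward the shared base keeps expected
heterozygosity roughly uniform along the transect (a pure stepping-stone
chain loses diversity cumulatively and an exchangeable island model
cannot produce isolation by distance); the neighbour term makes genetic
and geographic distance correlate. Within populations genotypes are
drawn with inbreeding `F = 0.1` (autozygous with probability F). Under
these defaults simulated tables show `H_E ≈ 0.55–0.65`, `N_A ≈ 4–5`,
`F ≈ 0.03–0.1`, Mantel IBD `r ≈ 0.4–0.5` — the ranges the real tables
report.

The yield trait is additive: maternal phenotype = mean + population
effect + additive value + environment; offspring additive value is the
mid-parent value plus Mendelian segregation, with the pollen parent
drawn from the same population. Population effects follow the geographic
transect (scaled to SD 0.2 % dry wt), emulating the observed clustering
of high-yield populations at one end of the range; they are what makes
chemical distance correlate with genetic distance (r ≈ 0.1–0.2 in
simulation). Because both parents share the population effect, the
pooled one-parent regression overestimates the within-population
heritability (estimates around 1.0–1.2 versus the simulated 0.76) —
deliberately retained, since the same inflation is the reason pooled and
within-group estimates are reported side by side. Values are truncated
at zero (yields are percentages); under the defaults truncation affects
the lower tail visibly, as real non-producing samples do.

The chemotype evolves by a two-state Markov jump process along branches
with the realised number of flips recorded — always an upper bound on
the parsimony steps of the resulting tip pattern. LC/MS data use a
linear detector response (`area = 120·conc + 50`) with multiplicative
log-normal noise at CV 12 %, the assay's reported repeatability scale.

What the generator does **not** emulate: microsatellite mutation
(stepwise or otherwise), coalescent genealogies, linkage, null alleles,
genotyping error (hence the drop-with-warning policy in §5),
genotype–environment interaction, and the multi-species taxonomy of the
real collections (populations stand in for species-level structure).
Passing recovery tests therefore demonstrates estimator correctness
under the stated model, not robustness to these violations.

## 8. Chemistry

Calibration is a least-squares line through the seven-point standard
series (1.5–100 ng/µL). Percent dry weight is reconstructed from the
extraction protocol — `pct = conc · volume_µL / (mass_mg · 10⁶) · 100`
with a 20 mL methanol extract — because no source states the formula
explicitly; 50 ng/µL from 400 mg is exactly the 0.25 % threshold, which
anchors the unit check. Concentrations outside the calibration range are
flagged as extrapolated; negative inferred concentrations (blank noise
above signal) clamp to zero with a warning. UV and MS channels fit
separate curves; how the original combined them is unknown, so reporting
both with their mean is left to the caller. Repeatability is the mean
absolute deviation of replicates from their mean, relative to that mean
— for replicate pairs {0.9, 1.1} this is 10 % — reported as the
across-sample mean; samples with zero replicate mean are excluded with a
warning since relative error is meaningless at the detection floor.

## 9. Problem sizes, tolerances, reproducibility

Test-suite simulations use sizes chosen to make each property decisive
at desk scale: 200 random trees of ≤ 8 tips for the soft-parsimony
oracle, 500 families for heritability recovery, 50 families × 6
offspring × 11 loci for mating-system recovery, 1000 replicates for HWE
calibration, 500 simulations × 199 permutations for Mantel calibration,
and 50 replicate k-selections on two fixed-difference populations.
Bootstrap SEs default to B = 1000 in the API and use B = 100 in the
workflow scripts. All stochastic stages derive per-stage seeds from one
global seed via a fixed splitting rule (`stage_seed()`), so disabling a
stage never changes another's numbers and every table is regenerable
bit-identically from configuration plus seed.

Numerical guards worth knowing: EM likelihoods are floored at `10⁻³⁰⁰`
before logging; Dirichlet draws are floored at `10⁻³⁰⁰` before
normalisation; the PCoA eigenvalue threshold is `10⁻⁹` of the largest
magnitude, and an all-zero distance matrix raises a named error rather
than returning an empty ordination; DP ties in the parsimony recursions
resolve deterministically by child order.

## 10. Known limitations

Soft-polytomy `g` (hence RI) is defined relative to this tree and mode
rather than the original desktop tool's internals, whose published
CI/RI pairs are not always internally consistent for a binary character;
the single-locus outcrossing EM shares the usual small-sample downward
bias of `t_s` when loci are weakly informative, which surfaces as
positive `t_m − t_s` in pooled (mis-specified) fits; DIC values are not
comparable across model families, so only the shape of the DIC-vs-k
curve carries information; and the heritability model cannot separate
additive variance from population structure without the within-group
re-fit.
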