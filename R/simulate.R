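#' Configuration for the synthetic study design
#'
#' Defaults reproduce the field design the analyses assume: nine populations
#' of 10-15 genotyped parents, eleven microsatellite loci, maternal progeny
#' arrays of ~6 offspring, predominant outcrossing, a strongly heritable
#' quantitative yield spanning 0-1.5 percent dry weight around the 0.25
#' percent pharmacopoeia threshold, and populations on a 1-D geographic
#' gradient so genetic and geographic divergence correlate.
#'
#' @param n_pops number of populations.
#' @param parents_per_pop integer vector of candidate family counts per
#'   population; each population draws its size uniformly from this set.
#' @param n_loci number of codominant loci.
#' @param alleles_per_locus alleles segregating at each locus.
#' @param theta divergence parameter in `[0, 1)`: each population's allele
#'   frequencies are a Dirichlet draw with concentration `(1 - theta) /
#'   theta` (so 0 means identical frequencies everywhere) around a local
#'   mean that mixes the shared base frequencies with the neighbouring
#'   population's.
#' @param rho spatial autocorrelation in `[0, 1)`: weight of the
#'   neighbouring population in the local mean; 0 gives an exchangeable
#'   island model, larger values give isolation by distance along the
#'   transect.
#' @param f_inbreeding within-population inbreeding F in `[0, 1]`.
#' @param t_true true outcrossing rate for progeny arrays.
#' @param offspring_per_family offspring per maternal family.
#' @param h2_true true narrow-sense heritability of the yield trait.
#' @param env_sd environmental standard deviation of the trait (percent dry
#'   weight units).
#' @param trait_mean population mean yield (percent dry weight).
#' @param trait_pop_sd standard deviation of population-level additive
#'   trait effects (between-population yield divergence, the feature that
#'   links chemical to genetic distance).
#' @param geo_scale spacing between adjacent populations (planar units).
#' @param seed integer RNG seed; a fixed seed makes every generator
#'   byte-reproducible.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 9, parents_per_pop = 10:15, n_loci = 11,
                       alleles_per_locus = 10, theta = 0.15, rho = 0.7,
                       f_inbreeding = 0.1, t_true = 0.9,
                       offspring_per_family = 6, h2_true = 0.76,
                       env_sd = 0.12, trait_mean = 0.25, trait_pop_sd = 0.2,
                       geo_scale = 50, seed = 1L) {
  stopifnot(n_pops >= 1, all(parents_per_pop >= 1), n_loci >= 1,
            alleles_per_locus >= 1, theta >= 0, theta < 1,
            rho >= 0, rho < 1,
            f_inbreeding >= 0, f_inbreeding <= 1,
            t_true >= 0, t_true <= 1, offspring_per_family >= 1,
            h2_true >= 0, h2_true <= 1, env_sd >= 0, geo_scale > 0)
  structure(as.list(environment()), class = "sim_config")
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Simulate parent genotypes for diverging populations
#'
#' Allele frequencies follow a mean-reverting Dirichlet chain along a 1-D
#' geographic gradient: population j's frequencies are drawn from
#' `Dirichlet(c * ((1 - rho) * base + rho * p[j-1]))` with
#' `c = (1 - theta) / theta`. The pull toward the shared base keeps
#' diversity comparable across the transect while the neighbour term makes
#' nearby populations resemble each other more than distant ones, so
#' isolation by distance emerges without the runaway loss of
#' heterozygosity a pure stepping-stone chain would show. Within
#' populations, genotypes are drawn with inbreeding `F` (an individual is
#' autozygous with probability F).
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed` when given.
#' @return a [genotype_table()] of parents with planar coordinates.
#' @export
simulate_island_populations <- function(config = sim_config(), seed = NULL) {
  cfg <- config
  if (cfg$alleles_per_locus < 1) stop("degenerate config: 0 alleles")
  set.seed(if (is.null(seed)) cfg$seed else seed)
  A <- cfg$alleles_per_locus
  codes <- 100L + 2L * seq_len(A)  # microsatellite-style fragment sizes
  # frequency chain per locus
  rho <- if (is.null(cfg$rho)) 0.7 else cfg$rho
  freqs <- vector("list", cfg$n_loci)
  for (l in seq_len(cfg$n_loci)) {
    base <- rdirichlet1(rep(1, A))
    pops <- matrix(0, cfg$n_pops, A)
    prev <- base
    for (j in seq_len(cfg$n_pops)) {
      centre <- (1 - rho) * base + rho * prev
      prev <- if (cfg$theta == 0) centre
              else rdirichlet1(pmax(centre, 1e-8) *
                                 (1 - cfg$theta) / cfg$theta)
      pops[j, ] <- prev
    }
    freqs[[l]] <- pops
  }
  npar <- if (length(cfg$parents_per_pop) == 1L)
    rep(cfg$parents_per_pop, cfg$n_pops)
  else sample(cfg$parents_per_pop, cfg$n_pops, replace = TRUE)
  n <- sum(npar)
  pop_lab <- sprintf("pop%02d", seq_len(cfg$n_pops))
  population <- rep(pop_lab, npar)
  samples <- paste0(population, "_p", unlist(lapply(npar, seq_len)))
  alleles <- matrix(0L, n, 2L * cfg$n_loci)
  for (l in seq_len(cfg$n_loci)) {
    for (j in seq_len(cfg$n_pops)) {
      rows <- which(population == pop_lab[j])
      p <- freqs[[l]][j, ]
      auto <- stats::runif(length(rows)) < cfg$f_inbreeding
      a1 <- sample.int(A, length(rows), replace = TRUE, prob = p)
      a2 <- ifelse(auto, a1,
                   sample.int(A, length(rows), replace = TRUE, prob = p))
      alleles[rows, 2L * l - 1L] <- codes[a1]
      alleles[rows, 2L * l] <- codes[a2]
    }
  }
  x <- rep(cfg$geo_scale * seq_len(cfg$n_pops), npar) +
    stats::runif(n, -cfg$geo_scale / 50, cfg$geo_scale / 50)
  y <- stats::runif(n, -cfg$geo_scale / 50, cfg$geo_scale / 50)
  gt <- genotype_table(samples, population, "parent", NA_character_,
                       alleles, sprintf("loc%02d", seq_len(cfg$n_loci)),
                       lat = y, lon = x, coord_type = "planar")
  attr(gt, "true_freqs") <- freqs
  gt
}

#' Simulate maternal progeny arrays under mixed mating
#'
#' Each offspring is selfed with probability `1 - t_true` (both gametes
#' Mendelian from the mother) or outcrossed (one maternal gamete, one pollen
#' allele drawn from the mother's own population allele frequencies).
#'
#' @param mothers a fully genotyped [genotype_table()] of parents.
#' @param t_true true outcrossing rate in `[0, 1]`.
#' @param offspring_per_family offspring per mother.
#' @param seed integer RNG seed.
#' @return a [genotype_table()] combining the mothers (generation `parent`)
#'   and their offspring (generation `offspring`, `mother` set).
#' @export
simulate_progeny_arrays <- function(mothers, t_true = 0.9,
                                    offspring_per_family = 6, seed = 1L) {
  stopifnot(t_true >= 0, t_true <= 1, offspring_per_family >= 1)
  if (any(mothers$alleles == 0L)) stop("missing maternal genotypes")
  set.seed(seed)
  L <- length(mothers$loci)
  n_m <- length(mothers$samples)
  # pollen pool: per-population allele frequencies from the parents
  pops <- unique(mothers$population)
  pool <- lapply(seq_len(L), function(l) {
    al <- locus_alleles(mothers, l)
    out <- lapply(pops, function(popn) {
      rows <- mothers$population == popn
      tab <- table(c(al[rows, 1L], al[rows, 2L]))
      stats::setNames(as.numeric(tab) / sum(tab), names(tab))
    })
    names(out) <- pops
    out
  })
  n_o <- n_m * offspring_per_family
  off <- matrix(0L, n_o, 2L * L)
  mom_of <- rep(seq_len(n_m), each = offspring_per_family)
  selfed <- stats::runif(n_o) >= t_true
  for (l in seq_len(L)) {
    al <- locus_alleles(mothers, l)
    g1 <- al[mom_of, 1L]; g2 <- al[mom_of, 2L]
    pickA <- ifelse(stats::runif(n_o) < 0.5, g1, g2)
    pickB <- ifelse(stats::runif(n_o) < 0.5, g1, g2)  # second selfing gamete
    pollen <- integer(n_o)
    for (popn in unique(mothers$population)) {
      rows <- which(mothers$population[mom_of] == popn)
      p <- pool[[l]][[popn]]
      pollen[rows] <- as.integer(names(p))[
        sample.int(length(p), length(rows), replace = TRUE, prob = p)]
    }
    second <- ifelse(selfed, pickB, pollen)
    off[, 2L * l - 1L] <- pmin(pickA, second)
    off[, 2L * l] <- pmax(pickA, second)
  }
  ids <- paste0(mothers$samples[mom_of], "_o",
                rep(seq_len(offspring_per_family), times = n_m))
  gt <- genotype_table(
    c(mothers$samples, ids),
    c(mothers$population, mothers$population[mom_of]),
    c(mothers$generation, rep("offspring", n_o)),
    c(mothers$mother, mothers$samples[mom_of]),
    rbind(mothers$alleles, off), mothers$loci,
    lat = c(mothers$lat, mothers$lat[mom_of]),
    lon = c(mothers$lon, mothers$lon[mom_of]),
    coord_type = mothers$coord_type)
  attr(gt, "selfed") <- stats::setNames(selfed, ids)
  gt
}

#' Simulate parent and offspring yield under an additive trait model
#'
#' Maternal phenotype = mean + population effect + additive value +
#' environment; offspring additive value = half the maternal and half a
#' same-population pollen parent's additive value plus Mendelian
#' segregation. Within one population the expected slope of mean offspring
#' on the single known parent is `h2_true / 2`. Population-level additive
#' effects (`pop_effect_sd > 0`) emulate between-population yield
#' divergence; because both parents then share the population effect, the
#' pooled-across-populations one-parent regression is inflated relative to
#' the within-population heritability — the behaviour reported for
#' structured samples. Within-population additive variance comes from
#' `Va = h2 / (1 - h2) * env_sd^2`; values are truncated at zero (rare
#' under the defaults) since yields are percentages.
#'
#' @param families a [genotype_table()] containing parents and offspring
#'   with `mother` links (e.g. from [simulate_progeny_arrays()]).
#' @param h2_true true within-population narrow-sense heritability in
#'   `[0, 1]`.
#' @param env_sd environmental standard deviation; must be 0 when
#'   `h2_true = 1` (additive s.d. then defaults to 0.1).
#' @param trait_mean mean yield, percent dry weight.
#' @param pop_effect_sd s.d. of population-level additive effects (0
#'   disables them).
#' @param seed integer RNG seed.
#' @return a [trait_table()] covering every sample in `families`, with the
#'   per-sample additive values as attribute `"additive"`.
#' @export
simulate_parent_offspring_trait <- function(families, h2_true = 0.76,
                                            env_sd = 0.1, trait_mean = 0.25,
                                            pop_effect_sd = 0, seed = 1L) {
  stopifnot(h2_true >= 0, h2_true <= 1, env_sd >= 0, pop_effect_sd >= 0)
  set.seed(seed)
  if (h2_true >= 1 - 1e-12) {
    if (env_sd > 0) stop("h2_true = 1 requires env_sd = 0")
    va <- 0.1^2
  } else {
    va <- h2_true / (1 - h2_true) * env_sd^2
  }
  # population-level additive effects follow the geographic transect (the
  # study's high-yield populations cluster at one end of its range), scaled
  # to the requested standard deviation
  pops <- unique(families$population)
  g_pop <- if (length(pops) > 1L && pop_effect_sd > 0)
    stats::setNames(as.numeric(scale(seq_along(pops))) * pop_effect_sd, pops)
  else stats::setNames(rep(0, length(pops)), pops)
  is_par <- families$generation == "parent"
  n <- length(families$samples)
  add <- numeric(n)
  add[is_par] <- g_pop[families$population[is_par]] +
    stats::rnorm(sum(is_par), 0, sqrt(va))
  midx <- match(families$mother, families$samples)
  off <- which(!is_par & !is.na(midx))
  sire <- g_pop[families$population[off]] +
    stats::rnorm(length(off), 0, sqrt(va))
  add[off] <- (add[midx[off]] + sire) / 2 +
    stats::rnorm(length(off), 0, sqrt(va / 2))
  pct <- pmax(0, trait_mean + add + stats::rnorm(n, 0, env_sd))
  tt <- trait_table(families$samples, pct)
  attr(tt, "additive") <- stats::setNames(add, families$samples)
  tt
}

#' Simulate a binary character on a tree by a two-state Markov process
#'
#' The state evolves along each branch as a continuous-time two-state chain
#' with the given gain (absent to present) and loss rates; the root state is
#' drawn from the stationary distribution (or fixed). The realised number of
#' state flips is recorded, and is always at least the parsimony step count
#' of the resulting tip pattern.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param gain_rate,loss_rate non-negative transition rates.
#' @param seed integer RNG seed.
#' @param root_state optional 0/1 root state; default draws from the
#'   stationary distribution (absent when both rates are 0).
#' @return a [binary_character()] with attribute `"true_changes"`.
#' @export
simulate_binary_character_on_tree <- function(tree, gain_rate = 1,
                                              loss_rate = 1, seed = 1L,
                                              root_state = NULL) {
  stopifnot(gain_rate >= 0, loss_rate >= 0)
  if (is.null(tree$edge.length)) stop("missing branch lengths")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  if (is.null(root_state)) {
    tot <- gain_rate + loss_rate
    root_state <- if (tot == 0) 0L
                  else stats::rbinom(1L, 1L, gain_rate / tot)
  }
  state <- integer(ntip + tree$Nnode)
  state[root] <- as.integer(root_state)
  changes <- 0L
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    s <- state[par]; t_left <- ord$edge.length[e]
    repeat {
      r <- if (s == 0L) gain_rate else loss_rate
      if (r == 0) break
      w <- stats::rexp(1L, r)
      if (w > t_left) break
      t_left <- t_left - w
      s <- 1L - s
      changes <- changes + 1L
    }
    state[child] <- s
  }
  bc <- binary_character(stats::setNames(state[seq_len(ntip)],
                                         tree$tip.label),
                         coding = "simulated")
  attr(bc, "true_changes") <- changes
  bc
}

#' Simulate LC/MS calibration standards and sample peak areas
#'
#' Produces a standard series (seven concentrations, 1.5-100 ng/uL by
#' default) and per-sample peak areas consistent with the true yields in a
#' trait table, under a linear detector response with multiplicative noise.
#'
#' @param traits a [trait_table()] of true yields (percent dry weight).
#' @param slope,intercept detector response (area per ng/uL and blank area).
#' @param standards standard concentrations, ng/uL.
#' @param mass_mg sample mass per extraction (recycled), mg.
#' @param volume_ul extract volume, uL.
#' @param noise_cv coefficient of variation of multiplicative area noise.
#' @param seed integer RNG seed.
#' @return list with `standards` (conc, area) and `areas` (sample, area,
#'   mass_mg) data frames.
#' @export
simulate_lcms <- function(traits, slope = 120, intercept = 50,
                          standards = c(1.5, 3, 6, 12.5, 25, 50, 100),
                          mass_mg = 400, volume_ul = 20000,
                          noise_cv = 0.12, seed = 1L) {
  set.seed(seed)
  std <- data.frame(conc = standards,
                    area = slope * standards + intercept)
  mass <- rep_len(mass_mg, nrow(traits))
  conc <- traits$oridonin_pct / 100 * mass * 1e6 / volume_ul  # ng/uL
  area <- (slope * conc + intercept) *
    exp(stats::rnorm(nrow(traits), 0, noise_cv))
  list(standards = std,
       areas = data.frame(sample = traits$sample, area = area,
                          mass_mg = mass, stringsAsFactors = FALSE))
}
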