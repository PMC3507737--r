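#' Derive a stage-specific seed from the global seed
#'
#' Deterministic splitting rule: `(seed * 101 + stage index * 997) mod
#' (2^31 - 1)`, so every stochastic stage gets its own reproducible stream
#' and disabling one stage never shifts another's numbers.
#'
#' @param seed global integer seed.
#' @param stage stage index or name (names map to fixed indices).
#' @return integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1, traits = 2, popgen = 3, distance = 4,
              mating = 5, cluster = 6, herit = 7, lability = 8, chem = 9)
  i <- if (is.character(stage)) stages[[stage]] else as.integer(stage)
  as.integer((as.numeric(seed) * 101 + i * 997) %% (2^31 - 1))
}

#' Configuration for the end-to-end analysis
#'
#' @param sim a [sim_config()] describing the synthetic study design.
#' @param seed global seed; per-stage seeds derive via [stage_seed()].
#' @param mantel_permutations permutations for Mantel tests.
#' @param reshuffles character reshuffles for the lability test.
#' @param bootstrap_B bootstrap replicates for mating-system SEs.
#' @param k_range candidate cluster numbers.
#' @param runs_per_k replicate sampler runs per k.
#' @param sweeps,burn_in Gibbs sampler regimen per run.
#' @param tree_tips tips of the simulated phylogeny for the lability stage.
#' @param gain_rate,loss_rate chemotype transition rates on the tree.
#' @param stages character vector of stages to run.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(sim = sim_config(), seed = 1L,
                            mantel_permutations = 999, reshuffles = 1000,
                            bootstrap_B = 100, k_range = 1:4,
                            runs_per_k = 3, sweeps = 400, burn_in = 150,
                            tree_tips = 60, gain_rate = 0.3,
                            loss_rate = 0.3,
                            stages = c("popgen", "distance", "mating",
                                       "cluster", "herit", "lability",
                                       "chem")) {
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full analysis workflow on synthetic data
#'
#' Simulates the study design (populations, progeny arrays, yield trait,
#' chemotype on a tree, LC/MS areas), then runs each configured stage in
#' dependency order. A failing stage is logged and skipped; its dependents
#' are marked unavailable.
#'
#' @param config an [analysis_config()].
#' @return list of class `report_bundle` with one element per stage plus
#'   `data` (the simulated inputs) and `log` (per-stage status).
#' @export
run_pipeline <- function(config = analysis_config()) {
  cfg <- config
  log <- list()
  note <- function(stage, status, msg = "") {
    log[[stage]] <<- list(status = status, message = msg)
  }
  res <- list()

  parents <- simulate_island_populations(cfg$sim,
                                         seed = stage_seed(cfg$seed, "simulate"))
  fams <- simulate_progeny_arrays(parents, t_true = cfg$sim$t_true,
                                  offspring_per_family =
                                    cfg$sim$offspring_per_family,
                                  seed = stage_seed(cfg$seed, "simulate") + 1L)
  traits <- simulate_parent_offspring_trait(
    fams, h2_true = cfg$sim$h2_true, env_sd = cfg$sim$env_sd,
    trait_mean = cfg$sim$trait_mean,
    pop_effect_sd = cfg$sim$trait_pop_sd,
    seed = stage_seed(cfg$seed, "traits"))
  tree <- ape::rcoal(cfg$tree_tips)
  tree$tip.label <- sprintf("taxon%02d", seq_len(cfg$tree_tips))
  # the observed chemotype is polymorphic; redraw (new derived seed) in the
  # rare event a simulated history leaves all tips in one state
  char <- NULL
  for (try in 0:19) {
    char <- simulate_binary_character_on_tree(
      tree, cfg$gain_rate, cfg$loss_rate,
      seed = stage_seed(cfg$seed, "lability") + try)
    if (length(unique(as.integer(char))) == 2L) break
  }
  lcms <- simulate_lcms(traits, seed = stage_seed(cfg$seed, "chem"))
  res$data <- list(parents = parents, families = fams, traits = traits,
                   tree = tree, character = char, lcms = lcms)
  note("simulate", "ok")

  run_stage <- function(stage, fun) {
    if (!stage %in% cfg$stages) { note(stage, "disabled"); return(NULL) }
    tryCatch({
      out <- fun()
      note(stage, "ok")
      out
    }, error = function(e) {
      note(stage, "failed", conditionMessage(e))
      NULL
    })
  }

  res$popgen <- run_stage("popgen", function() {
    ls <- per_locus_stats(fams, generation = "parent")
    list(locus_stats = ls, summary = population_summary(ls),
         hwe = hwe_test_table(fams), pooling = pooling_fis_check(fams))
  })

  res$distance <- run_stage("distance", function() {
    par_gt <- subset_genotypes(fams, fams$generation == "parent")
    dgen <- genotypic_distance(par_gt)
    dgeo <- scalar_distance_matrix(cbind(par_gt$lon, par_gt$lat),
                                   labels = par_gt$samples)
    val <- stats::setNames(traits$oridonin_pct, traits$sample)
    dchem <- scalar_distance_matrix(val[par_gt$samples],
                                    labels = par_gt$samples)
    sseed <- stage_seed(cfg$seed, "distance")
    dgeo_log <- tryCatch(
      scalar_distance_matrix(cbind(par_gt$lon, par_gt$lat),
                             transform = "log", labels = par_gt$samples),
      error = function(e) NULL)
    list(pcoa = pcoa(dgen),
         mantel_geo = mantel_test(dgen, dgeo, cfg$mantel_permutations,
                                  seed = sseed),
         mantel_geo_log = if (!is.null(dgeo_log))
           mantel_test(dgen, dgeo_log, cfg$mantel_permutations,
                       seed = sseed + 1L),
         mantel_chem = mantel_test(dgen, dchem, cfg$mantel_permutations,
                                   seed = sseed + 2L),
         genetic = dgen, geographic = dgeo, chemical = dchem)
  })

  res$mating <- run_stage("mating", function() {
    mating_system_by_population(fams, B = cfg$bootstrap_B,
                                seed = stage_seed(cfg$seed, "mating"))
  })

  res$cluster <- run_stage("cluster", function() {
    par_gt <- subset_genotypes(fams, fams$generation == "parent")
    sseed <- stage_seed(cfg$seed, "cluster")
    runs <- list()
    for (k in cfg$k_range)
      for (r in seq_len(cfg$runs_per_k))
        runs[[length(runs) + 1L]] <-
          gibbs_admixture(par_gt, k, sweeps = cfg$sweeps,
                          burn_in = cfg$burn_in,
                          seed = sseed + 31L * k + r)
    sel <- select_k(runs)
    kbest <- sel$k
    best_runs <- Filter(function(r) r$k == kbest, runs)
    cons <- if (kbest > 1 && length(best_runs) >= 2)
      align_runs(best_runs)$consensus else best_runs[[1L]]$Q
    list(runs = runs, selection = sel, consensus_Q = cons)
  })

  res$herit <- run_stage("herit", function() {
    pairs <- family_means(traits, fams)
    list(pairs = pairs, fit = parent_offspring_regression(pairs))
  })

  res$lability <- run_stage("lability", function() {
    character_reshuffle_test(tree, char, n_reshuffles = cfg$reshuffles,
                             seed = stage_seed(cfg$seed, "lability") + 1L)
  })

  res$chem <- run_stage("chem", function() {
    curve <- fit_calibration(lcms$standards$conc, lcms$standards$area)
    quant <- quantify_percent_dry_weight(
      lcms$areas$area, curve, mass_mg = lcms$areas$mass_mg,
      sample = lcms$areas$sample)
    list(curve = curve, quant = quant,
         fraction_above_threshold = mean(quant$above_threshold))
  })

  res$log <- log
  res$seed <- cfg$seed
  class(res) <- "report_bundle"
  res
}

#' Write the tabular products of a report bundle
#'
#' @param bundle a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  if (!is.null(bundle$popgen)) {
    w(bundle$popgen$summary, "popgen_summary.csv")
    w(bundle$popgen$locus_stats, "popgen_per_locus.csv")
    w(bundle$popgen$hwe, "hwe_tests.csv")
    w(bundle$popgen$pooling, "pooling_fis.csv")
  }
  if (!is.null(bundle$herit)) {
    f <- bundle$herit$fit
    w(data.frame(n_families = f$n_families, slope = f$slope, se = f$se,
                 t = f$t, p = f$p, h2 = f$h2), "heritability.csv")
    w(bundle$herit$pairs, "family_means.csv")
  }
  if (!is.null(bundle$lability)) {
    x <- bundle$lability
    w(data.frame(steps = x$observed_steps, min_steps = x$min_steps,
                 max_steps = x$max_steps, ci = x$ci, ri = x$ri,
                 null_mean = x$null_mean, null_sd = x$null_sd,
                 p = x$p_value, mode = x$polytomy_mode), "lability.csv")
  }
  if (!is.null(bundle$distance)) {
    m <- bundle$distance
    tests <- Filter(Negate(is.null),
                    list(geo = m$mantel_geo, geo_log = m$mantel_geo_log,
                         chem = m$mantel_chem))
    w(do.call(rbind, Map(function(x, nm)
      data.frame(comparison = nm, n = x$n_samples, r = x$r, p = x$p),
      tests, names(tests))), "mantel.csv")
    pc <- m$pcoa
    w(data.frame(axis = seq_along(pc$percent[1:2]),
                 percent = pc$percent[1:2]), "pcoa_percent.csv")
  }
  if (!is.null(bundle$mating)) {
    w(bundle$mating, "mating_system.csv")
  }
  if (!is.null(bundle$cluster)) {
    w(data.frame(k = as.integer(names(bundle$cluster$selection$dic)),
                 dic = unname(bundle$cluster$selection$dic)), "dic.csv")
    utils::write.csv(bundle$cluster$consensus_Q,
                     file.path(dir, "consensus_Q.csv"))
  }
  if (!is.null(bundle$chem)) {
    w(bundle$chem$quant, "quantification.csv")
  }
  invisible(dir)
}
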