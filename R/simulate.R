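#' Scenario configuration for the synthetic-data generator
#'
#' Bundles the knobs of the synthetic study design: a regional species pool
#' on a simulated phylogeny, a set of focal species with plot-level
#' communities, and a two-treatment (control vs competitor removal)
#' demographic census whose planted treatment effect scales with the focal
#' species' phylogenetic distinctiveness. With `treatment_effect_slope` s
#' and D_i the focal's small-grain mean pairwise distance on the
#' square-root-transformed cophenetic scale, the expected difference in
#' log lambda between removal and control is `s * (max D - D_i)`: the
#' least distinct species benefits most from competitor removal, so the
#' implied regression coefficient of effect size on distinctiveness is
#' `-s`. At the default tree depth the across-focal spread of D is a few
#' sqrt-Myr, so the default slope plants effects of roughly 0 to 0.4 on
#' the log scale.
#'
#' @param n_regional_species Species-pool size (default 80).
#' @param n_focal Number of focal species (default 14).
#' @param community_richness_range Integer pair of co-occurring species
#'   richness, at least 11 (default `c(12, 25)`).
#' @param treatment_effect_slope Planted slope of the competition effect
#'   per unit sqrt-distance distinctiveness (default 0.15; 0 gives the
#'   null scenario).
#' @param trait_signal Named or unnamed per-trait Brownian signal in
#'   `[0, 1]` (1 = full Brownian motion, 0 = tip-shuffled).
#' @param noise_sd Species-level sd of the planted log-lambda difference
#'   around its expectation (default 0.005; kept well below the
#'   demographic sampling noise so bootstrap intervals, which propagate
#'   demographic uncertainty only, retain near-nominal coverage).
#' @param n_individuals Individuals per species x treatment (default 100).
#' @param n_plots_per_treatment Plots per species x treatment (default 4).
#' @param prop_ipm Fraction of focal species modelled with a
#'   size-structured IPM rather than a stage-structured MPM (default 0.5).
#' @param prop_no_cover Fraction of community members recorded without a
#'   cover value, as happens for canopy species (default 0.15).
#' @param congener_fraction Target fraction of pool species sharing a genus
#'   with at least one other (default 0.5).
#' @param tree_depth Root-to-tip depth of the simulated tree in arbitrary
#'   time units (default 100, the order of angiosperm crown ages in Myr).
#' @param max_planted_effect Cap on the expected planted log-lambda
#'   difference (default 0.8, a lambda ratio of about 2.2). Keeps target
#'   growth rates inside the biological regime the generating vital rates
#'   emulate, whatever the realised distinctiveness spread.
#' @param seed Master integer seed.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_regional_species = 80,
                            n_focal = 14,
                            community_richness_range = c(12, 25),
                            treatment_effect_slope = 0.15,
                            trait_signal = 1,
                            noise_sd = 0.005,
                            n_individuals = 100,
                            n_plots_per_treatment = 4,
                            prop_ipm = 0.5,
                            prop_no_cover = 0.15,
                            congener_fraction = 0.5,
                            tree_depth = 100,
                            max_planted_effect = 0.8,
                            seed = 1) {
  if (n_focal > n_regional_species) stop("n_focal must be <= pool size")
  if (community_richness_range[1] < 11) {
    stop("community richness must be >= 11 (rarefaction at k = 11)")
  }
  if (community_richness_range[2] > n_regional_species - 1) {
    stop("richness range exceeds pool size - 1")
  }
  if (n_individuals <= 0 || n_plots_per_treatment < 2) {
    stop("need positive sample sizes and >= 2 plots per treatment")
  }
  structure(list(
    n_regional_species = n_regional_species, n_focal = n_focal,
    community_richness_range = community_richness_range,
    treatment_effect_slope = treatment_effect_slope,
    trait_signal = trait_signal, noise_sd = noise_sd,
    n_individuals = n_individuals,
    n_plots_per_treatment = n_plots_per_treatment,
    prop_ipm = prop_ipm, prop_no_cover = prop_no_cover,
    congener_fraction = congener_fraction, tree_depth = tree_depth,
    max_planted_effect = max_planted_effect,
    seed = as.integer(seed)), class = "scenario_config")
}

#' Simulate an ultrametric regional phylogeny
#'
#' Pure-birth (Yule) tree with unit speciation rate, rescaled to a fixed
#' root-to-tip depth. Tip labels are binomial-style `Genus_species`
#' strings; shallow clades are collapsed into shared genera so that a
#' controllable fraction of tips has congeners (exercising congeneric
#' placement of missing species).
#'
#' @param n_tips Number of tips (at least 3).
#' @param seed Integer seed.
#' @param depth Root-to-tip depth after rescaling (default 100).
#' @param congener_fraction Target fraction of tips sharing a genus
#'   (default 0.5).
#' @return An ultrametric [ape::phylo].
#' @export
simulate_phylogeny <- function(n_tips, seed = 1, depth = 100,
                               congener_fraction = 0.5) {
  if (n_tips < 3) stop("n_tips must be >= 3")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length * depth / max(tip_depths(tree))
  # group shallow clades into genera via average-linkage clusters
  n_genera <- max(1, n_tips - round(congener_fraction * n_tips / 2))
  grp <- stats::cutree(stats::hclust(
    stats::as.dist(ape::cophenetic.phylo(tree)), method = "average"),
    k = min(n_genera, n_tips))
  labs <- character(n_tips)
  for (g in unique(grp)) {
    members <- which(grp == g)
    labs[members] <- sprintf("Genus%03d_sp%d", g, seq_along(members))
  }
  tree$tip.label[match(names(grp), tree$tip.label)] <- labs
  validate_tree(tree)
  tree
}

# Brownian motion on the tree: preorder accumulation of Gaussian edge
# increments. Returns a named tip vector.
sim_bm <- function(tree, sigma = 1) {
  nt <- ape::Ntip(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  ne <- nrow(post$edge)
  inc <- stats::rnorm(ne, 0, sigma * sqrt(post$edge.length))
  vals <- numeric(nt + tree$Nnode)
  for (i in rev(seq_len(ne))) { # reverse postorder = preorder
    vals[post$edge[i, 2]] <- vals[post$edge[i, 1]] + inc[i]
  }
  stats::setNames(vals[seq_len(nt)], tree$tip.label)
}

#' Simulate species traits with tunable phylogenetic signal
#'
#' Continuous traits evolve by Brownian motion on the tree; a signal of 1
#' keeps the Brownian values, 0 shuffles them across tips, and
#' intermediate values shuffle the corresponding fraction of tips.
#' Circular month-of-flowering traits wrap a scaled Brownian latent onto
#' months 1-12; binary traits threshold a Brownian latent at its median.
#'
#' @param tree An [ape::phylo].
#' @param kinds Named character vector of trait kinds (`continuous`,
#'   `circular_month`, `binary`); the default emulates a field-typical set
#'   of height, SLA, leaf toughness, first-flowering month and two binary
#'   traits.
#' @param signal Per-trait signal in `[0, 1]`, recycled.
#' @param seed Integer seed.
#' @param missing_frac Fraction of values set missing at random.
#' @return A [trait_table()].
#' @export
simulate_traits <- function(tree,
                            kinds = c(height = "continuous",
                                      sla = "continuous",
                                      toughness = "continuous",
                                      flowering = "circular_month",
                                      nfix = "binary",
                                      clonal = "binary"),
                            signal = 1, seed = 1, missing_frac = 0) {
  if (ape::Ntip(tree) < 3) stop("need >= 3 tips")
  ok <- c("continuous", "circular_month", "binary")
  if (!all(kinds %in% ok)) {
    stop("unknown trait kind: ", paste(setdiff(kinds, ok), collapse = ", "))
  }
  set.seed(as.integer(seed))
  signal <- rep_len(signal, length(kinds))
  n <- ape::Ntip(tree)
  vals <- list()
  for (i in seq_along(kinds)) {
    latent <- sim_bm(tree)
    s <- signal[i]
    if (s < 1) {
      k <- round((1 - s) * n)
      if (k >= 2) {
        idx <- sample.int(n, k)
        latent[idx] <- latent[idx][sample.int(k)]
      }
    }
    v <- switch(kinds[[i]],
      continuous = latent,
      circular_month = (floor(latent / stats::sd(latent) * 3) %% 12) + 1,
      binary = as.numeric(latent > stats::median(latent)))
    if (missing_frac > 0) {
      v[sample.int(n, round(missing_frac * n))] <- NA
    }
    vals[[names(kinds)[i]]] <- unname(v)
  }
  trait_table(tree$tip.label, as.data.frame(vals), kinds)
}

#' Simulate plot-level communities around focal species
#'
#' Draws one small-grain community per focal species from the regional
#' pool. Each focal has its own phylogenetic assortment parameter, so
#' communities range from clusters of close relatives to overdispersed
#' assemblages; this is the habitat-filtering analogue that decouples
#' plot-level distinctiveness from whole-pool distinctiveness. Members get
#' strictly positive percent covers; a configurable fraction is flagged as
#' present without recorded cover.
#'
#' @param tree Regional phylogeny.
#' @param config A [scenario_config()].
#' @return Named list (one element per focal species) of community
#'   samples: `list(focal =, members = data.frame(species, cover),
#'   grain = "small")`, with `NA` cover marking members lacking abundance.
#' @export
simulate_communities <- function(tree, config) {
  set.seed(config$seed + 1L)
  rng <- config$community_richness_range
  if (rng[2] > ape::Ntip(tree) - 1) stop("richness range infeasible")
  pool <- tree$tip.label
  Dp <- cophenetic_matrix(tree, "sqrt")
  # focal species come from the interquartile range of pool-level MPD:
  # established aliens have resident relatives and are not phylogenetic
  # outliers of the flora
  pool_mpd <- vapply(pool, function(s) mean(Dp[s, setdiff(pool, s)]),
                     numeric(1))
  qs <- stats::quantile(pool_mpd, c(0.25, 0.75))
  candidates <- pool[pool_mpd >= qs[1] & pool_mpd <= qs[2]]
  if (length(candidates) < config$n_focal) candidates <- pool
  focals <- sort(sample(candidates, config$n_focal))
  Dp <- Dp / max(Dp)
  out <- list()
  for (f in focals) {
    r <- seq(rng[1], rng[2])[sample.int(rng[2] - rng[1] + 1L, 1)]
    others <- setdiff(pool, f)
    # habitat filtering at a random phylogenetic depth: the community is a
    # window in the focal's sorted distance spectrum, so realized
    # small-grain distinctiveness is set by the window position and is
    # largely independent of the focal's pool-level distinctiveness
    ord <- others[order(Dp[f, others])]
    start <- sample.int(length(ord) - r + 1, 1)
    members <- ord[seq(start, start + r - 1)]
    members <- sample(members) # unordered, as recorded in the field
    cover <- stats::rlnorm(r, meanlog = 0, sdlog = 1)
    cover <- 100 * cover / sum(cover)
    n_nc <- round(config$prop_no_cover * r)
    if (n_nc > 0) cover[sample.int(r, n_nc)] <- NA
    out[[f]] <- list(focal = f,
                     members = data.frame(species = members, cover = cover),
                     grain = "small")
  }
  out
}

# Solve the fecundity level that gives a target lambda (monotone in f).
solve_fecundity <- function(lambda_of_f, target) {
  stats::uniroot(function(lf) lambda_of_f(exp(lf)) - target,
                 lower = log(1e-6), upper = log(1e4), tol = 1e-10)$root
}

mpm_generating_matrix <- function(f) {
  matrix(c(0.2, 0.3,
           f, 0.6), 2, 2, byrow = FALSE,
         dimnames = list(c("juvenile", "adult"), c("juvenile", "adult")))
}

ipm_generating_coeffs <- function(fec_intercept) {
  structure(list(
    survival = c(intercept = -1.0, slope = 0.8),
    growth = c(intercept = 0.55, slope = 0.7, sd = 0.35),
    fecundity = c(intercept = fec_intercept, slope = 0.5),
    establishment = 0.01,
    recruit_size = c(mean = 0.5, sd = 0.3),
    seed_bank = NULL,
    size_range = c(-1, 4)), class = "vital_rates")
}

ipm_lambda_of_f <- function(f) {
  co <- ipm_generating_coeffs(log(f))
  spectral_radius(build_ipm_kernel(co, bounds = c(-1.5, 4.5),
                                   meshpoints = 100))
}

# Simulate one stage-structured census stratum from a generating matrix.
sim_mpm_records <- function(n, A, f, species, treatment, n_plots,
                            id_offset) {
  stages <- c("juvenile", "adult")
  stage <- sample(stages, n, replace = TRUE, prob = c(0.6, 0.4))
  rec <- data.frame(
    id = paste0(species, "_", treatment, "_", id_offset + seq_len(n)),
    species = species, treatment = treatment,
    plot = paste0(species, "_", treatment, "_p",
                  rep_len(seq_len(n_plots), n)),
    year = 1L, stage_t = stage, stage_t1 = NA_character_,
    size_t = NA_real_, size_t1 = NA_real_,
    surv = NA_real_, repro = 0)
  for (i in seq_len(n)) {
    p <- A[, rec$stage_t[i]]
    fate_probs <- c(p["juvenile"], p["adult"])
    # fecundity entry is not a transition; adults' recruit production is
    # drawn separately below
    if (rec$stage_t[i] == "adult") fate_probs["juvenile"] <- 0
    die <- max(0, 1 - sum(fate_probs))
    fate <- sample(c("juvenile", "adult", "DEAD"), 1,
                   prob = c(fate_probs, die))
    rec$stage_t1[i] <- fate
    rec$surv[i] <- as.numeric(fate != "DEAD")
  }
  adults <- rec$stage_t == "adult"
  rec$repro[adults] <- stats::rpois(sum(adults), f)
  rec
}

# Simulate one size-structured census stratum from generating coefficients.
sim_ipm_records <- function(n, coeffs, species, treatment, n_plots,
                            id_offset) {
  z <- stats::rnorm(n, 1.5, 0.7)
  eta <- coeffs$survival[["intercept"]] + coeffs$survival[["slope"]] * z
  surv <- stats::rbinom(n, 1, stats::plogis(eta))
  z1 <- ifelse(surv == 1,
               stats::rnorm(n, coeffs$growth[["intercept"]] +
                              coeffs$growth[["slope"]] * z,
                            coeffs$growth[["sd"]]),
               NA_real_)
  seeds <- stats::rpois(n, exp(coeffs$fecundity[["intercept"]] +
                                 coeffs$fecundity[["slope"]] * z))
  rec <- data.frame(
    id = paste0(species, "_", treatment, "_", id_offset + seq_len(n)),
    species = species, treatment = treatment,
    plot = paste0(species, "_", treatment, "_p",
                  rep_len(seq_len(n_plots), n)),
    year = 1L, stage_t = NA_character_, stage_t1 = NA_character_,
    size_t = z, size_t1 = z1, surv = as.numeric(surv), repro = seeds)
  n_recruits <- stats::rbinom(1, sum(seeds), coeffs$establishment)
  n_recruits <- max(2L, n_recruits) # recruit size distribution needs >= 2
  rz <- stats::rnorm(n_recruits, coeffs$recruit_size[["mean"]],
                     coeffs$recruit_size[["sd"]])
  rbind(rec, data.frame(
    id = paste0(species, "_", treatment, "_r", seq_len(n_recruits)),
    species = species, treatment = treatment,
    plot = paste0(species, "_", treatment, "_p",
                  rep_len(seq_len(n_plots), n_recruits)),
    year = 1L, stage_t = NA_character_, stage_t1 = NA_character_,
    size_t = NA_real_, size_t1 = rz, surv = NA_real_, repro = 0))
}

#' Simulate two-treatment demographic censuses with planted effects
#'
#' For each focal species, draws individual-level census records for a
#' control and a competitor-removal treatment from a known generating
#' model (stage-structured for MPM species, size-structured for IPM
#' species). Control growth rates sit near 0.9 with small lognormal
#' heterogeneity; the removal treatment's fecundity is solved so that the
#' generating log-lambda difference equals
#' `treatment_effect_slope * (max D - D_i) + noise`, with `D_i` the
#' community-driven component of the focal's small-grain mean pairwise
#' distance (square-root cophenetic scale, orthogonalized in-sample
#' against pool-level distinctiveness so the large-grain predictor is
#' uncoupled by construction). Per-plot competitor biomass is
#' lognormal(0, 0.5). The
#' generating growth rates and planted effects are returned in a
#' ground-truth table.
#'
#' @param communities Output of [simulate_communities()].
#' @param tree Regional phylogeny.
#' @param config A [scenario_config()].
#' @return List with `census` (one data frame, see [census_records]),
#'   `biomass` (per plot), `model` (named vector, `"MPM"`/`"IPM"` per
#'   species), `model_specs` (per-species model specification for
#'   refitting) and `ground_truth` (species, distinctiveness, generating
#'   lambdas, planted effect).
#' @export
simulate_demography <- function(communities, tree, config) {
  set.seed(config$seed + 2L)
  focals <- names(communities)
  Dp <- cophenetic_matrix(tree, "sqrt")
  D_i <- vapply(focals, function(f) {
    focal_distinctiveness(Dp, f, communities[[f]]$members$species,
                          metric = "MPD")
  }, numeric(1))
  # the planted coupling uses the community-driven component of
  # small-grain distinctiveness: orthogonalized in-sample against
  # pool-level distinctiveness, so the large-grain predictor is
  # uncoupled by construction
  dl_i <- vapply(focals, function(f) {
    focal_distinctiveness(Dp, f, setdiff(rownames(Dp), f), metric = "MPD")
  }, numeric(1))
  b <- stats::cov(D_i, dl_i) / stats::var(dl_i)
  V_i <- D_i - b * (dl_i - mean(dl_i))
  maxD <- max(V_i)
  # expected planted differences: linear in the community component,
  # capped to the biological regime, then re-orthogonalized so the cap's
  # nonlinearity cannot re-couple them to the large grain
  delta_exp <- pmin(config$treatment_effect_slope * (maxD - V_i),
                    config$max_planted_effect)
  if (stats::var(dl_i) > 0 && stats::sd(delta_exp) > 0) {
    b2 <- stats::cov(delta_exp, dl_i) / stats::var(dl_i)
    delta_exp <- delta_exp - b2 * (dl_i - mean(dl_i))
  }
  n_ipm <- round(config$prop_ipm * length(focals))
  model <- stats::setNames(
    rep(c("IPM", "MPM"), c(n_ipm, length(focals) - n_ipm)), focals)
  census <- list()
  truth <- list()
  specs <- list()
  biomass <- list()
  for (f in focals) {
    delta <- delta_exp[[f]] + stats::rnorm(1, 0, config$noise_sd)
    lam_c <- 0.9 * exp(stats::rnorm(1, 0, 0.05))
    lam_r <- lam_c * exp(delta)
    n <- config$n_individuals
    np <- config$n_plots_per_treatment
    if (model[[f]] == "MPM") {
      lam_of_f <- function(ff) dominant_lambda(mpm_generating_matrix(ff))
      f_c <- exp(solve_fecundity(lam_of_f, lam_c))
      f_r <- exp(solve_fecundity(lam_of_f, lam_r))
      census[[f]] <- rbind(
        sim_mpm_records(n, mpm_generating_matrix(f_c), f_c, f, "control",
                        np, 0),
        sim_mpm_records(n, mpm_generating_matrix(f_r), f_r, f, "removal",
                        np, n))
      specs[[f]] <- default_model_spec("MPM")
    } else {
      a_c <- solve_fecundity(ipm_lambda_of_f, lam_c)
      a_r <- solve_fecundity(ipm_lambda_of_f, lam_r)
      census[[f]] <- rbind(
        sim_ipm_records(n, ipm_generating_coeffs(a_c), f, "control", np, 0),
        sim_ipm_records(n, ipm_generating_coeffs(a_r), f, "removal", np, n))
      sp <- default_model_spec("IPM")
      sp$meshpoints <- 100
      specs[[f]] <- sp
    }
    plots <- unique(census[[f]]$plot)
    biomass[[f]] <- data.frame(
      species = f, plot = plots,
      treatment = ifelse(grepl("removal", plots), "removal", "control"),
      biomass = stats::rlnorm(length(plots), 0, 0.5))
    truth[[f]] <- data.frame(
      species = f, model = model[[f]], distinctiveness = D_i[[f]],
      distinctiveness_large = dl_i[[f]], planted_variable = V_i[[f]],
      lambda_control = lam_c, lambda_removal = lam_r,
      planted_log_ratio = delta,
      planted_effect = effect_size_of_competition(lam_r, lam_c))
  }
  list(census = do.call(rbind, c(census, make.row.names = FALSE)),
       biomass = do.call(rbind, c(biomass, make.row.names = FALSE)),
       model = model, model_specs = specs,
       ground_truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

#' Simulate a complete synthetic scenario
#'
#' Convenience wrapper: phylogeny, traits, communities and demography from
#' one [scenario_config()].
#'
#' @param config A [scenario_config()].
#' @return List with `tree`, `traits`, `communities` and the elements of
#'   [simulate_demography()]'s bundle.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  tree <- simulate_phylogeny(config$n_regional_species, seed = config$seed,
                             depth = config$tree_depth,
                             congener_fraction = config$congener_fraction)
  traits <- simulate_traits(tree, signal = config$trait_signal,
                            seed = config$seed + 3L)
  communities <- simulate_communities(tree, config)
  demo <- simulate_demography(communities, tree, config)
  c(list(tree = tree, traits = traits, communities = communities,
         config = config), demo)
}

#' Write a synthetic scenario to disk
#'
#' Writes the Newick tree and tab-separated tables (communities, traits,
#' census, biomass, ground truth) to a directory.
#'
#' @param bundle Output of [simulate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(bundle$tree, file.path(dir, "tree.nwk"))
  comm <- do.call(rbind, lapply(bundle$communities, function(cm) {
    data.frame(focal = cm$focal, species = cm$members$species,
               cover = cm$members$cover, grain = cm$grain)
  }))
  tw <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tw(comm, "communities.tsv")
  tr <- data.frame(species = rownames(bundle$traits),
                   as.data.frame(bundle$traits))
  tw(tr, "traits.tsv")
  tw(data.frame(trait = names(trait_kinds(bundle$traits)),
                kind = unname(trait_kinds(bundle$traits))),
     "trait_kinds.tsv")
  tw(bundle$census, "census.tsv")
  tw(bundle$biomass, "biomass.tsv")
  tw(bundle$ground_truth, "ground_truth.tsv")
  invisible(dir)
}
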