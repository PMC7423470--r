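# Shared fixtures, all built in code.

# ((A:1,B:1):1,C:2); -- depth-2 ultrametric three-tip tree
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# balanced eight-tip ultrametric tree, depth 4
tree8 <- function() {
  txt <- paste0("(((t1:1,t2:1):1,(t3:1,t4:1):1):2,",
                "((t5:1,t6:1):1,(t7:1,t8:1):1):2);")
  ape::read.tree(text = txt)
}

# independent cophenetic oracle: sum branch lengths along the node path
path_sum_dist <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  path <- ape::nodepath(tree, ia, ib)
  s <- 0
  for (k in seq_len(length(path) - 1)) {
    e <- which((tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1]) |
                 (tree$edge[, 2] == path[k] & tree$edge[, 1] == path[k + 1]))
    s <- s + tree$edge.length[e]
  }
  s
}

# stage-structured census where exact counts are controlled
make_stage_records <- function(stage_t, stage_t1, repro = 0,
                               treatment = "control", species = "sp") {
  n <- length(stage_t)
  data.frame(id = paste0("i", seq_len(n)), species = species,
             treatment = treatment, plot = "p1", year = 1L,
             stage_t = stage_t, stage_t1 = stage_t1,
             size_t = NA_real_, size_t1 = NA_real_,
             surv = as.numeric(stage_t1 != "DEAD"),
             repro = rep_len(repro, n))
}

# size-structured census drawn from known vital-rate coefficients
make_size_records <- function(n, surv_coef = c(0.5, 0.6),
                              growth_coef = c(0.8, 0.7), growth_sd = 0.3,
                              fec_coef = c(3.5, 0.4), establishment = 0.02,
                              recruit = c(0.4, 0.25),
                              treatment = "control", species = "sp") {
  z <- stats::rnorm(n, 1.5, 0.8)
  surv <- stats::rbinom(n, 1, stats::plogis(surv_coef[1] + surv_coef[2] * z))
  z1 <- ifelse(surv == 1,
               stats::rnorm(n, growth_coef[1] + growth_coef[2] * z,
                            growth_sd), NA_real_)
  seeds <- stats::rpois(n, exp(fec_coef[1] + fec_coef[2] * z))
  rec <- data.frame(id = paste0("i", seq_len(n)), species = species,
                    treatment = treatment, plot = "p1", year = 1L,
                    stage_t = NA_character_, stage_t1 = NA_character_,
                    size_t = z, size_t1 = z1, surv = as.numeric(surv),
                    repro = seeds)
  nr <- max(2L, stats::rbinom(1, sum(seeds), establishment))
  rbind(rec, data.frame(
    id = paste0("r", seq_len(nr)), species = species,
    treatment = treatment, plot = "p1", year = 1L,
    stage_t = NA_character_, stage_t1 = NA_character_, size_t = NA_real_,
    size_t1 = stats::rnorm(nr, recruit[1], recruit[2]),
    surv = NA_real_, repro = 0))
}

# vital-rate coefficient object without fitting
make_vital_rates <- function(survival = c(intercept = 0.5, slope = 0),
                             growth = c(intercept = 0.3, slope = 0.8,
                                        sd = 0.3),
                             fecundity = c(intercept = -Inf, slope = 0),
                             establishment = 1,
                             recruit_size = c(mean = 0.5, sd = 0.3),
                             seed_bank = NULL, size_range = c(-1, 4)) {
  structure(list(survival = survival, growth = growth,
                 fecundity = fecundity, establishment = establishment,
                 recruit_size = recruit_size, seed_bank = seed_bank,
                 size_range = size_range), class = "vital_rates")
}

# small mixed-type trait table used across gower tests
mixed_traits <- function() {
  trait_table(
    species = c("s1", "s2", "s3", "s4"),
    values = data.frame(
      height = c(1, 2, 3, 4),
      sla = c(10, 20, 30, 40),
      flowering = c(1, 12, 6, 7),
      nfix = c(0, 1, 0, 1)),
    kinds = c(height = "continuous", sla = "continuous",
              flowering = "circular_month", nfix = "binary"))
}
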