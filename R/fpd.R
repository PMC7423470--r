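#' Combine phylogenetic and functional distances
#'
#' Weighted Euclidean combination of a phylogenetic and a functional
#' distance matrix: `FPD = sqrt(a * PD^2 + (1 - a) * FD^2)`, with `a = 1`
#' purely phylogenetic and `a = 0` purely functional. Because the two
#' matrices live on different scales, each is first divided by its own
#' maximum off-diagonal entry (`standardization = "max_scale"`, the
#' default) so the weighting is meaningful; pass `"none"` to combine raw
#' matrices.
#'
#' @param PD,FD Symmetric distance matrices over the same label set.
#' @param a Phylogenetic weight in `[0, 1]`.
#' @param standardization `"max_scale"` or `"none"`.
#' @return Combined distance matrix (labels in `PD` order).
#' @export
combine_fpd <- function(PD, FD, a,
                        standardization = c("max_scale", "none")) {
  standardization <- match.arg(standardization)
  if (a < 0 || a > 1) stop("a must be in [0, 1]")
  lab <- rownames(PD)
  if (is.null(lab) || is.null(rownames(FD)) ||
      !setequal(lab, rownames(FD))) {
    stop("PD and FD must share the same label set")
  }
  FD <- FD[lab, lab]
  PD <- PD[lab, lab] # strips attributes via subsetting
  if (standardization == "max_scale") {
    mp <- max(PD[upper.tri(PD)])
    mf <- max(FD[upper.tri(FD)])
    if (mp == 0 || mf == 0) stop("all-zero matrix cannot be max-scaled")
    PD <- PD / mp
    FD <- FD / mf
  }
  out <- sqrt(a * PD^2 + (1 - a) * FD^2)
  dimnames(out) <- list(lab, lab)
  out
}

adj_r2 <- function(r2, n, p) 1 - (1 - r2) * (n - 1) / (n - p - 1)

#' Regress competition effect sizes on distinctiveness and biomass
#'
#' Ordinary least squares of the per-species effect size of competitor
#' removal on a distinctiveness metric and the z-scored competitor
#' biomass.
#'
#' @param effect_sizes Named numeric vector (one value per species).
#' @param distinctiveness Numeric vector aligned with `effect_sizes`.
#' @param biomass Numeric vector aligned with `effect_sizes`; z-scored
#'   internally.
#' @return List with `coefficients` (intercept, distinctiveness, biomass),
#'   `adj_r2`, `r2`, `n`, `residuals`.
#' @export
regress_effect_size <- function(effect_sizes, distinctiveness, biomass) {
  n <- length(effect_sizes)
  if (length(distinctiveness) != n || length(biomass) != n) {
    stop("inputs must have equal length")
  }
  if (n < 4) stop("need n >= 4 species (2 predictors + intercept + 1)")
  if (stats::sd(distinctiveness) == 0 || stats::sd(biomass) == 0) {
    stop("constant predictor")
  }
  bz <- (biomass - mean(biomass)) / stats::sd(biomass)
  X <- cbind(intercept = 1, distinctiveness = distinctiveness,
             biomass = bz)
  if (qr(X)$rank < 3) stop("rank-deficient design")
  fit <- stats::lm.fit(X, effect_sizes)
  rss <- sum(fit$residuals^2)
  tss <- sum((effect_sizes - mean(effect_sizes))^2)
  r2 <- 1 - rss / tss
  list(coefficients = fit$coefficients,
       adj_r2 = adj_r2(r2, n, 2), r2 = r2, n = n,
       residuals = fit$residuals)
}

#' Sweep the phylogenetic weighting parameter
#'
#' For each value of `a` on a regular grid over `[0, 1]`, combines each
#' focal species' community-level phylogenetic and functional distance
#' matrices, recomputes the focal's distinctiveness from the combined
#' matrix, refits the effect-size regression, and records the adjusted R².
#' The grid endpoints reproduce the phylogeny-only (`a = 1`) and
#' traits-only (`a = 0`) models.
#'
#' @param PD_list,FD_list Named lists (one per focal species) of
#'   community-level distance matrices, each containing the focal and its
#'   co-occurring species.
#' @param communities Community samples as from [simulate_communities()]
#'   (used for member sets and cover weights).
#' @param effect_sizes,biomass Named per-species vectors (names matching
#'   `PD_list`).
#' @param metric Distinctiveness metric passed to
#'   [focal_distinctiveness()].
#' @param a_step Grid increment; must divide 1 exactly (default 0.025,
#'   a 41-point grid).
#' @param standardization Passed to [combine_fpd()] (applied per
#'   community).
#' @return Data frame with one row per grid point (`a`, coefficients,
#'   `adj_r2`) and attributes `best_a` and `best_adj_r2` (arg-max at grid
#'   resolution).
#' @export
sweep_a <- function(PD_list, FD_list, communities, effect_sizes, biomass,
                    metric = "MPD", a_step = 0.025,
                    standardization = "max_scale") {
  m <- round(1 / a_step)
  if (abs(1 / a_step - m) > 1e-12) stop("a_step must divide 1 exactly")
  focals <- names(PD_list)
  grid <- (0:m) / m
  rows <- lapply(grid, function(a) {
    d <- vapply(focals, function(f) {
      FPD <- combine_fpd(PD_list[[f]], FD_list[[f]], a, standardization)
      mem <- intersect(communities[[f]]$members$species, rownames(FPD))
      w <- NULL
      if (metric %in% c("AW_MPD", "AW_NND")) {
        w <- communities[[f]]$members$cover[
          match(mem, communities[[f]]$members$species)]
      }
      focal_distinctiveness(FPD, f, mem, weights = w, metric = metric)
    }, numeric(1))
    fit <- regress_effect_size(effect_sizes[focals], d, biomass[focals])
    data.frame(a = a,
               intercept = fit$coefficients[["intercept"]],
               slope = fit$coefficients[["distinctiveness"]],
               biomass_slope = fit$coefficients[["biomass"]],
               adj_r2 = fit$adj_r2)
  })
  out <- do.call(rbind, rows)
  best <- which.max(out$adj_r2)
  attr(out, "best_a") <- out$a[best]
  attr(out, "best_adj_r2") <- out$adj_r2[best]
  out
}

#' Propagate demographic uncertainty into the regression
#'
#' Refits the effect-size regression once per demographic bootstrap
#' replicate: replicate `b` regresses the `b`-th bootstrap effect-size
#' draw of every species on the fixed predictors. 95% confidence
#' intervals are the 2.5 and 97.5 percentiles of each coefficient and of
#' the adjusted R² across replicates.
#'
#' @param effect_size_draws Matrix (species x replicates) of bootstrap
#'   effect sizes, rownames = species.
#' @param distinctiveness,biomass Named per-species vectors.
#' @param n_boot Number of replicates to use (default all columns).
#' @param seed Unused placeholder for interface stability; the procedure
#'   is deterministic given the draws.
#' @return List with `draws` (data frame of per-replicate coefficients and
#'   adj R²), `ci` (2.5/97.5 percentile bounds per quantity), and
#'   `observed` if point-estimate effect sizes are supplied via
#'   `point_effect_sizes`.
#' @param point_effect_sizes Optional named vector of point-estimate
#'   effect sizes for the observed-value row.
#' @export
bootstrap_regression <- function(effect_size_draws, distinctiveness,
                                 biomass, n_boot = ncol(effect_size_draws),
                                 seed = NULL, point_effect_sizes = NULL) {
  if (ncol(effect_size_draws) < n_boot) {
    stop("need >= n_boot effect-size draws per species")
  }
  sp <- rownames(effect_size_draws)
  draws <- lapply(seq_len(n_boot), function(b) {
    fit <- regress_effect_size(effect_size_draws[sp, b],
                               distinctiveness[sp], biomass[sp])
    data.frame(intercept = fit$coefficients[["intercept"]],
               slope = fit$coefficients[["distinctiveness"]],
               biomass_slope = fit$coefficients[["biomass"]],
               adj_r2 = fit$adj_r2)
  })
  draws <- do.call(rbind, draws)
  ci <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975)))
  colnames(ci) <- c("lower", "upper")
  out <- list(draws = draws, ci = ci)
  if (!is.null(point_effect_sizes)) {
    fit <- regress_effect_size(point_effect_sizes[sp],
                               distinctiveness[sp], biomass[sp])
    out$observed <- c(fit$coefficients, adj_r2 = fit$adj_r2)
  }
  out
}
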