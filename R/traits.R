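#' Construct a mixed-type trait table
#'
#' A trait table is a data frame of species-level trait values carrying a
#' `kinds` attribute that declares how each trait enters the Gower distance:
#' `continuous` (any units; range-normalised), `circular_month` (month of
#' first flowering, 1-12), `binary` (0/1) or `categorical` (label, expanded
#' to dummy variables that share one trait weight). Missing values are `NA`.
#'
#' @param species Character vector of species names.
#' @param values Data frame (one column per trait) aligned with `species`.
#' @param kinds Named character vector mapping every trait to its kind.
#' @return A `trait_table`: the data frame with rownames `species` and
#'   attribute `kinds`.
#' @export
trait_table <- function(species, values, kinds) {
  values <- as.data.frame(values)
  if (length(species) != nrow(values)) stop("species/values length mismatch")
  if (anyDuplicated(species)) stop("duplicate species")
  bad <- setdiff(names(values), names(kinds))
  if (length(bad) > 0) stop("traits without a declared kind: ",
                            paste(bad, collapse = ", "))
  ok <- c("continuous", "circular_month", "binary", "categorical")
  if (!all(kinds %in% ok)) {
    stop("unknown trait kind: ", paste(setdiff(kinds, ok), collapse = ", "))
  }
  for (tr in names(values)) {
    v <- values[[tr]]
    if (kinds[[tr]] == "circular_month" &&
        !all(is.na(v) | (v >= 1 & v <= 12))) {
      stop("circular_month trait '", tr, "' outside [1, 12]")
    }
    if (kinds[[tr]] == "binary" && !all(is.na(v) | v %in% c(0, 1))) {
      stop("binary trait '", tr, "' not in {0, 1}")
    }
  }
  rownames(values) <- species
  attr(values, "kinds") <- kinds[names(values)]
  class(values) <- c("trait_table", "data.frame")
  values
}

trait_kinds <- function(table) attr(table, "kinds")

#' Screen out highly correlated continuous traits
#'
#' Computes pairwise Pearson correlations among the continuous traits and,
#' for every pair exceeding the threshold in absolute value, drops the
#' later-listed trait. Constant traits have undefined correlations and are
#' flagged and excluded up front.
#'
#' @param table A [trait_table()].
#' @param threshold Absolute correlation above which the later trait of a
#'   pair is dropped. Default 0.8.
#' @return List with `retained` (all trait names that survive, including
#'   non-continuous traits), `dropped`, `constant`, and `report` (a data
#'   frame of all screened pairs with their correlation and decision).
#' @export
correlation_screen <- function(table, threshold = 0.8) {
  kinds <- trait_kinds(table)
  cont <- names(kinds)[kinds == "continuous"]
  if (length(cont) < 2) stop("need >= 2 continuous traits to screen")
  constant <- cont[vapply(cont, function(tr) {
    v <- table[[tr]][!is.na(table[[tr]])]
    length(unique(v)) < 2
  }, logical(1))]
  cont <- setdiff(cont, constant)
  dropped <- character(0)
  rows <- list()
  if (length(cont) >= 2) {
    for (i in seq_len(length(cont) - 1)) {
      for (j in seq(i + 1, length(cont))) {
        a <- cont[i]; b <- cont[j]
        if (a %in% dropped || b %in% dropped) next
        r <- stats::cor(table[[a]], table[[b]],
                        use = "pairwise.complete.obs")
        drop_b <- is.finite(r) && abs(r) > threshold
        if (drop_b) dropped <- c(dropped, b)
        rows[[length(rows) + 1]] <- data.frame(
          trait_1 = a, trait_2 = b, r = r,
          dropped = if (drop_b) b else NA_character_)
      }
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trait_1 = character(0), trait_2 = character(0),
               r = numeric(0), dropped = character(0))
  list(retained = setdiff(names(kinds), c(dropped, constant)),
       dropped = dropped, constant = constant, report = report)
}

# Per-trait dissimilarity matrices in [0, 1]; categorical traits contribute a
# block of dummy columns sharing one unit of weight.
gower_components <- function(table, traits) {
  kinds <- trait_kinds(table)
  n <- nrow(table)
  comps <- list()
  for (tr in traits) {
    v <- table[[tr]]
    kind <- kinds[[tr]]
    obs <- outer(!is.na(v), !is.na(v), "&")
    if (kind == "continuous") {
      rng <- diff(range(v, na.rm = TRUE))
      # zero range leaves the normalisation undefined: the trait carries
      # no information and is excluded (discrete constants, whose
      # dissimilarity is a well-defined 0, are kept)
      if (rng == 0) next
      d <- abs(outer(v, v, "-")) / rng
      comps[[tr]] <- list(d = d, obs = obs, weight_share = 1)
    } else if (kind == "circular_month") {
      gap <- abs(outer(v, v, "-"))
      d <- pmin(gap, 12 - gap) / 6
      comps[[tr]] <- list(d = d, obs = obs, weight_share = 1)
    } else if (kind == "binary") {
      d <- abs(outer(v, v, "-"))
      comps[[tr]] <- list(d = d, obs = obs, weight_share = 1)
    } else { # categorical: dummy expansion, weight split over dummies
      lev <- sort(unique(v[!is.na(v)]))
      for (lv in lev) {
        b <- as.numeric(v == lv)
        d <- abs(outer(b, b, "-"))
        comps[[paste0(tr, "=", lv)]] <-
          list(d = d, obs = obs, weight_share = 1 / length(lev))
      }
    }
  }
  comps
}

#' Mixed-type Gower distance with circular variables
#'
#' Functional distance between species from traits of mixed kinds, following
#' the Gower framework extended to circular variables. Per-trait
#' dissimilarities are scaled to `[0, 1]`: continuous traits by
#' `|difference| / observed range`; flowering month by the circular gap
#' `min(|d|, 12 - |d|) / 6` (so January and December are 1/6 apart, not
#' maximally distant); binary and dummy-expanded categorical traits by 0/1
#' mismatch. The distance between two species is the weighted mean of the
#' per-trait dissimilarities over traits observed in *both* species
#' (pairwise deletion with renormalised weights); a categorical trait's
#' weight is split equally over its dummy variables.
#'
#' @param table A [trait_table()].
#' @param traits Trait names to use; default all.
#' @param weights Optional positive per-trait weights, named or parallel to
#'   `traits`; default equal.
#' @return Symmetric distance matrix in `[0, 1]` with species dimnames and
#'   `transform` attribute `"gower"`.
#' @export
gower_distance <- function(table, traits = NULL, weights = NULL) {
  kinds <- trait_kinds(table)
  if (is.null(traits)) traits <- names(kinds)
  unknown <- setdiff(traits, names(kinds))
  if (length(unknown) > 0) stop("unknown traits: ",
                                paste(unknown, collapse = ", "))
  if (nrow(table) < 2) stop("need >= 2 species")
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(traits)),
                                                   traits)
  if (is.null(names(weights))) names(weights) <- traits
  if (any(weights <= 0)) stop("weights must be positive")
  comps <- gower_components(table, traits)
  n <- nrow(table)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (nm in names(comps)) {
    cmp <- comps[[nm]]
    w <- weights[[sub("=.*$", "", nm)]] * cmp$weight_share
    ok <- cmp$obs
    d <- cmp$d
    d[!ok] <- 0
    num <- num + w * d
    den <- den + w * ok
  }
  if (any(den[upper.tri(den)] == 0)) {
    idx <- which(den == 0 & upper.tri(den), arr.ind = TRUE)[1, ]
    stop("species pair with no shared non-missing traits: ",
         rownames(table)[idx[1]], " / ", rownames(table)[idx[2]])
  }
  D <- num / den
  diag(D) <- 0
  dimnames(D) <- list(rownames(table), rownames(table))
  attr(D, "transform") <- "gower"
  D
}

# Align a named trait vector with the tree's tips; errors on mismatch < 4.
match_tree_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait vector must be named by species")
  common <- intersect(tree$tip.label, names(trait)[!is.na(trait)])
  if (length(common) < 4) stop("need >= 4 species shared by tree and trait")
  tree <- if (length(common) < ape::Ntip(tree)) {
    ape::keep.tip(tree, common)
  } else tree
  list(tree = tree, x = trait[tree$tip.label])
}

#' Blomberg's K with a permutation test
#'
#' Phylogenetic signal for a continuous trait: the ratio of observed to
#' Brownian-motion-expected `MSE0 / MSE`, where `MSE0` is the trait variance
#' about the phylogenetically corrected mean and `MSE` the
#' variance-covariance-corrected mean squared error. `K = 1` is the
#' Brownian-motion expectation on the given tree; `K < 1` less signal,
#' `K > 1` more. Significance comes from tip-label permutations: signal
#' makes the observed `MSE` small, so the p-value is the add-one-corrected
#' proportion of permutations with `MSE` at or below the observed.
#'
#' @param tree An [ape::phylo].
#' @param trait Named numeric vector (names are species).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `statistic = "K"`, `value`, `p_value`, `n_perm`.
#' @export
blombergs_K <- function(tree, trait, n_perm = 999, seed = 1) {
  m <- match_tree_trait(tree, trait)
  x <- m$x
  n <- length(x)
  if (stats::sd(x) == 0) stop("trait is constant")
  C <- ape::vcv(m$tree)
  W <- solve(C)
  one <- rep(1, n)
  wsum <- as.numeric(one %*% W %*% one)
  mse_of <- function(xx) {
    a <- as.numeric(one %*% W %*% xx) / wsum
    r <- xx - a
    as.numeric(r %*% W %*% r) / (n - 1)
  }
  mse0_of <- function(xx) {
    a <- as.numeric(one %*% W %*% xx) / wsum
    sum((xx - a)^2) / (n - 1)
  }
  obs_ratio <- mse0_of(x) / mse_of(x)
  exp_ratio <- (sum(diag(C)) - n / wsum) / (n - 1)
  K <- obs_ratio / exp_ratio
  if (n_perm == 0) {
    return(list(statistic = "K", value = K, p_value = NA_real_,
                n_perm = 0L))
  }
  set.seed(as.integer(seed))
  # Vectorised permutation MSEs: one matrix of permuted traits.
  P <- vapply(seq_len(n_perm), function(i) x[sample.int(n)], numeric(n))
  WP <- W %*% P
  a_p <- as.numeric(one %*% WP) / wsum
  mse_p <- (colSums(P * WP) - 2 * a_p * colSums(WP) + a_p^2 * wsum) / (n - 1)
  obs_mse <- mse_of(x)
  p <- (1 + sum(mse_p <= obs_mse)) / (n_perm + 1)
  list(statistic = "K", value = K, p_value = p, n_perm = n_perm)
}

# Precompute the traversal of a tree once; the returned closure sums
# |parent - child| state changes over edges, with internal-node states the
# unweighted means of their daughters' (post-order averaging).
state_change_calculator <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  kids <- split(post$edge[, 2], post$edge[, 1])
  ord <- unique(post$edge[, 1]) # postorder: children before parents
  kids <- kids[as.character(ord)]
  parents <- post$edge[, 1]
  children <- post$edge[, 2]
  tips <- tree$tip.label
  function(x) {
    vals <- c(x[tips], numeric(nn))
    for (i in seq_along(ord)) {
      vals[ord[i]] <- mean(vals[kids[[i]]])
    }
    sum(abs(vals[parents] - vals[children]))
  }
}

sum_state_changes <- function(tree, x) state_change_calculator(tree)(x)

#' Fritz-Purvis D for binary traits
#'
#' Phylogenetic signal for a 0/1 trait as the position of the observed sum
#' of state changes between the expectations under two reference models:
#' `D = (d_obs - mean d_BM) / (mean d_random - mean d_BM)`, where `d` is the
#' sum over edges of the absolute change in estimated nodal state, `d_BM`
#' comes from thresholded Brownian simulations preserving the observed
#' prevalence, and `d_random` from tip shuffles. `D` is about 0 for a trait
#' evolved by thresholded Brownian motion and about 1 for a phylogenetically
#' random trait; strongly clumped traits give `D < 0`, overdispersed ones
#' `D > 1`.
#'
#' @param tree An [ape::phylo].
#' @param trait Named 0/1 vector with both states present.
#' @param n_sim Simulations per reference model (default 1000).
#' @param seed Integer seed.
#' @return List with `statistic = "D"`, `value`, `p_value` (vs the random
#'   model, one-tailed towards clumping), `p_vs_bm`, `p_vs_random`, `n_sim`.
#' @export
fritz_purvis_D <- function(tree, trait, n_sim = 1000, seed = 1) {
  m <- match_tree_trait(tree, trait)
  x <- m$x
  if (length(unique(x)) < 2) stop("trait is monomorphic")
  if (!all(x %in% c(0, 1))) stop("trait must be binary 0/1")
  tree <- m$tree
  n <- length(x)
  k1 <- sum(x)
  calc <- state_change_calculator(tree)
  d_obs <- calc(x)
  set.seed(as.integer(seed))
  d_rand <- vapply(seq_len(n_sim), function(i) {
    xx <- stats::setNames(x[sample.int(n)], names(x))
    calc(xx)
  }, numeric(1))
  C_chol <- chol(ape::vcv(tree))
  d_bm <- vapply(seq_len(n_sim), function(i) {
    latent <- as.numeric(t(C_chol) %*% stats::rnorm(n))
    # threshold preserving the observed prevalence
    xx <- stats::setNames(as.numeric(rank(latent, ties.method = "first") >
                                       n - k1), tree$tip.label)
    calc(xx)
  }, numeric(1))
  D <- (d_obs - mean(d_bm)) / (mean(d_rand) - mean(d_bm))
  list(statistic = "D", value = D,
       p_value = (1 + sum(d_rand <= d_obs)) / (n_sim + 1),
       p_vs_bm = (1 + sum(d_bm >= d_obs)) / (n_sim + 1),
       p_vs_random = (1 + sum(d_rand <= d_obs)) / (n_sim + 1),
       n_sim = n_sim)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries of two
#' distance matrices sharing a label set, with significance from permuting
#' the labels of the second matrix. One-tailed for positive association,
#' with the add-one correction so p is never 0.
#'
#' @param D1,D2 Symmetric distance matrices with identical dimnames sets.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed.
#' @return List with `statistic = "mantel_r"`, `value`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = 1) {
  lab <- rownames(D1)
  if (is.null(lab) || is.null(rownames(D2))) stop("matrices must be labelled")
  if (!setequal(lab, rownames(D2))) stop("label sets differ")
  if (length(lab) < 4) stop("need >= 4 labels")
  D2 <- D2[lab, lab]
  lt <- lower.tri(D1)
  v1 <- D1[lt]
  if (stats::sd(v1) == 0 || stats::sd(D2[lt]) == 0) {
    stop("zero variance in a distance triangle")
  }
  r_obs <- stats::cor(v1, D2[lt])
  set.seed(as.integer(seed))
  n <- length(lab)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(v1, D2[p, p][lt])
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  list(statistic = "mantel_r", value = r_obs, p_value = p, n_perm = n_perm)
}
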