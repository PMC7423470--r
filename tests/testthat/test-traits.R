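test_that("trait tables validate kinds and ranges", {
  expect_error(trait_table("a", data.frame(x = 1), c(x = "odd")), "unknown")
  expect_error(trait_table(c("a", "b"),
                           data.frame(m = c(0, 5)),
                           c(m = "circular_month")), "outside")
  expect_error(trait_table(c("a", "b"), data.frame(b = c(0, 2)),
                           c(b = "binary")), "not in")
  tt <- mixed_traits()
  expect_s3_class(tt, "trait_table")
  expect_named(fpdist:::trait_kinds(tt),
               c("height", "sla", "flowering", "nfix"))
})

test_that("correlation screen drops the later trait of correlated pairs", {
  tt <- trait_table(
    paste0("s", 1:20),
    data.frame(a = 1:20, b = (1:20) * 2 + 0.0001 * rnorm(20),
               c = rnorm(20), k = rep(1, 20)),
    c(a = "continuous", b = "continuous", c = "continuous",
      k = "continuous"))
  res <- correlation_screen(tt, threshold = 0.8)
  expect_equal(res$dropped, "b")
  expect_equal(res$constant, "k")
  expect_true(all(c("a", "c") %in% res$retained))
  # threshold 1: nothing dropped
  res1 <- correlation_screen(tt, threshold = 1)
  expect_length(res1$dropped, 0)
  expect_s3_class(res$report, "data.frame")
})

test_that("independent traits survive the screen", {
  set.seed(14)
  hits <- replicate(50, {
    tt <- trait_table(paste0("s", 1:100),
                      data.frame(a = rnorm(100), b = rnorm(100)),
                      c(a = "continuous", b = "continuous"))
    length(correlation_screen(tt, 0.8)$dropped)
  })
  expect_equal(mean(hits == 0), 1)
})

test_that("gower distance matches hand-computed mixed-type examples", {
  # identical trait vectors -> 0
  tt <- trait_table(c("a", "b", "c"),
                    data.frame(x = c(1, 1, 3), y = c(0, 0, 1)),
                    c(x = "continuous", y = "binary"))
  expect_equal(unname(gower_distance(tt)["a", "b"]), 0)

  # two binary traits, one mismatch -> 0.5
  tb <- trait_table(c("a", "b"), data.frame(x = c(0, 1), y = c(1, 1)),
                    c(x = "binary", y = "binary"))
  expect_equal(unname(gower_distance(tb)["a", "b"]), 0.5)

  # months 1 vs 12: circular gap 1 -> 1/6
  tm <- trait_table(c("a", "b"), data.frame(m = c(1, 12)),
                    c(m = "circular_month"))
  expect_equal(unname(gower_distance(tm)["a", "b"]), 1 / 6,
               tolerance = 1e-12)

  # mixed example by hand: continuous |2-1|/range(3) = 1/3, binary 1,
  # equal weights -> (1/3 + 1) / 2
  tx <- trait_table(c("a", "b", "c"),
                    data.frame(x = c(1, 2, 4), y = c(0, 1, 0)),
                    c(x = "continuous", y = "binary"))
  expect_equal(unname(gower_distance(tx)["a", "b"]), (1 / 3 + 1) / 2,
               tolerance = 1e-12)

  # categorical: dummies share one trait weight
  tc <- trait_table(c("a", "b"),
                    data.frame(g = c("tree", "herb"), y = c(0, 0)),
                    c(g = "categorical", y = "binary"))
  # g expands to two dummies each mismatching (1), weight 1/2 each;
  # distance = (0.5 * 1 + 0.5 * 1 + 1 * 0) / (0.5 + 0.5 + 1) = 0.5
  expect_equal(unname(gower_distance(tc)["a", "b"]), 0.5)
})

test_that("gower handles missing values by pairwise deletion", {
  tt <- trait_table(c("a", "b", "c"),
                    data.frame(x = c(1, NA, 3), y = c(0, 1, 1)),
                    c(x = "continuous", y = "binary"))
  D <- gower_distance(tt)
  expect_equal(unname(D["a", "b"]), 1) # only binary shared
  expect_equal(unname(D["a", "c"]), (1 + 1) / 2)
  tt2 <- trait_table(c("a", "b"),
                     data.frame(x = c(1, NA), y = c(NA, 1)),
                     c(x = "continuous", y = "continuous"))
  expect_error(gower_distance(tt2), "no shared")
})

test_that("gower invariants: bounds, symmetry, rotation, inert traits", {
  tt <- mixed_traits()
  D <- gower_distance(tt)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 4))

  # rotating all months by a constant leaves distances unchanged
  rot <- mixed_traits()
  rot$flowering <- ((rot$flowering + 4 - 1) %% 12) + 1
  expect_equal(gower_distance(rot), D, tolerance = 1e-12)

  # adding a trait identical across species changes nothing
  aug <- cbind(as.data.frame(tt), same = 1)
  aug_t <- trait_table(rownames(tt), aug,
                       c(fpdist:::trait_kinds(tt), same = "continuous"))
  expect_equal(unname(gower_distance(aug_t)), unname(D), tolerance = 1e-12)
})

test_that("Blomberg's K is exactly 1 on a star tree and matches picante", {
  star <- ape::read.tree(text = "(a:2,b:2,c:2,d:2,e:2);")
  set.seed(3)
  x <- stats::setNames(rnorm(5), star$tip.label)
  res <- blombergs_K(star, x, n_perm = 99, seed = 1)
  expect_equal(res$value, 1, tolerance = 1e-10)

  skip_if_not_installed("picante")
  tr <- simulate_phylogeny(25, seed = 8)
  y <- fpdist:::sim_bm(tr)
  ours <- blombergs_K(tr, y, n_perm = 0)$value
  theirs <- picante::Kcalc(y[tr$tip.label], tr)
  expect_equal(ours, as.numeric(theirs), tolerance = 1e-8)
})

test_that("K permutation p-value detects strong signal and is deterministic", {
  tr <- simulate_phylogeny(40, seed = 9)
  y <- fpdist:::sim_bm(tr)
  r1 <- blombergs_K(tr, y, n_perm = 199, seed = 2)
  r2 <- blombergs_K(tr, y, n_perm = 199, seed = 2)
  expect_identical(r1$p_value, r2$p_value)
  expect_lt(r1$p_value, 0.05)
  expect_error(blombergs_K(tr, stats::setNames(rep(1, 40), tr$tip.label)),
               "constant")
})

test_that("clade-clustered binary traits give negative D", {
  tr <- tree8()
  x <- stats::setNames(c(1, 1, 1, 1, 0, 0, 0, 0), tr$tip.label)
  # hand oracle for the observed sum of changes: node means are 1 and 0 in
  # the two clades, 0.5 at the root; only the two root edges change
  expect_equal(fpdist:::sum_state_changes(tr, x), 1)
  res <- fritz_purvis_D(tr, x, n_sim = 300, seed = 4)
  expect_lt(res$value, 0)
  expect_error(fritz_purvis_D(tr, stats::setNames(rep(1, 8), tr$tip.label)),
               "monomorphic")
})

test_that("mantel r equals 1 for identical or rescaled matrices", {
  tr <- simulate_phylogeny(12, seed = 5)
  D1 <- cophenetic_matrix(tr, "sqrt")
  expect_equal(mantel_test(D1, D1, n_perm = 49, seed = 1)$value, 1)
  expect_equal(mantel_test(D1, 2 * D1, n_perm = 49, seed = 1)$value, 1)
  Z <- D1 * 0
  expect_error(mantel_test(D1, Z, n_perm = 9), "variance")

  skip_if_not_installed("vegan")
  set.seed(6)
  M <- as.matrix(stats::dist(matrix(rnorm(24), 12)))
  dimnames(M) <- dimnames(D1)
  ours <- mantel_test(D1, M, n_perm = 99, seed = 3)$value
  theirs <- vegan::mantel(stats::as.dist(D1), stats::as.dist(M),
                          permutations = 5)$statistic
  expect_equal(ours, as.numeric(theirs), tolerance = 1e-10)
})
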