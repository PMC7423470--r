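test_that("MPM entries are observed transition frequencies", {
  # 10 in A: 5 -> B, 5 die
  rec <- make_stage_records(rep("A", 10),
                            c(rep("B", 5), rep("DEAD", 5)))
  rec <- rbind(rec, make_stage_records("B", "B"))
  P <- build_mpm(rec, c("A", "B"), fecundity_map = c(B = "A"))
  expect_equal(P["B", "A"], 0.5)
  expect_equal(sum(P[, "A"]), 0.5)

  # stasis only: identity pattern, lambda 1
  stay <- rbind(make_stage_records(rep("A", 4), rep("A", 4)),
                make_stage_records(rep("B", 4), rep("B", 4)))
  Pid <- build_mpm(stay, c("A", "B"), c(B = "A"))
  expect_equal(unname(Pid), diag(2), ignore_attr = TRUE)
  expect_equal(dominant_lambda(Pid), 1)

  # 4 adults produce 12 recruits -> fecundity 3
  fec <- rbind(make_stage_records(rep("juvenile", 3), rep("adult", 3)),
               make_stage_records(rep("adult", 4), rep("adult", 4),
                                  repro = 3))
  Pf <- build_mpm(fec, c("juvenile", "adult"), c(adult = "juvenile"))
  expect_equal(Pf["juvenile", "adult"], 3.0)

  expect_error(build_mpm(make_stage_records("A", "A"), c("A", "B"),
                         c(B = "A")), "stage")
})

test_that("pooled MPM equals count-weighted reconstruction from plots", {
  set.seed(8)
  plots <- lapply(1:3, function(p) {
    n <- sample(10:25, 1)
    st <- sample(c("juvenile", "adult"), n, replace = TRUE)
    st1 <- ifelse(stats::runif(n) < 0.3, "DEAD",
                  sample(c("juvenile", "adult"), n, replace = TRUE))
    r <- make_stage_records(st, st1, repro = stats::rpois(n, 2))
    r$plot <- paste0("p", p)
    r$id <- paste0("p", p, "_", seq_len(n))
    r
  })
  pooled <- do.call(rbind, plots)
  P_pool <- build_mpm(pooled, c("juvenile", "adult"), c(adult = "juvenile"))
  # weighted average of per-plot transition counts = pooled frequencies
  counts <- function(d, i, j) sum(d$stage_t == i & d$stage_t1 == j)
  n_at <- function(d, i) sum(d$stage_t == i)
  for (i in c("juvenile", "adult")) {
    for (j in c("juvenile", "adult")) {
      manual <- sum(sapply(plots, counts, i, j)) /
        sum(sapply(plots, n_at, i))
      trans <- P_pool[j, i] -
        if (i == "adult" && j == "juvenile") {
          sum(pooled$repro[pooled$stage_t == "adult"]) /
            n_at(pooled, "adult")
        } else 0
      expect_equal(trans, manual, tolerance = 1e-12)
    }
  }
})

test_that("seed-bank stage routes fecundity and germination", {
  rec <- rbind(make_stage_records(rep("juvenile", 5), rep("adult", 5)),
               make_stage_records(rep("adult", 5), rep("adult", 5),
                                  repro = 4))
  sb <- list(entry = 0.25, stasis = 0.5, germination = 0.2)
  P <- build_mpm(rec, c("juvenile", "adult"), c(adult = "juvenile"), sb)
  expect_equal(dim(P), c(3, 3))
  expect_equal(P["juvenile", "adult"], 4 * 0.75)
  expect_equal(P["seedbank", "adult"], 4 * 0.25)
  expect_equal(P["seedbank", "seedbank"], 0.5)
  expect_equal(P["juvenile", "seedbank"], 0.2)
})

test_that("vital-rate fitting matches glm/lm oracles and recovers truth", {
  set.seed(42)
  rec <- make_size_records(2000)
  vr <- fit_vital_rates(rec)
  obs <- rec[!is.na(rec$size_t), ]
  g <- stats::glm(surv ~ size_t, binomial, data = obs)
  expect_equal(unname(vr$survival), unname(coef(g)), tolerance = 1e-6)
  # recovery within 3 standard errors of the generating values
  se <- summary(g)$coefficients[, 2]
  expect_lt(abs(vr$survival[["intercept"]] - 0.5), 3 * se[1])
  expect_lt(abs(vr$survival[["slope"]] - 0.6), 3 * se[2])
  gl <- stats::lm(size_t1 ~ size_t, data = obs[obs$surv == 1, ])
  expect_equal(unname(vr$growth[1:2]), unname(coef(gl)), tolerance = 1e-8)
  sg <- summary(gl)$coefficients[, 2]
  expect_lt(abs(vr$growth[["intercept"]] - 0.8), 3 * sg[1])
  expect_lt(abs(vr$growth[["slope"]] - 0.7), 3 * sg[2])
  expect_equal(vr$growth[["sd"]], 0.3, tolerance = 0.02)

  # exact linear growth -> zero residual sd is rejected
  n <- 30
  z <- seq(0, 3, length.out = n)
  det_rec <- data.frame(id = paste0("i", 1:n), species = "sp",
                        treatment = "control", plot = "p", year = 1L,
                        stage_t = NA_character_, stage_t1 = NA_character_,
                        size_t = z, size_t1 = 0.9 * z + 1,
                        surv = c(0, rep(1, n - 1)), repro = 2)
  det_rec$size_t1[1] <- NA
  expect_error(fit_vital_rates(det_rec), "sd must be > 0")

  all_dead <- make_size_records(50)
  all_dead$surv[!is.na(all_dead$size_t)] <- 0
  all_dead$size_t1[!is.na(all_dead$size_t)] <- NA
  expect_error(fit_vital_rates(all_dead), "degenerate survival")
})

test_that("separated survival falls back to capped ridge coefficients", {
  n <- 40
  z <- c(seq(-2, -0.1, length.out = 20), seq(0.1, 2, length.out = 20))
  rec <- data.frame(id = paste0("i", 1:n), species = "sp",
                    treatment = "control", plot = "p", year = 1L,
                    stage_t = NA_character_, stage_t1 = NA_character_,
                    size_t = z, size_t1 = NA_real_,
                    surv = as.numeric(z > 0), repro = 0)
  rec$size_t1[rec$surv == 1] <- z[rec$surv == 1] + rnorm(20, 0, 0.1)
  rec <- rbind(rec, data.frame(id = c("r1", "r2"), species = "sp",
                               treatment = "control", plot = "p",
                               year = 1L, stage_t = NA_character_,
                               stage_t1 = NA_character_, size_t = NA_real_,
                               size_t1 = c(0.1, 0.2), surv = NA_real_,
                               repro = 0))
  rec$repro[rec$size_t > 1 & !is.na(rec$size_t)] <- 5
  vr <- fit_vital_rates(rec)
  expect_true(all(is.finite(vr$survival)))
})

test_that("IPM kernel reproduces closed-form lambdas", {
  # survival-only kernel with constant s: every column sums to s, lambda = s
  co <- make_vital_rates(survival = c(intercept = stats::qlogis(0.7),
                                      slope = 0),
                         growth = c(intercept = 0, slope = 0.9, sd = 0.2))
  K <- build_ipm_kernel(co, bounds = c(-6, 6), meshpoints = 600)
  expect_equal(unname(colSums(K)[150:450]), rep(0.7, 301), tolerance = 1e-6)
  expect_equal(dominant_lambda(K), 0.7, tolerance = 1e-6)

  # fecundity-only rank-1 kernel: lambda = establishment * sum(f * c) form
  co2 <- make_vital_rates(survival = c(intercept = -20, slope = 0),
                          fecundity = c(intercept = log(2), slope = 0),
                          establishment = 0.5,
                          recruit_size = c(mean = 0, sd = 0.4))
  K2 <- build_ipm_kernel(co2, bounds = c(-5, 5), meshpoints = 400)
  # rank-1 kernel's non-zero eigenvalue equals its trace-equivalent mass
  h <- attr(K2, "h")
  z <- attr(K2, "mesh")
  lam_closed <- sum(0.5 * 2 * stats::dnorm(z, 0, 0.4) * h)
  expect_equal(dominant_lambda(K2), lam_closed, tolerance = 1e-6)

  # meshpoint refinement changes lambda by < 1e-4
  co3 <- make_vital_rates(survival = c(intercept = 0, slope = 0.5),
                          growth = c(intercept = 0.4, slope = 0.7,
                                     sd = 0.3),
                          fecundity = c(intercept = 0.5, slope = 0.3),
                          establishment = 0.2,
                          recruit_size = c(mean = 0.3, sd = 0.3))
  l500 <- dominant_lambda(build_ipm_kernel(co3, c(-2, 5), 500))
  l1000 <- dominant_lambda(build_ipm_kernel(co3, c(-2, 5), 1000))
  expect_lt(abs(l500 - l1000), 1e-4)

  expect_error(build_ipm_kernel(co3, c(2, 2), 100), "bounds")
  expect_error(build_ipm_kernel(co3, c(-2, 5), 5), "meshpoints")
  bad <- co3; bad$growth[["sd"]] <- NA
  expect_error(build_ipm_kernel(bad, c(-2, 5), 100), "non-finite")
})

test_that("dominant eigenvalue matches analytic spectra", {
  expect_equal(dominant_lambda(matrix(c(0, 0.5, 4, 0), 2, 2)), sqrt(2),
               tolerance = 1e-10)
  expect_equal(dominant_lambda(diag(2)), 1)
  expect_equal(dominant_lambda(diag(c(0.5, 0.2))), 0.5)
  expect_error(dominant_lambda(matrix(c(0, 1, NA, 0), 2, 2)), "finite")
  expect_error(dominant_lambda(matrix(1, 2, 3)), "square")

  # power-iteration path agrees with eigen on a large kernel
  co <- make_vital_rates(survival = c(intercept = 0, slope = 0.5),
                         growth = c(intercept = 0.4, slope = 0.7, sd = 0.3),
                         fecundity = c(intercept = 0.5, slope = 0.3),
                         establishment = 0.2,
                         recruit_size = c(mean = 0.3, sd = 0.3))
  K <- build_ipm_kernel(co, c(-2, 5), 700)
  l_power <- dominant_lambda(K)
  l_eigen <- max(Mod(eigen(K, only.values = TRUE)$values))
  expect_equal(l_power, l_eigen, tolerance = 1e-8)
})

test_that("Perron root is monotone and substochastic matrices decay", {
  set.seed(11)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    A <- matrix(stats::runif(k * k), k, k)
    A <- sweep(A, 2, colSums(A) * stats::runif(1, 1.05, 2), "/")
    expect_lte(dominant_lambda(A), 1 + 1e-12) # column sums < 1
    Fm <- matrix(0, k, k)
    Fm[1, k] <- stats::runif(1, 0.5, 3)
    l1 <- dominant_lambda(A + Fm)
    l2 <- dominant_lambda(A + 2.5 * Fm)
    expect_gte(l2, l1 - 1e-12)
  }
})

test_that("effect size follows the offset log response ratio", {
  expect_identical(effect_size_of_competition(1, 1), 0)
  expect_identical(effect_size_of_competition(0, 0), 0)
  expect_equal(effect_size_of_competition(1.5, 0.5), log(2),
               tolerance = 1e-12)
  expect_error(effect_size_of_competition(-0.1, 1), ">= 0")
  # alternative reading: quotient of logs
  expect_equal(
    effect_size_of_competition(1.5, 0.6, method = "ratio_of_logs"),
    log(2) / log(1.1), tolerance = 1e-12)
})

test_that("bootstrap identity resample equals the point estimate", {
  set.seed(21)
  recs <- rbind(make_size_records(80, treatment = "control"),
                make_size_records(80, fec_coef = c(3.9, 0.4),
                                  treatment = "removal"))
  recs$id <- paste(recs$treatment, recs$id)
  sp <- default_model_spec("IPM")
  sp$meshpoints <- 80
  bt <- bootstrap_effect_sizes(recs, sp, n_boot = 3, seed = 1,
                               resample = FALSE)
  expect_equal(bt$draws, rep(bt$point, 3), tolerance = 1e-7)

  st <- rbind(make_stage_records(sample(c("juvenile", "adult"), 60, TRUE),
                                 sample(c("juvenile", "adult", "DEAD"), 60,
                                        TRUE), repro = rpois(60, 2)),
              local({
                r <- make_stage_records(
                  sample(c("juvenile", "adult"), 60, TRUE),
                  sample(c("juvenile", "adult", "DEAD"), 60, TRUE),
                  repro = rpois(60, 3), treatment = "removal")
                r$id <- paste0("rm", seq_len(60)); r
              }))
  btm <- bootstrap_effect_sizes(st, default_model_spec("MPM"), n_boot = 2,
                                seed = 1, resample = FALSE)
  expect_equal(btm$draws, rep(btm$point, 2), tolerance = 1e-12)

  # determinism under a fixed seed
  b1 <- bootstrap_effect_sizes(st, default_model_spec("MPM"), n_boot = 25,
                               seed = 9)
  b2 <- bootstrap_effect_sizes(st, default_model_spec("MPM"), n_boot = 25,
                               seed = 9)
  expect_identical(b1$draws, b2$draws)
})

test_that("bootstrap sd tracks the Monte-Carlo sampling sd", {
  # MPM with known generating matrix: compare bootstrap spread against the
  # sd of the estimator across fresh simulated datasets
  lam_of_f <- function(ff) dominant_lambda(fpdist:::mpm_generating_matrix(ff))
  f_c <- exp(fpdist:::solve_fecundity(lam_of_f, 0.9))
  f_r <- exp(fpdist:::solve_fecundity(lam_of_f, 1.1))
  gen <- function() {
    r <- rbind(fpdist:::sim_mpm_records(100, fpdist:::mpm_generating_matrix(f_c),
                                        f_c, "sp", "control", 4, 0),
               fpdist:::sim_mpm_records(100, fpdist:::mpm_generating_matrix(f_r),
                                        f_r, "sp", "removal", 4, 100))
    r
  }
  spec <- default_model_spec("MPM")
  set.seed(31)
  mc <- replicate(200, {
    r <- gen()
    effect_size_of_competition(
      fpdist:::lambda_for_records(r[r$treatment == "removal", ], spec),
      fpdist:::lambda_for_records(r[r$treatment == "control", ], spec))
  })
  bt <- bootstrap_effect_sizes(gen(), spec, n_boot = 400, seed = 5)
  expect_lt(abs(sd(bt$draws) - sd(mc)) / sd(mc), 0.25)
})
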