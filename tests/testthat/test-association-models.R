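test_that("standardization gives zero mean, unit sd, and is idempotent", {
  set.seed(2)
  m <- cbind(a = rnorm(30, 5, 3), b = runif(30, 0, 100))
  z <- standardize(m)
  expect_equal(unname(colMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unclass(standardize(z))[, ], z[, ], tolerance = 1e-12)
  expect_equal(unname(standardize(cbind(x = c(1, 2, 3)))[, 1]), c(-1, 0, 1))
  expect_error(standardize(cbind(ok = 1:5, flat = rep(2, 5))), "flat")
})

test_that("standardized OLS matches the normal-equations oracle", {
  set.seed(9)
  for (rep in 1:20) {
    X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
    y <- rnorm(20)
    fit <- fit_standardized_ols(y, X)
    expect_equal(unname(fit$coefficients), as.vector(oracle_ols_coef(y, X)),
                 tolerance = 1e-8)
    # adjusted R2 formula
    r2 <- fit$r2
    expect_equal(fit$adjusted_r2, 1 - (1 - r2) * 19 / (20 - 3 - 1),
                 tolerance = 1e-12)
    # AIC formula
    expect_equal(fit$aic, 20 * log(fit$rss / 20) + 2 * (3 + 2),
                 tolerance = 1e-12)
  }
})

test_that("a response equal to one predictor is fit perfectly", {
  set.seed(4)
  x <- as.vector(scale(rnorm(25)))
  X <- cbind(x = x)
  # lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fit_standardized_ols(x, X))
  expect_equal(unname(fit$coefficients), 1, tolerance = 1e-10)
  expect_equal(fit$adjusted_r2, 1, tolerance = 1e-10)
})

test_that("collinear designs are rejected with the offender named", {
  set.seed(5)
  x <- rnorm(20)
  X <- cbind(a = x, b = 2 * x, c = rnorm(20))
  expect_error(fit_standardized_ols(rnorm(20), X), "collinear")
})

test_that("best-subset AIC always keeps a dominant signal, usually alone", {
  # a strong predictor is always selected; spurious companions can enter
  # only at the ~16% per-noise-variable rate the AIC penalty allows
  n <- 56
  exact <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    X <- standardize(matrix(rnorm(n * 5), n,
                            dimnames = list(NULL, c("sig", "n1", "n2", "n3",
                                                    "n4"))))
    y <- as.vector(scale(3 * X[, "sig"] + rnorm(n, 0, 0.3)))
    best <- best_subset_aic(y, X)
    expect_true("sig" %in% best$predictor_names)
    if (identical(best$predictor_names, "sig")) exact <- exact + 1
  }
  # P(no spurious variable enters) ~ 0.84^4 ~ 0.5 per seed
  expect_gte(exact, 5)
})

test_that("duplicate predictors are pruned by AIC parsimony, first-listed wins", {
  set.seed(8)
  n <- 40
  x <- as.vector(scale(rnorm(n)))
  y <- as.vector(scale(x + rnorm(n, 0, 0.4)))
  pool <- cbind(first = x, second = x, junk = as.vector(scale(rnorm(n))))
  best <- best_subset_aic(y, pool)
  expect_identical(best$predictor_names, "first")
})

test_that("the AIC winner never beats the full-pool fit on raw R2", {
  set.seed(10)
  n <- 56
  X <- standardize(matrix(rnorm(n * 6), n,
                          dimnames = list(NULL, paste0("v", 1:6))))
  y <- as.vector(scale(X[, 1] * 0.5 + rnorm(n)))
  best <- best_subset_aic(y, X)
  full <- fit_standardized_ols(y, X)
  expect_lte(best$r2, full$r2 + 1e-12)
  # group bookkeeping
  best2 <- best_subset_aic(y, X, groups = list(ENV = c("v1", "v2"),
                                               COM = c("v3", "v4", "v5",
                                                       "v6")))
  expect_true(all(best2$winner_groups %in% c("ENV", "COM")))
})

test_that("standardized coefficients are invariant to predictor rescaling", {
  set.seed(12)
  n <- 30
  raw <- cbind(a = rnorm(n, 10, 4), b = runif(n))
  y <- as.vector(scale(raw[, 1] - 2 * raw[, 2] + rnorm(n, 0, 0.5)))
  f1 <- fit_standardized_ols(y, standardize(raw))
  f2 <- fit_standardized_ols(y, standardize(sweep(raw, 2, c(37, 0.01), "*")))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-10)
  expect_equal(f1$adjusted_r2, f2$adjusted_r2, tolerance = 1e-10)
})

test_that("perf_model methods behave like a fitted model object", {
  set.seed(13)
  X <- standardize(matrix(rnorm(60), 20, dimnames = list(NULL, c("a", "b",
                                                                 "c"))))
  y <- as.vector(scale(X[, 1] + rnorm(20, 0, 0.5)))
  fit <- fit_standardized_ols(y, X)
  expect_equal(unname(coef(fit)), unname(fit$coefficients))
  expect_equal(length(residuals(fit)), 20)
  expect_equal(predict(fit) + residuals(fit), y, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_output(print(fit), "adjusted R")
})

test_that("db-RDA recovers a planted environmental gradient", {
  set.seed(15)
  n <- 40
  grad <- seq(0, 1, length.out = n)
  # community driven deterministically by one variable
  m <- cbind(100 * (1 - grad), 100 * grad, 50) + 0.0
  tab <- community_table(round(m), seq_len(n))
  bc <- bray_curtis(tab)
  env <- cbind(driver = grad, noise = rnorm(n))
  res <- dbrda_variance(bc, env)
  expect_gt(res$constrained_fraction, 0.9)
  expect_error(dbrda_variance(bc, cbind(a = grad, b = grad)), "collinear")
})

test_that("db-RDA constrained fraction matches vegan's dbrda", {
  set.seed(16)
  tab <- random_table(15, 10, seed = 16)
  bc <- bray_curtis(tab)
  env <- data.frame(e1 = rnorm(15), e2 = runif(15))
  res <- dbrda_variance(bc, env)
  ref <- vegan::dbrda(bc ~ e1 + e2, data = as.data.frame(scale(env)))
  ref_frac <- ref$CCA$tot.chi / (ref$tot.chi)
  # implementations differ in how negative-eigenvalue axes are treated;
  # agreement is expected only to a few percent
  expect_equal(res$constrained_fraction, ref_frac, tolerance = 0.08)
})

test_that("null environment explains about p/(n-1) with a calibrated test", {
  set.seed(17)
  hits <- 0
  fracs <- numeric(20)
  for (i in 1:20) {
    tab <- random_table(30, 15, seed = 100 + i)
    bc <- bray_curtis(tab)
    env <- matrix(rnorm(60), 30, dimnames = list(NULL, c("x1", "x2")))
    res <- dbrda_variance(bc, env, permutations = 99, seed = i)
    fracs[i] <- res$constrained_fraction
    if (res$p_value > 0.05) hits <- hits + 1
  }
  expect_gt(hits, 20 * 0.7)                    # mostly non-significant
  expect_lt(abs(mean(fracs) - 2 / 29), 0.05)   # p/(n-1) expectation
})

test_that("model tables cover the seven group combinations", {
  run <- cached_run(11)
  part <- partition_nitrogen(run$chem)
  ratio <- moving_average(part$day, part$ratio, 6.25)
  div <- rarefy_diversity(run$community, depth = 30000, reps = 5, seed = 3)
  bc <- bray_curtis(run$community)
  ord <- nmds(bc, k = 3, restarts = 5, seed = 5,
              sample_days = run$community$sample_days)
  env <- data.frame(temperature = run$chem$temperature, ph = run$chem$ph,
                    do = run$chem$do)
  tabs <- performance_model_table(ratio, env,
                                  div[, c("richness", "shannon", "pielou")],
                                  ord$points)
  expect_equal(nrow(tabs$table), 7)
  expect_true(all(c("ENV", "DIV", "COM", "ENV+DIV+COM") %in%
                    tabs$table$model))
  expect_true(all(tabs$table$adjusted_r2 <= 1))
  gen <- aggregate_taxa(run$community, "genus")
  rel <- relative_abundance(gen)
  top <- names(sort(colMeans(rel), decreasing = TRUE))[1:10]
  g <- genus_model_table(ratio, rel[, top])
  expect_equal(nrow(g$table), 11)
  expect_identical(g$table$model[11], "multivariate")
})
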