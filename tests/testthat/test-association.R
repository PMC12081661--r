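test_that("the vectorized SNP scan reproduces lm exactly", {
  set.seed(1)
  n <- 400
  g <- simulate_genotypes(n, c(0.2, 0.4, 0.35))
  x <- cbind(cov1 = rnorm(n), cov2 = rbinom(n, 1, 0.4))
  y <- 0.4 * g[, 1] + 0.2 * x[, 1] + rnorm(n)
  res <- snp_regression(y, g, covariates = x)
  for (j in 1:3) {
    fit <- summary(lm(y ~ g[, j] + x))$coefficients
    expect_equal(res$beta[j], fit[2, 1], tolerance = 1e-12)
    expect_equal(res$se[j], fit[2, 2], tolerance = 1e-12)
    expect_equal(res$pvalue[j], fit[2, 4], tolerance = 1e-12)
  }
  expect_equal(res$tstat, res$beta / res$se, tolerance = 1e-10)
})

test_that("weighted scans match WLS with HC1 sandwich standard errors", {
  skip_if_not_installed("sandwich")
  set.seed(2)
  n <- 300
  g <- simulate_genotypes(n, 0.3)
  x <- cbind(rnorm(n))
  y <- 0.3 * g[, 1] + rnorm(n)
  w <- runif(n, 0.5, 4)
  res <- snp_regression(y, g, covariates = x, weights = w)
  fit <- lm(y ~ g[, 1] + x, weights = w)
  expect_equal(res$beta[1], unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(res$se[1],
               sqrt(diag(sandwich::vcovHC(fit, type = "HC1")))[[2]],
               tolerance = 1e-10)
})

test_that("OLS recovers a planted genetic effect", {
  set.seed(3)
  n <- 50000
  g <- simulate_genotypes(n, 0.3)
  y <- 0.5 * g[, 1] + rnorm(n)
  res <- snp_regression(y, g)
  expect_lt(abs(res$beta[1] - 0.5), 3 * res$se[1])
})

test_that("null SNPs reject at the nominal rate", {
  set.seed(4)
  n <- 2000
  g <- simulate_genotypes(n, runif(1000, 0.05, 0.5))
  y <- rnorm(n)
  res <- snp_regression(y, g)
  rate <- mean(res$pvalue < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("equal weights reduce WLS to OLS", {
  set.seed(5)
  n <- 500
  g <- simulate_genotypes(n, 0.25)
  y <- 0.2 * g[, 1] + rnorm(n)
  a <- snp_regression(y, g)
  b <- snp_regression(y, g, weights = rep(2, n), robust = FALSE)
  expect_equal(a$beta, b$beta, tolerance = 1e-10)
  expect_equal(a$se, b$se, tolerance = 1e-10)
})

test_that("zero-variance dosages are flagged, not dropped", {
  set.seed(6)
  g <- cbind(snp_1 = rep(2L, 100), snp_2 = rbinom(100, 2, 0.3))
  res <- snp_regression(rnorm(100), g)
  expect_equal(nrow(res), 2)
  expect_true(is.na(res$beta[1]))
  expect_false(is.na(res$beta[2]))
})

test_that("noise covariates barely move the estimates", {
  set.seed(7)
  n <- 5000
  g <- simulate_genotypes(n, runif(200, 0.1, 0.5))
  y <- g %*% rnorm(200, 0, 0.02) + rnorm(n)
  base <- snp_regression(as.vector(y), g)
  noisy <- snp_regression(as.vector(y), g, covariates = matrix(rnorm(n * 3), n))
  frac <- mean(abs(base$beta - noisy$beta) < base$se)
  expect_gte(frac, 0.95)
})

test_that("gene-by-sex models recover a planted interaction", {
  set.seed(8)
  n <- 20000
  g <- simulate_genotypes(n, 0.3)
  sex <- rbinom(n, 1, 0.5)
  # effect 0.3 in reference sex, 0.1 in the other: interaction -0.2
  y <- (0.3 - 0.2 * sex) * g[, 1] + rnorm(n)
  res <- gxsex_regression(y, g, sex)
  expect_lt(abs(res$interaction_beta[1] + 0.2), 3 * res$interaction_se[1])
  expect_lt(abs(res$beta[1] - 0.3), 3 * res$se[1])
  # cross-check against lm
  fit <- summary(lm(y ~ g[, 1] * sex))$coefficients
  expect_equal(res$interaction_beta[1], fit[4, 1], tolerance = 1e-10)
  expect_equal(res$interaction_se[1], fit[4, 2], tolerance = 1e-10)
})

test_that("gene-by-sex interactions are calibrated under the null", {
  set.seed(9)
  n <- 3000
  g <- simulate_genotypes(n, runif(500, 0.1, 0.5))
  sex <- rbinom(n, 1, 0.5)
  y <- 0.1 * g[, 1] + rnorm(n)
  res <- gxsex_regression(y, g, sex)
  rate <- mean(res$interaction_p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
  # permuted sex: interactions centred on zero
  y2 <- (0.3 * sex) * g[, 1] + rnorm(n)
  res2 <- gxsex_regression(y2, g[, 1, drop = FALSE], sample(sex))
  expect_lt(abs(res2$interaction_beta[1]), 3 * res2$interaction_se[1])
  expect_error(gxsex_regression(y, g, rep(1, n)), "both sexes")
})

test_that("IPW weights behave under a known participation model", {
  set.seed(10)
  n <- 50000
  p0 <- rnorm(n)
  age <- runif(n, 40, 69)
  prob <- plogis(0.5 + 0.8 * p0 - 0.01 * age)
  part <- rbinom(n, 1, prob)
  ipw <- estimate_ipw_weights(part, cbind(p0 = p0, age = age),
                              truncation = 1)
  idx <- part == 1
  expect_gt(cor(ipw$weights[idx], 1 / prob[idx]), 0.95)
  # truncation is monotone
  ipw99 <- estimate_ipw_weights(part, cbind(p0 = p0, age = age),
                                truncation = 0.99)
  expect_lte(max(ipw99$weights[idx]), max(ipw$weights[idx]))
  expect_lte(ipw$ess_kish, sum(idx))
})

test_that("participation independent of predictors gives constant weights", {
  set.seed(11)
  n <- 20000
  part <- rbinom(n, 1, 0.5)
  x <- cbind(rnorm(n))
  ipw <- estimate_ipw_weights(part, x)
  expect_lt(abs(ipw$mean_weight - 2), 0.1)
  expect_lt(diff(range(ipw$weights[part == 1])), 0.5)
})

test_that("IPW with true weights removes participation-induced attenuation", {
  sc <- scenario(50000, n_snps = 1, maf = 0.3, alpha = 0.4, gamma = 0,
                 error_sd = 0.5, seed = 12,
                 participation = participation_model(p0_obs = 2.5))
  co <- simulate_cohort(sc)
  full <- snp_regression(co$p0_obs, dosage_matrix(co))
  sc$participation <- calibrate_participation(sc, 0.5, cohort = co)
  co <- apply_participation(co, sc, quiet = TRUE)
  sub <- co[co$participates == 1, ]
  unw <- snp_regression(sub$p0_obs, dosage_matrix(sub))
  wtd <- snp_regression(sub$p0_obs, dosage_matrix(sub),
                        weights = sub$true_weight)
  # unweighted attenuates; weighting restores the full-cohort effect
  expect_gt(full$beta[1] - unw$beta[1], 3 * unw$se[1])
  expect_lt(abs(wtd$beta[1] - full$beta[1]), 3 * wtd$se[1])
})

test_that("weighting does not flip the sign of strong associations", {
  sc <- scenario(20000, n_snps = 30, maf = 0.3,
                 alpha = seq(-0.4, 0.4, length.out = 30), gamma = 0,
                 error_sd = 0.5, seed = 13,
                 participation = participation_model(p0_obs = 0.8))
  co <- simulate_cohort(sc)
  sc$participation <- calibrate_participation(sc, 0.7, cohort = co)
  co <- apply_participation(co, sc, quiet = TRUE)
  sub <- co[co$participates == 1, ]
  g <- dosage_matrix(sub)
  unw <- snp_regression(sub$p0_obs, g)
  wtd <- snp_regression(sub$p0_obs, g, weights = sub$true_weight)
  strong <- abs(unw$tstat) > 4
  expect_gt(sum(strong), 0)
  expect_true(all(sign(unw$beta[strong]) == sign(wtd$beta[strong])))
})

test_that("summary-statistic standardization preserves z-scores exactly", {
  a <- data.frame(snp_id = "rs1", model_tag = "P0", beta = 0.5, se = 0.1,
                  tstat = 5, pvalue = 1e-6, n = 100, weighted = FALSE)
  s <- standardize_stats(a)
  expect_equal(s$gamma_std, 0.5)
  expect_equal(s$se_std, 0.1)
  # zero map
  a$beta <- 0
  expect_equal(standardize_stats(a)$gamma_std, 0)
  # algebraic identity on random fixtures
  set.seed(14)
  r <- data.frame(snp_id = paste0("s", 1:200), beta = rnorm(200),
                  se = runif(200, 0.01, 1), n = sample(1e3:1e6, 200))
  s2 <- standardize_stats(r)
  expect_equal(s2$gamma_std / s2$se_std, r$beta / r$se, tolerance = 1e-12)
  expect_equal(s2$se_std, 1 / sqrt(r$n))
  expect_error(standardize_stats(transform(r, n = NA)), "positive finite")
})

test_that("realized variance explained matches a regression oracle", {
  expect_equal(realized_h2(c(0, 0), c(0.2, 0.3), 1), 0)
  expect_equal(realized_h2(1, 0.5, 1), 0.5)
  expect_warning(h <- realized_h2(10, 0.5, 1), "clipping")
  expect_equal(h, 1)
  sc <- scenario(50000, n_snps = 10, maf = 0.3, alpha = 0.15, gamma = 0,
                 beta_env = -0.02, error_sd = 0.5, seed = 15)
  co <- simulate_cohort(sc)
  h2 <- realized_h2(sc$alpha, sc$maf, var(co$p0_obs))
  r2 <- summary(lm(co$p0_obs ~ dosage_matrix(co)))$r.squared
  expect_lt(abs(h2 - r2), 3 * sqrt(2 / 50000) * 2)
})
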