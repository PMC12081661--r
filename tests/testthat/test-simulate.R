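test_that("genotype dosages follow Hardy-Weinberg moments", {
  g <- simulate_genotypes(10000, 0.5, seed = 1)
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_lt(abs(mean(g) - 1.0), 3 * se)

  # degenerate limit: maf -> 0
  g0 <- simulate_genotypes(100, 1e-6, seed = 2)
  expect_true(all(g0 == 0))

  # binomial variance at maf = 0.2
  g2 <- simulate_genotypes(50000, 0.2, seed = 3)
  v_true <- 2 * 0.2 * 0.8
  # MC SE of a binomial dosage variance, via resampling the generator
  v_reps <- replicate(30, var(as.vector(simulate_genotypes(50000, 0.2))))
  expect_lt(abs(var(as.vector(g2)) - v_true), 3 * sd(v_reps))
  expect_true(all(g2 %in% 0:2))
})

test_that("genotype simulation rejects invalid allele frequencies", {
  expect_error(simulate_genotypes(10, c(0.2, NA)), "maf")
  expect_error(simulate_genotypes(10, 0.7), "maf")
  expect_error(simulate_genotypes(10, -0.1), "maf")
})

test_that("null cohort is constant at the intercept", {
  sc <- scenario(50, alpha = 0, gamma = 0, beta_env = 0,
                 lambda_intercept = 3, error_sd = 0, seed = 1)
  co <- simulate_cohort(sc)
  expect_equal(co$p0_obs, rep(3, 50))
  expect_equal(co$p1_obs, rep(3, 50))
})

test_that("cohort structure invariants hold", {
  sc <- scenario(20000, n_snps = 3, maf = c(0.1, 0.3, 0.5), alpha = 0.2,
                 gamma = 0.01, error_sd = 0.6, seed = 7)
  co <- simulate_cohort(sc)
  expect_true(all(co$fu > 0))
  expect_equal(co$age1 - co$age0, co$fu)
  # measurement-error SD recovered
  err0 <- co$p0_obs - co$p0_latent
  expect_lt(abs(sd(err0) - 0.6), 3 * 0.6 * sqrt(1 / (2 * 20000)))
  # dosage means near 2*maf
  se_maf <- sqrt(2 * sc$maf * (1 - sc$maf) / 20000)
  expect_true(all(abs(colMeans(dosage_matrix(co)) - 2 * sc$maf) < 3 * se_maf))
})

test_that("seed-fixed determinism yields identical cohorts", {
  sc <- scenario(500, n_snps = 2, alpha = 0.1, gamma = 0.02,
                 error_sd = 0.3, seed = 11,
                 participation = participation_model(intercept = 0.5))
  c1 <- simulate_cohort(sc)
  c2 <- simulate_cohort(sc)
  expect_identical(c1, c2)
  p1 <- apply_participation(c1, sc, seed = 4, quiet = TRUE)
  p2 <- apply_participation(c2, sc, seed = 4, quiet = TRUE)
  expect_identical(p1, p2)
})

test_that("error-free linear change is exactly the environmental shift", {
  sc <- scenario(2000, n_snps = 2, alpha = 0.3, gamma = c(0.2, -0.1),
                 beta_env = -0.04, error_sd = 0, seed = 5)
  co <- simulate_cohort(sc)
  g <- dosage_matrix(co)
  de <- co$e1 - co$e0
  expected <- -(sc$beta_env * de + drop(g %*% sc$gamma) * de)
  expect_equal(diff_score(co$p0_obs, co$p1_obs), expected, tolerance = 1e-12)
})

test_that("fixed environmental shift is recovered exactly by OLS on clean data", {
  # gamma = 0.2, beta = 0, alpha = 0, no error, E1 - E0 = 5 fixed:
  # regressing (P0 - P1) on G must give slope -0.2 * 5 = -1 exactly
  sc <- scenario(1000, n_snps = 1, maf = 0.3, alpha = 0, gamma = 0.2,
                 beta_env = 0, error_sd = 0, env_slope = 1, env_noise_sd = 0,
                 fu_range = c(5, 5), seed = 9)
  co <- simulate_cohort(sc)
  d <- diff_score(co$p0_obs, co$p1_obs)
  fit <- lm(d ~ co$snp_1)
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 1e-10)
})

test_that("additive genetic variance matches the 2pq formula", {
  sc <- scenario(100000, n_snps = 1, maf = 0.3, alpha = 0.1, gamma = 0,
                 beta_env = 0, error_sd = 0, env_noise_sd = 0, seed = 13)
  co <- simulate_cohort(sc)
  v_true <- 0.1^2 * 2 * 0.3 * 0.7
  v_obs <- var(co$p0_latent)
  expect_lt(abs(v_obs - v_true), 3 * v_true * sqrt(2 / 100000) * 2)
})

test_that("variance accounting: genetic + environmental components add up", {
  sc <- scenario(50000, n_snps = 5, maf = 0.25, alpha = 0.2, gamma = 0,
                 beta_env = -0.03, error_sd = 0, env_noise_sd = 2, seed = 17)
  co <- simulate_cohort(sc)
  mo <- scenario_moments(sc)
  v_expected <- sum(sc$alpha^2 * mo$v_g) + sc$beta_env^2 * mo$v_e0
  v_obs <- var(co$p0_latent)
  expect_lt(abs(v_obs - v_expected), 3 * v_expected * sqrt(2 / 50000) * 2)
})

test_that("intercept-only participation halves the sample at logit 0", {
  sc <- scenario(10000, participation = participation_model(intercept = 0),
                 seed = 21)
  co <- apply_participation(simulate_cohort(sc), sc, quiet = TRUE)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(co$participates) - 0.5), 3 * se)
  expect_equal(co$true_weight, rep(2, 10000))
})

test_that("selection on the phenotype raises the participants' mean (enumeration oracle)", {
  # 10-row fixture: brute-force the expected participants' mean over all
  # 2^10 participation patterns and compare with the simulated mean
  p0 <- c(1.2, -0.5, 0.3, 2.1, -1.4, 0.8, -0.2, 1.7, 0.1, -0.9)
  prob <- plogis(1.5 * p0)
  patterns <- expand.grid(rep(list(0:1), 10))
  pat_mean <- apply(patterns, 1, function(s)
    if (sum(s) == 0) NA_real_ else sum(s * p0) / sum(s))
  pat_prob <- apply(patterns, 1, function(s)
    prod(ifelse(s == 1, prob, 1 - prob)))
  keep <- !is.na(pat_mean)
  oracle_mean <- sum(pat_mean[keep] * pat_prob[keep]) / sum(pat_prob[keep])
  expect_gt(oracle_mean, mean(p0))

  # simulated counterpart under the same fixture
  set.seed(31)
  sim_means <- replicate(4000, {
    s <- rbinom(10, 1, prob)
    if (sum(s) == 0) NA_real_ else mean(p0[s == 1])
  })
  expect_lt(abs(mean(sim_means, na.rm = TRUE) - oracle_mean),
            3 * sd(sim_means, na.rm = TRUE) / sqrt(sum(!is.na(sim_means))))
})

test_that("participation intercept can emulate a 21% repeat-visit response", {
  sc <- attrition_scenario(n = 20000)
  sc$seed <- 23
  cohort <- simulate_cohort(sc)
  sc$participation <- calibrate_participation(sc, 0.21, cohort = cohort)
  cohort <- apply_participation(cohort, sc, quiet = TRUE)
  expect_lt(abs(mean(cohort$participates) - 0.21),
            3 * sqrt(0.21 * 0.79 / 20000))
})

test_that("all-zero participation is a degenerate-sample error", {
  sc <- scenario(100, participation = participation_model(intercept = -40),
                 seed = 25)
  co <- simulate_cohort(sc)
  expect_error(apply_participation(co, sc, quiet = TRUE), "degenerate")
})

test_that("intercept-only selection leaves the phenotype distribution unchanged", {
  # retained vs dropped rows: KS non-significant at 0.01 in >= 95/100 seeds
  ok <- vapply(1:100, function(s) {
    sc <- scenario(1000, error_sd = 0.5,
                   participation = participation_model(intercept = 0),
                   seed = 1000 + s)
    co <- apply_participation(simulate_cohort(sc), sc, quiet = TRUE)
    suppressWarnings(
      ks.test(co$p0_obs[co$participates == 1],
              co$p0_obs[co$participates == 0])$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(ok), 95)
})

test_that("non-positive observed phenotypes under exponential decline are flagged", {
  sc <- scenario(2000, n_snps = 1, alpha = 0, gamma = 0, beta_env = -0.005,
                 lambda_intercept = 0.5, error_sd = 3,
                 decline_form = "exponential", seed = 27)
  expect_warning(co <- simulate_cohort(sc), "non-positive")
  expect_gt(attr(co, "n_nonpositive"), 0)
})

test_that("cohort tables round-trip through TSV", {
  sc <- scenario(50, n_snps = 2, seed = 29)
  co <- simulate_cohort(sc)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(as.data.frame(co2), as.data.frame(co), tolerance = 1e-12,
               ignore_attr = TRUE)
})
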