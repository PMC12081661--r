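# Shared scenario builders for the test suite. All sizes here are chosen to
# keep individual test files fast; the acceptance tests use the full study
# conditions.

# Baseline-effect-only scenario (the residual-change bias setting).
baseline_effect_scenario <- function(n = 20000, alpha = 0.3, error_sd = 0.6,
                                     n_snps = 1, seed = NULL) {
  scenario(n, n_snps = n_snps, maf = 0.3, alpha = alpha, gamma = 0,
           error_sd = error_sd, seed = seed)
}

# Gene-by-age (longitudinal) effect scenario.
gxe_scenario <- function(n = 20000, gamma = 0.05, error_sd = 0.5,
                         seed = NULL) {
  scenario(n, n_snps = 1, maf = 0.3, alpha = 0, gamma = gamma,
           error_sd = error_sd, seed = seed)
}

# Proportional (exponential) decline on a positive scale; small log-scale
# coefficients keep phenotypes in a realistic positive range.
exponential_scenario <- function(n = 20000, alpha = 0.02, gamma = -0.002,
                                 error_sd = 0, seed = NULL) {
  scenario(n, n_snps = 1, maf = 0.3, alpha = alpha, gamma = gamma,
           beta_env = -0.005, lambda_intercept = 3, error_sd = error_sd,
           env_noise_sd = 2, decline_form = "exponential", seed = seed)
}

# Age-related decline with phenotype-dependent follow-up participation;
# total baseline variance ~1 so the age slope is ~ -0.02 SD/year.
attrition_scenario <- function(n = 50000, select_coef = 2.5) {
  scenario(n, n_snps = 1, alpha = 0, gamma = 0, beta_env = -0.02,
           lambda_intercept = 30, error_sd = 0.985, env_noise_sd = 2,
           participation = participation_model(p0_obs = select_coef))
}

# Simulated two-sample MR instrument set: k strong instruments, true causal
# effect `gam`, optional directional pleiotropy `intercept` and balanced
# ratio noise `het_sd`.
simulate_mr_input <- function(seed, k = 20, gam = 0.17, intercept = 0,
                              het_sd = 0, se_o = 0.01) {
  set.seed(seed)
  be <- stats::rnorm(k, 0.1, 0.02)
  bo <- intercept + gam * be + stats::rnorm(k, 0, se_o) +
    if (het_sd > 0) be * stats::rnorm(k, 0, het_sd) else 0
  mr_input(be, rep(0.01, k), bo, rep(se_o, k))
}
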