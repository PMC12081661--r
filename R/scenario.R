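#' Define a two-wave simulation scenario
#'
#' A scenario is the complete parameterization of the generative model used
#' throughout the package. The latent phenotype of individual i at wave
#' t (0 = baseline, 1 = follow-up) is
#' \deqn{P_t = \lambda + \alpha G + \beta E_t + \gamma G E_t (+ s_m \cdot sex + s_g \cdot G \cdot sex)}
#' and the observed phenotype adds independent Gaussian measurement error at
#' each wave, \eqn{P^*_t = P_t + \varepsilon_t}. The environment is age-linked:
#' \eqn{E_t = \mathrm{env\_slope} \cdot (age_t - \mathrm{env\_center}) + u_i}
#' with a per-individual
#' Gaussian intercept \eqn{u_i}, so the gene-by-environment effect
#' \eqn{\gamma} acts as a gene-by-age effect and
#' \eqn{E_1 - E_0 = \mathrm{env\_slope} \cdot FU} is deterministic given the
#' follow-up duration. With `decline_form = "exponential"` the same linear
#' predictor is exponentiated, giving proportional (baseline-dependent)
#' decline on the raw scale that is exactly linear on the log scale.
#'
#' Per-SNP effect vectors `alpha` (cross-sectional) and `gamma`
#' (longitudinal) live on the same SNP panel, so a variant can carry a
#' baseline effect, a change effect, both, or neither.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param n_snps Number of independent biallelic SNPs (>= 1).
#' @param maf Per-SNP effect-allele frequency in (0, 0.5]; recycled.
#' @param alpha Per-SNP time-invariant (baseline) genetic effect, phenotype
#'   units per allele; recycled.
#' @param gamma Per-SNP gene-by-environment effect, phenotype units per
#'   allele per environment unit; recycled.
#' @param beta_env Environmental main effect (phenotype units per
#'   environment unit). Negative values produce age-related decline under
#'   the age-linked default environment.
#' @param lambda_intercept Phenotype intercept. The default keeps linear-form
#'   phenotypes well away from zero so log-difference scores are defined.
#' @param error_sd Measurement-error SD; length 1 (both waves) or 2
#'   (per-wave).
#' @param env_slope Environment change per year of age (default 1: the
#'   environment is age itself plus individual noise).
#' @param env_center Age (years) at which the environment is zero;
#'   defaults to the midpoint of `age0_range`. Centering makes `gamma` a
#'   pure gene-by-age (change) effect at the cohort's mean baseline age,
#'   so a variant can be longitudinal-only; an uncentered environment
#'   (`env_center = 0`) lets `gamma` also contribute a baseline effect
#'   `gamma * E[E0]`.
#' @param env_noise_sd SD of the per-individual environment intercept.
#' @param age0_range Baseline age range (years), sampled uniformly.
#'   Default 40-69, a typical adult biobank recruitment window.
#' @param fu_range Follow-up duration range (years), sampled uniformly;
#'   lower bound must be positive. Default 2-12.
#' @param decline_form `"linear"` or `"exponential"`.
#' @param sex_main Main effect of sex (male = 1) on the phenotype.
#' @param sex_gxsex Per-SNP gene-by-sex interaction effect; recycled.
#' @param participation Optional participation model from
#'   [participation_model()]: follow-up participation is Bernoulli with
#'   logit linear in the observed baseline phenotype, baseline age and sex.
#' @param seed Integer seed making the simulated cohort reproducible.
#'
#' @return An object of class `"scenario"` (a validated list).
#' @seealso [simulate_cohort()], [apply_participation()],
#'   [oracle_res_expectation()]
#' @export
#' @examples
#' sc <- scenario(n_individuals = 1000, n_snps = 2, maf = c(0.2, 0.4),
#'                alpha = 0.3, gamma = 0, seed = 1)
#' sc
scenario <- function(n_individuals,
                     n_snps = 1L,
                     maf = 0.3,
                     alpha = 0,
                     gamma = 0,
                     beta_env = -0.02,
                     lambda_intercept = 30,
                     error_sd = 0.5,
                     env_slope = 1,
                     env_center = NULL,
                     env_noise_sd = 2,
                     age0_range = c(40, 69),
                     fu_range = c(2, 12),
                     decline_form = c("linear", "exponential"),
                     sex_main = 0,
                     sex_gxsex = 0,
                     participation = NULL,
                     seed = NULL) {
  decline_form <- match.arg(decline_form)
  n_individuals <- as.integer(n_individuals)
  n_snps <- as.integer(n_snps)
  if (is.na(n_individuals) || n_individuals < 2L)
    stop("'n_individuals' must be an integer >= 2", call. = FALSE)
  if (is.na(n_snps) || n_snps < 1L)
    stop("'n_snps' must be an integer >= 1", call. = FALSE)

  maf <- rep_len(as.numeric(maf), n_snps)
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5))
    stop("every 'maf' must be finite and in (0, 0.5]", call. = FALSE)
  alpha <- rep_len(as.numeric(alpha), n_snps)
  gamma <- rep_len(as.numeric(gamma), n_snps)
  sex_gxsex <- rep_len(as.numeric(sex_gxsex), n_snps)
  if (any(!is.finite(c(alpha, gamma, sex_gxsex, beta_env, lambda_intercept,
                       env_slope, env_noise_sd, sex_main))))
    stop("effect parameters must be finite", call. = FALSE)

  error_sd <- as.numeric(error_sd)
  if (!length(error_sd) %in% c(1L, 2L) || any(!is.finite(error_sd)) ||
      any(error_sd < 0))
    stop("'error_sd' must be one or two non-negative finite values",
         call. = FALSE)
  error_sd <- rep_len(error_sd, 2L)

  if (length(age0_range) != 2L || diff(age0_range) < 0)
    stop("'age0_range' must be c(lower, upper) with lower <= upper",
         call. = FALSE)
  if (length(fu_range) != 2L || fu_range[1] <= 0 || diff(fu_range) < 0)
    stop("'fu_range' must be c(lower, upper) with 0 < lower <= upper",
         call. = FALSE)
  if (env_noise_sd < 0) stop("'env_noise_sd' must be >= 0", call. = FALSE)
  if (is.null(env_center)) env_center <- mean(age0_range)
  if (!is.finite(env_center)) stop("'env_center' must be finite", call. = FALSE)

  if (!is.null(participation) && !inherits(participation, "participation_model"))
    stop("'participation' must come from participation_model()", call. = FALSE)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("'seed' must be coercible to integer", call. = FALSE)
  }

  structure(list(
    n_individuals = n_individuals, n_snps = n_snps, maf = maf,
    alpha = alpha, gamma = gamma, beta_env = as.numeric(beta_env),
    lambda_intercept = as.numeric(lambda_intercept), error_sd = error_sd,
    env_slope = as.numeric(env_slope), env_center = as.numeric(env_center),
    env_noise_sd = as.numeric(env_noise_sd),
    age0_range = as.numeric(age0_range), fu_range = as.numeric(fu_range),
    decline_form = decline_form, sex_main = as.numeric(sex_main),
    sex_gxsex = sex_gxsex, participation = participation, seed = seed
  ), class = "scenario")
}

#' Logistic follow-up participation model
#'
#' Participation at follow-up is Bernoulli with
#' `logit(p) = intercept + p0_obs * P0_obs + age0 * age + sex * SEX`.
#' Selection acts on the *observed* baseline phenotype, so attrition is
#' missing-not-at-random with respect to the latent trait but correctable
#' by inverse probability weighting given observed covariates.
#'
#' @param intercept Log-odds intercept.
#' @param p0_obs Coefficient on the observed baseline phenotype.
#' @param age0 Coefficient on baseline age (years).
#' @param sex Coefficient on sex (male = 1).
#' @return An object of class `"participation_model"`.
#' @export
participation_model <- function(intercept = 0, p0_obs = 0, age0 = 0, sex = 0) {
  coefs <- c(intercept = intercept, p0_obs = p0_obs, age0 = age0, sex = sex)
  if (any(!is.finite(coefs)))
    stop("participation coefficients must be finite", call. = FALSE)
  structure(as.list(coefs), class = "participation_model")
}

#' Calibrate the participation intercept to a target rate
#'
#' Solves for the intercept of a participation model so that the marginal
#' participation rate in a cohort simulated under `scenario` matches
#' `target_rate`, holding the slope coefficients fixed. Used, e.g., to
#' emulate the roughly 21% response rate typical of biobank repeat-visit
#' invitations, or to sweep attrition levels.
#'
#' @param scenario A [scenario()]; its `participation` slot supplies the
#'   slope coefficients (an intercept already present is ignored).
#' @param target_rate Desired marginal participation probability in (0, 1).
#' @param cohort Optional pre-simulated cohort to calibrate against;
#'   defaults to simulating one from `scenario`.
#' @return A `participation_model` with the calibrated intercept.
#' @export
calibrate_participation <- function(scenario, target_rate, cohort = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  if (!is.finite(target_rate) || target_rate <= 0 || target_rate >= 1)
    stop("'target_rate' must be in (0, 1)", call. = FALSE)
  pm <- scenario$participation
  if (is.null(pm)) pm <- participation_model()
  if (is.null(cohort)) cohort <- simulate_cohort(scenario)
  lp_slope <- pm$p0_obs * cohort$p0_obs + pm$age0 * cohort$age0 +
    pm$sex * cohort$sex
  f <- function(b0) mean(stats::plogis(b0 + lp_slope)) - target_rate
  lo <- -max(lp_slope) - 40
  hi <- -min(lp_slope) + 40
  b0 <- stats::uniroot(f, interval = c(lo, hi), tol = 1e-10)$root
  participation_model(intercept = b0, p0_obs = pm$p0_obs,
                      age0 = pm$age0, sex = pm$sex)
}

#' @export
print.scenario <- function(x, ...) {
  cat("Two-wave simulation scenario\n")
  cat(sprintf("  individuals: %d, SNPs: %d, decline: %s\n",
              x$n_individuals, x$n_snps, x$decline_form))
  cat(sprintf("  maf: %s\n", .abbrev_num(x$maf)))
  cat(sprintf("  alpha: %s  gamma: %s\n",
              .abbrev_num(x$alpha), .abbrev_num(x$gamma)))
  cat(sprintf("  beta_env: %g  lambda: %g  error_sd: %s\n",
              x$beta_env, x$lambda_intercept, .abbrev_num(x$error_sd)))
  cat(sprintf("  env: slope %g per year centred at age %g, noise SD %g\n",
              x$env_slope, x$env_center, x$env_noise_sd))
  cat(sprintf("  age0: U(%g, %g)  FU: U(%g, %g) years\n",
              x$age0_range[1], x$age0_range[2],
              x$fu_range[1], x$fu_range[2]))
  if (!is.null(x$participation))
    cat(sprintf("  participation logit: %.3g + %.3g*P0 + %.3g*age0 + %.3g*sex\n",
                x$participation$intercept, x$participation$p0_obs,
                x$participation$age0, x$participation$sex))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

.abbrev_num <- function(v, k = 4L) {
  if (length(v) <= k) paste(signif(v, 4), collapse = ", ")
  else paste0(paste(signif(v[seq_len(k)], 4), collapse = ", "), ", ... [",
              length(v), "]")
}

#' Write / read a scenario as a YAML config
#'
#' @param scenario A [scenario()] object.
#' @param path File path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario`
#'   returns the reconstructed `scenario`.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "scenario"))
  x <- unclass(scenario)
  if (!is.null(x$participation)) x$participation <- unclass(x$participation)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- yaml::read_yaml(path)
  pm <- NULL
  if (!is.null(x$participation))
    pm <- do.call(participation_model, x$participation)
  scenario(
    n_individuals = x$n_individuals, n_snps = x$n_snps, maf = x$maf,
    alpha = x$alpha, gamma = x$gamma, beta_env = x$beta_env,
    lambda_intercept = x$lambda_intercept, error_sd = x$error_sd,
    env_slope = x$env_slope, env_center = x$env_center,
    env_noise_sd = x$env_noise_sd,
    age0_range = x$age0_range, fu_range = x$fu_range,
    decline_form = x$decline_form, sex_main = x$sex_main,
    sex_gxsex = x$sex_gxsex, participation = pm, seed = x$seed
  )
}
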