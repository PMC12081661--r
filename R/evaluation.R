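#' Model-implied moments of a linear-form scenario
#'
#' Population moments of the generative model used by the analytic oracle
#' and for constructing estimator targets: allele-frequency moments,
#' environment mean/variance at baseline, and the expected environment
#' change between waves.
#'
#' @param scenario A [scenario()] object.
#' @return A list with `m_g`, `v_g` (per-SNP dosage mean/variance),
#'   `m_e0`, `v_e0`, `m_de` (mean of `E1 - E0`), `v_de`.
#' @keywords internal
#' @export
scenario_moments <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  sc <- scenario
  var_unif <- function(r) diff(r)^2 / 12
  list(
    m_g = 2 * sc$maf,
    v_g = 2 * sc$maf * (1 - sc$maf),
    m_e0 = sc$env_slope * (mean(sc$age0_range) - sc$env_center),
    v_e0 = sc$env_slope^2 * var_unif(sc$age0_range) + sc$env_noise_sd^2,
    m_de = sc$env_slope * mean(sc$fu_range),
    v_de = sc$env_slope^2 * var_unif(sc$fu_range)
  )
}

#' Analytic expectation of the residual-change coefficient
#'
#' Closed-form large-sample expectation of the per-SNP coefficient in the
#' regression of the residual change score (difference score residualized
#' on the observed baseline) on dosage, derived from the model-implied
#' covariances of the linear-form generative model:
#' \deqn{E[\hat\beta_j] = \frac{Cov(\Delta, G_j) - b\,Cov(P^*_0, G_j)}{Var(G_j)},
#'   \quad b = \frac{Cov(\Delta, P^*_0)}{Var(P^*_0)}.}
#' With no gene-by-environment effect the expression collapses to
#' `-alpha_j * sigma0^2 / Var(P0_obs)`: a spurious association whose
#' magnitude grows with both the baseline genetic effect and the
#' measurement-error variance — the mechanism by which baseline adjustment
#' manufactures false-positive "change" loci.
#'
#' @param scenario A linear-form [scenario()] without sex effects.
#' @return Numeric vector of expected coefficients, one per SNP.
#' @export
oracle_res_expectation <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  sc <- scenario
  if (sc$decline_form != "linear")
    stop("oracle supports the linear decline form only", call. = FALSE)
  if (sc$sex_main != 0 || any(sc$sex_gxsex != 0))
    stop("oracle does not support sex effects", call. = FALSE)
  mo <- scenario_moments(sc)
  s0_sq <- sc$error_sd[1]^2

  v_c <- sum(sc$gamma^2 * mo$v_g)               # Var(beta + sum gamma_j G_j)
  m_c <- sc$beta_env + sum(sc$gamma * mo$m_g)
  s_ag <- sum(sc$alpha * sc$gamma * mo$v_g)     # Cov(sum alpha G, sum gamma G)

  var_p0 <- sum(sc$alpha^2 * mo$v_g) + mo$v_e0 * (v_c + m_c^2) +
    mo$m_e0^2 * v_c + 2 * mo$m_e0 * s_ag + s0_sq
  cov_d_p0 <- -mo$m_de * (s_ag + mo$m_e0 * v_c) + s0_sq
  b <- cov_d_p0 / var_p0

  # per-SNP: Cov(D, G_j) = -m_de * gamma_j * v_g; Cov(P0*, G_j) = (alpha_j +
  # gamma_j * m_e0) * v_g
  -mo$m_de * sc$gamma - b * (sc$alpha + sc$gamma * mo$m_e0)
}

#' Large-sample targets of the four association models
#'
#' The estimands each model recovers under the generative model: the
#' baseline model targets `alpha_j + gamma_j * E[E0]`; the difference and
#' log-difference models target `-gamma_j * E[E1 - E0]` on their
#' respective scales (the log target applies to the exponential form;
#' under the linear form the log-difference coefficient has no clean
#' population target and is reported as `NA`); the residual-change model
#' is assigned the difference-score target, with its analytic expectation
#' from [oracle_res_expectation()] tracked separately.
#'
#' @param scenario A [scenario()] object.
#' @return A list of per-SNP target vectors: `p0`, `diff`, `res`, `log`.
#' @export
estimator_targets <- function(scenario) {
  mo <- scenario_moments(scenario)
  t_diff <- -scenario$gamma * mo$m_de
  list(p0 = scenario$alpha + scenario$gamma * mo$m_e0,
       diff = t_diff,
       res = t_diff,
       log = if (scenario$decline_form == "exponential") t_diff
             else rep(NA_real_, scenario$n_snps))
}

#' Run a simulation scenario through the full estimation pipeline
#'
#' For each replicate: simulate a cohort, apply selective participation if
#' the scenario defines it, build the change scores (difference, residual
#' change, log-difference, each residualized on baseline age, follow-up
#' duration, their interaction and squared age; baseline residualized on
#' age and squared age), and scan every SNP under the four association
#' models. Aggregates per-estimator bias against the model targets,
#' empirical spread, mean model SE, and rejection rates at 0.05
#' (calibration) and 5e-8 (genome-wide discovery).
#'
#' Replicates in which an estimator fails (e.g. log scores on a
#' non-positive phenotype) are dropped for that estimator and counted;
#' more than 5% failed replicates aborts the scenario.
#'
#' @param scenario A [scenario()] object.
#' @param n_reps Number of replicates.
#' @param seed Master seed; replicate r runs under `seed + r`.
#' @param weights `"none"`, `"true"` (the stored inverse participation
#'   probabilities) or `"estimated"` (logistic weights refit per
#'   replicate) — only meaningful when the scenario has a participation
#'   model.
#' @return A `data.frame` of class `"eval_report"`, one row per estimator
#'   (`P0`, `DIFF`, `RES`, `LOG`), with `mean_estimate`, `true_target`,
#'   `bias`, `empirical_sd`, `mean_se`, `reject_05`, `reject_gw`,
#'   `oracle`, `n_reps_used`, `n_dropped`. The per-replicate, per-SNP
#'   estimate matrices are attached as attribute `"estimates"`.
#' @export
run_scenario <- function(scenario, n_reps, seed = 1L,
                         weights = c("none", "true", "estimated")) {
  stopifnot(inherits(scenario, "scenario"))
  weights <- match.arg(weights)
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("'n_reps' must be >= 1", call. = FALSE)
  seed <- as.integer(seed)
  m <- scenario$n_snps
  tags <- c("P0", "DIFF", "RES", "LOG")

  est <- se <- pv <- lapply(tags, function(t)
    matrix(NA_real_, nrow = n_reps, ncol = m))
  names(est) <- names(se) <- names(pv) <- tags
  dropped <- stats::setNames(integer(4), tags)

  for (r in seq_len(n_reps)) {
    sc_r <- scenario
    sc_r$seed <- seed + r
    fit_r <- tryCatch(
      .fit_one_rep(sc_r, weights),
      error = function(e) e)
    if (inherits(fit_r, "error")) {
      dropped <- dropped + 1L
      next
    }
    for (t in tags) {
      if (is.null(fit_r[[t]])) {
        dropped[t] <- dropped[t] + 1L
      } else {
        est[[t]][r, ] <- fit_r[[t]]$beta
        se[[t]][r, ] <- fit_r[[t]]$se
        pv[[t]][r, ] <- fit_r[[t]]$pvalue
      }
    }
  }
  if (any(dropped > 0.05 * n_reps))
    stop(sprintf(
      "more than 5%% of replicates failed (dropped: %s); scenario aborted",
      paste(sprintf("%s=%d", tags, dropped), collapse = ", ")),
      call. = FALSE)

  targets <- estimator_targets(scenario)
  names(targets) <- tags
  oracle <- rep(NA_real_, 4)
  if (scenario$decline_form == "linear" && scenario$sex_main == 0 &&
      all(scenario$sex_gxsex == 0))
    oracle[3] <- mean(oracle_res_expectation(scenario))

  rows <- lapply(seq_along(tags), function(i) {
    t <- tags[i]
    e <- est[[t]]; s <- se[[t]]; p <- pv[[t]]
    used <- sum(stats::complete.cases(e))
    tg <- mean(targets[[t]])
    me <- mean(e, na.rm = TRUE)
    data.frame(
      estimator = t,
      mean_estimate = me,
      true_target = tg,
      bias = me - tg,
      empirical_sd = if (used >= 2L)
        mean(apply(e, 2, stats::sd, na.rm = TRUE)) else NA_real_,
      mean_se = mean(s, na.rm = TRUE),
      reject_05 = mean(p < 0.05, na.rm = TRUE),
      reject_gw = mean(p < 5e-8, na.rm = TRUE),
      oracle = oracle[i],
      n_reps_used = used,
      n_dropped = dropped[t],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("eval_report", "data.frame")
  attr(out, "scenario") <- scenario
  attr(out, "seed") <- seed
  attr(out, "estimates") <- est
  attr(out, "pvalues") <- pv
  out
}

# One replicate: simulate, score, scan. Returns a list of assoc_result
# per tag (LOG set to NULL when log scores are undefined).
.fit_one_rep <- function(sc, weights) {
  cohort <- simulate_cohort(sc)
  w <- NULL
  if (!is.null(sc$participation)) {
    cohort <- apply_participation(cohort, sc, quiet = TRUE)
    if (weights == "estimated") {
      ipw <- estimate_ipw_weights(
        cohort$participates,
        cbind(p0_obs = cohort$p0_obs, age0 = cohort$age0, sex = cohort$sex))
      cohort$est_weight <- ipw$weights
    }
    cohort <- cohort[cohort$participates == 1L, ]
    if (weights == "true") w <- cohort$true_weight
    if (weights == "estimated") w <- cohort$est_weight
  }
  g <- dosage_matrix(cohort)
  age0 <- cohort$age0
  fu <- cohort$fu

  p0r <- stats::lm.fit(cbind(1, age0, age0^2), cohort$p0_obs)$residuals
  dd <- diff_score(cohort$p0_obs, cohort$p1_obs)
  dd_r <- residualize_change(dd, age0, fu)
  dr <- residual_change(dd, cohort$p0_obs)
  dr_r <- residualize_change(dr, age0, fu)
  dl_r <- NULL
  if (all(cohort$p0_obs > 0) && all(cohort$p1_obs > 0))
    dl_r <- residualize_change(log_score(cohort$p0_obs, cohort$p1_obs),
                               age0, fu)

  fit <- function(y, tag) {
    if (is.null(y)) return(NULL)
    snp_regression(y, g, weights = w, model_tag = tag)
  }
  list(P0 = fit(p0r, "P0"), DIFF = fit(dd_r, "DIFF"),
       RES = fit(dr_r, "RES"), LOG = fit(dl_r, "LOG"))
}

#' @export
print.eval_report <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("Scenario evaluation (n = %d, SNPs = %d, %s decline)\n",
              sc$n_individuals, sc$n_snps, sc$decline_form))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Age effect on a standardized baseline phenotype
#'
#' (Weighted) univariate regression of the standardized baseline score on
#' baseline age; the slope is decline in outcome SDs per additional year
#' of age. Weighted fits report heteroscedasticity-robust (HC1) standard
#' errors, as required for inverse-probability-weighted estimates.
#'
#' @param p0_z Baseline phenotype as a plain z-score,
#'   `(P0 - mean) / sd` — not age-residualized, since age is the
#'   regressor of interest here.
#' @param age0 Baseline age (years).
#' @param weights Optional non-negative weights.
#' @param label Sub-sample label carried into the result.
#' @return One-row `data.frame`: `label`, `alpha_hat`, `se`, `n`,
#'   `weighted`.
#' @export
age_effect <- function(p0_z, age0, weights = NULL, label = NA_character_) {
  cc <- is.finite(p0_z) & is.finite(age0)
  if (!is.null(weights)) cc <- cc & is.finite(weights) & weights > 0
  y <- p0_z[cc]; a <- age0[cc]
  n <- length(y)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(a) == 0) stop("age has zero variance", call. = FALSE)
  x <- cbind(1, a)
  if (is.null(weights)) {
    fit <- stats::lm.fit(x, y)
    rss <- sum(fit$residuals^2)
    xtx_inv <- chol2inv(qr.R(fit$qr))
    se <- sqrt(rss / (n - 2L) * xtx_inv[2, 2])
    b <- fit$coefficients[2]
    weighted <- FALSE
  } else {
    w <- weights[cc]
    sw <- sqrt(w)
    fit <- stats::lm.fit(x * sw, y * sw)
    b <- fit$coefficients[2]
    e <- y - x %*% fit$coefficients
    bread <- chol2inv(qr.R(fit$qr))
    xe <- x * as.vector(w * e)
    meat <- crossprod(xe)
    vc <- bread %*% meat %*% bread * n / (n - 2L)
    se <- sqrt(vc[2, 2])
    weighted <- TRUE
  }
  data.frame(label = label, alpha_hat = unname(b), se = unname(se),
             n = n, weighted = weighted, stringsAsFactors = FALSE)
}

#' Age-effect attenuation under increasing attrition
#'
#' Sweeps a grid of attrition rates (1 - participation rate). At each
#' level the scenario's participation slopes are kept and the intercept is
#' recalibrated to hit the target rate; the age effect on the full-sample-
#' standardized baseline score is then re-estimated in the participating
#' sub-sample, unweighted and weighted by true and by estimated inverse
#' probability weights, alongside the full-sample reference. Selection on
#' the observed phenotype truncates its distribution, attenuating the age
#' slope; IPW undoes the distortion.
#'
#' @param scenario A [scenario()] whose participation model supplies the
#'   selection slopes (typically on `p0_obs`).
#' @param attrition_grid Attrition rates in \[0, 1); 0 means everyone
#'   participates.
#' @param seed Master seed.
#' @param n_reps Replicates averaged per grid point.
#' @param truncation Weight truncation quantile for estimated weights.
#' @return A `data.frame` of class `"attenuation_curve"`: one row per
#'   (attrition level, estimator) with `alpha_hat` (mean over reps), `se`
#'   (mean model SE), `empirical_sd`, `attrition_realized`, `status`.
#' @export
attenuation_curve <- function(scenario, attrition_grid, seed = 1L,
                              n_reps = 1L, truncation = 0.99) {
  stopifnot(inherits(scenario, "scenario"))
  if (is.null(scenario$participation))
    stop("scenario needs a participation model (its slopes drive selection)",
         call. = FALSE)
  if (any(attrition_grid < 0 | attrition_grid >= 1))
    stop("attrition rates must be in [0, 1)", call. = FALSE)
  seed <- as.integer(seed)
  labs <- c("full", "unweighted", "ipw_true", "ipw_estimated")
  acc <- list()

  rep_acc <- list()
  for (a in attrition_grid) {
    mats <- array(NA_real_, dim = c(n_reps, length(labs), 2),
                  dimnames = list(NULL, labs, c("alpha", "se")))
    realized <- rep(NA_real_, n_reps)
    status <- "ok"
    for (r in seq_len(n_reps)) {
      sc_r <- scenario
      sc_r$seed <- seed + r
      cohort <- simulate_cohort(sc_r)
      # plain z-score on the full sample: the age effect is the estimand,
      # and the scale must stay fixed across sub-samples
      p0z <- (cohort$p0_obs - mean(cohort$p0_obs)) / stats::sd(cohort$p0_obs)
      full <- age_effect(p0z, cohort$age0, label = "full")
      mats[r, "full", ] <- c(full$alpha_hat, full$se)
      if (a == 0) {
        realized[r] <- 0
        mats[r, c("unweighted", "ipw_true", "ipw_estimated"), ] <-
          matrix(c(full$alpha_hat, full$se), 3, 2, byrow = TRUE)
        next
      }
      res <- tryCatch({
        pm <- calibrate_participation(sc_r, target_rate = 1 - a,
                                      cohort = cohort)
        sc_r$participation <- pm
        cohort <- apply_participation(cohort, sc_r, quiet = TRUE)
        idx <- cohort$participates == 1L
        ipw <- estimate_ipw_weights(
          cohort$participates,
          cbind(p0_obs = cohort$p0_obs, age0 = cohort$age0,
                sex = cohort$sex),
          truncation = truncation)
        list(
          unweighted = age_effect(p0z[idx], cohort$age0[idx]),
          ipw_true = age_effect(p0z[idx], cohort$age0[idx],
                                weights = cohort$true_weight[idx]),
          ipw_estimated = age_effect(p0z[idx], cohort$age0[idx],
                                     weights = ipw$weights[idx]),
          rate = mean(idx))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        status <- paste("skipped:", conditionMessage(res))
        next
      }
      realized[r] <- 1 - res$rate
      for (l in c("unweighted", "ipw_true", "ipw_estimated"))
        mats[r, l, ] <- c(res[[l]]$alpha_hat, res[[l]]$se)
    }
    rep_acc[[length(rep_acc) + 1L]] <- data.frame(
      attrition = a, rep = seq_len(n_reps),
      do.call(cbind, lapply(stats::setNames(labs, labs),
                            function(l) mats[, l, "alpha"])))
    for (l in labs) {
      al <- mats[, l, "alpha"]
      acc[[length(acc) + 1L]] <- data.frame(
        attrition = a, estimator = l,
        alpha_hat = mean(al, na.rm = TRUE),
        se = mean(mats[, l, "se"], na.rm = TRUE),
        empirical_sd = if (n_reps >= 2L) stats::sd(al, na.rm = TRUE)
                       else NA_real_,
        attrition_realized = mean(realized, na.rm = TRUE),
        n_reps = sum(is.finite(al)),
        status = status, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, acc)
  class(out) <- c("attenuation_curve", "data.frame")
  attr(out, "scenario") <- scenario
  attr(out, "replicates") <- do.call(rbind, rep_acc)
  out
}
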