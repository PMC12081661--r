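#' Construct a two-sample MR input
#'
#' @param beta_exposure,se_exposure Instrument effects and SEs on the
#'   exposure (standardized scale).
#' @param beta_outcome,se_outcome Instrument effects and SEs on the
#'   outcome.
#' @param snp_id Optional instrument identifiers.
#' @return An object of class `"mr_input"`.
#' @export
mr_input <- function(beta_exposure, se_exposure, beta_outcome, se_outcome,
                     snp_id = NULL) {
  k <- length(beta_exposure)
  if (length(se_exposure) != k || length(beta_outcome) != k ||
      length(se_outcome) != k)
    stop("all instrument vectors must have equal length", call. = FALSE)
  if (any(!is.finite(c(beta_exposure, se_exposure, beta_outcome, se_outcome))))
    stop("instrument statistics must be finite", call. = FALSE)
  if (any(se_exposure <= 0) || any(se_outcome <= 0))
    stop("all standard errors must be positive", call. = FALSE)
  if (is.null(snp_id)) snp_id <- paste0("iv_", seq_len(k))
  structure(list(snp_id = as.character(snp_id),
                 beta_exposure = as.numeric(beta_exposure),
                 se_exposure = as.numeric(se_exposure),
                 beta_outcome = as.numeric(beta_outcome),
                 se_outcome = as.numeric(se_outcome),
                 k = k, status = "ok"),
            class = "mr_input")
}

#' Select genetic instruments for an exposure
#'
#' Joins exposure and outcome standardized summary statistics on `snp_id`
#' and retains SNPs whose exposure association passes the significance
#' threshold. Exposures with fewer than `min_k` passing instruments are
#' not an error: the returned object carries an explicit skipped status,
#' mirroring the rule that MR is only run for exposures with at least five
#' genome-wide significant instruments.
#'
#' @param exposure_stats,outcome_stats `std_sumstats` data frames
#'   (columns `snp_id`, `gamma_std`, `se_std`, `n`).
#' @param p_threshold Exposure p-value threshold (default `5e-8`).
#' @param min_k Minimum instrument count (default 5).
#' @return An `mr_input`; check `$status` before estimating.
#' @export
select_instruments <- function(exposure_stats, outcome_stats,
                               p_threshold = 5e-8, min_k = 5L) {
  if (anyDuplicated(exposure_stats$snp_id) ||
      anyDuplicated(outcome_stats$snp_id))
    stop("duplicated snp_id in summary statistics", call. = FALSE)
  if (!is.finite(p_threshold) || p_threshold <= 0)
    stop("'p_threshold' must be positive", call. = FALSE)
  j <- match(exposure_stats$snp_id, outcome_stats$snp_id)
  keep <- !is.na(j)
  ex <- exposure_stats[keep, ]
  out <- outcome_stats[j[keep], ]
  z <- ex$gamma_std / ex$se_std
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  sel <- p < p_threshold
  k <- sum(sel)
  if (k < min_k) {
    return(structure(list(snp_id = character(0),
                          beta_exposure = numeric(0), se_exposure = numeric(0),
                          beta_outcome = numeric(0), se_outcome = numeric(0),
                          k = k,
                          status = sprintf(
                            "skipped: insufficient instruments (k=%d < %d)",
                            k, min_k)),
                     class = "mr_input"))
  }
  mr_input(ex$gamma_std[sel], ex$se_std[sel],
           out$gamma_std[sel], out$se_std[sel],
           snp_id = ex$snp_id[sel])
}

#' Inverse-variance weighted MR estimate
#'
#' The IVW estimate is the weighted average of per-instrument Wald ratios
#' `r_j = beta_outcome / beta_exposure` with first-order weights
#' `w_j = (beta_exposure / se_outcome)^2`, equivalently the zero-intercept
#' weighted regression of outcome effects on exposure effects. The default
#' standard error uses multiplicative random effects: the fixed-effect SE
#' `1/sqrt(sum(w))` is scaled by `sqrt(Q / (k - 1))` floored at 1, so it
#' never undercuts the fixed-effect SE. `method = "fixed"` gives the plain
#' fixed-effect SE.
#'
#' @param input An `mr_input` with `k >= 2` (a single instrument returns
#'   the bare Wald ratio with its first-order SE, as a diagnostic).
#' @param method `"random"` (multiplicative, default) or `"fixed"`.
#' @return A list of class `"mr_result"`: `estimate`, `se`, `pvalue`, `k`,
#'   `q_statistic`, `q_df`, `q_pvalue`, `f_statistic`, `method`.
#' @export
mr_ivw <- function(input, method = c("random", "fixed")) {
  method <- match.arg(method)
  .check_mr_input(input)
  if (any(input$beta_exposure == 0))
    stop("beta_exposure of 0 makes a Wald ratio undefined", call. = FALSE)
  r <- input$beta_outcome / input$beta_exposure
  w <- (input$beta_exposure / input$se_outcome)^2
  est <- sum(w * r) / sum(w)
  se_fe <- sqrt(1 / sum(w))
  k <- input$k
  if (k >= 2L) {
    q <- sum(w * (r - est)^2)
    q_df <- k - 1L
    q_p <- stats::pchisq(q, df = q_df, lower.tail = FALSE)
    phi <- q / q_df
  } else {
    q <- NA_real_; q_df <- NA_integer_; q_p <- NA_real_; phi <- 1
  }
  se <- if (method == "random") se_fe * sqrt(max(1, phi)) else se_fe
  z <- est / se
  structure(list(estimate = est, se = se,
                 pvalue = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
                 k = k, q_statistic = q, q_df = q_df, q_pvalue = q_p,
                 f_statistic = instrument_strength(input),
                 method = method),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("IVW (%s effects): estimate = %.4g (SE %.4g), p = %.3g, k = %d\n",
              x$method, x$estimate, x$se, x$pvalue, x$k))
  if (!is.na(x$q_statistic))
    cat(sprintf("  Cochran Q = %.4g on %d df (p = %.3g); mean F = %.4g\n",
                x$q_statistic, x$q_df, x$q_pvalue, x$f_statistic))
  invisible(x)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j * (r_j - estimate)^2)` over the per-instrument Wald
#' ratios, referred to a chi-square with `k - 1` degrees of freedom.
#'
#' @param input An `mr_input` with `k >= 2`.
#' @param estimate The pooled causal estimate (e.g. from [mr_ivw()]);
#'   defaults to recomputing the IVW estimate.
#' @return A list with `q_statistic`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(input, estimate = NULL) {
  .check_mr_input(input, min_k = 2L)
  r <- input$beta_outcome / input$beta_exposure
  w <- (input$beta_exposure / input$se_outcome)^2
  if (is.null(estimate)) estimate <- sum(w * r) / sum(w)
  q <- sum(w * (r - estimate)^2)
  q_df <- input$k - 1L
  list(q_statistic = q, q_df = q_df,
       q_pvalue = stats::pchisq(q, df = q_df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights `1 / se_outcome^2`), after orienting instruments so
#' all exposure effects are non-negative. A non-zero intercept indicates
#' directional horizontal pleiotropy. Standard errors use the
#' multiplicative-error scaling floored at 1 and t-tests on `k - 2`
#' degrees of freedom.
#'
#' @param input An `mr_input` with `k >= 3`.
#' @return A list of class `"mr_egger"`: `intercept`, `intercept_se`,
#'   `intercept_p`, `slope`, `slope_se`, `slope_p`, `k`.
#' @export
mr_egger <- function(input) {
  .check_mr_input(input, min_k = 3L)
  s <- ifelse(input$beta_exposure < 0, -1, 1)
  bx <- input$beta_exposure * s
  by <- input$beta_outcome * s
  if (stats::sd(bx) == 0)
    stop("all exposure effects equal after orientation; Egger slope not identified",
         call. = FALSE)
  w <- 1 / input$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  scale <- max(1, sm$sigma)
  co <- sm$coefficients
  se <- co[, "Std. Error"] / sm$sigma * scale
  df <- input$k - 2L
  tt <- co[, "Estimate"] / se
  p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  structure(list(intercept = co[1, 1], intercept_se = se[1],
                 intercept_p = p[1],
                 slope = co[2, 1], slope_se = se[2], slope_p = p[2],
                 k = input$k),
            class = "mr_egger")
}

#' Mean instrument strength (F-statistic)
#'
#' Mean over instruments of the squared exposure z-score,
#' `(beta_exposure / se_exposure)^2`. Values above 10 are conventionally
#' taken to indicate low risk of weak-instrument bias. On the standardized
#' scale this depends only on the z-scores, not on any rescaling of N.
#'
#' @param input An `mr_input`.
#' @return The mean F-statistic.
#' @export
instrument_strength <- function(input) {
  .check_mr_input(input, min_k = 1L)
  mean((input$beta_exposure / input$se_exposure)^2)
}

#' Correlate two vectors of MR estimates
#'
#' Pearson correlation (with two-sided p-value) between paired causal-
#' effect estimates, e.g. cross-sectional versus longitudinal effects of
#' the same exposures.
#'
#' @param effects_a,effects_b Paired numeric vectors (length >= 3).
#' @return A list with `r`, `pvalue`, `n`.
#' @export
effect_correlation <- function(effects_a, effects_b) {
  if (length(effects_a) != length(effects_b))
    stop("effect vectors must be paired", call. = FALSE)
  cc <- is.finite(effects_a) & is.finite(effects_b)
  a <- effects_a[cc]; b <- effects_b[cc]
  if (length(a) < 3L) stop("need at least 3 paired estimates", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in an effect vector", call. = FALSE)
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n = length(a))
}

#' Multiple-testing flags across exposures
#'
#' Three-level significance labels: `"nominal"` at `p < 0.05`,
#' `"suggestive"` at `p < 0.05 / n_dimensions` (Bonferroni over exposure
#' dimensions, e.g. 0.05/11 = 0.005), `"conservative"` at
#' `p < 0.05 / n_exposures` (Bonferroni over all exposures tested, e.g.
#' 0.05/106 ~= 0.00047), and `"none"` otherwise.
#'
#' @param pvalues Numeric vector of p-values.
#' @param n_dimensions Number of independent exposure dimensions
#'   (default 11).
#' @param n_exposures Total number of exposures tested (default 106).
#' @return Ordered factor with levels `none < nominal < suggestive <
#'   conservative`; thresholds attached as an attribute.
#' @export
multiple_testing <- function(pvalues, n_dimensions = 11L, n_exposures = 106L) {
  if (n_dimensions < 1L || n_exposures < 1L)
    stop("dimension counts must be positive", call. = FALSE)
  t_sug <- 0.05 / n_dimensions
  t_con <- 0.05 / n_exposures
  lab <- rep("none", length(pvalues))
  lab[pvalues < 0.05] <- "nominal"
  lab[pvalues < t_sug] <- "suggestive"
  lab[pvalues < t_con] <- "conservative"
  lab[is.na(pvalues)] <- NA
  structure(factor(lab, levels = c("none", "nominal", "suggestive",
                                   "conservative"), ordered = TRUE),
            thresholds = c(nominal = 0.05, suggestive = t_sug,
                           conservative = t_con))
}

#' One-stop MR analysis for an exposure-outcome pair
#'
#' Selects instruments, runs IVW with heterogeneity and pleiotropy
#' diagnostics, and returns a one-row data frame (skipped exposures yield
#' a row with `NA` estimates and the skip status).
#'
#' @inheritParams select_instruments
#' @inheritParams mr_ivw
#' @param exposure_id,outcome_id Labels carried into the result.
#' @return One-row `data.frame` with estimate, SE, p, k, F, Q (+df, p),
#'   Egger intercept (+se, p), heterogeneity/pleiotropy flags at 0.05, and
#'   `status`.
#' @export
mr_analysis <- function(exposure_stats, outcome_stats,
                        p_threshold = 5e-8, min_k = 5L,
                        method = c("random", "fixed"),
                        exposure_id = "exposure", outcome_id = "outcome") {
  method <- match.arg(method)
  inp <- select_instruments(exposure_stats, outcome_stats,
                            p_threshold = p_threshold, min_k = min_k)
  base <- data.frame(exposure = exposure_id, outcome = outcome_id,
                     estimate = NA_real_, se = NA_real_, pvalue = NA_real_,
                     k = inp$k, f_statistic = NA_real_,
                     q_statistic = NA_real_, q_df = NA_integer_,
                     q_pvalue = NA_real_,
                     egger_intercept = NA_real_,
                     egger_intercept_se = NA_real_,
                     egger_intercept_p = NA_real_,
                     heterogeneity = NA, pleiotropy = NA,
                     status = inp$status, stringsAsFactors = FALSE)
  if (inp$status != "ok") return(base)
  ivw <- mr_ivw(inp, method = method)
  base$estimate <- ivw$estimate
  base$se <- ivw$se
  base$pvalue <- ivw$pvalue
  base$f_statistic <- ivw$f_statistic
  base$q_statistic <- ivw$q_statistic
  base$q_df <- ivw$q_df
  base$q_pvalue <- ivw$q_pvalue
  base$heterogeneity <- !is.na(ivw$q_pvalue) && ivw$q_pvalue < 0.05
  if (inp$k >= 3L) {
    eg <- mr_egger(inp)
    base$egger_intercept <- eg$intercept
    base$egger_intercept_se <- eg$intercept_se
    base$egger_intercept_p <- eg$intercept_p
    base$pleiotropy <- eg$intercept_p < 0.05
  }
  base
}

.check_mr_input <- function(input, min_k = 1L) {
  if (!inherits(input, "mr_input"))
    stop("'input' must be an mr_input object", call. = FALSE)
  if (input$status != "ok")
    stop("mr_input status is not ok: ", input$status, call. = FALSE)
  if (input$k < min_k)
    stop(sprintf("need at least %d instrument(s), have %d", min_k, input$k),
         call. = FALSE)
  invisible(TRUE)
}
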