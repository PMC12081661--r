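#' Per-SNP linear association scan
#'
#' Regresses an outcome on each dosage column separately, adjusting for a
#' shared covariate matrix, via the Frisch-Waugh-Lovell decomposition:
#' outcome and dosages are (weighted-)projected off the covariates once,
#' then each SNP reduces to a simple (weighted) regression. This is exactly
#' equivalent to fitting `outcome ~ snp + covariates` per SNP with
#' `lm`/`lm.wfit`, but vectorized across thousands of SNPs.
#'
#' With `weights` (e.g. inverse probability of participation weights) the
#' fit is weighted least squares and, because IPW invalidates the
#' homoscedastic variance estimator, standard errors are
#' heteroscedasticity-robust (HC1 sandwich) by default. Unweighted fits use
#' classical OLS standard errors.
#'
#' @param outcome Numeric outcome vector (a change score or baseline
#'   score).
#' @param dosages Numeric matrix, one column per SNP.
#' @param covariates Optional numeric matrix of covariates (no intercept
#'   column; one is added).
#' @param weights Optional non-negative weights.
#' @param robust Use sandwich (HC1) standard errors; defaults to `TRUE`
#'   when weights are supplied.
#' @param model_tag Label stored with each result, e.g. `"P0"`, `"DIFF"`,
#'   `"RES"`, `"LOG"`.
#' @param snp_ids SNP identifiers; defaults to `colnames(dosages)`.
#' @return A `data.frame` of class `"assoc_result"` with columns `snp_id`,
#'   `model_tag`, `beta`, `se`, `tstat`, `pvalue`, `n`, `weighted`.
#'   Zero-variance dosage columns yield `NA` estimates (flagged, not
#'   dropped).
#' @export
snp_regression <- function(outcome, dosages, covariates = NULL,
                           weights = NULL, robust = !is.null(weights),
                           model_tag = "P0", snp_ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(snp_ids)) snp_ids <- colnames(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(m))
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  weighted <- !is.null(weights)

  cc <- is.finite(outcome)
  if (!is.null(covariates)) cc <- cc & rowSums(!is.finite(covariates)) == 0
  if (weighted) cc <- cc & is.finite(weights) & weights > 0
  y <- outcome[cc]
  g <- dosages[cc, , drop = FALSE]
  n <- length(y)
  x <- if (is.null(covariates)) matrix(1, n, 1L)
       else cbind(1, covariates[cc, , drop = FALSE])
  w <- if (weighted) weights[cc] else rep(1, n)
  p_full <- ncol(x) + 1L
  if (n < p_full + 1L)
    stop("too few complete-case rows for the covariate count", call. = FALSE)
  if (weighted && any(w < 0)) stop("weights must be >= 0", call. = FALSE)

  sw <- sqrt(w)
  xs <- x * sw
  qx <- qr(xs)
  ys <- y * sw
  y_t <- ys - qr.fitted(qx, ys)           # weighted residual * sqrt(w)
  g_t <- g * sw
  g_t <- g_t - qr.fitted(qx, g_t)

  gg <- colSums(g_t^2)                    # = sum w * gtilde^2
  gy <- colSums(g_t * y_t)
  yy <- sum(y_t^2)
  ok <- gg > .Machine$double.eps * n
  beta <- ifelse(ok, gy / gg, NA_real_)
  df <- n - p_full

  if (!robust) {
    rss <- yy - beta^2 * gg
    se <- sqrt(pmax(rss, 0) / df / gg)
  } else {
    # HC1 sandwich for the SNP coefficient via FWL: meat = sum (w g~ e)^2
    # where residual e = y~ - beta g~ (on the original, not sqrt(w), scale)
    e_t <- y_t - g_t * rep(beta, each = n)          # sqrt(w) * e
    meat <- colSums((g_t * e_t)^2)                  # sum w^2 g~^2 e^2
    se <- sqrt(meat * n / (n - p_full)) / gg
  }
  tstat <- beta / se
  pvalue <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)

  out <- data.frame(snp_id = snp_ids, model_tag = model_tag,
                    beta = beta, se = se, tstat = tstat, pvalue = pvalue,
                    n = n, weighted = weighted,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Per-SNP gene-by-sex interaction scan
#'
#' Fits `outcome ~ snp + sex + snp:sex + covariates` for each SNP and
#' reports both the main genetic effect (in the reference sex, coded 0)
#' and the interaction term.
#'
#' @inheritParams snp_regression
#' @param sex Binary vector (0 = reference sex, 1 = other); both levels
#'   must be present.
#' @return An `assoc_result` data frame with additional columns
#'   `interaction_beta`, `interaction_se`, `interaction_p`.
#' @export
gxsex_regression <- function(outcome, dosages, sex, covariates = NULL,
                             model_tag = "P0", snp_ids = NULL) {
  dosages <- as.matrix(dosages)
  if (length(unique(sex[is.finite(sex)])) < 2L)
    stop("both sexes must be present for an interaction model", call. = FALSE)
  m <- ncol(dosages)
  if (is.null(snp_ids)) snp_ids <- colnames(dosages)
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(m))
  if (!is.null(covariates)) covariates <- as.matrix(covariates)

  cc <- is.finite(outcome) & is.finite(sex)
  if (!is.null(covariates)) cc <- cc & rowSums(!is.finite(covariates)) == 0
  y <- outcome[cc]
  s <- sex[cc]
  g <- dosages[cc, , drop = FALSE]
  cv <- if (!is.null(covariates)) covariates[cc, , drop = FALSE]
  n <- length(y)

  res <- vector("list", m)
  for (j in seq_len(m)) {
    gj <- g[, j]
    x <- cbind(1, gj, s, gj * s, cv)
    fit <- stats::lm.fit(x, y)
    k <- fit$rank
    df <- n - k
    rss <- sum(fit$residuals^2)
    xtx_inv <- chol2inv(qr.R(fit$qr)[seq_len(k), seq_len(k), drop = FALSE])
    vc <- rss / df * diag(xtx_inv)
    # coefficient order after pivoting
    coefs <- fit$coefficients
    pos_g <- 2L; pos_gs <- 4L
    se <- rep(NA_real_, length(coefs))
    se[fit$qr$pivot[seq_len(k)]] <- sqrt(vc)
    b_g <- coefs[pos_g]; se_g <- se[pos_g]
    b_gs <- coefs[pos_gs]; se_gs <- se[pos_gs]
    res[[j]] <- c(b_g, se_g, b_gs, se_gs, df)
  }
  res <- do.call(rbind, res)
  tstat <- res[, 1] / res[, 2]
  ti <- res[, 3] / res[, 4]
  out <- data.frame(
    snp_id = snp_ids, model_tag = model_tag,
    beta = res[, 1], se = res[, 2], tstat = tstat,
    pvalue = 2 * stats::pt(abs(tstat), df = res[, 5], lower.tail = FALSE),
    n = n, weighted = FALSE,
    interaction_beta = res[, 3], interaction_se = res[, 4],
    interaction_p = 2 * stats::pt(abs(ti), df = res[, 5], lower.tail = FALSE),
    stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Estimate inverse probability of participation weights
#'
#' Fits a logistic regression of the follow-up participation indicator on
#' observed predictors (typically the observed baseline phenotype, baseline
#' age and sex) and returns, for participants, the inverse of the fitted
#' participation probability, truncated at an upper quantile to limit the
#' influence of extreme weights.
#'
#' @param participates Binary participation indicator (both classes
#'   present).
#' @param predictors Numeric matrix or data frame of predictors.
#' @param truncation Upper quantile at which participant weights are capped
#'   (default 0.99; use 1 for no truncation).
#' @return A list of class `"ipw_weights"`: `weights` (full-length vector,
#'   `NA` for non-participants), `fitted_prob`, `mean_weight`,
#'   `ess_kish` (Kish effective sample size), `participation_rate`, `fit`.
#' @export
estimate_ipw_weights <- function(participates, predictors, truncation = 0.99) {
  predictors <- as.matrix(predictors)
  if (length(unique(participates)) < 2L)
    stop("both participation classes must be present", call. = FALSE)
  if (!is.finite(truncation) || truncation <= 0 || truncation > 1)
    stop("'truncation' must be in (0, 1]", call. = FALSE)
  dat <- data.frame(.part = participates, predictors)
  fit <- suppressWarnings(
    stats::glm(.part ~ ., data = dat, family = stats::binomial()))
  prob <- fit$fitted.values
  separated <- min(prob[participates == 1L]) > max(prob[participates == 0L])
  if (!fit$converged || separated)
    stop(paste("participation model shows (quasi-)separation;",
               "reduce or rescale the predictor set"), call. = FALSE)
  w <- rep(NA_real_, length(participates))
  idx <- participates == 1L
  w[idx] <- 1 / prob[idx]
  if (truncation < 1) {
    cap <- stats::quantile(w[idx], truncation, names = FALSE)
    w[idx] <- pmin(w[idx], cap)
  }
  wp <- w[idx]
  structure(list(weights = w, fitted_prob = prob,
                 mean_weight = mean(wp),
                 ess_kish = sum(wp)^2 / sum(wp^2),
                 participation_rate = mean(participates),
                 fit = fit),
            class = "ipw_weights")
}

#' Standardize association statistics for Mendelian randomization
#'
#' Converts per-SNP estimates to the standardized scale used for
#' two-sample MR on z-scores:
#' `gamma_std = (beta / se) / sqrt(n)` and `se_std = 1 / sqrt(n)`.
#' The z-score `beta / se` is preserved exactly.
#'
#' @param assoc An `assoc_result` data frame (needs `beta`, `se`, `n`).
#' @return A `data.frame` of class `"std_sumstats"` with `snp_id`,
#'   `gamma_std`, `se_std`, `n`.
#' @export
standardize_stats <- function(assoc) {
  need <- c("snp_id", "beta", "se", "n")
  if (!all(need %in% names(assoc)))
    stop("'assoc' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(assoc$n)) || any(assoc$n <= 0))
    stop("every 'n' must be a positive finite sample size", call. = FALSE)
  if (any(is.finite(assoc$se) & assoc$se <= 0))
    stop("every 'se' must be positive", call. = FALSE)
  out <- data.frame(snp_id = assoc$snp_id,
                    gamma_std = (assoc$beta / assoc$se) / sqrt(assoc$n),
                    se_std = 1 / sqrt(assoc$n),
                    n = assoc$n,
                    stringsAsFactors = FALSE)
  class(out) <- c("std_sumstats", "data.frame")
  out
}

#' Realized variance explained by additive SNP effects
#'
#' The simulation-truth analogue of SNP heritability:
#' `sum(effect^2 * 2 * maf * (1 - maf)) / outcome_variance`, clipped to
#' \[0, 1\] with a warning if clipping occurs.
#'
#' @param effects Per-SNP additive effects on the outcome scale.
#' @param mafs Per-SNP allele frequencies.
#' @param outcome_variance Total variance of the outcome (> 0).
#' @return Proportion of variance explained.
#' @export
realized_h2 <- function(effects, mafs, outcome_variance) {
  if (!is.finite(outcome_variance) || outcome_variance <= 0)
    stop("'outcome_variance' must be positive", call. = FALSE)
  if (length(effects) != length(mafs))
    stop("'effects' and 'mafs' must have equal length", call. = FALSE)
  h2 <- sum(effects^2 * 2 * mafs * (1 - mafs)) / outcome_variance
  if (h2 > 1) {
    warning("variance explained exceeds 1; clipping", call. = FALSE)
    h2 <- 1
  }
  h2
}

#' Write / read standardized summary statistics as TSV
#'
#' @param stats A `std_sumstats` or `assoc_result` data frame.
#' @param path File path.
#' @return `write_sumstats` returns `path` invisibly; `read_sumstats` a
#'   data frame.
#' @export
write_sumstats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = "NA",
                    check.names = FALSE)
}
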