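#' Absolute change (difference score)
#'
#' Baseline minus follow-up, oriented so that larger values indicate more
#' decline for phenotypes where high scores mean better function.
#'
#' @param p0,p1 Baseline and follow-up phenotype vectors (equal length,
#'   finite).
#' @return `p0 - p1`.
#' @export
diff_score <- function(p0, p1) {
  .check_pair(p0, p1)
  p0 - p1
}

#' Relative change (log-difference score)
#'
#' `log(p0) - log(p1)`; insensitive to the baseline level under
#' proportional change. Both waves must be strictly positive; non-positive
#' values are an error naming the offending rows (no silent shifting). A
#' documented opt-in `shift` is provided for simulation studies where a
#' constant offset is part of the design; it is never applied implicitly.
#'
#' @inheritParams diff_score
#' @param shift Constant added to both waves before taking logs
#'   (default 0).
#' @return `log(p0 + shift) - log(p1 + shift)`.
#' @export
log_score <- function(p0, p1, shift = 0) {
  .check_pair(p0, p1)
  p0 <- p0 + shift
  p1 <- p1 + shift
  bad <- which(p0 <= 0 | p1 <= 0)
  if (length(bad))
    stop("log_score requires strictly positive phenotypes; non-positive at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L),
         call. = FALSE)
  log(p0) - log(p1)
}

#' Conditional change (residual change score)
#'
#' Residuals of the difference score after regressing out the observed
#' baseline phenotype, indexing change no longer predictable by baseline.
#' This definition is convenient but biased when a predictor also affects
#' the (error-contaminated) baseline; see [oracle_res_expectation()].
#'
#' @param delta_diff Difference-score vector.
#' @param p0_obs Observed baseline phenotype vector.
#' @return OLS residuals of `delta_diff` on intercept + `p0_obs`.
#' @export
residual_change <- function(delta_diff, p0_obs) {
  .check_pair(delta_diff, p0_obs)
  if (length(delta_diff) < 3L)
    stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(p0_obs) == 0)
    stop("baseline phenotype has zero variance; residual change undefined",
         call. = FALSE)
  stats::lm.fit(cbind(1, p0_obs), delta_diff)$residuals
}

#' Residualize change scores for age and follow-up duration
#'
#' OLS residuals of a change score on intercept, baseline age, follow-up
#' duration, their interaction, and squared baseline age (the quadratic
#' term absorbs non-linear rates of change). Aliased columns in a
#' rank-deficient design (e.g. constant follow-up duration) are dropped
#' with a warning rather than failing.
#'
#' @param delta Change-score vector.
#' @param age0 Baseline age (years).
#' @param fu Follow-up duration (years).
#' @return Residual vector with covariate effects removed.
#' @export
residualize_change <- function(delta, age0, fu) {
  n <- length(delta)
  if (length(age0) != n || length(fu) != n)
    stop("inputs must have equal length", call. = FALSE)
  if (any(!is.finite(delta)) || any(!is.finite(age0)) || any(!is.finite(fu)))
    stop("inputs must be finite", call. = FALSE)
  x <- cbind(`(Intercept)` = 1, age0 = age0, fu = fu,
             `age0:fu` = age0 * fu, `age0^2` = age0^2)
  if (n <= ncol(x))
    stop("need more observations than regressors", call. = FALSE)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning("rank-deficient design; dropping aliased column(s): ",
            paste(colnames(x)[setdiff(seq_len(ncol(x)), keep)],
                  collapse = ", "), call. = FALSE)
    x <- x[, keep, drop = FALSE]
  }
  stats::lm.fit(x, delta)$residuals
}

#' Standardized baseline score
#'
#' Residualizes the observed baseline phenotype for age and age squared,
#' then z-scores the residuals to mean 0, SD 1, so a subsequent regression
#' slope on age is in SD-per-year units and composites can be averaged
#' across phenotypes.
#'
#' @param p0_obs Observed baseline phenotype.
#' @param age0 Baseline age (years).
#' @return Z-scored, age-residualized baseline vector.
#' @export
standardize_baseline <- function(p0_obs, age0) {
  .check_pair(p0_obs, age0)
  if (length(p0_obs) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(p0_obs) == 0)
    stop("baseline phenotype has zero variance", call. = FALSE)
  r <- stats::lm.fit(cbind(1, age0, age0^2), p0_obs)$residuals
  s <- stats::sd(r)
  if (s < .Machine$double.eps^0.5)
    stop("zero residual variance after age adjustment; cannot z-score",
         call. = FALSE)
  (r - mean(r)) / s
}

#' Composite score by row-wise mean imputation
#'
#' Averages standardized component scores per individual. Missing entries
#' are replaced by the mean of the row's observed entries before averaging
#' — which is identical to simply averaging the observed entries. Rows
#' with fewer than `min_observed` observed components get a missing
#' composite (never zero).
#'
#' @param components Numeric matrix, one column per standardized component
#'   score, `NA` for missing.
#' @param min_observed Minimum observed components per row (default 1).
#' @return A `data.frame` with columns `composite` and `n_observed`.
#' @export
#' @examples
#' m <- rbind(c(0.5, -0.5), c(2, NA))
#' composite_score(m)
composite_score <- function(components, min_observed = 1L) {
  components <- as.matrix(components)
  min_observed <- as.integer(min_observed)
  if (is.na(min_observed) || min_observed < 1L)
    stop("'min_observed' must be a positive integer", call. = FALSE)
  n_obs <- rowSums(!is.na(components))
  comp <- rowMeans(components, na.rm = TRUE)
  comp[n_obs < min_observed] <- NA_real_
  comp[n_obs == 0L] <- NA_real_
  data.frame(composite = comp, n_observed = n_obs)
}

#' Build the full change-score table for a cohort
#'
#' Computes the three change definitions, their age/follow-up-duration
#' residualized versions, the standardized baseline score, and (when
#' several phenotype columns are supplied via multiple cohorts elsewhere)
#' the inputs to composite construction. The pipeline order follows the
#' two-wave protocol: raw change first, then baseline residualization for
#' the conditional score, then age/FU residualization
#' (`baseline_first = FALSE` swaps the last two steps for sensitivity
#' analyses).
#'
#' @param cohort A `cohort_table`.
#' @param definitions Character subset of `c("diff", "res", "log")`.
#' @param baseline_first For the conditional score: residualize on the
#'   observed baseline before (`TRUE`, default) or after the age/FU
#'   residualization.
#' @param log_shift Passed to [log_score()].
#' @param participants_only Restrict to rows with `participates == 1`
#'   (default TRUE: follow-up data only exist for participants).
#' @return A `data.frame` of class `"change_score_table"` with columns
#'   `delta_diff`, `delta_res`, `delta_log`, `delta_*_resid`, `p0_z`, plus
#'   `age0`, `fu`, `sex` and the dosage columns carried over for
#'   downstream association scans.
#' @export
change_scores <- function(cohort, definitions = c("diff", "res", "log"),
                          baseline_first = TRUE, log_shift = 0,
                          participants_only = TRUE) {
  stopifnot(inherits(cohort, "cohort_table"))
  definitions <- match.arg(definitions, c("diff", "res", "log"),
                           several.ok = TRUE)
  if (participants_only) cohort <- cohort[cohort$participates == 1L, ]
  p0 <- cohort$p0_obs
  p1 <- cohort$p1_obs
  age0 <- cohort$age0
  fu <- cohort$fu

  out <- cohort[c(grep("^snp_", names(cohort), value = TRUE),
                  "sex", "age0", "fu", "true_weight")]
  dd <- diff_score(p0, p1)
  if ("diff" %in% definitions) {
    out$delta_diff <- dd
    out$delta_diff_resid <- residualize_change(dd, age0, fu)
  }
  if ("res" %in% definitions) {
    if (baseline_first) {
      dr <- residual_change(dd, p0)
      out$delta_res <- dr
      out$delta_res_resid <- residualize_change(dr, age0, fu)
    } else {
      dr <- residual_change(residualize_change(dd, age0, fu), p0)
      out$delta_res <- dr
      out$delta_res_resid <- dr
    }
  }
  if ("log" %in% definitions) {
    dl <- log_score(p0, p1, shift = log_shift)
    out$delta_log <- dl
    out$delta_log_resid <- residualize_change(dl, age0, fu)
  }
  out$p0_z <- standardize_baseline(p0, age0)
  class(out) <- c("change_score_table", "data.frame")
  attr(out, "scenario") <- attr(cohort, "scenario")
  out
}

#' Write / read a change-score table as TSV
#'
#' @param scores A `change_score_table`.
#' @param path File path.
#' @return `write_scores` returns `path` invisibly; `read_scores` the
#'   table.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  out <- utils::read.delim(path, sep = "\t", na.strings = "NA",
                           check.names = FALSE)
  class(out) <- c("change_score_table", "data.frame")
  out
}

.check_pair <- function(a, b) {
  if (length(a) != length(b))
    stop("inputs must have equal length", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("inputs must be finite", call. = FALSE)
  invisible(TRUE)
}
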