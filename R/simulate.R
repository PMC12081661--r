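#' Simulate biallelic SNP dosages under Hardy-Weinberg proportions
#'
#' Each SNP j is an independent draw of 0/1/2 effect-allele counts,
#' `Binomial(2, maf[j])` per individual (no LD, no relatedness).
#'
#' @param n Number of individuals.
#' @param mafs Vector of effect-allele frequencies, each in (0, 0.5].
#' @param seed Optional integer seed.
#' @return Integer matrix `n x length(mafs)` with columns `snp_1`, ...
#' @export
#' @examples
#' g <- simulate_genotypes(100, c(0.1, 0.4), seed = 1)
#' colMeans(g)  # close to 2 * maf
simulate_genotypes <- function(n, mafs, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer", call. = FALSE)
  mafs <- as.numeric(mafs)
  if (any(!is.finite(mafs)) || any(mafs <= 0) || any(mafs > 0.5))
    stop("every maf must be finite and in (0, 0.5]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  m <- length(mafs)
  g <- matrix(stats::rbinom(n * m, size = 2L, prob = rep(mafs, each = n)),
              nrow = n, ncol = m)
  colnames(g) <- paste0("snp_", seq_len(m))
  g
}

#' Simulate a two-wave cohort from a scenario
#'
#' Draws genotypes, sex, baseline age, follow-up duration and the
#' individual-level environment, builds the latent phenotypes from the
#' structural model (see [scenario()]) at both waves, and adds independent
#' Gaussian measurement error per wave. Under the exponential form the
#' linear predictor is exponentiated before error is added; rows where
#' additive error drives an observed phenotype non-positive are flagged in
#' the `"n_nonpositive"` attribute (they are never silently altered).
#'
#' The returned cohort has `participates = 1` and `true_weight = 1` for
#' everyone; [apply_participation()] overwrites these when a participation
#' model is in play.
#'
#' @param scenario A [scenario()] object.
#' @return A `data.frame` of class `"cohort_table"` with columns
#'   `snp_1..snp_m`, `sex`, `age0`, `age1`, `fu`, `e0`, `e1`,
#'   `p0_latent`, `p1_latent`, `p0_obs`, `p1_obs`, `participates`,
#'   `true_weight`. The generating `scenario` is kept as an attribute.
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  sc <- scenario
  if (!is.null(sc$seed)) set.seed(sc$seed)
  n <- sc$n_individuals

  g <- simulate_genotypes(n, sc$maf)
  sex <- stats::rbinom(n, 1L, 0.5)
  age0 <- stats::runif(n, sc$age0_range[1], sc$age0_range[2])
  fu <- stats::runif(n, sc$fu_range[1], sc$fu_range[2])
  age1 <- age0 + fu
  u <- if (sc$env_noise_sd > 0) stats::rnorm(n, 0, sc$env_noise_sd) else numeric(n)
  e0 <- sc$env_slope * (age0 - sc$env_center) + u
  e1 <- sc$env_slope * (age1 - sc$env_center) + u

  g_alpha <- drop(g %*% sc$alpha)
  g_gamma <- drop(g %*% sc$gamma)
  g_sex <- drop(g %*% sc$sex_gxsex)
  sex_term <- sc$sex_main * sex + g_sex * sex

  eta0 <- sc$lambda_intercept + g_alpha + sc$beta_env * e0 + g_gamma * e0 + sex_term
  eta1 <- sc$lambda_intercept + g_alpha + sc$beta_env * e1 + g_gamma * e1 + sex_term
  if (sc$decline_form == "exponential") {
    p0_latent <- exp(eta0)
    p1_latent <- exp(eta1)
  } else {
    p0_latent <- eta0
    p1_latent <- eta1
  }
  eps0 <- if (sc$error_sd[1] > 0) stats::rnorm(n, 0, sc$error_sd[1]) else numeric(n)
  eps1 <- if (sc$error_sd[2] > 0) stats::rnorm(n, 0, sc$error_sd[2]) else numeric(n)
  p0_obs <- p0_latent + eps0
  p1_obs <- p1_latent + eps1

  out <- data.frame(g, sex = sex, age0 = age0, age1 = age1, fu = fu,
                    e0 = e0, e1 = e1,
                    p0_latent = p0_latent, p1_latent = p1_latent,
                    p0_obs = p0_obs, p1_obs = p1_obs,
                    participates = 1L, true_weight = 1)
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "scenario") <- sc
  if (sc$decline_form == "exponential") {
    n_nonpos <- sum(p0_obs <= 0 | p1_obs <= 0)
    attr(out, "n_nonpositive") <- n_nonpos
    if (n_nonpos > 0)
      warning(sprintf(
        "%d row(s) have non-positive observed phenotypes after additive error",
        n_nonpos), call. = FALSE)
  }
  out
}

#' Extract the dosage matrix from a cohort table
#'
#' @param cohort A `cohort_table`.
#' @return Numeric matrix of dosages, columns `snp_*`.
#' @export
dosage_matrix <- function(cohort) {
  cols <- grep("^snp_", names(cohort), value = TRUE)
  as.matrix(cohort[cols])
}

#' Apply selective follow-up participation to a cohort
#'
#' Draws the follow-up participation indicator from the scenario's logistic
#' model (logit linear in observed baseline phenotype, baseline age and
#' sex) and stores each row's true inverse-probability weight
#' `1 / P(participate)`. The marginal participation rate is attached as an
#' attribute and reported via `message()`.
#'
#' @param cohort A `cohort_table` from [simulate_cohort()].
#' @param scenario The scenario holding the participation model; defaults
#'   to the one stored in `cohort`.
#' @param seed Optional integer seed for the participation draws.
#' @param quiet Suppress the rate message.
#' @return The cohort with `participates` and `true_weight` filled in.
#' @export
apply_participation <- function(cohort, scenario = attr(cohort, "scenario"),
                                seed = NULL, quiet = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  pm <- scenario$participation
  if (is.null(pm))
    stop("scenario has no participation model", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lp <- pm$intercept + pm$p0_obs * cohort$p0_obs +
    pm$age0 * cohort$age0 + pm$sex * cohort$sex
  prob <- stats::plogis(lp)
  part <- stats::rbinom(nrow(cohort), 1L, prob)
  if (sum(part) == 0L)
    stop("degenerate sample: no individual participates at follow-up",
         call. = FALSE)
  cohort$participates <- part
  cohort$true_weight <- 1 / prob
  rate <- mean(part)
  attr(cohort, "participation_rate") <- rate
  if (!quiet)
    message(sprintf("follow-up participation rate: %.1f%% (%d / %d)",
                    100 * rate, sum(part), nrow(cohort)))
  cohort
}

#' Write / read a cohort table as TSV
#'
#' One row per individual, dosages as integer columns `snp_*`, missing
#' values as `NA`.
#'
#' @param cohort A `cohort_table`.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.delim(path, sep = "\t", na.strings = "NA",
                           check.names = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
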