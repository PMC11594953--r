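#' Ordinary least-squares fit with full inference table
#'
#' Thin wrapper around the QR least-squares solver returning the
#' coefficient table the validity analyses report: estimates, standard
#' errors, t statistics, two-sided p values and 95% confidence
#' intervals. Rank-deficient designs are rejected with the name of the
#' first collinear column rather than silently dropped.
#'
#' @param y Numeric outcome vector.
#' @param X Numeric predictor matrix (one row per observation). An
#'   intercept column is prepended unless `intercept = FALSE`.
#' @param intercept Prepend an intercept column.
#' @param conf_level Confidence level for the intervals.
#' @return A `linear_fit`: `coefficients` data frame (estimate, se, t,
#'   p_value, ci_lower, ci_upper), `sigma`, `df_residual`,
#'   `n_observations`.
#' @export
linear_fit <- function(y, X = NULL, intercept = TRUE, conf_level = 0.95) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (nrow(X) != n) stop("outcome and predictors differ in length")
  if (anyNA(y) || anyNA(X)) stop("missing values in outcome or predictors")
  if (intercept) X <- cbind("(Intercept)" = 1, X)
  p <- ncol(X)
  if (p == 0) stop("no predictors; set intercept = TRUE for an intercept-only fit")
  if (n <= p) stop("need more observations than coefficients (n = ", n, ", p = ", p, ")")
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):p]]
    stop("rank-deficient design: column(s) ", paste(dropped, collapse = ", "),
         " are collinear with the others")
  }
  fit <- lm.fit(X, y)
  coef <- fit$coefficients
  res <- fit$residuals
  df_res <- n - p
  sigma2 <- sum(res^2) / df_res
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- coef / se
  pval <- 2 * pt(abs(tval), df_res, lower.tail = FALSE)
  crit <- qt(1 - (1 - conf_level) / 2, df_res)
  tab <- data.frame(
    term = colnames(X), estimate = unname(coef), se = unname(se),
    t = unname(tval), p_value = unname(pval),
    ci_lower = unname(coef - crit * se), ci_upper = unname(coef + crit * se)
  )
  structure(
    list(coefficients = tab, sigma = sqrt(sigma2), df_residual = df_res,
         n_observations = n, conf_level = conf_level,
         fitted = fit$fitted.values, residuals = res),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Least-squares fit (n = %d, residual df = %d, sigma = %.4g)\n",
              x$n_observations, x$df_residual, x$sigma))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

# design matrix for the covariate-adjusted validity fits:
# SF total + age + sex (male = 1) + comorbidity count
validity_design <- function(cohort, sf_source) {
  sf <- category_code(cohort_sf_category(cohort, sf_source))
  sex_male <- as.integer(cohort$sex == "male")
  cbind(sf_total = sf, age = cohort$age, sex_male = sex_male,
        comorbidities = cohort$comorbidity_count)
}

#' Concurrent validity: long-form total regressed on short-form score
#'
#' Fits the PIH 96-point total on the short-form risk score, adjusting
#' for age, sex and comorbidity count. The short-form coefficient is the
#' headline association: each additional short-form risk point should
#' shift the long-form total downward.
#'
#' @param cohort Cohort data frame with PIH items, short-form domains,
#'   and demographics.
#' @inheritParams mace_summary
#' @return A `linear_fit`.
#' @export
concurrent_validity <- function(cohort, sf_source = c("nurse", "derived")) {
  sf_source <- match.arg(sf_source)
  lf_total <- score_pih(cohort)$total
  linear_fit(lf_total, validity_design(cohort, sf_source))
}

#' Predictive validity: 12-month event count regressed on short-form score
#'
#' Fits the 12-month composite event count (unplanned cardiovascular +
#' heart-failure admissions + death) on the short-form risk score with
#' the same covariate adjustment as [concurrent_validity()]. A linear
#' count model is used for transparency of the coefficient scale.
#'
#' @inheritParams concurrent_validity
#' @return A `linear_fit`.
#' @export
predictive_validity <- function(cohort, sf_source = c("nurse", "derived")) {
  sf_source <- match.arg(sf_source)
  events <- cohort$unplanned_cv_admissions + cohort$hf_admissions +
    as.integer(as.logical(cohort$died))
  linear_fit(events, validity_design(cohort, sf_source))
}
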