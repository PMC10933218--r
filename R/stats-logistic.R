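#' Binary logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit of a binary outcome on a covariate
#' table, reporting per-covariate odds ratios with Wald 95% confidence
#' intervals and p-values. Rows with missing values are dropped listwise.
#' Quasi-complete separation is detected heuristically (divergent
#' coefficients or standard errors) and flagged; the intervals are then
#' unreliable.
#'
#' The `cv_scale` convenience argument rescales a `cv_pct` column from
#' percent to fraction (`cv_pct / 100`) before fitting, since a CV
#' biomarker may enter the model on either scale and the odds ratio is
#' per-unit.
#'
#' @param outcome binary vector (see [roc_analysis()] for accepted
#'   codings); must contain both classes.
#' @param covariates data frame of covariates (numeric or two-level
#'   factors); no covariate may be constant. `NULL` fits the
#'   intercept-only model.
#' @param positive which outcome value counts as the event.
#' @param cv_scale `"percent"` (leave `cv_pct` as is) or `"fraction"`
#'   (divide by 100).
#' @param conf_level confidence level for the Wald intervals.
#' @return A `logistic_result` list: `table` (data frame with `term`,
#'   `estimate` (log-odds), `or`, `ci_low`, `ci_high`, `p_value`),
#'   `converged`, `separation`, `n`, and the underlying `fit`.
#' @export
logistic_fit <- function(outcome, covariates, positive = NULL,
                         cv_scale = c("percent", "fraction"),
                         conf_level = 0.95) {
  cv_scale <- match.arg(cv_scale)
  y <- as_binary_labels(outcome, positive)
  if (is.null(covariates))
    covariates <- data.frame(row.names = seq_along(y))  # intercept-only
  if (!is.data.frame(covariates)) covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(y))
    stop("covariates must have one row per outcome")
  if (cv_scale == "fraction" && "cv_pct" %in% names(covariates)) {
    covariates$cv_frac <- covariates$cv_pct / 100
    covariates$cv_pct <- NULL
  }
  dat <- cbind(data.frame(.y = as.integer(y)), covariates)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$.y)) < 2)
    stop("outcome must contain both classes")
  if (ncol(dat) > 1) {
    const <- vapply(dat[-1], function(x) length(unique(x)) < 2, TRUE)
    if (any(const))
      stop("constant covariate(s): ",
           paste(names(dat[-1])[const], collapse = ", "))
  }
  fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  z <- est / se
  tab <- data.frame(term = names(est),
                    estimate = unname(est),
                    or = exp(unname(est)),
                    ci_low = exp(unname(est - zq * se)),
                    ci_high = exp(unname(est + zq * se)),
                    p_value = 2 * pnorm(-abs(unname(z))),
                    stringsAsFactors = FALSE)
  separation <- any(abs(est) > 15) || any(se > 100) ||
    all(fit$fitted.values > 0.9999 | fit$fitted.values < 1e-4)
  structure(list(table = tab,
                 converged = fit$converged && !separation,
                 separation = separation,
                 n = nrow(dat),
                 fit = fit),
            class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("Logistic regression (n = %d)%s\n", x$n,
              if (x$separation) " [separation detected: CIs unreliable]"
              else ""))
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-20s OR %8.3f [%.3f, %.3f], p = %.4g\n", tab$term[i],
                tab$or[i], tab$ci_low[i], tab$ci_high[i], tab$p_value[i]))
  invisible(x)
}
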