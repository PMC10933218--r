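#' ROC analysis with Youden operating point
#'
#' The AUC is the probability that a randomly chosen positive subject's
#' score outranks a randomly chosen negative's, with ties counting 1/2 —
#' the normalized Mann-Whitney U statistic, computed here from mid-ranks.
#' The operating point maximizes the Youden index (sensitivity +
#' specificity - 1) over cutoffs of the form "positive if score >= c";
#' Youden ties are broken towards the higher specificity. The 95% AUC
#' confidence interval uses the DeLong structural-component variance. For
#' a binary score the AUC equals (sensitivity + specificity) / 2.
#'
#' @param labels binary outcome per subject (logical, 0/1, or a factor
#'   whose second level — or `positive` — is the event).
#' @param scores numeric (or ordinal) scores, higher = more positive.
#' @param positive which label value counts as positive; default: `TRUE`,
#'   `1`, or the last factor level.
#' @param conf_level confidence level for the AUC interval.
#' @return A `roc_result` list: `auc`, `ci` (length 2), `sensitivity`
#'   and `specificity` in percent, `cutoff`, `youden`, `n_positive`,
#'   `n_negative`.
#' @export
roc_analysis <- function(labels, scores, positive = NULL,
                         conf_level = 0.95) {
  y <- as_binary_labels(labels, positive)
  scores <- as.numeric(scores)
  if (length(y) != length(scores)) stop("labels and scores must be paired")
  keep <- !is.na(y) & !is.na(scores)
  y <- y[keep]; scores <- scores[keep]
  m <- sum(y); k <- sum(!y)
  if (m == 0 || k == 0) stop("both classes must be present")

  auc <- rank_auc(y, scores)
  v <- delong_components(y, scores)
  se <- sqrt(max(0, stats::var(v$v10) / m + stats::var(v$v01) / k))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * zq * se))

  # operating points: positive if score >= c, over all observed scores
  cuts <- sort(unique(scores))
  sens <- vapply(cuts, function(c) mean(scores[y] >= c), 1)
  spec <- vapply(cuts, function(c) mean(scores[!y] < c), 1)
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  if (length(best) > 1) best <- best[which.max(spec[best])]
  structure(list(auc = auc, ci = ci, se = se,
                 sensitivity = 100 * sens[best],
                 specificity = 100 * spec[best],
                 cutoff = cuts[best], youden = youden[best],
                 n_positive = m, n_negative = k),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f [%.3f, %.3f]; sensitivity %.2f%%, specificity %.2f%% at cutoff %g\n",
              x$auc, x$ci[1], x$ci[2], x$sensitivity, x$specificity,
              x$cutoff))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two classifiers scored on the same subjects using
#' DeLong's structural-component estimate of the variance of the AUC
#' difference, with a two-sided z-test. Identical (or rank-equivalent)
#' score vectors give a difference of 0 and p = 1.
#'
#' @param labels binary outcome per subject (see [roc_analysis()]).
#' @param scores_1,scores_2 paired score vectors on the same subjects.
#' @param positive which label value counts as positive.
#' @param conf_level confidence level for the difference interval.
#' @return A `delong_comparison` list: `auc_1`, `auc_2`, `difference`,
#'   `ci` (on the difference), `z`, `p_value`.
#' @export
delong_compare <- function(labels, scores_1, scores_2, positive = NULL,
                           conf_level = 0.95) {
  y <- as_binary_labels(labels, positive)
  if (length(scores_1) != length(y) || length(scores_2) != length(y))
    stop("scores must be paired with labels (equal lengths)")
  s1 <- as.numeric(scores_1); s2 <- as.numeric(scores_2)
  m <- sum(y); k <- sum(!y)
  if (m == 0 || k == 0) stop("both classes must be present")
  c1 <- delong_components(y, s1)
  c2 <- delong_components(y, s2)
  auc1 <- mean(c1$v10); auc2 <- mean(c2$v10)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / k
  diff <- auc1 - auc2
  zq <- qnorm(1 - (1 - conf_level) / 2)
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(diff) < 1e-12) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(var_diff)
  }
  p <- 2 * pnorm(-abs(z))
  ci <- diff + c(-1, 1) * zq * sqrt(max(0, var_diff))
  structure(list(auc_1 = auc1, auc_2 = auc2, difference = diff,
                 ci = ci, z = z, p_value = p,
                 var_difference = var_diff),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.3f vs %.3f, difference %.3f [%.3f, %.3f], z = %.3f, p = %.4g\n",
              x$auc_1, x$auc_2, x$difference, x$ci[1], x$ci[2], x$z,
              x$p_value))
  invisible(x)
}

# Mid-rank AUC (normalized Mann-Whitney U).
rank_auc <- function(y, scores) {
  r <- rank(scores)
  m <- sum(y); k <- sum(!y)
  (sum(r[y]) - m * (m + 1) / 2) / (m * k)
}

# DeLong structural components: v10[i] = mean_j psi(x_i, y_j) over
# negatives j for each positive i, and v01[j] symmetrically, where
# psi = 1, 1/2, 0 for x > y, x == y, x < y. Computed via mid-ranks.
delong_components <- function(y, scores) {
  pos <- scores[y]; neg <- scores[!y]
  m <- length(pos); k <- length(neg)
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos)
  r_neg <- rank(neg)
  v10 <- (r_all[seq_len(m)] - r_pos) / k
  v01 <- 1 - (r_all[m + seq_len(k)] - r_neg) / m
  list(v10 = v10, v01 = v01)
}

as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) {
    if (!is.null(positive)) return(labels == positive)
    return(labels)
  }
  if (is.factor(labels) || is.character(labels)) {
    f <- as.factor(labels)
    lev <- levels(f)
    if (is.null(positive)) positive <- lev[length(lev)]
    if (!positive %in% lev) stop("positive level '", positive, "' not found")
    return(f == positive)
  }
  x <- as.numeric(labels)
  if (is.null(positive)) positive <- 1
  x == positive
}
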