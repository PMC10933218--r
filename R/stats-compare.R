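#' Two-group comparison
#'
#' Compares two groups the way case-control imaging studies report
#' Table-1-style contrasts. Continuous data use Student's t-test
#' (equal-variance) or the Mann-Whitney U-test; `method = "auto"` picks
#' the nonparametric test when a Shapiro-Wilk normality pre-check
#' (alpha 0.05, per group) fails in either group. Categorical data use the
#' chi-square test, without continuity correction when all expected counts
#' are >= 5 and with Yates' correction otherwise.
#'
#' @param a,b numeric vectors (continuous scale), or — for
#'   `scale = "categorical"` — the two rows of a contingency table given
#'   as count vectors of equal length.
#' @param scale `"continuous"` or `"categorical"`.
#' @param method `"auto"`, `"parametric"` or `"nonparametric"`
#'   (continuous scale only).
#' @param alpha significance level recorded with the result (default 0.05
#'   for two groups).
#' @return A `group_comparison` list: `test_name`, `statistic`, `p_value`,
#'   `alpha_used`, `significant`, and per-group `summaries`.
#' @export
compare_two <- function(a, b, scale = c("continuous", "categorical"),
                        method = c("auto", "parametric", "nonparametric"),
                        alpha = 0.05) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  if (scale == "categorical") {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) != length(b) || length(a) < 2)
      stop("categorical comparison needs two count vectors of equal length >= 2")
    tab <- rbind(a, b)
    if (any(tab < 0) || any(rowSums(tab) == 0))
      stop("empty group in contingency table")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    correct <- any(expected < 5) && identical(dim(tab), c(2L, 2L))
    ht <- suppressWarnings(chisq.test(tab, correct = correct))
    res <- list(test_name = if (correct) "chi-square (Yates)" else "chi-square",
                statistic = unname(ht$statistic),
                p_value = ht$p.value,
                alpha_used = alpha,
                summaries = list(a = a, b = b))
  } else {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) < 2 || length(b) < 2)
      stop("each group needs at least 2 observations")
    use_np <- switch(method,
                     parametric = FALSE,
                     nonparametric = TRUE,
                     auto = !groups_look_normal(list(a, b)))
    if (use_np) {
      ht <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
      name <- "Mann-Whitney U"
    } else {
      ht <- t.test(a, b, var.equal = TRUE)
      name <- "Student t"
    }
    res <- list(test_name = name,
                statistic = unname(ht$statistic),
                p_value = ht$p.value,
                alpha_used = alpha,
                summaries = list(a = summarize_group(a),
                                 b = summarize_group(b)))
  }
  res$significant <- res$p_value < res$alpha_used
  structure(res, class = "group_comparison")
}

#' Three-group comparison with corrected pairwise follow-ups
#'
#' Omnibus one-way ANOVA (or Kruskal-Wallis when a normality pre-check
#' fails or `method = "nonparametric"`) over three groups, followed by the
#' three pairwise comparisons (P1: group 1 vs 2, P2: group 1 vs 3,
#' P3: group 2 vs 3), each judged at the Bonferroni-corrected level
#' alpha = 0.05/3 = 0.0167.
#'
#' @param groups list of exactly 3 numeric vectors (optionally named).
#' @param method `"auto"`, `"parametric"` or `"nonparametric"`.
#' @param pairwise_alpha corrected significance level for the pairwise
#'   comparisons (default 0.0167).
#' @return A `group_comparison` list with `test_name`, `statistic`,
#'   `p_value` (omnibus), `alpha_used` and a `pairwise` data frame
#'   (`comparison`, `p_value`, `significant`).
#' @export
compare_three <- function(groups,
                          method = c("auto", "parametric", "nonparametric"),
                          pairwise_alpha = 0.05 / 3) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) != 3)
    stop("'groups' must be a list of exactly 3 numeric vectors")
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 observations")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", 1:3)
  use_np <- switch(method,
                   parametric = FALSE,
                   nonparametric = TRUE,
                   auto = !groups_look_normal(groups))
  x <- unlist(groups)
  g <- factor(rep(nm, vapply(groups, length, 1L)), levels = nm)
  if (use_np) {
    ht <- kruskal.test(x, g)
    name <- "Kruskal-Wallis"
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    fit <- aov(x ~ g)
    s <- summary(fit)[[1]]
    name <- "one-way ANOVA"
    stat <- s[["F value"]][1]
    p <- s[["Pr(>F)"]][1]
  }
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  pw <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    ij <- pairs[[i]]
    cmp <- compare_two(groups[[ij[1]]], groups[[ij[2]]],
                       method = if (use_np) "nonparametric" else "parametric",
                       alpha = pairwise_alpha)
    data.frame(comparison = sprintf("P%d: %s vs %s", i, nm[ij[1]], nm[ij[2]]),
               p_value = cmp$p_value,
               significant = cmp$p_value < pairwise_alpha,
               stringsAsFactors = FALSE)
  }))
  structure(list(test_name = name, statistic = stat, p_value = p,
                 alpha_used = pairwise_alpha,
                 significant = p < pairwise_alpha,
                 summaries = lapply(groups, summarize_group),
                 pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (alpha %.4g)\n",
              x$test_name, x$statistic, x$p_value, x$alpha_used))
  if (!is.null(x$pairwise)) {
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %s: p = %.4g%s\n", x$pairwise$comparison[i],
                  x$pairwise$p_value[i],
                  if (x$pairwise$significant[i]) " *" else ""))
  }
  invisible(x)
}

summarize_group <- function(x) {
  list(n = length(x), mean = mean(x), sd = sd(x),
       median = median(x),
       iqr = unname(quantile(x, c(0.25, 0.75))))
}

# Shapiro-Wilk pre-check, alpha 0.05 per group; large groups are checked
# on an evenly spaced subsample of their order statistics (the test is
# defined for n <= 5000).
groups_look_normal <- function(groups, alpha = 0.05) {
  all(vapply(groups, function(x) {
    if (length(x) < 3 || sd(x) == 0) return(FALSE)
    if (length(x) > 5000)
      x <- sort(x)[round(seq(1, length(x), length.out = 5000))]
    shapiro.test(x)$p.value >= alpha
  }, TRUE))
}

#' Percentage from a count
#'
#' @param numerator,denominator non-negative counts with
#'   `numerator <= denominator` and `denominator > 0`.
#' @param digits decimals to round the percentage to (default 1, the
#'   conventional reporting precision).
#' @return Percentage, `100 * numerator / denominator`, rounded.
#' @export
proportion <- function(numerator, denominator, digits = 1) {
  if (denominator <= 0) stop("denominator must be > 0")
  if (numerator < 0 || numerator > denominator)
    stop("numerator must lie in [0, denominator]")
  round(100 * numerator / denominator, digits)
}
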