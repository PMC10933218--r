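test_that("two-group comparisons return the expected statistics", {
  # identical groups: Mann-Whitney with mid-ranks gives p ~ 1
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  mw <- compare_two(x, x, method = "nonparametric")
  expect_gt(mw$p_value, 0.9)
  # identical groups: zero t statistic
  tt <- compare_two(c(1, 2, 3), c(1, 2, 3), method = "parametric")
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  expect_error(compare_two(numeric(0), x), "at least 2")
})

test_that("chi-square on the perianal contingency matches the hand formula", {
  # CD: 129 yes / 215 no; UC: 18 yes / 219 no
  a <- 129; b <- 215; c <- 18; d <- 219; n <- a + b + c + d
  chi_hand <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  cmp <- compare_two(c(129, 215), c(18, 219), scale = "categorical")
  expect_equal(cmp$test_name, "chi-square")  # expected counts all >= 5
  expect_equal(cmp$statistic, chi_hand)
  expect_lt(cmp$p_value, 0.001)
  # small expected counts switch on Yates correction
  cmp2 <- compare_two(c(2, 30), c(8, 25), scale = "categorical")
  expect_match(cmp2$test_name, "Yates")
})

test_that("auto method selection uses a normality pre-check", {
  set.seed(5)
  norm_a <- rnorm(60); norm_b <- rnorm(60)
  expect_equal(compare_two(norm_a, norm_b)$test_name, "Student t")
  skew_a <- rexp(60); skew_b <- rexp(60)
  expect_equal(compare_two(skew_a, skew_b)$test_name, "Mann-Whitney U")
})

test_that("three-group comparison flags pairwise contrasts at 0.0167", {
  set.seed(11)
  base <- rnorm(50)
  g <- list(a = base, b = base, c = base)
  same <- compare_three(g, method = "parametric")
  expect_equal(same$p_value, 1)
  expect_false(any(same$pairwise$significant))

  # one group shifted by 10 SDs: omnibus and its two contrasts flagged
  shifted <- list(a = rnorm(50), b = rnorm(50), c = rnorm(50) + 10)
  res <- compare_three(shifted, method = "parametric")
  expect_lt(res$p_value, 1e-10)
  expect_equal(res$pairwise$significant, c(FALSE, TRUE, TRUE))

  # a contrast with p ~ 0.03 is NOT significant at the corrected level
  x <- c(1, 2, 3, 4, 5)
  res2 <- compare_three(list(x, x + 2.6, x), method = "parametric")
  p12 <- res2$pairwise$p_value[1]
  expect_gt(p12, 0.0167); expect_lt(p12, 0.05)
  expect_false(res2$pairwise$significant[1])
  expect_equal(res2$alpha_used, 0.05 / 3)
  expect_error(compare_three(list(x, x)), "exactly 3")
})

test_that("proportions reproduce printed one-decimal percentages", {
  expect_equal(proportion(129, 344), 37.5)
  expect_equal(proportion(18, 237), 7.6)
  expect_equal(proportion(0, 100), 0)
  expect_error(proportion(1, 0), "> 0")
  expect_error(proportion(5, 4), "numerator")
})

test_that("logistic regression recovers odds ratios and flags separation", {
  set.seed(21)
  n <- 1e4
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.4)  # independent of x
  fit <- logistic_fit(y, data.frame(x = x))
  row <- fit$table[fit$table$term == "x", ]
  expect_true(row$ci_low <= 1 && 1 <= row$ci_high)

  # intercept-only, balanced outcome: odds = 1
  fit0 <- logistic_fit(rep(c(0, 1), 50), NULL)
  expect_equal(fit0$table$or[1], 1, tolerance = 1e-6)

  # coefficient bias < 5% at n = 5000 under a known model
  set.seed(22)
  n <- 5000
  cvf <- rnorm(n, 0.28, 0.14)           # CV on the fraction scale
  beta <- log(6)
  p <- plogis(-1 + beta * cvf)
  y <- rbinom(n, 1, p)
  fit2 <- logistic_fit(y, data.frame(cv = cvf))
  b_hat <- fit2$table$estimate[fit2$table$term == "cv"]
  expect_lt(abs(b_hat - beta) / beta, 0.05)
  expect_true(fit2$converged)

  # complete separation is detected
  ys <- rep(c(0, 1), each = 20)
  xs <- c(rnorm(20, -5), rnorm(20, 5))
  fits <- logistic_fit(ys, data.frame(x = xs))
  expect_true(fits$separation)

  expect_error(logistic_fit(rep(1, 10), data.frame(x = rnorm(10))),
               "both classes")
  expect_error(logistic_fit(rep(c(0, 1), 5), data.frame(x = rep(2, 10))),
               "constant covariate")
})

test_that("cv_scale = 'fraction' rescales the CV covariate", {
  set.seed(23)
  cvp <- rnorm(500, 28, 14)
  y <- rbinom(500, 1, plogis(-1 + 0.02 * cvp))
  f_pct <- logistic_fit(y, data.frame(cv_pct = cvp), cv_scale = "percent")
  f_frac <- logistic_fit(y, data.frame(cv_pct = cvp), cv_scale = "fraction")
  b_pct <- f_pct$table$estimate[f_pct$table$term == "cv_pct"]
  b_frac <- f_frac$table$estimate[f_frac$table$term == "cv_frac"]
  expect_equal(b_frac, b_pct * 100, tolerance = 1e-6)
})

test_that("t-test type-I error is calibrated near the nominal level", {
  set.seed(31)
  rejections <- mean(replicate(2000, {
    compare_two(rnorm(30), rnorm(30), method = "parametric")$p_value < 0.05
  }))
  expect_gte(rejections, 0.03)
  expect_lte(rejections, 0.07)
})
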