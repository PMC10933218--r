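test_that("AUC equals the brute-force pairwise probability", {
  # perfect, uninformative, and random score patterns
  y <- rep(c(1, 0), c(30, 40))
  expect_equal(roc_analysis(y, ifelse(y == 1, 2, 1))$auc, 1)
  expect_equal(roc_analysis(y, rep(7, 70))$auc, 0.5)
  for (s in 1:5) {
    set.seed(s)
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    scores <- sample(seq(-3, 3, 0.5), n, replace = TRUE)  # many ties
    expect_equal(roc_analysis(y, scores)$auc, brute_force_auc(y, scores))
  }
  expect_error(roc_analysis(rep(1, 10), rnorm(10)), "both classes")
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(8)
  y <- rbinom(120, 1, 0.5)
  s <- rnorm(120)
  a0 <- roc_analysis(y, s)$auc
  expect_equal(roc_analysis(y, exp(s))$auc, a0)
  expect_equal(roc_analysis(y, 3 * s - 10)$auc, a0)
  expect_equal(roc_analysis(y, rank(s))$auc, a0)
})

test_that("a binary predictor yields AUC = (sens + spec)/2 at its cutoff", {
  # perianal-disease style 2x2: 40/100 positive among cases, 5/50 controls
  y <- rep(c(1, 0), c(100, 50))
  s <- c(rep(1, 40), rep(0, 60), rep(1, 5), rep(0, 45))
  r <- roc_analysis(y, s)
  expect_equal(r$sensitivity, 40)
  expect_equal(r$specificity, 90)
  expect_equal(r$auc, (0.40 + 0.90) / 2)
})

test_that("AUC and DeLong machinery agree with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(150, 1, 0.4)
  s1 <- rnorm(150) + y
  s2 <- rnorm(150) + 0.6 * y
  r <- roc_analysis(y, s1)
  pr <- pROC::roc(y, s1, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$ci, ci[c(1, 3)], tolerance = 1e-8)
  d <- delong_compare(y, s1, s2)
  pd <- pROC::roc.test(pr, pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(d$p_value, pd$p.value, tolerance = 1e-8)
})

test_that("DeLong comparison degenerates correctly for equivalent classifiers", {
  y <- rep(c(1, 0), c(12, 15))
  s <- c(rnorm(12, 1), rnorm(15))
  d <- delong_compare(y, s, s)
  expect_equal(d$difference, 0)
  expect_equal(d$p_value, 1)
  # strictly monotone transform: same ranks, zero AUC difference
  d2 <- delong_compare(y, s, exp(s) + 2)
  expect_equal(d2$difference, 0)
  expect_error(delong_compare(y, s, s[-1]), "paired")
})

test_that("DeLong variance agrees with a stratified bootstrap oracle", {
  y <- rep(c(1, 0), c(4, 6))
  s1 <- c(2.3, 1.1, 3.4, 0.9, 0.4, 1.5, -0.2, 1.0, 2.1, 0.3)
  s2 <- c(1.9, 0.7, 2.8, 1.4, 0.8, 1.2, 0.1, 0.6, 1.7, 0.5)
  d <- delong_compare(y, s1, s2)
  psi <- function(p, n) outer(p, n, function(a, b) (a > b) + 0.5 * (a == b))
  P1 <- psi(s1[y == 1], s1[y == 0])
  P2 <- psi(s2[y == 1], s2[y == 0])
  set.seed(123)
  B <- 1e5
  diffs <- numeric(B)
  for (b in seq_len(B)) {
    pi <- sample.int(4, replace = TRUE)
    ni <- sample.int(6, replace = TRUE)
    diffs[b] <- mean(P1[pi, ni]) - mean(P2[pi, ni])
  }
  expect_lt(abs(var(diffs) - d$var_difference) / d$var_difference, 0.15)
})

test_that("DeLong p-values are near-uniform under the null", {
  set.seed(99)
  ps <- replicate(2000, {
    y <- rep(c(1, 0), each = 50)
    delong_compare(y, rnorm(100), rnorm(100))$p_value
  })
  ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(ks, 0.05)
})

test_that("Youden ties break towards higher specificity", {
  # two cutoffs share the maximal Youden index; the higher-specificity
  # operating point must be reported
  y <- c(1, 1, 0, 0)
  s <- c(4, 2, 3, 1)
  r <- roc_analysis(y, s)
  # cutoffs >= 2: sens 1, spec 0.5 (J = .5); >= 4: sens .5, spec 1 (J = .5)
  expect_equal(r$specificity, 100)
  expect_equal(r$sensitivity, 50)
  expect_equal(r$cutoff, 4)
})
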