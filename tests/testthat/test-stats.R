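test_that("exact Mann-Whitney agrees with full enumeration", {
  ## worked example: complete separation of {1,2,3} vs {4,5,6}
  m <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(m$statistic), 0)
  expect_equal(m$p_value, 0.1)             # 2 / C(6,3)
  ## all sample size pairs up to 6, tie-free draws
  set.seed(31)
  for (n1 in 2:6) for (n2 in 2:6) {
    x <- sample(seq_len(100), n1); y <- sample(seq_len(100) + 200, n2)
    y <- y + runif(n2)                     # guarantee no ties
    m <- mann_whitney(x, y)
    expect_true(m$exact)
    expect_equal(m$p_value, mwu_enum_p(x, y), tolerance = 1e-12,
                 label = paste("n1,n2 =", n1, n2))
  }
  ## identical samples: no separation
  expect_gte(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney P is invariant under monotone transforms", {
  set.seed(8)
  x <- rlnorm(24); y <- rlnorm(13, 0.4)
  p1 <- mann_whitney(x, y)$p_value
  p2 <- mann_whitney(log(x), log(y))$p_value
  p3 <- mann_whitney(exp(x / 10), exp(y / 10))$p_value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("categorical tests switch on the expected-count rule", {
  ## sparse 2x2 goes through Fisher; matches hypergeometric enumeration
  tab <- matrix(c(5, 0, 0, 5), 2, 2)
  ct <- categorical_test(tab)
  expect_equal(ct$test, "fisher")
  expect_equal(ct$p_value, 2 / 252, tolerance = 1e-12)
  expect_equal(ct$p_value, fisher_enum_p(tab), tolerance = 1e-12)
  set.seed(4)
  for (k in 1:10) {
    tab <- matrix(rbinom(4, 8, 0.5), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ct <- categorical_test(tab)
    if (ct$test == "fisher")
      expect_equal(ct$p_value, fisher_enum_p(tab), tolerance = 1e-10)
  }
  ## identical rows: P = 1
  expect_equal(categorical_test(matrix(c(10, 10, 10, 10), 2, 2))$p_value,
               1, tolerance = 1e-12)
  ## big balanced 2x3 goes through chi-square; hand statistic oracle
  tab3 <- matrix(c(20, 10, 15, 18, 12, 9), nrow = 2, byrow = TRUE)
  ct3 <- categorical_test(tab3)
  expect_equal(ct3$test, "chi_square")
  E <- outer(rowSums(tab3), colSums(tab3)) / sum(tab3)
  X2 <- sum((tab3 - E)^2 / E)
  expect_equal(unname(ct3$statistic), X2, tolerance = 1e-12)
  expect_equal(ct3$p_value, pchisq(X2, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(categorical_test(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "margin")
  expect_error(categorical_test(matrix(c(1.5, 2, 3, 4), 2, 2)), "integer")
})

test_that("Spearman pruning keeps the lowest-P cluster representative", {
  set.seed(12)
  n <- 60
  a <- rnorm(n)
  tab <- data.frame(A = a, B = a * 2 + 1e-8 * rnorm(n),
                    C = -a + 1e-8 * rnorm(n), D = rnorm(n))
  pv <- c(A = 0.003, B = 0.018, C = 0.001, D = 0.04)
  ## no edges: everything kept
  res0 <- spearman_prune(tab[, c("A", "D")], c("A", "D"), pv)
  expect_setequal(res0$kept, c("A", "D"))
  ## perfectly correlated pair: keep the lower-P member
  res1 <- spearman_prune(tab, c("A", "B"), pv)
  expect_identical(res1$kept, "A")
  ## chain A~B, A~C (negative edge counts too): one survivor of {A,B,C}
  res2 <- spearman_prune(tab, c("A", "B", "C", "D"), pv)
  expect_setequal(res2$kept, c("C", "D"))    # C has the lowest P in the cluster
  expect_length(res2$components, 2L)
  ## tie on P: lexicographic name
  pv2 <- c(A = 0.01, B = 0.01)
  expect_identical(spearman_prune(tab, c("A", "B"), pv2)$kept, "A")
  expect_error(spearman_prune(tab, c("A", "Z"), pv), "missing from table")
})

test_that("univariate logistic regression recovers known parameters", {
  set.seed(21)
  n <- 2000
  x <- rnorm(n, 50, 20)
  y <- rbinom(n, 1, plogis(-2 + 0.05 * x))
  fit <- univariate_logistic(x, y, variable = "x")
  expect_true(fit$converged)
  b <- fit$terms$coefficient
  expect_lt(abs(b - 0.05) / 0.05, 0.2)
  expect_equal(fit$terms$odds_ratio, exp(b))
  expect_true(fit$terms$ci_low <= fit$terms$odds_ratio &&
                fit$terms$odds_ratio <= fit$terms$ci_high)
  ## rescaling the predictor rescales the slope exactly
  fit10 <- univariate_logistic(x / 10, y, variable = "x")
  expect_equal(fit10$terms$coefficient, 10 * b, tolerance = 1e-6)
  ## a null predictor's CI covers OR = 1
  z <- rnorm(n)
  fit0 <- univariate_logistic(z, y, variable = "z")
  expect_true(fit0$terms$ci_low < 1 && 1 < fit0$terms$ci_high)
  ## perfect separation is flagged, not silently reported
  xs <- c(rnorm(30, -5), rnorm(30, 5)); ys <- rep(0:1, each = 30)
  expect_false(univariate_logistic(xs, ys)$converged)
  expect_error(univariate_logistic(x, rep(1, n)), "both classes")
})

test_that("backward stepwise elimination keeps informative terms", {
  ## informative + pure noise: noise is dropped in nearly all replicates
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 300
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 1.2 * x1))
    bs <- backward_stepwise(data.frame(x1 = x1, x2 = x2),
                            c("x1", "x2"), y)
    identical(bs$variables, "x1")
  }, logical(1))
  expect_gte(mean(hits), 0.85)
  ## all-noise: intercept-only final model at a rate consistent with the
  ## 0.10 removal threshold
  empty <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    n <- 200
    y <- rbinom(n, 1, 0.4)
    bs <- backward_stepwise(data.frame(x = rnorm(n)), "x", y)
    length(bs$variables) == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.8)
  ## single strongly informative variable survives and equals the
  ## univariate fit
  set.seed(77)
  n <- 500; x <- rnorm(n)
  y <- rbinom(n, 1, plogis(x))
  bs <- backward_stepwise(data.frame(x = x), "x", y)
  uv <- univariate_logistic(x, y, "x")
  expect_identical(bs$variables, "x")
  expect_equal(bs$terms$coefficient, uv$terms$coefficient)
  expect_error(backward_stepwise(data.frame(x = x), character(0), y),
               "at least one")
})

test_that("ROC analysis matches brute-force pair counting and the U identity", {
  ## worked example
  r <- roc_analysis(c(1, 2, 3, 2.5, 4, 5), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 8 / 9, tolerance = 1e-12)
  ## perfect separation
  rp <- roc_analysis(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(rp$auc, 1)
  expect_equal(rp$sensitivity, 1)
  expect_equal(rp$specificity, 1)
  ## AUC = U/(n1 n2), ties counted one half, on tied random data
  set.seed(14)
  for (k in 1:5) {
    sc <- sample(1:8, 40, replace = TRUE)
    lb <- rep(c(0, 1), c(24, 16))
    r2 <- roc_analysis(sc, lb)
    u <- unname(mann_whitney(sc[lb == 1], sc[lb == 0])$statistic)
    a <- auc_brute(sc, lb)
    ## the empirical curve is reported in the recorded direction; with
    ## half-weight ties the reversed-direction area is its complement
    if (r2$direction == "lower-score-event") { u <- 24 * 16 - u; a <- 1 - a }
    expect_equal(r2$auc, u / (24 * 16), tolerance = 1e-12)
    expect_equal(r2$auc, a, tolerance = 1e-12)
  }
  ## reported cutoff attains the reported sensitivity/specificity
  set.seed(3)
  sc <- rnorm(60); lb <- rbinom(60, 1, plogis(2 * sc))
  if (length(unique(lb)) == 2) {
    r3 <- roc_analysis(sc, lb)
    sens <- mean(sc[lb == 1] >= r3$cutoff)
    spec <- mean(sc[lb == 0] < r3$cutoff)
    expect_equal(r3$sensitivity, sens, tolerance = 1e-9)
    expect_equal(r3$specificity, spec, tolerance = 1e-9)
  }
  ## constant scores flagged
  expect_warning(rc <- roc_analysis(rep(1, 10), rep(c(0, 1), 5)),
                 "constant")
  expect_equal(rc$auc, 0.5)
  expect_equal(rc$flag, "constant-scores")
})
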