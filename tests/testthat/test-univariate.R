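test_that("Anderson-Darling matches the reference implementation and has power", {
  set.seed(1)
  x <- rnorm(50)
  got <- anderson_darling(x)
  ref <- nortest::ad.test(x)           # reference implementation
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  # nortest reports the uncorrected A^2; rescale by the small-sample factor
  expect_equal(got$A2_star,
               unname(ref$statistic) * (1 + 0.75 / 50 + 2.25 / 50^2),
               tolerance = 1e-12)
  # strongly lognormal samples are rejected most of the time
  set.seed(2)
  rej <- vapply(1:200, function(i)
    anderson_darling(exp(rnorm(50)))$reject, TRUE)
  expect_gt(mean(rej), 0.9)
  expect_error(anderson_darling(rep(1, 20)), "constant")
  expect_warning(anderson_darling(rnorm(7) + 1:7), "n < 8")
})

test_that("F test matches closed-form CDF evaluation and is symmetric", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  got <- f_test_equal_var(x, y)
  expect_equal(got$F, var(x) / var(y), tolerance = 1e-12)
  expect_equal(got$F, 0.25, tolerance = 1e-12)
  p_oracle <- 2 * min(pf(0.25, 3, 3), 1 - pf(0.25, 3, 3))
  expect_equal(got$p, p_oracle, tolerance = 1e-12)
  swapped <- f_test_equal_var(y, x)
  expect_equal(swapped$F, 1 / got$F, tolerance = 1e-12)
  expect_equal(swapped$p, got$p, tolerance = 1e-12)
  same <- f_test_equal_var(x, x)
  expect_equal(same$F, 1); expect_equal(same$p, 1)
  expect_error(f_test_equal_var(rep(1, 3), x), "zero variance")
})

test_that("t tests agree with the hand-computed pooled formula", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 6)
  # hand computation: pooled s^2 = 2.5, se = sqrt(2.5 * 2/5) = 1
  got <- student_t(x, y)
  expect_equal(got$t, -1, tolerance = 1e-12)
  expect_equal(got$df, 8)
  expect_equal(got$p, 2 * pt(-1, 8), tolerance = 1e-12)
  # equal n, equal variance: Welch reduces to Student exactly
  w <- welch_t(x, y)
  expect_equal(w$t, got$t, tolerance = 1e-12)
  expect_equal(w$df, 8, tolerance = 1e-12)
  # identical samples
  expect_equal(student_t(x, x)$p, 1)
  expect_equal(welch_t(x, x)$p, 1)
  # Welch df never exceeds n1 + n2 - 2
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(5 + i, sd = runif(1, 0.2, 3)); b <- rnorm(30, sd = 1)
    expect_lte(welch_t(a, b)$df, length(a) + length(b) - 2 + 1e-9)
  }
})

test_that("KS statistic equals the brute-force ECDF supremum", {
  expect_equal(ks_two_sample(1:10, 1:10)$D, 0)
  expect_equal(ks_two_sample(1:10, 1:10)$p, 1)
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(5, 6, 7, 8))$D, 1)
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30, 0.4)
  got <- ks_two_sample(x, y)$D
  pooled <- c(x, y)
  brute <- max(vapply(pooled, function(t)
    abs(mean(x <= t) - mean(y <= t)), 0))
  expect_equal(got, brute, tolerance = 1e-12)
})

test_that("Mann-Whitney U, exact enumeration, and the AUC identity hold", {
  got <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(got$U, 0)
  expect_equal(got$p, 2 / choose(4, 2), tolerance = 1e-12)  # all 6 labelings
  same <- mann_whitney_u(1:10, 1:10)
  expect_equal(same$auc, 0.5)
  expect_gt(same$p, 0.99)
  # U/(n1 n2) equals the pairwise win fraction (+ half ties), 50 instances
  set.seed(5)
  for (i in 1:50) {
    x <- sample(1:20, sample(3:12, 1), replace = TRUE)
    y <- sample(1:20, sample(3:12, 1), replace = TRUE)
    pair <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(mann_whitney_u(x, y)$auc, mean(pair), tolerance = 1e-12)
  }
})

test_that("the selection tree routes each distributional regime correctly", {
  set.seed(6)
  # normal, equal variance -> Student's t
  d1 <- select_and_test(rnorm(60, 10), rnorm(50, 10))
  expect_equal(d1$final_test, "Student_t")
  expect_equal(d1$route, "AD_pass_F_pass")
  expect_equal(d1$central_type, "mean")
  # normal, very unequal variance -> Welch
  set.seed(7)
  d2 <- select_and_test(rnorm(60, 10, 1), rnorm(50, 10, 4))
  expect_equal(d2$final_test, "Welch")
  expect_equal(d2$route, "AD_pass_F_fail")
  # both lognormal, same shape -> Mann-Whitney with medians
  set.seed(8)
  d3 <- select_and_test(exp(rnorm(60)), exp(rnorm(50)))
  expect_equal(d3$final_test, "MannWhitneyU")
  expect_equal(d3$central_type, "median")
  # one skewed vs one normal of different shape -> Welch with the
  # different-shape note
  set.seed(12)
  d4 <- select_and_test(exp(rnorm(80, 0, 0.8)), rnorm(80, 1.2, 0.3))
  expect_equal(d4$route, "AD_fail_KS_fail")
  expect_equal(d4$final_test, "Welch")
  expect_match(d4$note, "not.*same shape")
  expect_true(all(c(d1$p_value, d2$p_value, d3$p_value, d4$p_value) >= 0 &
                    c(d1$p_value, d2$p_value, d3$p_value, d4$p_value) <= 1))
})

test_that("multiplicity correction reproduces the null conclusion and dominance", {
  # fifteen analytes at raw p = 0.03: Bonferroni lifts to 0.45
  adj <- multiplicity_correct(rep(0.03, 15), "bonferroni")
  expect_equal(adj, rep(0.45, 15))
  expect_true(all(adj > 0.05))       # no longer significant after correction
  expect_equal(multiplicity_correct(0.2), 0.2)   # single p unchanged
  set.seed(9)
  for (i in 1:100) {
    p <- runif(sample(2:20, 1))
    expect_true(all(multiplicity_correct(p, "holm") <=
                      multiplicity_correct(p, "bonferroni") + 1e-12))
  }
})

test_that("sample-size formula reproduces the a priori study size", {
  expect_identical(min_sample_size(0.5, 0.1, 0.8), 49L)
  expect_lte(min_sample_size(5, 0.1, 0.8), 2L)
  expect_identical(min_sample_size(0.5, 0.1, 0.8, sided = "one"), 36L)
  # power-simulation oracle: n = 49 sits at the edge of 80% power and
  # dominates n - 2 (the normal approximation rounds just below target)
  pw <- function(n) power.t.test(n = n, delta = 0.5, sd = 1,
                                 sig.level = 0.1)$power
  expect_gte(pw(49), 0.78)
  expect_lt(pw(47), pw(49))
  expect_lt(pw(49), pw(51))
  set.seed(10)
  sim <- mean(replicate(4000, t.test(rnorm(49, 0.5), rnorm(49))$p.value < 0.1))
  expect_lt(abs(sim - pw(49)), 0.025)
})
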