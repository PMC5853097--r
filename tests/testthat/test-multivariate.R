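test_that("FDA recovers the hand-computed discriminant on a tiny instance", {
  # 2 variables, 3 + 3 points
  Xa <- rbind(c(1, 2), c(2, 3), c(3, 5))
  Xn <- rbind(c(4, 1), c(5, 2), c(6, 2))
  tab <- data.frame(cohort = rep(c("ASD", "NEU"), each = 3),
                    AA = c(Xa[, 1], Xn[, 1]), DHA = c(Xa[, 2], Xn[, 2]))
  tab <- cohort_table(tab)
  fit <- fda_fit(tab, variables = c("AA", "DHA"), ridge = 0,
                 standardize = FALSE)
  # closed form, computed independently: Sw^{-1} (m1 - m2)
  Sw <- (crossprod(sweep(Xa, 2, colMeans(Xa))) +
           crossprod(sweep(Xn, 2, colMeans(Xn)))) / (6 - 2)
  w_hand <- solve(Sw, colMeans(Xa) - colMeans(Xn))
  w_hand <- w_hand / sqrt(sum(w_hand^2))
  # direction defined up to sign
  s <- sign(sum(w_hand * fit$weights))
  expect_lt(max(abs(fit$weights - s * w_hand)), 1e-10)
})

test_that("FDA separates distant clouds and its C-statistic is scale/sign invariant", {
  set.seed(30)
  n <- 60
  tab <- cohort_table(data.frame(
    cohort = rep(c("ASD", "NEU"), each = n),
    AA = c(rnorm(n, 28), rnorm(n, 20)),
    DHA = c(rnorm(n, 12), rnorm(n, 20))))
  fit <- fda_fit(tab, variables = c("AA", "DHA"))
  expect_gt(fit$score_c_statistic$c_statistic, 0.99)
  expect_gte(fit$score_c_statistic$c_statistic, 0.5)
  # affine rescaling of an input leaves scores equivalent (ridge ~ 0)
  tab2 <- tab; tab2$AA <- tab2$AA * 1000
  fit2 <- fda_fit(tab2, variables = c("AA", "DHA"), ridge = 0,
                  standardize = FALSE)
  fit1 <- fda_fit(tab, variables = c("AA", "DHA"), ridge = 0,
                  standardize = FALSE)
  expect_equal(fit2$score_c_empirical$c_statistic,
               fit1$score_c_empirical$c_statistic, tolerance = 1e-9)
})

test_that("FDA score separation matches the optimal-projection oracle for shared-covariance normals", {
  set.seed(31)
  n <- 5000
  S <- matrix(c(1, 0.5, 0.5, 2), 2)
  L <- chol(S)
  delta <- c(1, 0.5)
  Xn <- matrix(rnorm(2 * n), n) %*% L + 10
  Xa <- sweep(matrix(rnorm(2 * n), n) %*% L + 10, 2, -delta)
  tab <- cohort_table(data.frame(cohort = rep(c("ASD", "NEU"), each = n),
                                 AA = c(Xa[, 1], Xn[, 1]),
                                 DHA = c(Xa[, 2], Xn[, 2])))
  fit <- fda_fit(tab, variables = c("AA", "DHA"))
  # oracle: project on the true optimal direction S^{-1} delta
  w_opt <- solve(S, delta)
  c_opt <- c_statistic(Xa %*% w_opt, Xn %*% w_opt,
                       method = "empirical")$c_statistic
  expect_lt(abs(fit$score_c_empirical$c_statistic - c_opt), 0.01)
})

test_that("FDA input handling: missing rows dropped, singular scatter flagged", {
  tab <- default_tab(31)
  tab$AA[1] <- NA
  expect_warning(fit <- fda_fit(tab), "missing")
  expect_equal(fit$n_dropped, 1L)
  expect_length(fit$weights, 15L)
  # duplicated column makes the scatter singular at zero ridge
  dup <- tab
  dup$DHA_AA <- dup$AA   # collinear with AA after standardization
  expect_error(suppressWarnings(fda_fit(dup, ridge = 0)), "ridge")
})

test_that("PLS reproduces exact fits, least squares, and its kernel reduction", {
  set.seed(32)
  n <- 40
  tab <- data.frame(cohort = rep(c("ASD", "NEU"), each = n / 2),
                    AA = rnorm(n, 10), DHA = rnorm(n, 10),
                    EPA = rnorm(n, 10))
  tab$severity_total <- 2 * tab$AA + 1
  tab <- cohort_table(tab)
  # y exactly linear in one predictor: one component gives R^2 = 1
  m1 <- pls_regress(tab, "AA", "severity_total", n_components = 1)
  expect_lt(abs(m1$r_squared - 1), 1e-10)
  # full components on full-rank X reproduce least squares
  tab$severity_total <- rnorm(n)
  m3 <- pls_regress(tab, c("AA", "DHA", "EPA"), "severity_total",
                    n_components = 3)
  ls <- lm(severity_total ~ AA + DHA + EPA, data = tab)
  expect_lt(max(abs(m3$fitted - fitted(ls))), 1e-8)
  # kernel PLS with a (wide) RBF approaching linear behaviour is exercised
  # via its exact linear-kernel reduction below
  kfit <- fattyroc:::kernel_pls1(tcrossprod(scale(as.matrix(
    tab[c("AA", "DHA", "EPA")]), scale = FALSE)),
    tab$severity_total - mean(tab$severity_total), 2)
  lfit <- fattyroc:::nipals_pls1(scale(as.matrix(
    tab[c("AA", "DHA", "EPA")]), scale = FALSE),
    tab$severity_total - mean(tab$severity_total), 2)
  lin_fitted <- drop(scale(as.matrix(tab[c("AA", "DHA", "EPA")]),
                           scale = FALSE) %*% lfit$beta)
  expect_lt(max(abs(drop(kfit$Kc %*% kfit$alpha) - lin_fitted)), 1e-8)
  # too many components is a hard error
  expect_error(pls_regress(tab, c("AA", "DHA"), "severity_total",
                           n_components = 3), "rank")
})

test_that("severity unrelated to the panel yields poor out-of-sample R^2", {
  set.seed(33)
  spec <- default_study_spec(seed = 33)
  tab <- generate_cohort(spec)
  tab$severity_score <- rnorm(nrow(tab), 50, 10)   # independent of panel
  r2s <- vapply(1:5, function(i) {
    tab$severity_score <- rnorm(nrow(tab), 50, 10)
    pls_regress(tab, fa_measured(), "severity_score",
                n_components = 2, loo = TRUE)$r_squared_loo
  }, 0)
  expect_true(all(r2s <= 0.1))
})

test_that("seafood correlations match hand computation and the coupling direction", {
  # 5-row hand table
  tab <- tiny_cohort(3, 2)
  tab$seafood_meals_per_month <- c(1, 4, 2, 6, 3)
  r_hand <- sum((tab$DHA - mean(tab$DHA)) *
                  (tab$seafood_meals_per_month -
                     mean(tab$seafood_meals_per_month))) /
    sqrt(sum((tab$DHA - mean(tab$DHA))^2) *
           sum((tab$seafood_meals_per_month -
                  mean(tab$seafood_meals_per_month))^2))
  got <- seafood_correlation(tab, groups = "pooled",
                             analytes = c("DHA", "EPA", "AA"))
  expect_lt(abs(got$pooled[got$analyte == "DHA"] - r_hand), 1e-12)
  # analyte equal to intake plus tiny noise -> correlation near 1
  set.seed(34)
  tab2 <- tiny_cohort(10, 10, seed = 35)
  tab2$seafood_meals_per_month <- rpois(20, 5)
  tab2$EPA <- tab2$seafood_meals_per_month + rnorm(20, 0, 1e-3)
  got2 <- seafood_correlation(tab2, groups = "pooled",
                              analytes = c("DHA", "EPA", "AA"))
  expect_gt(got2$pooled[got2$analyte == "EPA"], 0.99)
  # too few complete pairs -> NA with warning
  tab3 <- tiny_cohort(3, 2)
  tab3$seafood_meals_per_month <- c(1, NA, NA, NA, 2)
  expect_warning(
    got3 <- seafood_correlation(tab3, groups = "pooled", analytes = "DHA"),
    "fewer than 3")
  expect_true(all(is.na(got3$pooled)))
  # Spearman option returns rank correlation
  sp <- seafood_correlation(tab, groups = "pooled",
                            analytes = c("DHA", "EPA"),
                            method = "spearman")
  expect_equal(sp$pooled[sp$analyte == "DHA"],
               cor(tab$DHA, tab$seafood_meals_per_month,
                   method = "spearman"))
})
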