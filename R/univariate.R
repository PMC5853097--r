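#' Anderson-Darling normality test
#'
#' Case-3 composite normality test (mean and variance estimated from the
#' sample) with the small-sample correction
#' A*^2 = A^2 (1 + 0.75/n + 2.25/n^2) and the D'Agostino-Stephens
#' piecewise-exponential p-value approximation.
#'
#' @param x numeric vector (n >= 8 recommended; warns below).
#' @param alpha rejection level.
#' @return list with `A2_star`, `p`, `reject`, `n`.
#' @export
anderson_darling <- function(x, alpha = 0.05) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 4) stop("Anderson-Darling needs n >= 4", call. = FALSE)
  if (n < 8) warning("Anderson-Darling with n < 8 is unreliable",
                     call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant vector: Anderson-Darling requires nonzero variance",
         call. = FALSE)
  p <- stats::pnorm((x - mean(x)) / stats::sd(x))
  p <- pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(p) + log(1 - rev(p))))
  A2s <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  pval <- if (A2s < 0.2) {
    1 - exp(-13.436 + 101.14 * A2s - 223.73 * A2s^2)
  } else if (A2s < 0.34) {
    1 - exp(-8.318 + 42.796 * A2s - 59.938 * A2s^2)
  } else if (A2s < 0.6) {
    exp(0.9177 - 4.279 * A2s - 1.38 * A2s^2)
  } else if (A2s < 10) {
    exp(1.2937 - 5.709 * A2s + 0.0186 * A2s^2)
  } else 3.7e-24
  list(A2_star = A2s, p = pval, reject = pval < alpha, n = n)
}

#' Two-sided F test for equal variances
#'
#' F = s1^2/s2^2 with p = 2 min(P(F' <= F), P(F' >= F)) under
#' F(n1-1, n2-1).
#'
#' @param x,y numeric vectors, n >= 2 each, nonzero variances.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
f_test_equal_var <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: F test undefined", call. = FALSE)
  ft <- stats::var.test(x, y)
  list(F = unname(ft$statistic), df1 = unname(ft$parameter[1]),
       df2 = unname(ft$parameter[2]), p = ft$p.value)
}

#' Two-sample t tests
#'
#' `student_t()` is the pooled-variance test with df = n1 + n2 - 2;
#' `welch_t()` uses the Welch-Satterthwaite effective df. Two-sided.
#'
#' @param x,y numeric vectors, n >= 2 each.
#' @return list with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
student_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero pooled variance: t test undefined", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_x = mean(x), mean_y = mean(y))
}

#' @rdname student_t
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero pooled variance: t test undefined", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_x = mean(x), mean_y = mean(y))
}

#' Two-sample Kolmogorov-Smirnov test of distribution shape
#'
#' D is the supremum over pooled jump points of |ECDF1 - ECDF2|; the
#' p-value uses the asymptotic Kolmogorov distribution at effective
#' n = n1 n2 / (n1 + n2).
#'
#' @param x,y numeric vectors, n >= 3 each.
#' @return list with `D`, `p`.
#' @export
ks_two_sample <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 3, length(y) >= 3)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Mann-Whitney U test for a median difference
#'
#' U via midranks; the exact-enumeration p-value when n1 + n2 <= 12 with no
#' ties, otherwise the tie-corrected normal approximation with continuity
#' correction. `auc` is the empirical probability that a random x exceeds a
#' random y, U/(n1 n2) (ties count one half).
#'
#' @param x,y numeric vectors, n >= 3 each (not enforced for tiny
#'   enumeration fixtures; n >= 2 required).
#' @return list with `U`, `p`, `median_x`, `median_y`, `auc`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  n1 <- length(x); n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 + n2 <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  U <- unname(wt$statistic)
  list(U = U, p = wt$p.value,
       median_x = stats::median(x), median_y = stats::median(y),
       auc = U / (n1 * n2))
}

#' Normality-gated two-sample test selection
#'
#' Implements the decision tree used to compare each analyte between
#' cohorts: (i) if both cohorts fail to reject Anderson-Darling normality,
#' an F test gates between Student's t (equal variances) and Welch's test;
#' (ii) if either cohort rejects normality, a two-sample
#' Kolmogorov-Smirnov test of common shape gates between the Mann-Whitney U
#' test on medians (shape not rejected) and Welch's test on means (shape
#' rejected, flagged in `note`). All gates at `alpha_gate`.
#'
#' @param x,y numeric vectors (cases, controls).
#' @param alpha_gate gate significance level (0.05 by default).
#' @return object of class `test_decision`: `route`, `final_test`,
#'   `ad_p_asd`, `ad_p_neu`, `gate` ("F" or "KS"), `gate_p`, `statistic`,
#'   `df` (t family), `p_value`, `central_asd`, `central_neu` (means for the
#'   t family, medians for Mann-Whitney), `central_type`, `note`.
#' @export
select_and_test <- function(x, y, alpha_gate = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  ad1 <- anderson_darling(x, alpha_gate)
  ad2 <- anderson_darling(y, alpha_gate)
  note <- ""
  if (!ad1$reject && !ad2$reject) {
    ft <- f_test_equal_var(x, y)
    if (ft$p >= alpha_gate) {
      route <- "AD_pass_F_pass"; final <- "Student_t"; r <- student_t(x, y)
    } else {
      route <- "AD_pass_F_fail"; final <- "Welch"; r <- welch_t(x, y)
    }
    gate <- "F"; gate_p <- ft$p
    stat <- r$t; df <- r$df; p <- r$p
    c1 <- r$mean_x; c2 <- r$mean_y; ctype <- "mean"
  } else {
    kt <- ks_two_sample(x, y)
    gate <- "KS"; gate_p <- kt$p
    if (kt$p >= alpha_gate) {
      route <- "AD_fail_KS_pass"; final <- "MannWhitneyU"
      r <- mann_whitney_u(x, y)
      stat <- r$U; df <- NA_real_; p <- r$p
      c1 <- r$median_x; c2 <- r$median_y; ctype <- "median"
    } else {
      route <- "AD_fail_KS_fail"; final <- "Welch"
      r <- welch_t(x, y)
      stat <- r$t; df <- r$df; p <- r$p
      c1 <- r$mean_x; c2 <- r$mean_y; ctype <- "mean"
      note <- "Welch's test used after the distributions were found to not be of the same shape"
    }
  }
  structure(list(
    route = route, final_test = final,
    ad_p_asd = ad1$p, ad_p_neu = ad2$p, gate = gate, gate_p = gate_p,
    statistic = stat, df = df, p_value = p,
    central_asd = c1, central_neu = c2, central_type = ctype,
    n_asd = length(x), n_neu = length(y), note = note
  ), class = "test_decision")
}

#' @export
print.test_decision <- function(x, ...) {
  cat(sprintf("%s (route %s): stat=%.4g, p=%.4g; %s ASD=%.4g NEU=%.4g\n",
              x$final_test, x$route, x$statistic, x$p_value,
              x$central_type, x$central_asd, x$central_neu))
  if (nzchar(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Multiple-testing correction
#'
#' Bonferroni or Holm adjustment via [stats::p.adjust()]; adjusted values
#' are capped at 1 and monotone in the input.
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @param method "bonferroni" (default) or "holm".
#' @return adjusted p-values.
#' @export
multiplicity_correct <- function(p_values, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = method)
}

#' A priori per-group sample size for a two-sample comparison
#'
#' Normal-approximation sample size
#' n = 2 ((z_{1-alpha/2} + z_{power}) / d)^2 per group (one-sided uses
#' z_{1-alpha}), rounded to the nearest integer. With d = 0.5, alpha = 0.1,
#' power = 0.8 (two-sided) this gives 49 per group.
#'
#' @param d Cohen's d (> 0).
#' @param alpha significance level.
#' @param power target power.
#' @param sided "two" (default) or "one".
#' @return integer per-group sample size.
#' @export
min_sample_size <- function(d, alpha = 0.1, power = 0.8,
                            sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  za <- stats::qnorm(1 - if (sided == "two") alpha / 2 else alpha)
  zb <- stats::qnorm(power)
  as.integer(round(2 * ((za + zb) / d)^2))
}
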