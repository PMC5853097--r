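#' Partial least squares regression of severity on the analyte panel
#'
#' NIPALS PLS1 regression of a single numeric response (e.g. a severity
#' instrument score) on the analyte matrix, or its kernel extension fitted
#' on the double-centered Gram matrix. With a linear kernel the kernel
#' variant reproduces linear PLS fitted values; with full components on a
#' full-rank X, linear PLS reproduces ordinary least squares.
#'
#' @param tab a [cohort_table()] (or data.frame).
#' @param x_variables predictor column names.
#' @param y_label response column name (rows with missing response or
#'   predictors are dropped; at least 10 required).
#' @param n_components number of latent components (<= rank of centered X).
#' @param kernel "linear" (default, NIPALS on X) or "rbf".
#' @param gamma RBF width; default 1 / median squared pairwise distance.
#' @param loo also compute leave-one-out cross-validated R^2.
#' @return object of class `pls_model`: `n_components`, `kernel`,
#'   `r_squared` (in-sample), `r_squared_loo` (if requested), `fitted`,
#'   `target_label`, `n`.
#' @export
pls_regress <- function(tab, x_variables, y_label, n_components = 2,
                        kernel = c("linear", "rbf"), gamma = NULL,
                        loo = FALSE) {
  kernel <- match.arg(kernel)
  stopifnot(all(x_variables %in% names(tab)), y_label %in% names(tab))
  X <- as.matrix(tab[x_variables])
  y <- tab[[y_label]]
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(X)
  if (n < 10) stop("need >= 10 complete records, have ", n, call. = FALSE)
  Xc <- scale(X, scale = FALSE)
  if (n_components > qr(Xc)$rank)
    stop("n_components (", n_components, ") exceeds rank of centered X (",
         qr(Xc)$rank, ")", call. = FALSE)
  yc <- y - mean(y)

  fit_once <- function(Xtr, ytr, Xte) {
    if (kernel == "linear") {
      fit <- nipals_pls1(scale(Xtr, scale = FALSE), ytr - mean(ytr),
                         n_components)
      list(fit = drop(scale(Xtr, scale = FALSE) %*% fit$beta) + mean(ytr),
           pred = if (!is.null(Xte))
             drop(scale(Xte, center = colMeans(Xtr), scale = FALSE) %*%
                    fit$beta) + mean(ytr))
    } else {
      g <- gamma %||% default_gamma(Xtr)
      K <- rbf_kernel(Xtr, Xtr, g)
      kf <- kernel_pls1(K, ytr - mean(ytr), n_components)
      pred <- NULL
      if (!is.null(Xte)) {
        Kt <- rbf_kernel(Xte, Xtr, g)
        # center test kernel against the training kernel
        ntr <- nrow(Xtr)
        one <- matrix(1 / ntr, ntr, ntr)
        Ktc <- (Kt - matrix(rowMeans(Kt), nrow(Kt), ntr)) %*% (diag(ntr) - one)
        pred <- drop(Ktc %*% kf$alpha) + mean(ytr)
      }
      list(fit = drop(kf$Kc %*% kf$alpha) + mean(ytr), pred = pred)
    }
  }

  fitted <- fit_once(X, y, NULL)$fit
  ss <- function(e) sum(e^2)
  r2 <- 1 - ss(y - fitted) / ss(yc)
  r2_loo <- NA_real_
  if (loo) {
    pred <- vapply(seq_len(n), function(i)
      fit_once(X[-i, , drop = FALSE], y[-i], X[i, , drop = FALSE])$pred, 0)
    r2_loo <- 1 - ss(y - pred) / ss(yc)
  }
  structure(list(n_components = n_components, kernel = kernel,
                 gamma = if (kernel == "rbf") gamma %||% default_gamma(X),
                 r_squared = r2, r_squared_loo = r2_loo,
                 fitted = fitted, target_label = y_label, n = n),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS (%s, %d comp) for %s: R^2 = %.3f%s\n", x$kernel,
              x$n_components, x$target_label, x$r_squared,
              if (!is.na(x$r_squared_loo))
                sprintf(", LOO R^2 = %.3f", x$r_squared_loo) else ""))
  invisible(x)
}

# NIPALS PLS1 on centered X, centered y; returns regression vector beta
nipals_pls1 <- function(Xc, yc, ncomp) {
  p <- ncol(Xc)
  W <- P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  E <- Xc; f <- yc
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w); tt <- sum(t^2)
    pv <- drop(crossprod(E, t)) / tt
    qa <- sum(f * t) / tt
    E <- E - tcrossprod(t, pv)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- pv; q[a] <- qa
  }
  beta <- W %*% solve(crossprod(P, W), q)
  list(beta = drop(beta), W = W, P = P, q = q)
}

# kernel PLS1 on an uncentered Gram matrix; double-centers internally
kernel_pls1 <- function(K, yc, ncomp) {
  n <- nrow(K)
  one <- matrix(1 / n, n, n)
  Kc <- (diag(n) - one) %*% K %*% (diag(n) - one)
  T <- U <- matrix(0, n, ncomp)
  Kres <- Kc; f <- yc
  for (a in seq_len(ncomp)) {
    t <- drop(Kres %*% f); t <- t / sqrt(sum(t^2))
    u <- f
    T[, a] <- t; U[, a] <- u
    proj <- diag(n) - tcrossprod(t)
    Kres <- proj %*% Kres %*% proj
    f <- f - tcrossprod(t) %*% f
  }
  # dual coefficients (Rosipal-Trejo form)
  alpha <- U %*% solve(crossprod(T, Kc %*% U), crossprod(T, yc))
  list(alpha = drop(alpha), Kc = Kc, T = T)
}

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

default_gamma <- function(X) {
  d2 <- stats::dist(X)^2
  1 / stats::median(d2)
}
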