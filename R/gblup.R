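#' SNP-BLUP shrinkage constant
#'
#' The ridge penalty that makes marker-effect shrinkage equivalent to GBLUP
#' with base heritability `h2`:
#' `lambda = (1 - h2) * 2 * sum(p * (1 - p)) / h2`,
#' i.e. the residual-to-marker variance ratio when the additive variance
#' `h2` is split equally across markers scaled by `2 sum(p q)`.
#'
#' @param h2 base heritability, strictly between 0 and 1.
#' @param p per-marker allele frequencies in the training set.
#' @return a positive scalar.
#' @export
choose_lambda <- function(h2, p) {
  if (h2 <= 0 || h2 >= 1) stop("'h2' must lie strictly between 0 and 1")
  spq <- 2 * sum(p * (1 - p))
  if (spq <= 0) stop("all marker frequencies are degenerate (0 or 1)")
  (1 - h2) * spq / h2
}

#' Fit ridge regression of phenotypes on marker covariates (SNP-BLUP)
#'
#' Solves `(Xc' Xc + lambda I) beta = Xc' (y - mean(y))` with column-centred
#' allele counts `Xc` and an unpenalised intercept `mu = mean(y)`. When
#' markers outnumber records the equivalent n x n dual system
#' `beta = Xc' (Xc Xc' + lambda I)^{-1} (y - mean(y))` is solved instead;
#' both routes agree to numerical precision.
#'
#' @param X allele-count matrix (records x markers, values 0/1/2).
#' @param y phenotypes.
#' @param lambda ridge penalty (> 0), e.g. from [choose_lambda()].
#' @param method `"auto"` (dual when m > n), `"primal"` or `"dual"`.
#' @return An object of class `ridge_fit`: list with `mu`, `beta`,
#'   `center` (training column means), `lambda`, `n`, `m`.
#' @export
fit_ridge <- function(X, y, lambda,
                      method = c("auto", "primal", "dual")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (n < 2L) stop("at least two phenotyped animals are required")
  if (length(y) != n) stop("'y' must have one record per row of X")
  if (lambda <= 0) stop("'lambda' must be positive")
  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar)
  mu <- mean(y)
  yc <- y - mu
  if (method == "auto") method <- if (m > n) "dual" else "primal"
  beta <- if (method == "primal") {
    drop(solve(crossprod(Xc) + diag(lambda, m), crossprod(Xc, yc)))
  } else {
    K <- tcrossprod(Xc)
    drop(crossprod(Xc, solve(K + diag(lambda, n), yc)))
  }
  structure(list(mu = mu, beta = beta, center = xbar, lambda = lambda,
                 n = n, m = m),
            class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat(sprintf("SNP-BLUP fit: %d records, %d markers, lambda = %.4g\n",
              x$n, x$m, x$lambda))
  invisible(x)
}

#' Predict genomic breeding values
#'
#' `ghat_i = sum_j (x_ij - xbar_j) beta_j`, the genetic part of the ridge
#' prediction centred with the training means; the selection criterion of
#' the scheme engine. The intercept is deliberately excluded so that GEBVs
#' are deviations comparable across candidates.
#'
#' @param fit a `ridge_fit`.
#' @param X candidate allele-count matrix with the same marker set and
#'   coding as the training data.
#' @return numeric vector of GEBVs.
#' @export
predict_gebv <- function(fit, X) {
  stopifnot(inherits(fit, "ridge_fit"))
  X <- as.matrix(X)
  if (ncol(X) != fit$m)
    stop("candidate marker set does not match the training marker set")
  drop(sweep(X, 2L, fit$center) %*% fit$beta)
}
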