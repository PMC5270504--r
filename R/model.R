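#' Two-class Gaussian population model
#'
#' Constructs the population model underlying all moment computations: two
#' Gaussian class-conditional distributions \eqn{\Pi_0 \sim N(\mu_0, \cdot)}
#' and \eqn{\Pi_1 \sim N(\mu_1, \cdot)} with prior probabilities
#' \eqn{c_0, c_1 = 1 - c_0}. Two parameterizations are supported:
#'
#' * univariate: scalar means with class standard deviations `sigma0`,
#'   `sigma1` (possibly unequal — the heteroskedastic case);
#' * multivariate: mean vectors of length \eqn{d} with a common known
#'   covariance matrix `Sigma` (the homoskedastic case analysed for LDA with
#'   known covariance).
#'
#' Under mixture sampling with sample size \eqn{n}, class-0 counts are
#' \eqn{N_0 \sim } Binomial(\eqn{n, c_0}).
#'
#' @param mu0,mu1 Class means: scalars (univariate) or numeric vectors of a
#'   common length \eqn{d} (multivariate).
#' @param sigma0,sigma1 Positive class standard deviations (univariate mode
#'   only). `sigma1` defaults to `sigma0`.
#' @param Sigma Symmetric positive-definite \eqn{d \times d} common
#'   covariance matrix (multivariate mode only).
#' @param c0 Prior probability of class 0, strictly inside (0, 1).
#' @return An object of class `"gauss2"` with elements `mu0`, `mu1`, `c0`,
#'   `c1`, `d`, and either `sigma0`/`sigma1` or `Sigma`.
#' @examples
#' gauss2(0, 2)                        # univariate, unit variances
#' gauss2(c(0, 0), c(1, 1), Sigma = diag(2))
#' @export
gauss2 <- function(mu0, mu1, sigma0 = 1, sigma1 = sigma0, Sigma = NULL,
                   c0 = 0.5) {
  if (!is.numeric(mu0) || !is.numeric(mu1) || length(mu0) != length(mu1) ||
      length(mu0) < 1L || anyNA(mu0) || anyNA(mu1))
    stop_invalid("'mu0' and 'mu1' must be numeric vectors of equal length")
  check_prob(c0, "c0", open_lo = TRUE, open_hi = TRUE)
  d <- length(mu0)
  if (is.null(Sigma)) {
    if (d != 1L)
      stop_invalid("vector means require a common covariance matrix 'Sigma'")
    if (!is.numeric(sigma0) || !is.numeric(sigma1) ||
        length(sigma0) != 1L || length(sigma1) != 1L ||
        is.na(sigma0) || is.na(sigma1) || sigma0 <= 0 || sigma1 <= 0)
      stop_invalid("'sigma0' and 'sigma1' must be positive scalars")
    obj <- list(mu0 = as.numeric(mu0), mu1 = as.numeric(mu1),
                sigma0 = as.numeric(sigma0), sigma1 = as.numeric(sigma1),
                Sigma = NULL, c0 = c0, c1 = 1 - c0, d = 1L)
  } else {
    Sigma <- as.matrix(Sigma)
    if (nrow(Sigma) != d || ncol(Sigma) != d ||
        !isTRUE(all.equal(Sigma, t(Sigma), tolerance = 1e-10)))
      stop_invalid("'Sigma' must be a symmetric d x d matrix")
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop_invalid("'Sigma' must be positive definite")
    obj <- list(mu0 = as.numeric(mu0), mu1 = as.numeric(mu1),
                sigma0 = NULL, sigma1 = NULL, Sigma = Sigma,
                c0 = c0, c1 = 1 - c0, d = d)
  }
  class(obj) <- "gauss2"
  obj
}

#' @export
print.gauss2 <- function(x, ...) {
  mode <- if (is.null(x$Sigma)) "univariate" else
    sprintf("multivariate (d = %d, common known covariance)", x$d)
  cat("Two-class Gaussian population model,", mode, "\n")
  cat("  mu0 =", format(x$mu0, digits = 4),
      " mu1 =", format(x$mu1, digits = 4), "\n")
  if (is.null(x$Sigma)) {
    cat("  sigma0 =", format(x$sigma0, digits = 4),
        " sigma1 =", format(x$sigma1, digits = 4), "\n")
  }
  cat("  priors c0 =", format(x$c0, digits = 4),
      " c1 =", format(x$c1, digits = 4), "\n")
  delta <- tryCatch(mahalanobis_delta(x), error = function(e) NULL)
  if (!is.null(delta))
    cat("  Mahalanobis delta =", format(delta, digits = 6),
        " (equal-prior Bayes error", format(bayes_error(delta), digits = 4),
        ")\n")
  invisible(x)
}

is_univariate <- function(pop) is.null(pop$Sigma)

is_homoskedastic <- function(pop) {
  !is_univariate(pop) || isTRUE(all.equal(pop$sigma0, pop$sigma1))
}

#' Mahalanobis distance between the two populations
#'
#' Returns \eqn{\delta = \sqrt{(\mu_1-\mu_0)^T \Sigma^{-1} (\mu_1-\mu_0)}}
#' in the multivariate case, or \eqn{|\mu_1-\mu_0| / \sigma} in the
#' homoskedastic univariate case. Together with \eqn{n}, \eqn{\delta} fully
#' determines all expected LDA error rates in the homoskedastic model; the
#' equal-prior Bayes error is \eqn{\Phi(-\delta/2)}.
#'
#' @param pop A [gauss2()] population pair; must be homoskedastic.
#' @return Nonnegative scalar distance.
#' @export
mahalanobis_delta <- function(pop) {
  stopifnot(inherits(pop, "gauss2"))
  if (is_univariate(pop)) {
    if (!is_homoskedastic(pop))
      stop_invalid("Mahalanobis distance requires equal variances; ",
                   "got sigma0 != sigma1")
    return(abs(pop$mu1 - pop$mu0) / pop$sigma0)
  }
  dm <- pop$mu1 - pop$mu0
  sqrt(drop(crossprod(dm, solve(pop$Sigma, dm))))
}

#' Bayes error of the equal-prior homoskedastic Gaussian problem
#'
#' For two homoskedastic Gaussian populations with equal priors, the optimal
#' classification error is \eqn{\epsilon^* = \Phi(-\delta/2)} where
#' \eqn{\delta} is the Mahalanobis distance. `delta_from_bayes_error()` is the
#' exact inverse, \eqn{\delta = -2\Phi^{-1}(\epsilon^*)}.
#'
#' @param delta Nonnegative Mahalanobis distance(s), or a [gauss2()] object.
#' @param eps Bayes error(s) in (0, 0.5].
#' @return `bayes_error()`: probabilities in (0, 0.5];
#'   `delta_from_bayes_error()`: nonnegative distances.
#' @examples
#' bayes_error(0)                  # 0.5: indistinguishable populations
#' delta_from_bayes_error(0.025)   # about 3.92
#' @export
bayes_error <- function(delta) {
  if (inherits(delta, "gauss2")) delta <- mahalanobis_delta(delta)
  if (!is.numeric(delta) || anyNA(delta) || any(delta < 0))
    stop_invalid("'delta' must be nonnegative")
  stats::pnorm(-delta / 2)
}

#' @rdname bayes_error
#' @export
delta_from_bayes_error <- function(eps) {
  check_prob(eps, "eps", open_lo = TRUE)
  if (any(eps > 0.5))
    stop_invalid("a Bayes error cannot exceed 0.5")
  -2 * stats::qnorm(eps)
}

#' Binomial distribution of the class-0 sample count
#'
#' Under mixture sampling, the number of class-0 observations in a sample of
#' size \eqn{n} is Binomial(\eqn{n, c_0}). Returns the probability vector
#' over \eqn{n_0 = 0, \dots, n}, optionally truncating entries below
#' `drop_below` and renormalizing — used to bound the cost of mixture sums at
#' large \eqn{n}, where the neglected mass (< 1e-12 by default) is orders of
#' magnitude below the accuracy of the moment computations.
#'
#' @param n Sample size (>= 1).
#' @param c0 Class-0 prior in (0, 1).
#' @param drop_below Weights below this value are dropped (set to zero) and
#'   the remainder renormalized; use 0 to keep all terms.
#' @return Numeric vector of length `n + 1` summing to 1, named by `n0`.
#' @export
binomial_class_weights <- function(n, c0 = 0.5, drop_below = 0) {
  stopifnot(length(n) == 1L, n >= 1, n == round(n))
  check_prob(c0, "c0", open_lo = TRUE, open_hi = TRUE)
  w <- stats::dbinom(0:n, n, c0)
  if (drop_below > 0) {
    w[w < drop_below] <- 0
    w <- w / sum(w)
  }
  names(w) <- 0:n
  w
}
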