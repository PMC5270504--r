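# Exact conditional expectations of the true, resubstitution and bootstrap
# error rates of the LDA classifier with known covariance, for fixed class
# sample sizes (separate sampling), and their binomial mixture over the
# class-0 count (mixture sampling).
#
# All univariate formulas are joint probabilities of the signs of
# U = (mean1 - mean0) and V = (X - (mean0 + mean1)/2): the class-0 error is
# P(UV > 0) = Phi(a, b; rho) + Phi(-a, -b; rho) with (a, b, rho) the
# standardized means and correlation of (U, V). The variance of each class
# sample mean enters through a variance-inflation factor s_i: 1/n_i for the
# original classifier, and the squared-occupancy ratio of the bootstrap
# vector for a bootstrap classifier. In the multivariate homoskedastic case
# the same sign probability becomes the tail of a ratio of independent
# noncentral chi-squares, evaluated by chi2_ratio_tail().

# class-0 conditional error given variance inflations (univariate, general
# variances); the class-1 error is the same function with all class indices
# interchanged
uni_cond0 <- function(mu0, mu1, v0, v1, s0, s1) {
  A <- s0 * v0 + s1 * v1
  B <- (4 + s0) * v0 + s1 * v1
  rho <- (s0 * v0 - s1 * v1) / sqrt(A * B)
  a <- (mu1 - mu0) / sqrt(A)
  b <- (mu0 - mu1) / sqrt(B)
  pbvnorm(a, b, rho) + pbvnorm(-a, -b, rho)
}

# class-0 conditional resubstitution error (univariate); the training point
# takes part in its own class mean, which changes the V-variance term to
# (4 - 3/n0) v0 + v1/n1 and makes the (U, V) correlation negative
uni_resub0 <- function(mu0, mu1, v0, v1, n0, n1) {
  A <- v0 / n0 + v1 / n1
  B <- (4 - 3 / n0) * v0 + v1 / n1
  rho <- -A / sqrt(A * B)
  a <- (mu1 - mu0) / sqrt(A)
  b <- (mu0 - mu1) / sqrt(B)
  pbvnorm(a, b, rho) + pbvnorm(-a, -b, rho)
}

# class-0 conditional error given variance inflations (multivariate,
# homoskedastic, known covariance): doubly noncentral F tail
mv_cond0 <- function(d, delta2, s0, s1, tail = "imhof") {
  A <- s0 + s1
  B <- s0 + s1 + 4
  rho <- (s0 - s1) / sqrt(A * B)
  la <- (1 / sqrt(A) - 1 / sqrt(B))^2 * delta2 / (2 * (1 + rho))
  lb <- (1 / sqrt(A) + 1 / sqrt(B))^2 * delta2 / (2 * (1 - rho))
  chi2_ratio_tail(d, la, lb, rho, method = tail)
}

mv_resub0 <- function(d, delta2, n0, n1, tail = "imhof") {
  A <- 1 / n0 + 1 / n1
  B <- 4 - 3 / n0 + 1 / n1
  rho <- -A / sqrt(A * B)
  ok <- rho > -1
  out <- numeric(length(rho))
  if (any(ok)) {
    la <- (1 / sqrt(A) - 1 / sqrt(B))^2 * delta2 / (2 * (1 + rho))
    lb <- (1 / sqrt(A) + 1 / sqrt(B))^2 * delta2 / (2 * (1 - rho))
    out[ok] <- chi2_ratio_tail(d, la[ok], lb[ok], rho[ok], method = tail)
  }
  # n0 = 1: the single training point is its own class mean and is never
  # misclassified (rho = -1, infinite ratio threshold)
  out
}

check_design <- function(n0, n1) {
  if (any(n0 < 1) || any(n1 < 1) || any(n0 != round(n0)) ||
      any(n1 != round(n1)))
    stop_invalid("class sample sizes 'n0' and 'n1' must be integers >= 1 ",
                 "(degenerate single-class designs have no trained classifier)")
}

mv_delta2 <- function(pop) {
  dm <- pop$mu1 - pop$mu0
  drop(crossprod(dm, solve(pop$Sigma, dm)))
}

#' Conditional expected error rates of the LDA classifier
#'
#' Expected class-specific error rates of the LDA classifier (known
#' covariance) trained on \eqn{n_0} class-0 and \eqn{n_1} class-1
#' observations, i.e. under separate sampling. `true_error_cond()` gives the
#' expected true (generalization) error, `resub_error_cond()` the expected
#' resubstitution (apparent) error, and `boot_error_cond()` the expected
#' error of the classifier trained on the bootstrap sample described by the
#' bootstrap vector `C` (with class-0 occupying the first `n0` positions of
#' `C`). With `C = rep(1, n0 + n1)`, the bootstrap sample is the original
#' sample and `boot_error_cond()` reduces exactly to `true_error_cond()`.
#'
#' Univariate populations may have unequal variances; multivariate
#' populations use the common known covariance. The class-1 column is always
#' the class-0 expression with all class indices interchanged.
#'
#' @param pop A [gauss2()] population pair.
#' @param n0,n1 Class sample sizes (vectors are recycled; each >= 1).
#' @param C Integer bootstrap vector of length `n0 + n1` summing to
#'   `n0 + n1`; both class segments must have a positive total count.
#' @param tail Evaluation method for the multivariate chi-square ratio
#'   tails: `"imhof"` (three-moment approximation, the route behind the
#'   published tables; default) or `"exact"` (numerical quadrature). Ignored
#'   in the univariate case, which is evaluated exactly throughout.
#' @return A matrix with columns `e0`, `e1`: expected error rates specific to
#'   populations 0 and 1. Rows follow the recycled `n0`, `n1`.
#' @seealso [expected_true_error()] for the mixture-sampling aggregation,
#'   [s_values()] for the bootstrap variance-inflation statistics.
#' @examples
#' pop <- gauss2(0, 1)
#' true_error_cond(pop, 10, 10)
#' resub_error_cond(pop, 10, 10)   # optimistic: smaller than the true error
#' @export
true_error_cond <- function(pop, n0, n1, tail = c("imhof", "exact")) {
  stopifnot(inherits(pop, "gauss2"))
  check_design(n0, n1)
  tail <- match.arg(tail)
  if (is_univariate(pop)) {
    v0 <- pop$sigma0^2; v1 <- pop$sigma1^2
    e0 <- uni_cond0(pop$mu0, pop$mu1, v0, v1, 1 / n0, 1 / n1)
    e1 <- uni_cond0(pop$mu1, pop$mu0, v1, v0, 1 / n1, 1 / n0)
  } else {
    d2 <- mv_delta2(pop)
    e0 <- mv_cond0(pop$d, d2, 1 / n0, 1 / n1, tail)
    e1 <- mv_cond0(pop$d, d2, 1 / n1, 1 / n0, tail)
  }
  cbind(e0 = e0, e1 = e1)
}

#' @rdname true_error_cond
#' @export
resub_error_cond <- function(pop, n0, n1, tail = c("imhof", "exact")) {
  stopifnot(inherits(pop, "gauss2"))
  check_design(n0, n1)
  tail <- match.arg(tail)
  if (is_univariate(pop)) {
    v0 <- pop$sigma0^2; v1 <- pop$sigma1^2
    e0 <- uni_resub0(pop$mu0, pop$mu1, v0, v1, n0, n1)
    e1 <- uni_resub0(pop$mu1, pop$mu0, v1, v0, n1, n0)
  } else {
    d2 <- mv_delta2(pop)
    e0 <- mv_resub0(pop$d, d2, n0, n1, tail)
    e1 <- mv_resub0(pop$d, d2, n1, n0, tail)
  }
  cbind(e0 = e0, e1 = e1)
}

#' @rdname true_error_cond
#' @export
boot_error_cond <- function(pop, C, n0, tail = c("imhof", "exact")) {
  stopifnot(inherits(pop, "gauss2"))
  s <- s_values(C, n0)
  boot_error_cond_s(pop, s[["s0"]], s[["s1"]], match.arg(tail))
}

# bootstrap conditional error for given variance-inflation pair(s); the
# workhorse behind boot_error_cond() and the bootstrap-space expectations
boot_error_cond_s <- function(pop, s0, s1, tail = "imhof") {
  if (is_univariate(pop)) {
    v0 <- pop$sigma0^2; v1 <- pop$sigma1^2
    e0 <- uni_cond0(pop$mu0, pop$mu1, v0, v1, s0, s1)
    e1 <- uni_cond0(pop$mu1, pop$mu0, v1, v0, s1, s0)
  } else {
    d2 <- mv_delta2(pop)
    e0 <- mv_cond0(pop$d, d2, s0, s1, tail)
    e1 <- mv_cond0(pop$d, d2, s1, s0, tail)
  }
  cbind(e0 = e0, e1 = e1)
}

# weights over the nondegenerate class splits n0 = 1..n-1; `degenerate`
# chooses between renormalized exclusion of the single-class splits and
# including them at their continuum-limit error values
mixture_frame <- function(n, c0, degenerate, drop_below = 0) {
  stopifnot(length(n) == 1L, n >= 2, n == round(n))
  degenerate <- match.arg(degenerate, c("exclude", "limit"))
  w <- binomial_class_weights(n, c0, drop_below)
  mid <- 2:n                        # n0 = 1..n-1
  wmid <- w[mid]
  if (degenerate == "exclude") wmid <- wmid / sum(wmid)
  list(n0 = 1:(n - 1), w = wmid, w0 = w[1], wn = w[n + 1],
       limit = degenerate == "limit")
}

#' Expected LDA error rates under mixture sampling
#'
#' Aggregates the conditional expected error rates over the binomial
#' distribution of the class-0 count \eqn{N_0 \sim} Binomial(\eqn{n, c_0}):
#' the expected true error weights the class-specific errors by the priors
#' \eqn{(c_0, c_1)}, while the expected resubstitution error weights them by
#' the realized class fractions \eqn{(n_0/n, n_1/n)}.
#'
#' The conditional formulas are undefined for the single-class splits
#' \eqn{n_0 \in \{0, n\}} (no classifier can be trained). By default these
#' terms are excluded and the binomial weights renormalized; with
#' `degenerate = "limit"` they are included at their continuum-limit values
#' (the rule that assigns everything to the only observed class: true error
#' \eqn{c_0} or \eqn{c_1}, resubstitution error 0). The two conventions
#' differ by at most \eqn{2^{-n+1}} times a bounded factor.
#'
#' @param pop A [gauss2()] population pair.
#' @param n Total sample size (>= 2).
#' @param degenerate Handling of the single-class splits: `"exclude"`
#'   (renormalize, default) or `"limit"`.
#' @param tail Chi-square ratio tail method for multivariate models; see
#'   [true_error_cond()].
#' @param drop_below Binomial weights below this value are dropped and the
#'   rest renormalized (cost control for large `n`); 0 keeps all terms.
#' @return Scalar expected error rate.
#' @examples
#' pop <- gauss2(0, 1)
#' expected_true_error(pop, 10)
#' expected_resub_error(pop, 10)
#' @export
expected_true_error <- function(pop, n, degenerate = c("exclude", "limit"),
                                drop_below = 0,
                                tail = c("imhof", "exact")) {
  stopifnot(inherits(pop, "gauss2"))
  mf <- mixture_frame(n, pop$c0, match.arg(degenerate), drop_below)
  keep <- mf$w > 0
  e <- true_error_cond(pop, mf$n0[keep], n - mf$n0[keep], match.arg(tail))
  out <- sum(mf$w[keep] * (pop$c0 * e[, "e0"] + pop$c1 * e[, "e1"]))
  if (mf$limit) out <- out + mf$w0 * pop$c0 + mf$wn * pop$c1
  out
}

#' @rdname expected_true_error
#' @export
expected_resub_error <- function(pop, n, degenerate = c("exclude", "limit"),
                                 drop_below = 0,
                                 tail = c("imhof", "exact")) {
  stopifnot(inherits(pop, "gauss2"))
  mf <- mixture_frame(n, pop$c0, match.arg(degenerate), drop_below)
  keep <- mf$w > 0
  n0 <- mf$n0[keep]
  e <- resub_error_cond(pop, n0, n - n0, match.arg(tail))
  sum(mf$w[keep] * (n0 / n * e[, "e0"] + (n - n0) / n * e[, "e1"]))
  # "limit" adds zero: the single-class rule never errs on its own sample
}
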