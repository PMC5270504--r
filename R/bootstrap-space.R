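# The multinomial bootstrap-vector space: a bootstrap sample of n instances
# drawn with replacement from a sample of size n is described by the count
# vector C ~ Multinomial(n; 1/n, ..., 1/n). Everything the bootstrap LDA
# classifier does depends on C only through the per-class variance-inflation
# statistics s0, s1 (squared-occupancy ratios), which makes both exhaustive
# enumeration (small n) and Monte Carlo averaging (large n) tractable after
# aggregating identical (s0, s1) pairs.

#' Bootstrap count vectors
#'
#' `n_boot_vectors(n)` counts the distinct bootstrap samples of a size-`n`
#' sample, \eqn{\binom{2n-1}{n}}. `boot_vectors(n)` enumerates them all as
#' rows of a matrix (every composition of `n` into `n` nonnegative parts);
#' the count grows combinatorially, so enumeration is capped. `rboot_vectors()`
#' draws `M` vectors i.i.d. from the multinomial resampling distribution, and
#' `dboot_vector()` evaluates that distribution's mass function.
#'
#' @param n Sample size (>= 1).
#' @param max_n Enumeration cap; above it `boot_vectors()` refuses (use
#'   `rboot_vectors()` instead). The default cap of 12 corresponds to about
#'   1.35 million vectors.
#' @param M Number of Monte Carlo draws.
#' @param seed Optional seed; the caller's RNG state is preserved.
#' @param C An integer count vector.
#' @param log Return the log mass.
#' @return `boot_vectors()`/`rboot_vectors()`: integer matrix with `n`
#'   columns, one vector per row. `n_boot_vectors()`: a double (exact until
#'   it exceeds 2^53). `dboot_vector()`: probability mass of `C`.
#' @examples
#' boot_vectors(3)
#' n_boot_vectors(20)            # > 6.8e10: enumeration is hopeless
#' dboot_vector(c(1, 1))         # 0.5
#' @export
boot_vectors <- function(n, max_n = 12) {
  stopifnot(length(n) == 1L, n >= 1, n == round(n))
  if (n > max_n)
    stop_invalid(sprintf(paste0(
      "enumerating all %.3g bootstrap vectors at n = %d is not feasible; ",
      "use rboot_vectors() for Monte Carlo"), n_boot_vectors(n), n))
  compositions_matrix(as.integer(n), as.integer(n))
}

# all compositions of n into k nonnegative parts, built level by level
compositions_matrix <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  parts <- lapply(0:n, function(j)
    cbind(j, compositions_matrix(n - j, k - 1L), deparse.level = 0))
  do.call(rbind, parts)
}

#' @rdname boot_vectors
#' @export
n_boot_vectors <- function(n) {
  stopifnot(length(n) == 1L, n >= 1, n == round(n))
  choose(2 * n - 1, n)
}

#' @rdname boot_vectors
#' @export
rboot_vectors <- function(n, M, seed = NULL) {
  stopifnot(length(n) == 1L, n >= 1, n == round(n),
            length(M) == 1L, M >= 1, M == round(M))
  with_seed(seed, t(stats::rmultinom(M, n, rep(1 / n, n))))
}

#' @rdname boot_vectors
#' @export
dboot_vector <- function(C, log = FALSE) {
  C <- check_boot_vector(C)
  n <- length(C)
  lp <- lfactorial(n) - sum(lfactorial(C)) - n * log(n)
  if (log) lp else exp(lp)
}

check_boot_vector <- function(C) {
  if (!is.numeric(C) || anyNA(C) || any(C < 0) || any(C != round(C)))
    stop_invalid("a bootstrap vector must contain nonnegative integers")
  if (sum(C) != length(C))
    stop_invalid("a bootstrap vector of length n must sum to n")
  as.integer(C)
}

#' Per-class variance-inflation statistics of a bootstrap vector
#'
#' For a bootstrap vector `C` whose first `n0` positions hold the class-0
#' instances, returns the squared-occupancy ratios
#' \deqn{s_i = \frac{\sum_j C_{ij}^2}{\left(\sum_j C_{ij}\right)^2},}
#' computed per class segment. \eqn{s_i \sigma_i^2} is the variance of the
#' bootstrap sample mean of class \eqn{i} given `C`; \eqn{s_i} ranges from
#' \eqn{1/n_i} (the all-ones vector, i.e. the original sample) to 1 (all
#' class-\eqn{i} draws concentrated on a single instance).
#'
#' @param C Integer bootstrap vector (length n, summing to n).
#' @param n0 Number of leading positions belonging to class 0 (0 < n0 < n).
#' @return Named numeric vector `c(s0, s1)`.
#' @examples
#' s_values(rep(1, 10), 4)        # c(1/4, 1/6)
#' s_values(c(2, 1, 1, 0, 2, 0, 0, 2, 1, 1), 4)
#' @export
s_values <- function(C, n0) {
  C <- check_boot_vector(C)
  n <- length(C)
  stopifnot(length(n0) == 1L, n0 >= 1, n0 <= n - 1, n0 == round(n0))
  k0 <- sum(C[seq_len(n0)])
  k1 <- sum(C) - k0
  if (k0 == 0L || k1 == 0L)
    stop_invalid("bootstrap sample misses one class entirely ",
                 "(empty class segment); s-values are undefined")
  q0 <- sum(C[seq_len(n0)]^2)
  q1 <- sum(C^2) - q0
  c(s0 = q0 / k0^2, s1 = q1 / k1^2)
}

#' Expected zero-bootstrap error rate
#'
#' Expectation of the zero (leave-out) bootstrap error estimator for LDA
#' under the Gaussian model `pop` and mixture sampling with sample size `n`:
#' the bootstrap-classifier error, aggregated over the class-0 count
#' \eqn{N_0} and the bootstrap vector \eqn{C}.
#'
#' Three computational routes are available:
#'
#' * `"plugin"` (default): evaluates the bootstrap conditional-error formula
#'   once per class split at the deterministic variance inflations
#'   \eqn{\bar s_i = E[\sum_j C_j^2] / E[(\sum_j C_j)^2]} (ratio of
#'   multinomial moments over each class segment), i.e. the delta-method
#'   approximation of the bootstrap sample-mean variance. This deterministic
#'   route is the one that reproduces the published weight tables, and is
#'   essentially free.
#' * `"exact"`: averages the conditional error over every bootstrap vector,
#'   weighted by the multinomial mass function — the full expectation of the
#'   bootstrap-classifier error. Feasible for `n` up to about 12.
#' * `"mc"`: same average approximated with `M` seeded multinomial draws
#'   (default \eqn{M = 100 n^2}); one draw serves every class split by prefix
#'   segmentation, which is valid because the multinomial is exchangeable
#'   over positions.
#'
#' In the averaging routes, vectors whose class segment has zero total count
#' (no trainable bootstrap classifier) are excluded and the mass renormalized
#' within each split, matching the degenerate-split convention of
#' [expected_true_error()]. The `"plugin"` and averaging routes answer
#' slightly different questions — the plug-in ignores the dispersion of
#' \eqn{(s_0, s_1)} across bootstrap draws — and differ by \eqn{O(1/n)};
#' see the package vignette.
#'
#' @inheritParams expected_true_error
#' @param method Computational route, see Details.
#' @param tail Chi-square ratio tail method for multivariate models; see
#'   [true_error_cond()].
#' @param M Number of Monte Carlo vectors for `method = "mc"`.
#' @param seed Seed for the Monte Carlo route (the caller's RNG state is
#'   preserved).
#' @param max_n Cap for the exact enumeration route.
#' @return Scalar expected zero-bootstrap error rate.
#' @examples
#' pop <- gauss2(0, 1)
#' expected_boot_error(pop, 10)                      # plug-in
#' expected_boot_error(pop, 6, method = "exact")     # full average
#' @export
expected_boot_error <- function(pop, n,
                                method = c("plugin", "exact", "mc"),
                                M = 100 * n^2, seed = NULL,
                                degenerate = c("exclude", "limit"),
                                drop_below = 0, max_n = 12,
                                tail = c("imhof", "exact")) {
  stopifnot(inherits(pop, "gauss2"))
  method <- match.arg(method)
  tail <- match.arg(tail)
  mf <- mixture_frame(n, pop$c0, match.arg(degenerate), drop_below)
  keep <- mf$w > 0
  n0s <- mf$n0[keep]
  w <- mf$w[keep]

  per_split <- switch(method,
    plugin = boot_split_plugin(pop, n, n0s, tail),
    exact  = boot_split_average(pop, n, n0s, boot_vectors(n, max_n), NULL,
                                tail),
    mc     = boot_split_average(pop, n, n0s,
                                rboot_vectors(n, M, seed), M, tail))
  out <- sum(w * per_split)
  if (mf$limit) out <- out + mf$w0 * pop$c0 + mf$wn * pop$c1
  out
}

# prior-weighted bootstrap conditional error at the mean squared-occupancy
# ratios: E[sum C^2] = n0 (2n-1)/n and E[(sum C)^2] = n0^2 + n0 n1 / n over a
# class segment of n0 positions
boot_split_plugin <- function(pop, n, n0s, tail = "imhof") {
  n1s <- n - n0s
  s0 <- (n0s * (2 * n - 1) / n) / (n0s^2 + n0s * n1s / n)
  s1 <- (n1s * (2 * n - 1) / n) / (n1s^2 + n0s * n1s / n)
  e <- boot_error_cond_s(pop, s0, s1, tail)
  pop$c0 * e[, "e0"] + pop$c1 * e[, "e1"]
}

# full average over bootstrap vectors: aggregate identical (s0, s1) pairs
# across all vectors and splits, evaluate the conditional error once per
# unique pair, and average with multinomial mass (exact) or draw frequency
# (mc), renormalized over the vectors with both class segments nonempty
boot_split_average <- function(pop, n, n0s, Cm, M, tail = "imhof") {
  nv <- nrow(Cm)
  wv <- if (is.null(M)) {
    exp(lfactorial(n) - rowSums(lfactorial(Cm)) - n * log(n))
  } else {
    rep(1 / M, nv)
  }
  U <- upper.tri(matrix(0L, n, n), diag = TRUE) + 0
  pk <- Cm %*% U                  # prefix sums
  pq <- (Cm * Cm) %*% U           # prefix sums of squares
  qt <- pq[, n]

  keys <- s0l <- s1l <- wl <- spl <- vector("list", length(n0s))
  for (i in seq_along(n0s)) {
    n0 <- n0s[i]
    k0 <- pk[, n0]
    valid <- k0 > 0 & k0 < n
    q0 <- pq[valid, n0]
    k0 <- k0[valid]
    s0 <- q0 / k0^2
    s1 <- (qt[valid] - q0) / (n - k0)^2
    wt <- wv[valid]
    wt <- wt / sum(wt)
    # integer key identifying (split irrelevant) the pair (k0, q0, q1)
    keys[[i]] <- (q0 * (n^2 + 1) + (qt[valid] - q0)) * (n + 1) + k0
    s0l[[i]] <- s0
    s1l[[i]] <- s1
    wl[[i]] <- wt
    spl[[i]] <- rep.int(i, sum(valid))
  }
  key <- unlist(keys)
  s0 <- unlist(s0l)
  s1 <- unlist(s1l)
  wt <- unlist(wl)
  split_id <- unlist(spl)

  # aggregate weights per (split, s-pair); evaluate each unique s-pair once
  pair_key <- paste(split_id, key)
  agg <- rowsum(wt, pair_key, reorder = FALSE)
  first <- !duplicated(pair_key)
  stopifnot(identical(rownames(agg), pair_key[first]))
  us0 <- s0[first]
  us1 <- s1[first]
  usplit <- split_id[first]

  skey <- paste(us0, us1)
  sfirst <- !duplicated(skey)
  e <- boot_error_cond_s(pop, us0[sfirst], us1[sfirst], tail)
  val <- (pop$c0 * e[, "e0"] + pop$c1 * e[, "e1"])[match(skey, skey[sfirst])]

  out <- rowsum(agg[, 1] * val, usplit, reorder = FALSE)
  res <- numeric(length(n0s))
  res[as.integer(rownames(out))] <- out[, 1]
  res
}
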