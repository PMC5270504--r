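# Independent oracles used across the test files. These deliberately avoid
# the package's own formulas: the bivariate normal oracle integrates the
# density numerically, and the moment oracles simulate raw training sets and
# classify with elementary arithmetic.

# bivariate normal lower-orthant probability by conditioning quadrature:
# P(Z1 <= u, Z2 <= v) = int_{-inf}^{u} phi(x) Phi((v - rho x)/sqrt(1-rho^2)) dx
bvn_quad <- function(u, v, rho) {
  f <- function(x) dnorm(x) * pnorm((v - rho * x) / sqrt(1 - rho^2))
  integrate(f, -Inf, u, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# exact class errors of a univariate midpoint-threshold classifier with
# class means m0h, m1h (vectors), under N(mu_i, sd_i^2) populations
threshold_errors <- function(m0h, m1h, mu0, mu1, sd0, sd1) {
  mid <- (m0h + m1h) / 2
  lower <- m0h < m1h                   # predict 1 iff x > mid
  e0 <- ifelse(lower, 1 - pnorm(mid, mu0, sd0), pnorm(mid, mu0, sd0))
  e1 <- ifelse(lower, pnorm(mid, mu1, sd1), 1 - pnorm(mid, mu1, sd1))
  cbind(e0 = e0, e1 = e1)
}

# MC oracle for the conditional expected true error (univariate): draw the
# class sample means directly, average the exact errors of the trained rule
oracle_true_cond_uni <- function(pop, n0, n1, reps, seed) {
  withr_seed(seed)
  m0h <- rnorm(reps, pop$mu0, pop$sigma0 / sqrt(n0))
  m1h <- rnorm(reps, pop$mu1, pop$sigma1 / sqrt(n1))
  e <- threshold_errors(m0h, m1h, pop$mu0, pop$mu1, pop$sigma0, pop$sigma1)
  list(est = colMeans(e), se = apply(e, 2, sd) / sqrt(reps))
}

# MC oracle for the conditional expected resubstitution error: draw whole
# samples and count misclassified training points
oracle_resub_cond_uni <- function(pop, n0, n1, reps, seed) {
  withr_seed(seed)
  x0 <- matrix(rnorm(reps * n0, pop$mu0, pop$sigma0), reps, n0)
  x1 <- matrix(rnorm(reps * n1, pop$mu1, pop$sigma1), reps, n1)
  m0h <- rowMeans(x0)
  m1h <- rowMeans(x1)
  mid <- (m0h + m1h) / 2
  sgn <- sign(m0h - m1h)               # predict 1 iff sgn * (x - mid) < 0
  e0 <- rowMeans(sgn * (x0 - mid) < 0)
  e1 <- rowMeans(sgn * (x1 - mid) >= 0)
  e <- cbind(e0 = e0, e1 = e1)
  list(est = colMeans(e), se = apply(e, 2, sd) / sqrt(reps))
}

# MC oracle for the conditional expected bootstrap error given a fixed
# bootstrap vector C: draw the original sample, form the count-weighted
# bootstrap means, take the exact errors of the resulting threshold rule
oracle_boot_cond_uni <- function(pop, C, n0, reps, seed) {
  withr_seed(seed)
  n <- length(C)
  n1 <- n - n0
  x0 <- matrix(rnorm(reps * n0, pop$mu0, pop$sigma0), reps, n0)
  x1 <- matrix(rnorm(reps * n1, pop$mu1, pop$sigma1), reps, n1)
  c0 <- C[seq_len(n0)]
  c1 <- C[n0 + seq_len(n1)]
  m0h <- drop(x0 %*% c0) / sum(c0)
  m1h <- drop(x1 %*% c1) / sum(c1)
  e <- threshold_errors(m0h, m1h, pop$mu0, pop$mu1, pop$sigma0, pop$sigma1)
  list(est = colMeans(e), se = apply(e, 2, sd) / sqrt(reps))
}

# multivariate oracles (homoskedastic, known covariance): draw class sample
# means, classify one fresh test point per class per rep — fully independent
# of any closed-form error expression
oracle_true_cond_mv <- function(pop, n0, n1, reps, seed) {
  withr_seed(seed)
  d <- pop$d
  R <- chol(pop$Sigma)
  m0h <- matrix(rnorm(reps * d), reps, d) %*% (R / sqrt(n0))
  m0h <- sweep(m0h, 2, pop$mu0, "+")
  m1h <- matrix(rnorm(reps * d), reps, d) %*% (R / sqrt(n1))
  m1h <- sweep(m1h, 2, pop$mu1, "+")
  x0 <- sweep(matrix(rnorm(reps * d), reps, d) %*% R, 2, pop$mu0, "+")
  x1 <- sweep(matrix(rnorm(reps * d), reps, d) %*% R, 2, pop$mu1, "+")
  a <- (m0h - m1h) %*% solve(pop$Sigma)       # reps x d directions
  mid <- (m0h + m1h) / 2
  w0 <- rowSums((x0 - mid) * a)               # discriminant at the test point
  w1 <- rowSums((x1 - mid) * a)
  e0 <- w0 < 0
  e1 <- w1 >= 0
  list(est = c(e0 = mean(e0), e1 = mean(e1)),
       se = c(sd(e0), sd(e1)) / sqrt(reps))
}

oracle_resub_cond_mv <- function(pop, n0, n1, reps, seed) {
  withr_seed(seed)
  d <- pop$d
  R <- chol(pop$Sigma)
  Sinv <- solve(pop$Sigma)
  e <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    x0 <- sweep(matrix(rnorm(n0 * d), n0, d) %*% R, 2, pop$mu0, "+")
    x1 <- sweep(matrix(rnorm(n1 * d), n1, d) %*% R, 2, pop$mu1, "+")
    m0h <- colMeans(x0); m1h <- colMeans(x1)
    a <- Sinv %*% (m0h - m1h)
    mid <- (m0h + m1h) / 2
    e[r, 1] <- mean(sweep(x0, 2, mid) %*% a < 0)
    e[r, 2] <- mean(sweep(x1, 2, mid) %*% a >= 0)
  }
  list(est = colMeans(e), se = apply(e, 2, sd) / sqrt(reps))
}

oracle_boot_cond_mv <- function(pop, C, n0, reps, seed) {
  withr_seed(seed)
  d <- pop$d
  n <- length(C)
  n1 <- n - n0
  R <- chol(pop$Sigma)
  c0 <- C[seq_len(n0)]
  c1 <- C[n0 + seq_len(n1)]
  z0 <- matrix(rnorm(reps * n0 * d), reps, n0 * d)
  z1 <- matrix(rnorm(reps * n1 * d), reps, n1 * d)
  # count-weighted bootstrap means, built per dimension
  m0h <- matrix(pop$mu0, reps, d, byrow = TRUE)
  m1h <- matrix(pop$mu1, reps, d, byrow = TRUE)
  for (j in seq_len(d)) {
    zz0 <- z0[, (j - 1) * n0 + seq_len(n0), drop = FALSE]
    zz1 <- z1[, (j - 1) * n1 + seq_len(n1), drop = FALSE]
    # x = mu + z %*% R (per point); accumulate the weighted mean directly
    for (jj in seq_len(d)) {
      m0h[, jj] <- m0h[, jj] + drop(zz0 %*% c0) / sum(c0) * R[j, jj]
      m1h[, jj] <- m1h[, jj] + drop(zz1 %*% c1) / sum(c1) * R[j, jj]
    }
  }
  x0 <- sweep(matrix(rnorm(reps * d), reps, d) %*% R, 2, pop$mu0, "+")
  x1 <- sweep(matrix(rnorm(reps * d), reps, d) %*% R, 2, pop$mu1, "+")
  a <- (m0h - m1h) %*% solve(pop$Sigma)
  mid <- (m0h + m1h) / 2
  e0 <- rowSums((x0 - mid) * a) < 0
  e1 <- rowSums((x1 - mid) * a) >= 0
  list(est = c(e0 = mean(e0), e1 = mean(e1)),
       se = c(sd(e0), sd(e1)) / sqrt(reps))
}

withr_seed <- function(seed) {
  set.seed(seed)
  invisible(NULL)
}

pop_mv_eps <- function(eps, d = 2) {
  delta <- delta_from_bayes_error(eps)
  gauss2(numeric(d), c(delta, numeric(d - 1)), Sigma = diag(d))
}
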