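# Empirical side: train the LDA classifier (known covariance) on a labeled
# sample and estimate its error by resubstitution, the zero bootstrap, and
# convex combinations of the two.

#' Train the LDA classifier with known covariance
#'
#' Fits the linear discriminant
#' \deqn{W(x) = \left(x - \frac{\hat\mu_0 + \hat\mu_1}{2}\right)^T
#'              \Sigma^{-1} (\hat\mu_0 - \hat\mu_1)}
#' with \eqn{\hat\mu_i} the class sample means and \eqn{\Sigma} a fixed
#' (known) covariance matrix. A point is assigned to class 1 when
#' \eqn{W(x) < 0} and to class 0 when \eqn{W(x) \ge 0} — ties go to class 0.
#' In one dimension the covariance cancels and the rule is the midpoint
#' threshold between the class means.
#'
#' @param x Feature matrix (n rows) or vector; coerced to a matrix.
#' @param y Binary labels in \{0, 1\}; both classes must be present.
#' @param Sigma Known covariance matrix; `NULL` (default) uses the identity,
#'   which is exact in one dimension (the variance cancels) and corresponds
#'   to pre-standardized features otherwise.
#' @return An object of class `"lda_fit"`: list with the class means, the
#'   covariance, and the class counts.
#' @examples
#' fit <- lda_train(c(0, 1), c(0, 1))
#' predict(fit, c(0.2, 0.5, 0.9))     # 0 0 1: midpoint 0.5, tie to class 0
#' @export
lda_train <- function(x, y, Sigma = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x))
    stop_invalid("features must be numeric and complete (no missing values)")
  y <- as.integer(y)
  if (length(y) != nrow(x) || anyNA(y) || !all(y %in% c(0L, 1L)))
    stop_invalid("'y' must be labels in {0, 1}, one per row of 'x'")
  n0 <- sum(y == 0L)
  n1 <- sum(y == 1L)
  if (n0 == 0L || n1 == 0L)
    stop_invalid("both classes must be present to train the classifier")
  d <- ncol(x)
  if (is.null(Sigma)) Sigma <- diag(d)
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == d, ncol(Sigma) == d)
  structure(list(mu0 = colMeans(x[y == 0L, , drop = FALSE]),
                 mu1 = colMeans(x[y == 1L, , drop = FALSE]),
                 Sigma = Sigma, n0 = n0, n1 = n1, d = d),
            class = "lda_fit")
}

#' @export
print.lda_fit <- function(x, ...) {
  cat(sprintf("LDA classifier (known covariance), d = %d, n = %d + %d\n",
              x$d, x$n0, x$n1))
  cat("  mu0_hat =", format(x$mu0, digits = 4), "\n")
  cat("  mu1_hat =", format(x$mu1, digits = 4), "\n")
  invisible(x)
}

# signed discriminant value W(x) for each row of newdata
discriminant <- function(object, newdata) {
  z <- as.matrix(newdata)
  if (ncol(z) != object$d) {
    if (object$d == 1L) z <- matrix(as.numeric(z), ncol = 1L)
    else stop_invalid("newdata has the wrong number of columns")
  }
  dirv <- solve(object$Sigma, object$mu0 - object$mu1)
  mid <- (object$mu0 + object$mu1) / 2
  drop(sweep(z, 2, mid) %*% dirv)
}

#' @rdname lda_train
#' @param object An `"lda_fit"` classifier.
#' @param newdata Feature matrix or vector of points to classify.
#' @param ... Unused.
#' @export
predict.lda_fit <- function(object, newdata, ...) {
  as.integer(discriminant(object, newdata) < 0)
}

#' Error estimates for a trained LDA classifier
#'
#' `resub_error()` is the apparent error: the fraction of training points
#' misclassified by the classifier trained on them. `zero_boot_error()` is
#' the zero (leave-out) bootstrap estimator: for each of `B` bootstrap
#' resamples, an LDA classifier is trained on the resample and evaluated on
#' the training points that do not appear in it, and the per-replicate error
#' rates are averaged. Replicates in which no point is left out, or in which
#' the resample contains a single class, are redrawn (up to `100 * B`
#' attempts) so that the estimate always averages exactly `B` valid
#' replicates. `convex_error()` forms \eqn{(1-w)\,resub + w\,boot}; with the
#' default `w = 0.632` it is the classical 0.632 bootstrap estimator.
#'
#' @param x,y,Sigma Training features, labels and known covariance, as in
#'   [lda_train()].
#' @param fit Optionally, the classifier already trained on `(x, y)` (for
#'   `resub_error()`).
#' @param B Number of bootstrap replicates.
#' @param seed Optional seed; the caller's RNG state is preserved.
#' @param resub,boot Component estimates to combine.
#' @param w Convex weight; not restricted to \eqn{[0, 1]}.
#' @return Scalar error estimates.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(10), rnorm(10, 2)); y <- rep(0:1, each = 10)
#' r <- resub_error(x, y)
#' b <- zero_boot_error(x, y, B = 50, seed = 2)
#' convex_error(r, b)                      # 0.632 bootstrap estimate
#' @export
resub_error <- function(x, y, Sigma = NULL, fit = NULL) {
  if (is.null(fit)) fit <- lda_train(x, y, Sigma)
  mean(predict(fit, x) != as.integer(y))
}

#' @rdname resub_error
#' @export
zero_boot_error <- function(x, y, Sigma = NULL, B = 100, seed = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  n <- nrow(x)
  stopifnot(B >= 1)
  with_seed(seed, {
    errs <- numeric(B)
    b <- 0L
    attempts <- 0L
    while (b < B) {
      if (attempts >= 100L * B)
        stop_invalid("could not draw enough valid bootstrap replicates ",
                     "(every resample was degenerate)")
      attempts <- attempts + 1L
      idx <- sample.int(n, n, replace = TRUE)
      held <- setdiff(seq_len(n), idx)
      if (length(held) == 0L) next
      yb <- y[idx]
      if (all(yb == 0L) || all(yb == 1L)) next
      fit <- lda_train(x[idx, , drop = FALSE], yb, Sigma)
      b <- b + 1L
      errs[b] <- mean(predict(fit, x[held, , drop = FALSE]) != y[held])
    }
    mean(errs)
  })
}

#' @rdname resub_error
#' @export
convex_error <- function(resub, boot, w = 0.632) {
  stopifnot(is.numeric(resub), is.numeric(boot), is.numeric(w))
  (1 - w) * resub + w * boot
}

#' True error rate of a trained classifier under a known Gaussian model
#'
#' The linear discriminant \eqn{W(X)} is Gaussian under each class, so the
#' class-conditional error rates of a *given* trained classifier are single
#' normal probabilities: class 0 errs when \eqn{W(X) < 0}, i.e. with
#' probability \eqn{\Phi(-m_0/s)} where \eqn{m_0} and \eqn{s^2} are the mean
#' and variance of \eqn{W(X)} under \eqn{X \sim N(\mu_0, \Sigma)}. The
#' overall rate combines the two classes with the model priors. The
#' classifier must use the model's covariance for \eqn{s} to be exact.
#'
#' @param fit An `"lda_fit"` classifier.
#' @param pop The generating [gauss2()] model.
#' @return Scalar true error rate of `fit` under `pop`.
#' @examples
#' pop <- gauss2(0, 2)
#' oracle <- lda_train(c(0, 2), c(0, 1))    # means equal to the truth
#' true_error(oracle, pop)                  # equals the Bayes error
#' bayes_error(pop)
#' @export
true_error <- function(fit, pop) {
  stopifnot(inherits(fit, "lda_fit"), inherits(pop, "gauss2"))
  if (is_univariate(pop)) {
    Sig <- matrix(pop$sigma0^2)
    Sig1 <- matrix(pop$sigma1^2)
  } else {
    Sig <- Sig1 <- pop$Sigma
  }
  a <- solve(fit$Sigma, fit$mu0 - fit$mu1)   # discriminant direction
  qa0 <- drop(crossprod(a, Sig %*% a))
  qa1 <- drop(crossprod(a, Sig1 %*% a))
  if (qa0 <= 0 || qa1 <= 0)
    stop_invalid("degenerate classifier: estimated class means coincide")
  mid <- (fit$mu0 + fit$mu1) / 2
  m0 <- drop(crossprod(pop$mu0 - mid, a))    # E[W | class 0]
  m1 <- drop(crossprod(pop$mu1 - mid, a))
  e0 <- stats::pnorm(-m0 / sqrt(qa0))        # P(W < 0 | class 0)
  e1 <- stats::pnorm(m1 / sqrt(qa1))         # P(W >= 0 | class 1)
  pop$c0 * e0 + pop$c1 * e1
}

#' Read a delimited feature-label table
#'
#' Reads a CSV/TSV file with one row per sample, numeric feature columns and
#' a binary label column, for use with the empirical estimators. Missing
#' values are rejected.
#'
#' @param file Path to the delimited file.
#' @param label Name of the label column.
#' @param features Character vector of feature column names; `NULL` uses all
#'   non-label columns.
#' @param sep Field separator; `","` or `"\t"`.
#' @return List with elements `x` (feature matrix) and `y` (integer labels).
#' @export
read_labeled_table <- function(file, label = "y", features = NULL,
                               sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          check.names = FALSE)
  if (!label %in% names(df))
    stop_invalid(sprintf("label column '%s' not found", label))
  if (is.null(features)) features <- setdiff(names(df), label)
  if (!all(features %in% names(df)))
    stop_invalid("feature column(s) not found")
  x <- as.matrix(df[, features, drop = FALSE])
  y <- df[[label]]
  if (anyNA(x) || anyNA(y))
    stop_invalid("missing values are not supported")
  if (!all(y %in% c(0, 1)))
    stop_invalid("label column must be binary 0/1")
  list(x = x, y = as.integer(y))
}
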