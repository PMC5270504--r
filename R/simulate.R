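# Synthetic-data generation from the two-class Gaussian model and the
# bias/RMS benchmarking experiment for the error estimators.

#' Draw a mixture sample from a two-class Gaussian model
#'
#' Generates an i.i.d. sample of size `n` under mixture sampling: each label
#' is Bernoulli with the model priors, and the features are drawn from the
#' labeled class's Gaussian distribution.
#'
#' @param pop A [gauss2()] model.
#' @param n Sample size.
#' @param seed Optional seed; the caller's RNG state is preserved.
#' @return List with `x` (n x d feature matrix) and `y` (integer labels).
#' @examples
#' s <- rgauss2(gauss2(0, 2), 10, seed = 1)
#' table(s$y)
#' @export
rgauss2 <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "gauss2"), n >= 1)
  with_seed(seed, {
    y <- stats::rbinom(n, 1L, pop$c1)
    x <- if (is_univariate(pop)) {
      matrix(stats::rnorm(n,
                          mean = ifelse(y == 1L, pop$mu1, pop$mu0),
                          sd = ifelse(y == 1L, pop$sigma1, pop$sigma0)),
             ncol = 1L)
    } else {
      z <- matrix(stats::rnorm(n * pop$d), n, pop$d) %*% chol(pop$Sigma)
      mu <- rbind(pop$mu0, pop$mu1)[y + 1L, , drop = FALSE]
      z + mu
    }
    list(x = x, y = as.integer(y))
  })
}

#' Bias and RMS of the bootstrap error estimators on synthetic data
#'
#' Monte Carlo benchmark of resubstitution, the zero bootstrap, and convex
#' combinations thereof, against the closed-form true error of each trained
#' classifier. For every repetition a fresh mixture sample is drawn from
#' `pop` (samples containing a single class are redrawn and counted), the
#' LDA classifier with known covariance is trained, its exact true error is
#' computed from the model, and each estimator is evaluated on the sample.
#' Bias is `mean(estimate - true)` and RMS is
#' `sqrt(mean((estimate - true)^2))`, each with a Monte Carlo standard error.
#'
#' @param pop A [gauss2()] model.
#' @param n Training sample size per repetition.
#' @param reps Number of repetitions.
#' @param B Bootstrap replicates per repetition.
#' @param weights Named vector of convex weights to evaluate; each produces
#'   an estimator row named `conv_<name>`.
#' @param seed Seed governing the whole experiment (sampling and bootstrap).
#' @return A data.frame with one row per estimator (`resub`, `boot`, and one
#'   per weight): columns `estimator`, `bias`, `rms`, `se_bias`, `se_rms`.
#'   Attributes: `mean_true` (Monte Carlo mean of the true error), `redraws`
#'   (single-class samples redrawn), `reps`, `B`, `weights`.
#' @examples
#' pop <- gauss2(0, 2)
#' bias_rms_experiment(pop, n = 15, reps = 50, B = 20,
#'                     weights = c(b632 = 0.632), seed = 1)
#' @export
bias_rms_experiment <- function(pop, n, reps = 2000, B = 100,
                                weights = c(b632 = 0.632), seed = NULL) {
  stopifnot(inherits(pop, "gauss2"), reps >= 1, B >= 1,
            length(weights) >= 1, !is.null(names(weights)),
            all(nzchar(names(weights))))
  Sigma <- if (is_univariate(pop)) NULL else pop$Sigma
  est_names <- c("resub", "boot", paste0("conv_", names(weights)))
  dev <- matrix(NA_real_, reps, length(est_names),
                dimnames = list(NULL, est_names))
  true_err <- numeric(reps)
  redraws <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      repeat {
        s <- rgauss2(pop, n)
        if (any(s$y == 0L) && any(s$y == 1L)) break
        redraws <- redraws + 1L
      }
      fit <- lda_train(s$x, s$y, Sigma)
      tr <- true_error(fit, pop)
      re <- resub_error(s$x, s$y, fit = fit)
      bo <- zero_boot_error(s$x, s$y, Sigma, B = B)
      true_err[r] <- tr
      dev[r, ] <- c(re, bo, (1 - weights) * re + weights * bo) - tr
    }
  })
  bias <- colMeans(dev)
  rms <- sqrt(colMeans(dev^2))
  se_bias <- apply(dev, 2, stats::sd) / sqrt(reps)
  se_rms <- apply(dev^2, 2, stats::sd) / sqrt(reps) / (2 * pmax(rms, 1e-12))
  out <- data.frame(estimator = est_names, bias = bias, rms = rms,
                    se_bias = se_bias, se_rms = se_rms,
                    row.names = NULL)
  attr(out, "mean_true") <- mean(true_err)
  attr(out, "redraws") <- redraws
  attr(out, "reps") <- reps
  attr(out, "B") <- B
  attr(out, "weights") <- weights
  out
}
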