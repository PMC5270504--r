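# The convex bootstrap estimator (1-w) resub + w boot and the weight w* that
# makes it unbiased for the expected true error.

#' Unbiasedness weight of the convex bootstrap estimator
#'
#' Given the three expected error rates, the convex combination
#' \eqn{(1-w)\,\hat\epsilon^r + w\,\hat\epsilon^{boot}} is unbiased for the
#' expected true error exactly when
#' \deqn{w^* = \frac{E[\hat\epsilon^r] - E[\epsilon_n]}
#'                  {E[\hat\epsilon^r] - E[\hat\epsilon^{boot}]}.}
#' The value is returned unclipped: it is an identity, not a heuristic, and
#' can in principle fall outside \eqn{[0, 1]} (although all published table
#' regimes stay inside).
#'
#' @param e_true Expected true error \eqn{E[\epsilon_n]}.
#' @param e_resub Expected resubstitution error \eqn{E[\hat\epsilon^r]}.
#' @param e_boot Expected zero-bootstrap error \eqn{E[\hat\epsilon^{boot}]}.
#' @return The scalar weight \eqn{w^*}.
#' @examples
#' optimal_weight(e_true = 0.20, e_resub = 0.10, e_boot = 0.25)   # 2/3
#' @export
optimal_weight <- function(e_true, e_resub, e_boot) {
  stopifnot(is.numeric(e_true), is.numeric(e_resub), is.numeric(e_boot))
  denom <- e_resub - e_boot
  if (any(abs(denom) <= 1e-12))
    stop_invalid("resubstitution and bootstrap expectations coincide ",
                 "(denominator ~ 0); the weight is ill-conditioned.\n",
                 sprintf("  e_true = %.6g, e_resub = %.6g, e_boot = %.6g",
                         e_true, e_resub, e_boot))
  (e_resub - e_true) / denom
}

#' Expected-error moments and unbiasedness weight for a Gaussian model
#'
#' `lda_error_moments()` computes the triple of expected error rates (true,
#' resubstitution, zero bootstrap) of LDA with known covariance under the
#' model `pop` at sample size `n`; `weight_for_model()` applies
#' [optimal_weight()] to them. The model can be given either as a [gauss2()]
#' object or, in the homoskedastic equal-prior case where the weight depends
#' only on the Bayes error and the sample size, as a pair
#' (`bayes_error`, `d`): the corresponding canonical model has
#' \eqn{\mu_1 - \mu_0} at Mahalanobis distance \eqn{\delta =
#' -2\Phi^{-1}(\epsilon^*)}, identity covariance and equal priors.
#'
#' @param pop A [gauss2()] model, or `NULL` to build one from `bayes_error`.
#' @param n Sample size.
#' @param bayes_error Bayes error \eqn{\epsilon^* \in (0, 0.5)} (used when
#'   `pop` is `NULL`).
#' @param d Dimensionality of the canonical model (1 = univariate).
#' @param method,M,seed,degenerate,drop_below,max_n,tail Passed to
#'   [expected_boot_error()]; `degenerate`/`drop_below`/`tail` also govern
#'   the true and resubstitution mixtures.
#' @return `lda_error_moments()`: named vector
#'   `c(e_true, e_resub, e_boot)`; `weight_for_model()`: the scalar weight.
#' @examples
#' weight_for_model(n = 10, bayes_error = 0.025)          # about 0.72
#' m <- lda_error_moments(gauss2(0, 1), n = 20)
#' optimal_weight(m["e_true"], m["e_resub"], m["e_boot"])
#' @export
lda_error_moments <- function(pop = NULL, n, bayes_error = NULL, d = 1,
                              method = c("plugin", "exact", "mc"),
                              M = 100 * n^2, seed = NULL,
                              degenerate = c("exclude", "limit"),
                              drop_below = 0, max_n = 12,
                              tail = c("imhof", "exact")) {
  pop <- resolve_model(pop, bayes_error, d)
  method <- match.arg(method)
  degenerate <- match.arg(degenerate)
  tail <- match.arg(tail)
  c(e_true = expected_true_error(pop, n, degenerate, drop_below, tail),
    e_resub = expected_resub_error(pop, n, degenerate, drop_below, tail),
    e_boot = expected_boot_error(pop, n, method, M, seed, degenerate,
                                 drop_below, max_n, tail))
}

#' @rdname lda_error_moments
#' @export
weight_for_model <- function(pop = NULL, n, bayes_error = NULL, d = 1,
                             method = c("plugin", "exact", "mc"),
                             M = 100 * n^2, seed = NULL,
                             degenerate = c("exclude", "limit"),
                             drop_below = 0, max_n = 12,
                             tail = c("imhof", "exact")) {
  m <- lda_error_moments(pop, n, bayes_error, d, method, M, seed,
                         degenerate, drop_below, max_n, tail)
  optimal_weight(m[["e_true"]], m[["e_resub"]], m[["e_boot"]])
}

resolve_model <- function(pop, bayes_error, d) {
  if (!is.null(pop)) {
    stopifnot(inherits(pop, "gauss2"))
    return(pop)
  }
  if (is.null(bayes_error))
    stop_invalid("supply either a gauss2 model or a Bayes error")
  check_prob(bayes_error, "bayes_error", open_lo = TRUE, open_hi = TRUE)
  if (bayes_error >= 0.5)
    stop_invalid("'bayes_error' must be < 0.5")
  delta <- delta_from_bayes_error(bayes_error)
  if (d == 1) {
    gauss2(0, delta)
  } else {
    gauss2(numeric(d), c(delta, numeric(d - 1)), Sigma = diag(d))
  }
}

#' Weight table over Bayes error and sample size
#'
#' Tabulates the unbiasedness weight \eqn{w^*} on a grid of Bayes errors and
#' sample sizes for the homoskedastic equal-prior model of dimension `d` —
#' the regime in which \eqn{w^*} is a function of
#' (\eqn{\epsilon^*}, \eqn{n}) only. The returned object carries provenance
#' (dimension, method, `M`, seed, truncation) as attributes and can be
#' written to / read from a CSV with a JSON sidecar.
#'
#' `weight_lookup()` interpolates a table bilinearly in
#' (\eqn{\epsilon^*}, \eqn{n}); it is exact at grid nodes and refuses to
#' extrapolate outside the grid hull.
#'
#' @param bayes_errors Increasing grid of Bayes errors in (0, 0.5).
#' @param sample_sizes Increasing grid of sample sizes (>= 2).
#' @param d Dimensionality of the canonical homoskedastic model.
#' @inheritParams lda_error_moments
#' @param table A `"weight_table"` object.
#' @param bayes_error,n Query point for `weight_lookup()`.
#' @param file Path of the CSV file; the sidecar uses the same path with
#'   extension `.json`.
#' @param x,... Printing arguments.
#' @return `weight_table()`: a `"weight_table"` matrix (rows = Bayes errors,
#'   columns = sample sizes). `weight_lookup()`: interpolated weight(s).
#' @examples
#' tab <- weight_table(c(0.1, 0.2), c(10, 20))
#' weight_lookup(tab, 0.15, 15)
#' @export
weight_table <- function(bayes_errors, sample_sizes, d = 1,
                         method = c("plugin", "exact", "mc"),
                         M = NULL, seed = NULL, drop_below = 0,
                         tail = c("imhof", "exact")) {
  tail <- match.arg(tail)
  stopifnot(is.numeric(bayes_errors), is.numeric(sample_sizes),
            !is.unsorted(bayes_errors, strictly = TRUE),
            !is.unsorted(sample_sizes, strictly = TRUE))
  check_prob(bayes_errors, "bayes_errors", open_lo = TRUE, open_hi = TRUE)
  if (any(bayes_errors >= 0.5))
    stop_invalid("Bayes errors must be < 0.5")
  method <- match.arg(method)
  W <- matrix(NA_real_, length(bayes_errors), length(sample_sizes),
              dimnames = list(format(bayes_errors, trim = TRUE),
                              format(sample_sizes, trim = TRUE)))
  for (j in seq_along(sample_sizes)) {
    n <- sample_sizes[j]
    Mj <- if (is.null(M)) 100 * n^2 else M
    for (i in seq_along(bayes_errors)) {
      W[i, j] <- tryCatch(
        weight_for_model(n = n, bayes_error = bayes_errors[i], d = d,
                         method = method, M = Mj,
                         seed = if (is.null(seed)) NULL else seed + j,
                         drop_below = drop_below, tail = tail),
        error = function(e) NA_real_)
    }
  }
  structure(W, class = c("weight_table", class(W)),
            bayes_errors = bayes_errors, sample_sizes = sample_sizes,
            d = d, method = method, M = M, seed = seed,
            drop_below = drop_below, tail = tail)
}

#' @rdname weight_table
#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf(
    "Unbiased convex bootstrap weights (d = %d, method = %s)\n",
    attr(x, "d"), attr(x, "method")))
  cat("rows: Bayes error; columns: sample size\n")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' @rdname weight_table
#' @export
weight_lookup <- function(table, bayes_error, n) {
  stopifnot(inherits(table, "weight_table"))
  eg <- attr(table, "bayes_errors")
  ng <- attr(table, "sample_sizes")
  k <- max(length(bayes_error), length(n))
  bayes_error <- rep_len(bayes_error, k)
  n <- rep_len(n, k)
  if (any(bayes_error < eg[1] - 1e-12) || any(bayes_error > eg[length(eg)] + 1e-12) ||
      any(n < ng[1] - 1e-12) || any(n > ng[length(ng)] + 1e-12))
    stop_invalid("query outside the table grid; refusing to extrapolate")
  vapply(seq_len(k), function(idx) {
    interp_bilinear(eg, ng, unclass(table), bayes_error[idx], n[idx])
  }, numeric(1))
}

interp_bilinear <- function(xg, yg, Z, x, y) {
  i <- findInterval(x, xg, rightmost.closed = TRUE, all.inside = TRUE)
  j <- findInterval(y, yg, rightmost.closed = TRUE, all.inside = TRUE)
  tx <- if (xg[i + 1] == xg[i]) 0 else (x - xg[i]) / (xg[i + 1] - xg[i])
  ty <- if (yg[j + 1] == yg[j]) 0 else (y - yg[j]) / (yg[j + 1] - yg[j])
  (1 - tx) * (1 - ty) * Z[i, j] + tx * (1 - ty) * Z[i + 1, j] +
    (1 - tx) * ty * Z[i, j + 1] + tx * ty * Z[i + 1, j + 1]
}

#' @rdname weight_table
#' @export
write_weight_table <- function(table, file) {
  stopifnot(inherits(table, "weight_table"))
  df <- data.frame(bayes_error = attr(table, "bayes_errors"),
                   unclass(table), check.names = FALSE)
  names(df)[-1] <- paste0("n", attr(table, "sample_sizes"))
  utils::write.csv(df, file, row.names = FALSE)
  meta <- list(d = attr(table, "d"), method = attr(table, "method"),
               M = attr(table, "M"), seed = attr(table, "seed"),
               drop_below = attr(table, "drop_below"),
               priors = c(0.5, 0.5))
  jsonlite::write_json(meta, sidecar_path(file), auto_unbox = TRUE,
                       null = "null")
  invisible(file)
}

#' @rdname weight_table
#' @export
read_weight_table <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  eg <- df[[1]]
  ng <- as.numeric(sub("^n", "", names(df)[-1]))
  W <- as.matrix(df[, -1, drop = FALSE])
  dimnames(W) <- list(format(eg, trim = TRUE), format(ng, trim = TRUE))
  meta <- if (file.exists(sidecar_path(file))) {
    jsonlite::read_json(sidecar_path(file), simplifyVector = TRUE)
  } else {
    list(d = NA_integer_, method = NA_character_, M = NULL, seed = NULL,
         drop_below = 0)
  }
  structure(W, class = c("weight_table", class(W)),
            bayes_errors = eg, sample_sizes = ng,
            d = meta$d, method = meta$method, M = meta$M, seed = meta$seed,
            drop_below = meta$drop_below)
}

sidecar_path <- function(file) paste0(sub("\\.[^.]+$", "", file), ".json")
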