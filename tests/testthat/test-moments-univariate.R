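# exact univariate conditional moments and their mixture aggregation

test_that("conditional true and resubstitution errors match MC oracles", {
  reps <- 2e5
  cfgs <- list(
    list(pop = gauss2(0, 1), n0 = 10, n1 = 10),
    list(pop = gauss2(0, 1.8, sigma0 = 1.3, sigma1 = 0.7), n0 = 6, n1 = 14),
    list(pop = gauss2(-1, 1, sigma0 = 2), n0 = 4, n1 = 5))
  for (k in seq_along(cfgs)) {
    cf <- cfgs[[k]]
    e <- true_error_cond(cf$pop, cf$n0, cf$n1)
    o <- oracle_true_cond_uni(cf$pop, cf$n0, cf$n1, reps, seed = 100 + k)
    expect_equal(unname(e[1, ]), unname(o$est),
                 tolerance = max(3 * o$se / pmax(abs(o$est), 0.01)),
                 label = sprintf("true cfg %d", k))
    e <- resub_error_cond(cf$pop, cf$n0, cf$n1)
    o <- oracle_resub_cond_uni(cf$pop, cf$n0, cf$n1, reps, seed = 200 + k)
    expect_equal(unname(e[1, ]), unname(o$est),
                 tolerance = max(3 * o$se / pmax(abs(o$est), 0.01)),
                 label = sprintf("resub cfg %d", k))
  }
})

test_that("bootstrap conditional error matches its MC oracle", {
  reps <- 2e5
  pop <- gauss2(0, 1)
  C <- c(2, 2, 1, 0, 0, 0, 0, 1, 2, 2)
  e <- boot_error_cond(pop, C, 5)
  o <- oracle_boot_cond_uni(pop, C, 5, reps, seed = 301)
  expect_equal(unname(e[1, ]), unname(o$est), tolerance = max(3 * o$se / 0.05))
  # heteroskedastic, unbalanced split
  pop2 <- gauss2(0, 2, sigma0 = 1.5, sigma1 = 0.8)
  C2 <- c(3, 0, 1, 0, 2, 2, 0, 1, 0, 1)
  e2 <- boot_error_cond(pop2, C2, 4)
  o2 <- oracle_boot_cond_uni(pop2, C2, 4, reps, seed = 302)
  expect_equal(unname(e2[1, ]), unname(o2$est),
               tolerance = max(3 * o2$se / 0.05))
})

test_that("all-ones bootstrap vector reduces exactly to the true error", {
  pops <- list(gauss2(0, 1), gauss2(0.5, 2.5, sigma0 = 2, sigma1 = 0.6))
  for (pop in pops) {
    for (n0 in c(2, 5, 8)) {
      n <- 10
      expect_equal(boot_error_cond(pop, rep(1, n), n0),
                   true_error_cond(pop, n0, n - n0), tolerance = 1e-12)
    }
  }
})

test_that("interchanging the populations swaps the class errors", {
  pop <- gauss2(0, 1.4, sigma0 = 1.2, sigma1 = 0.9)
  swapped <- gauss2(1.4, 0, sigma0 = 0.9, sigma1 = 1.2)
  e <- true_error_cond(pop, 7, 12)
  es <- true_error_cond(swapped, 12, 7)
  expect_equal(e[1, "e0"], es[1, "e1"], ignore_attr = TRUE, tolerance = 1e-13)
  expect_equal(e[1, "e1"], es[1, "e0"], ignore_attr = TRUE, tolerance = 1e-13)
  r <- resub_error_cond(pop, 7, 12)
  rs <- resub_error_cond(swapped, 12, 7)
  expect_equal(unname(r[1, ]), unname(rev(rs[1, ])), tolerance = 1e-13)
})

test_that("symmetric coincident populations give one half everywhere", {
  pop <- gauss2(0, 0)
  e <- true_error_cond(pop, 5, 5)
  expect_equal(unname(e[1, ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(expected_true_error(pop, 12), 0.5, tolerance = 1e-12)
})

test_that("resubstitution is optimistic where true error is moderate", {
  pop <- gauss2(0, 1)
  expect_lt(resub_error_cond(pop, 5, 5)[1, "e0"],
            true_error_cond(pop, 5, 5)[1, "e0"])
})

test_that("single class-0 point classifies itself perfectly on resubstitution", {
  pop <- gauss2(0, 1)
  expect_equal(resub_error_cond(pop, 1, 9)[1, "e0"], 0, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("conditional errors are continuous and decreasing in delta", {
  deltas <- seq(0.2, 4, by = 0.1)
  e0 <- vapply(deltas, function(d)
    true_error_cond(gauss2(0, d), 6, 9)[1, "e0"], numeric(1))
  expect_true(all(diff(e0) < 0))
  expect_lt(max(abs(diff(e0))), 0.05)
})

test_that("mixture expectations match a full mixture-sampling MC oracle", {
  pop <- gauss2(0, 1)
  n <- 10
  reps <- 4000
  set.seed(77)
  tr <- re <- numeric(reps)
  kept <- 0
  while (kept < reps) {
    y <- rbinom(n, 1, 0.5)
    if (all(y == 0) || all(y == 1)) next
    kept <- kept + 1
    x <- rnorm(n, mean = y)
    fit <- lda_train(x, y)
    tr[kept] <- true_error(fit, pop)
    re[kept] <- resub_error(x, y, fit = fit)
  }
  expect_equal(expected_true_error(pop, n), mean(tr),
               tolerance = 3 * sd(tr) / sqrt(reps) / mean(tr))
  expect_equal(expected_resub_error(pop, n), mean(re),
               tolerance = 3 * sd(re) / sqrt(reps) / mean(re))
})

test_that("degenerate-split conventions differ by the binomial tail only", {
  pop <- gauss2(0, 1)
  a <- expected_true_error(pop, 10, degenerate = "exclude")
  b <- expected_true_error(pop, 10, degenerate = "limit")
  expect_lt(abs(a - b), 2^-9 + 1e-3)
  expect_error(true_error_cond(pop, 0, 10), "degenerate")
})
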