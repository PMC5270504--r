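# multinomial bootstrap-vector space

test_that("enumeration yields every composition exactly once", {
  V <- boot_vectors(2)
  expect_equal(nrow(V), 3)
  expect_true(all(rowSums(V) == 2))
  expect_equal(nrow(boot_vectors(3)), 10)           # C(5, 2)
  for (n in 2:8) {
    V <- boot_vectors(n)
    expect_equal(nrow(V), n_boot_vectors(n))
    expect_false(anyDuplicated(V) > 0)
    expect_true(all(rowSums(V) == n))
    p <- apply(V, 1, dboot_vector)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_gt(n_boot_vectors(20), 6.8e10)
  expect_error(boot_vectors(20), "Monte Carlo")
})

test_that("mass function matches closed forms", {
  expect_equal(dboot_vector(c(1, 1)), 0.5)
  expect_equal(dboot_vector(c(2, 0)), 0.25)
  expect_equal(dboot_vector(rep(1, 7)), factorial(7) / 7^7, tolerance = 1e-14)
  expect_error(dboot_vector(c(2, 1)), "sum")
  expect_error(dboot_vector(c(-1, 3)), "nonnegative")
})

test_that("sampled vectors reproduce the multinomial law", {
  M <- 2e4
  V <- rboot_vectors(5, M, seed = 9)
  expect_true(all(rowSums(V) == 5))
  # marginal mean 1 per position, sd of the mean = sqrt(4/5)/sqrt(M)
  expect_equal(unname(colMeans(V)), rep(1, 5),
               tolerance = 3 * sqrt(4 / 5) / sqrt(M))
  # empirical frequency of a specific vector vs its mass
  hit <- mean(apply(V, 1, function(r) all(r == c(1, 1, 1, 1, 1))))
  p <- dboot_vector(rep(1, 5))
  expect_equal(hit, p, tolerance = 3 * sqrt(p * (1 - p) / M) / p)
  expect_identical(V, rboot_vectors(5, M, seed = 9))   # determinism
})

test_that("s-values are the squared-occupancy ratios per class segment", {
  expect_equal(s_values(rep(1, 10), 4), c(s0 = 0.25, s1 = 1 / 6))
  expect_equal(s_values(c(4, 0, 0, 0, 1, 1, 1, 1, 1, 1), 4),
               c(s0 = 1, s1 = 1 / 6))
  expect_equal(s_values(c(2, 1, 1, 0, 2, 2, 1, 1, 0, 0), 4),
               c(s0 = 6 / 16, s1 = 10 / 36))
  expect_error(s_values(c(0, 0, 2, 2, 1, 1), 2), "empty class segment")
})

test_that("exact expectation equals a naive sum over all vectors", {
  pop <- gauss2(0, 1.2, sigma0 = 1.1, sigma1 = 0.8, c0 = 0.4)
  n <- 5
  V <- boot_vectors(n)
  w <- binomial_class_weights(n, pop$c0)
  naive <- 0
  wtot <- 0
  for (n0 in 1:(n - 1)) {
    acc <- 0
    vtot <- 0
    for (i in seq_len(nrow(V))) {
      k0 <- sum(V[i, 1:n0])
      if (k0 == 0 || k0 == n) next
      e <- boot_error_cond(pop, V[i, ], n0)
      p <- dboot_vector(V[i, ])
      acc <- acc + p * (pop$c0 * e[1, "e0"] + pop$c1 * e[1, "e1"])
      vtot <- vtot + p
    }
    naive <- naive + w[n0 + 1] * acc / vtot
    wtot <- wtot + w[n0 + 1]
  }
  expect_equal(expected_boot_error(pop, n, method = "exact"),
               unname(naive / wtot), tolerance = 1e-12)
})

test_that("exact and Monte Carlo routes agree", {
  pop <- gauss2(0, 1)
  ex <- expected_boot_error(pop, 6, method = "exact")
  mc <- expected_boot_error(pop, 6, method = "mc", M = 1e5, seed = 21)
  mc2 <- expected_boot_error(pop, 6, method = "mc", M = 1e5, seed = 22)
  se <- abs(mc - mc2)                 # crude scale of the MC noise
  expect_equal(mc, ex, tolerance = max(6 * se, 1e-3) / ex)
  expect_identical(mc, expected_boot_error(pop, 6, method = "mc", M = 1e5,
                                           seed = 21))
})

test_that("the zero bootstrap is pessimistic in the table regimes", {
  for (eps in c(0.1, 0.25)) {
    for (n in c(10, 20)) {
      pop <- gauss2(0, delta_from_bayes_error(eps))
      eb <- expected_boot_error(pop, n, method = if (n <= 10) "exact"
                                else "mc", M = 100 * n^2, seed = 3)
      expect_gt(eb, expected_true_error(pop, n))
    }
  }
})

test_that("plug-in route stays within O(1/n) of the full average", {
  pop <- gauss2(0, 1)
  pl <- expected_boot_error(pop, 10, method = "plugin")
  ex <- expected_boot_error(pop, 10, method = "exact")
  expect_lt(abs(pl - ex), 0.5 / 10)
  expect_gt(pl, expected_true_error(pop, 10))   # still pessimistic
})

test_that("symmetric null model gives one half in every mode", {
  pop <- gauss2(0, 0)
  expect_equal(expected_boot_error(pop, 8, method = "plugin"), 0.5,
               tolerance = 1e-10)
  expect_equal(expected_boot_error(pop, 6, method = "exact"), 0.5,
               tolerance = 1e-10)
})
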