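# empirical estimators: training, resubstitution, zero bootstrap, convex

test_that("the trained rule is the midpoint threshold with ties to class 0", {
  fit <- lda_train(c(0, 1), c(0, 1))
  expect_equal(unname(predict(fit, c(0.2, 0.49, 0.51))), c(0, 0, 1))
  expect_equal(unname(predict(fit, 0.5)), 0)      # W = 0 goes to class 0
  # two dimensions, identity covariance: perpendicular bisector
  fit2 <- lda_train(rbind(c(-1, -1), c(1, 1)), c(0, 1), diag(2))
  expect_equal(unname(predict(fit2, rbind(c(-0.1, 0), c(0.1, 0), c(0, 0)))),
               c(0, 1, 0))
  expect_error(lda_train(1:3, c(1, 1, 1)), "both classes")
})

test_that("resubstitution counts the misclassified training points", {
  x <- c(-1, -0.1, 0.2, 1)
  y <- c(0, 0, 1, 1)
  expect_equal(resub_error(x, y), 0)     # boundary 0.025 separates perfectly
  # an outlying mislabeled point is the only resubstitution error
  y2 <- c(1, 0, 1, 1)                    # means -0.1 and 0.0667
  expect_equal(resub_error(x, y2), 0.25)
})

test_that("a widely separated sample yields a zero bootstrap error of zero", {
  x <- c(rnorm(8, 0, 0.01), rnorm(8, 100, 0.01))
  y <- rep(0:1, each = 8)
  expect_equal(zero_boot_error(x, y, B = 30, seed = 4), 0)
})

test_that("zero bootstrap is seed-deterministic and leaves the RNG alone", {
  set.seed(1234)
  x <- c(rnorm(10), rnorm(10, 1.5))
  y <- rep(0:1, each = 10)
  before <- .Random.seed
  b1 <- zero_boot_error(x, y, B = 40, seed = 77)
  expect_identical(.Random.seed, before)
  expect_identical(b1, zero_boot_error(x, y, B = 40, seed = 77))
  expect_true(b1 >= 0 && b1 <= 1)
})

test_that("convex combination interpolates its endpoints", {
  expect_equal(convex_error(0.1, 0.3, 0), 0.1)
  expect_equal(convex_error(0.1, 0.3, 1), 0.3)
  expect_equal(convex_error(0.10, 0.30, 0.632), 0.2264, tolerance = 1e-12)
})

test_that("closed-form true error matches raw Monte Carlo classification", {
  pop <- gauss2(c(0, 0), c(1, 0.5), Sigma = matrix(c(1, 0.3, 0.3, 1), 2))
  set.seed(55)
  s <- rgauss2(pop, 20)
  fit <- lda_train(s$x, s$y, pop$Sigma)
  reps <- 4e5
  test0 <- sweep(matrix(rnorm(reps * 2), reps, 2) %*% chol(pop$Sigma), 2,
                 pop$mu0, "+")
  test1 <- sweep(matrix(rnorm(reps * 2), reps, 2) %*% chol(pop$Sigma), 2,
                 pop$mu1, "+")
  emp <- 0.5 * mean(predict(fit, test0) != 0) +
    0.5 * mean(predict(fit, test1) != 1)
  expect_equal(true_error(fit, pop), emp, tolerance = 3 / sqrt(reps) / emp)
})

test_that("plug-in of the exact means attains the Bayes error, and no
           classifier beats it", {
  pop <- gauss2(0, 2)
  oracle <- lda_train(c(0, 2), c(0, 1))          # means equal to the truth
  expect_equal(true_error(oracle, pop), bayes_error(pop), tolerance = 1e-12)
  set.seed(66)
  for (i in 1:200) {
    s <- rgauss2(pop, 8)
    if (all(s$y == 0) || all(s$y == 1)) next
    fit <- lda_train(s$x, s$y)
    expect_gte(true_error(fit, pop), bayes_error(pop) - 1e-12)
  }
})

test_that("all error estimates are translation equivariant", {
  set.seed(8)
  x <- matrix(rnorm(40), 20, 2)
  x[11:20, ] <- x[11:20, ] + 1
  y <- rep(0:1, each = 10)
  shift <- c(5, -3)
  xs <- sweep(x, 2, shift, "+")
  expect_equal(resub_error(x, y, diag(2)), resub_error(xs, y, diag(2)))
  expect_equal(zero_boot_error(x, y, diag(2), B = 25, seed = 31),
               zero_boot_error(xs, y, diag(2), B = 25, seed = 31))
  pop <- gauss2(c(0, 0), c(1, 1), Sigma = diag(2))
  pops <- gauss2(shift, c(1, 1) + shift, Sigma = diag(2))
  expect_equal(true_error(lda_train(x, y, diag(2)), pop),
               true_error(lda_train(xs, y, diag(2)), pops),
               tolerance = 1e-12)
})

test_that("labeled tables round-trip through the reader", {
  f <- file.path(tempdir(), "sample.csv")
  df <- data.frame(g1 = c(0.1, 0.2, 1.4, 1.9), g2 = c(0, -1, 2, 2.2),
                   y = c(0, 0, 1, 1))
  write.csv(df, f, row.names = FALSE)
  tab <- read_labeled_table(f, label = "y")
  expect_equal(dim(tab$x), c(4, 2))
  expect_identical(tab$y, c(0L, 0L, 1L, 1L))
  expect_error(read_labeled_table(f, label = "missing"), "not found")
})
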