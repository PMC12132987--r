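# Fold construction, cross-validation error computation and lambda selection.

test_that("folds partition the sample with near-equal sizes, reproducibly", {
  f10 <- make_folds(10, 10, seed = 1)
  expect_setequal(f10, 1:10)  # ten singletons

  f <- make_folds(100, 10, seed = 2)
  expect_equal(as.integer(table(f)), rep(10L, 10))

  f103 <- make_folds(103, 10, seed = 3)
  expect_true(max(table(f103)) - min(table(f103)) <= 1)

  expect_identical(make_folds(57, 7, seed = 9), make_folds(57, 7, seed = 9))
  expect_error(make_folds(5, 6), "exceeds")
  expect_error(make_folds(10, 1), ">= 2")
})

test_that("fold seeding does not disturb the session RNG", {
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(make_folds(50, 5, seed = 77))
  b <- rnorm(1)
  expect_identical(a, b)
})

test_that("cv_error averages per-fold errors exactly", {
  d <- random_bnt_data(n = 60, q = 3, seed = 50)
  folds <- make_folds(60, 5, seed = 51)
  ce <- cv_error(d, 2, folds, part = "continuous")
  expect_equal(ce$mean_error, mean(ce$per_fold_errors, na.rm = TRUE))
  expect_length(ce$per_fold_errors, 5)
})

test_that("constant-1/2 probabilities give deviance 2*ln(2) per held-out point", {
  # balanced outcome, lambda at lambda_max: the trained model is the
  # intercept-only fit with pi = 1/2
  set.seed(52)
  n <- 40
  x <- rep(c(0, 1.5), n / 2)
  d <- bnt_data(x, cbind(1, rnorm(n)))
  folds <- rep(1:4, each = 10)  # each fold balanced as well
  lmax <- lambda_max_bnt(d)$lambda1_max
  ce <- cv_error(d, lmax * 2, folds, part = "binomial")
  expect_equal(ce$mean_error, 2 * log(2), tolerance = 1e-6)
})

test_that("null-generator CV error approximates the outcome variance", {
  # pure-noise positive part: best prediction is the mean; CV mse ~ Var(x+)
  set.seed(53)
  n <- 400
  x <- ifelse(runif(n) < 0.5, 0, 2 + abs(rnorm(n)))
  d <- bnt_data(x, cbind(1, matrix(rnorm(3 * n), n, 3)))
  folds <- make_folds(n, 10, seed = 54)
  ce <- cv_error(d, 0.5, folds, part = "continuous")
  vpos <- var(x[x != 0])
  expect_lt(abs(ce$mean_error - vpos) / vpos, 0.25)
})

test_that("select_lambda returns the grid minimizer with larger-lambda ties", {
  d <- random_bnt_data(n = 60, q = 3, seed = 55)
  one <- select_lambda(d, grid = 2, part = "continuous", K = 5, seed = 56)
  expect_equal(one$lambda_selected, 2)

  res <- select_lambda(d, grid = bntreg:::lambda_grid(10, 25, 1e-3),
                       part = "continuous", K = 5, seed = 57)
  expect_equal(res$lambda_selected,
               res$lambda_grid[which.min(res$cv_errors)])
  expect_length(res$cv_errors, 25)
  # tie handling: on a flat curve the first (largest) lambda wins
  expect_equal(bntreg:::select_from_curve(c(5, 3, 1), c(0.2, 0.2, 0.2),
                                          c(0.01, 0.01, 0.01), "min"), 5)
})

test_that("CV error is invariant to fold relabeling", {
  d <- random_bnt_data(n = 50, q = 2, seed = 58)
  folds <- make_folds(50, 5, seed = 59)
  relab <- c(3, 5, 1, 2, 4)[folds]
  for (part in c("binomial", "continuous")) {
    a <- cv_error(d, 1, folds, part = part)
    b <- cv_error(d, 1, relab, part = part)
    expect_equal(a$mean_error, b$mean_error)
    expect_setequal(round(a$per_fold_errors, 12), round(b$per_fold_errors, 12))
  }
})

test_that("CV at lambda >= lambda_max matches intercept-only prediction error", {
  d <- random_bnt_data(n = 100, q = 3, seed = 60,
                       beta1 = c(0.2, 0.8, 0, 0), beta2 = c(0.5, 1, 0, 0))
  folds <- make_folds(100, 5, seed = 61)
  lmax <- lambda_max_bnt(d)$lambda2_max
  ce <- cv_error(d, lmax * 1.5, folds, part = "continuous")
  # intercept-only held-out error by hand
  per <- vapply(1:5, function(J) {
    tr <- folds != J & d$y == 1
    te <- folds == J & d$y == 1
    mean((d$x[te] - mean(d$x[tr]))^2)
  }, numeric(1))
  expect_equal(ce$per_fold_errors, per, tolerance = 1e-6)
})

test_that("signal covariates lower the minimum CV error vs intercept-only", {
  # strong continuous-part signal: min over the path clearly beats lambda_max
  wins <- 0
  for (s in 1:10) {
    d <- random_bnt_data(n = 120, q = 2, seed = 70 + s,
                         beta1 = c(0.3, 0, 0), beta2 = c(0.5, 1.2, 0))
    res <- select_lambda(d, bntreg:::lambda_grid(
      lambda_max_bnt(d)$lambda2_max * 1.2, 30, 1e-3),
      part = "continuous", K = 5, seed = 80 + s)
    if (min(res$cv_errors) < res$cv_errors[1] - 0.1) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("cv_bnt selects, refits and reports both parts", {
  sc <- bnt_scenario("s1", rho = 0, n = 200)
  d <- simulate_bnt_data(sc, seed = 90)
  cvf <- cv_bnt(d, penalty = "alasso", K = 5, seed = 91, nlambda = 40)
  expect_s3_class(cvf, "cv_bnt")
  expect_s3_class(cvf$fit, "bnt_pen")
  expect_equal(cvf$fit$lambda1, cvf$lambda1)
  expect_equal(cvf$cv1$lambda_selected,
               cvf$cv1$lambda_grid[which.min(cvf$cv1$cv_errors)])
  # the refit at the selected pair is reproducible from the stored lambdas
  refit <- bnt_penalized(d, penalty = "alasso", lambda1 = cvf$lambda1,
                         lambda2 = cvf$lambda2)
  expect_equal(unname(refit$beta1), unname(cvf$fit$beta1), tolerance = 1e-8)

  # joint mode runs and returns a fit on the same grids
  cvj <- cv_bnt(d, penalty = "lasso", K = 5, seed = 92, nlambda = 15,
                joint = TRUE)
  expect_true(cvj$lambda1 %in% cvj$cv1$lambda_grid)
})

test_that("single-class training folds raise an actionable error", {
  set.seed(93)
  x <- c(rep(0, 2), abs(rnorm(28, 2)))  # only two zeros
  d <- bnt_data(x, cbind(1, rnorm(30)))
  folds <- c(1, 2, rep(1:10, length.out = 28))
  # removing fold 1 and 2 in turn leaves some split single-class
  expect_error(cv_error(d, 1, ifelse(seq_len(30) <= 2, folds[1:2], 3),
                        part = "binomial"), "single outcome class")
})
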