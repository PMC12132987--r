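# Coordinate-descent solvers: single-coordinate updates against grid-search
# oracles, whole-problem solutions against an independent proximal-gradient
# solver, KKT conditions, lambda_max, exact zeros, and the Lasso /
# adaptive-Lasso reduction identity.

test_that("soft-thresholding operator matches its definition", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_equal(soft_threshold(1, 2), 0)
  expect_equal(soft_threshold(-1, 2), 0)
  expect_equal(soft_threshold(c(-2, 0, 5), 1), c(-1, 0, 4))
  expect_error(soft_threshold(1, -0.5), ">= 0")
})

grid_min_1d <- function(f, lo = -5, hi = 5, step = 1e-4) {
  g <- seq(lo, hi, by = step)
  g[which.min(vapply(g, f, numeric(1)))]
}

test_that("normal-part coordinate update equals the 1-D grid-search minimizer", {
  d <- random_bnt_data(n = 12, q = 2, seed = 21)
  beta2 <- c(0.5, -0.3, 0.8)
  for (k in 2:3) {
    lam <- 1
    om <- 1.3
    upd <- cd_update_normal(k, beta2, d, lam, om)
    oracle <- grid_min_1d(function(b) {
      bb <- beta2; bb[k] <- b
      normal_pen_objective(bb, d, lam, c(1, 1) * c(om, om))
    })
    expect_equal(upd, oracle, tolerance = 1e-3)
  }
  # lambda = 0: unpenalized coordinate least squares
  upd0 <- cd_update_normal(2, beta2, d, 0, 1)
  pos <- d$y == 1
  zk <- d$Z2[pos, 2]
  rp <- d$x[pos] - d$Z2[pos, -2] %*% beta2[-2]
  expect_equal(upd0, sum(zk * rp) / sum(zk^2))
  # orthogonal partial residuals: exact zero for any positive penalty
  set.seed(24)
  zk <- rnorm(8)
  xo <- rnorm(8)
  xo <- xo - zk * sum(zk * xo) / sum(zk^2)  # orthogonalize x against z_k
  dorth <- bnt_data(xo, cbind(1, zk), y = rep(1, 8))
  expect_identical(cd_update_normal(2, c(0, 0), dorth, 0.5, 1), 0)
})

test_that("logistic coordinate update equals the 1-D grid-search minimizer", {
  d <- random_bnt_data(n = 10, q = 2, seed = 22)
  beta1 <- c(0.2, 0.4, -0.6)
  st <- irls_quadratic(beta1, d)
  for (k in 2:3) {
    lam <- 1
    upd <- cd_update_logistic(k, beta1, st, d, lam, 1)
    oracle <- grid_min_1d(function(b) {
      bb <- beta1; bb[k] <- b
      sum(st$w * (st$gamma - drop(d$Z1 %*% bb))^2) + lam * sum(abs(bb[-1]))
    })
    expect_equal(upd, oracle, tolerance = 1e-3)
  }
})

test_that("IRLS quadratic has the defining work-response properties", {
  d <- random_bnt_data(n = 20, q = 2, seed = 23)
  st0 <- irls_quadratic(c(0, 0, 0), d)
  expect_equal(st0$w, rep(1 / 4, 20))
  expect_equal(st0$gamma, 4 * (d$y - 0.5))

  # gradient of the quadratic at the expansion point equals the score
  b <- c(0.3, -0.2, 0.5)
  st <- irls_quadratic(b, d)
  gq <- function(bb) -sum(st$w * (st$gamma - drop(d$Z1 %*% bb))^2)
  expect_equal(num_grad(gq, b) / 2, unname(score_binomial(b, d)),
               tolerance = 1e-6)

  # y identical to fitted probabilities: work response equals linear predictor
  eta <- drop(d$Z1 %*% b)
  d2 <- d
  d2$y <- plogis(eta)  # internal check only; bypasses the 0/1 constraint
  st2 <- irls_quadratic(b, d2)
  expect_equal(st2$gamma, eta)
})

test_that("penalized solvers match the proximal-gradient oracle", {
  # 25 random small instances per part; objective agreement within 1e-5
  for (s in 1:25) {
    q <- sample(2:4, 1)
    d <- random_bnt_data(n = sample(30:60, 1), q = q, seed = 3000 + s)
    om <- runif(q, 0.5, 2)
    lam2 <- runif(1, 0.5, 4)
    f2 <- fit_cd_normal(d, lam2, om)
    o2 <- ista_normal(d, lam2, om)
    expect_lt(abs(normal_pen_objective(f2$beta2, d, lam2, om) -
                  normal_pen_objective(o2, d, lam2, om)), 1e-5)

    lam1 <- runif(1, 0.5, 4)
    f1 <- fit_cd_logistic(d, lam1, om)
    o1 <- ista_logistic(d, lam1, om)
    expect_lt(abs(logistic_pen_objective(f1$beta1, d, lam1, om) -
                  logistic_pen_objective(o1, d, lam1, om)), 1e-5)
  }
})

test_that("KKT conditions hold at the reported solutions", {
  for (s in 1:5) {
    d <- random_bnt_data(n = 50, q = 4, seed = 3100 + s)
    om <- rep(1, 4)
    lam <- 3
    f2 <- fit_cd_normal(d, lam, om)
    pos <- d$y == 1
    g <- unname(2 * drop(crossprod(d$Z2[pos, ], d$x[pos] - d$Z2[pos, ] %*% f2$beta2)))
    for (j in 2:5) {
      if (f2$beta2[j] != 0) {
        expect_equal(g[j], lam * om[j - 1] * sign(f2$beta2[j]), tolerance = 1e-4)
      } else {
        expect_lte(abs(g[j]), lam * om[j - 1] + 1e-4)
      }
    }
    expect_lt(abs(g[1]), 1e-4)  # unpenalized intercept: zero gradient

    f1 <- fit_cd_logistic(d, lam, om)
    pi <- plogis(drop(d$Z1 %*% f1$beta1))
    g1 <- unname(2 * drop(crossprod(d$Z1, d$y - pi)))
    for (j in 2:5) {
      if (f1$beta1[j] != 0) {
        expect_equal(g1[j], lam * om[j - 1] * sign(f1$beta1[j]), tolerance = 1e-3)
      } else {
        expect_lte(abs(g1[j]), lam * om[j - 1] + 1e-3)
      }
    }
  }
})

test_that("lambda >= lambda_max produces the intercept-only model", {
  d <- random_bnt_data(n = 50, q = 4, seed = 31)
  lmax <- lambda_max_bnt(d)
  f2 <- fit_cd_normal(d, lmax$lambda2_max * 1.0001)
  expect_identical(unname(f2$beta2[-1]), rep(0, 4))
  expect_equal(f2$beta2[1], mean(d$x[d$y == 1]))
  f1 <- fit_cd_logistic(d, lmax$lambda1_max * 1.0001)
  expect_identical(unname(f1$beta1[-1]), rep(0, 4))
  expect_equal(f1$beta1[1], qlogis(mean(d$y)), tolerance = 1e-6)
  # just below lambda_max at least one coefficient enters
  f2b <- fit_cd_normal(d, lmax$lambda2_max * 0.98)
  expect_gt(length(f2b$active_set), 0)
})

test_that("zero penalty reproduces the unpenalized MLE", {
  d <- random_bnt_data(n = 60, q = 3, seed = 32)
  f2 <- fit_cd_normal(d, 0, tol = 1e-10)
  m2 <- fit_mle_continuous(d)
  expect_equal(f2$beta2, m2$beta2, tolerance = 1e-8)
  expect_equal(f2$sigma, m2$sigma, tolerance = 1e-8)
  f1 <- fit_cd_logistic(d, 0, tol_outer = 1e-8)
  m1 <- fit_mle_binomial(d)
  expect_equal(f1$beta1, unname(m1$beta1), tolerance = 1e-6)
})

test_that("inactive coefficients are bitwise zero", {
  d <- random_bnt_data(n = 40, q = 4, seed = 33)
  lmax <- lambda_max_bnt(d)
  f2 <- fit_cd_normal(d, lmax$lambda2_max * 0.5)
  expect_true(all(f2$beta2[-1][-f2$active_set] == 0))
  f1 <- fit_cd_logistic(d, lmax$lambda1_max * 0.5)
  inact1 <- setdiff(1:4, f1$active_set)
  expect_identical(unname(f1$beta1[-1][inact1]), rep(0, length(inact1)))
})

test_that("adaptive weights are reciprocal MLE magnitudes with a cap", {
  d <- random_bnt_data(n = 80, q = 3, seed = 34)
  w <- adaptive_weights(d)
  expect_equal(w$omega1, pmin(1 / abs(w$mle$beta1[-1]), 1e6), ignore_attr = TRUE)
  expect_equal(w$omega2, pmin(1 / abs(w$mle$beta2[-1]), 1e6), ignore_attr = TRUE)
  expect_true(all(w$omega1 > 0) && all(w$omega2 > 0))
})

test_that("adaptive Lasso with unit weights is bitwise identical to Lasso", {
  d <- random_bnt_data(n = 60, q = 4, seed = 35)
  fl <- bnt_penalized(d, penalty = "lasso", lambda1 = 2, lambda2 = 3)
  fa <- bnt_penalized(d, penalty = "alasso", lambda1 = 2, lambda2 = 3,
                      omega1 = rep(1, 4), omega2 = rep(1, 4))
  expect_identical(unname(fl$beta1), unname(fa$beta1))
  expect_identical(unname(fl$beta2), unname(fa$beta2))
  expect_identical(fl$sigma, fa$sigma)
})

test_that("the two penalized sub-problems are independent", {
  d <- random_bnt_data(n = 60, q = 3, seed = 36)
  fa <- bnt_penalized(d, penalty = "lasso", lambda1 = 1, lambda2 = 2)
  fb <- bnt_penalized(d, penalty = "lasso", lambda1 = 8, lambda2 = 2)
  expect_identical(unname(fa$beta2), unname(fb$beta2))
  fc <- bnt_penalized(d, penalty = "lasso", lambda1 = 1, lambda2 = 9)
  expect_identical(unname(fa$beta1), unname(fc$beta1))
})

test_that("warm-started paths equal cold starts at each lambda", {
  d <- random_bnt_data(n = 50, q = 4, seed = 37)
  lmax <- lambda_max_bnt(d)
  g2 <- bntreg:::lambda_grid(lmax$lambda2_max, 20, 1e-2)
  warm <- bntreg:::path_part(d, "continuous", g2, rep(1, 4))
  for (i in c(1, 7, 14, 20)) {
    cold <- fit_cd_normal(d, g2[i])
    expect_equal(unname(warm[i, ]), unname(cold$beta2), tolerance = 1e-5)
  }
  g1 <- bntreg:::lambda_grid(lmax$lambda1_max, 20, 1e-2)
  warm1 <- bntreg:::path_part(d, "binomial", g1, rep(1, 4))
  for (i in c(1, 10, 20)) {
    cold <- fit_cd_logistic(d, g1[i])
    expect_equal(unname(warm1[i, ]), unname(cold$beta1), tolerance = 1e-4)
  }
})

test_that("active-set size is non-increasing in lambda for the normal part", {
  d <- random_bnt_data(n = 60, q = 4, seed = 38)
  lmax <- lambda_max_bnt(d)
  g2 <- bntreg:::lambda_grid(lmax$lambda2_max, 30, 1e-3)
  path <- bntreg:::path_part(d, "continuous", g2, rep(1, 4))
  sizes <- rowSums(path[, -1] != 0)  # grid is descending in lambda
  expect_true(all(diff(sizes) >= 0))
})

test_that("penalized solvers agree with glmnet on matched objectives", {
  skip_if_not_installed("glmnet")
  d <- random_bnt_data(n = 60, q = 4, seed = 39)
  pos <- d$y == 1
  npos <- sum(pos)
  om <- c(0.5, 1, 1.5, 2)
  lam2 <- 6
  f2 <- fit_cd_normal(d, lam2, om, tol = 1e-9)
  # glmnet gaussian: (1/2n) RSS + lambda * sum pf~_j |b_j| with pf rescaled
  # to sum to nvars; match scales exactly
  gl <- glmnet::glmnet(d$Z2[pos, -1], d$x[pos], family = "gaussian",
                       penalty.factor = om, standardize = FALSE,
                       lambda = lam2 * sum(om) / (4 * 2 * npos), thresh = 1e-12)
  b_gl <- as.numeric(coef(gl))
  expect_lt(abs(normal_pen_objective(f2$beta2, d, lam2, om) -
                normal_pen_objective(b_gl, d, lam2, om)), 1e-4)
})
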