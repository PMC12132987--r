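# Independent oracles used across the test files.

# central-difference gradient
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# central-difference Hessian
num_hess <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in seq_len(j)) {
    ej <- numeric(p); ej[j] <- h
    ek <- numeric(p); ek[k] <- h
    H[j, k] <- H[k, j] <-
      (f(x + ej + ek) - f(x + ej - ek) - f(x - ej + ek) + f(x - ej - ek)) / (4 * h^2)
  }
  H
}

# Proximal-gradient (ISTA with backtracking) solver for
#   min_beta  g(beta) + lambda * sum_j pf_j |beta_j|
# with smooth part g supplied with its gradient. Independent of the
# coordinate-descent implementation under test.
ista_solve <- function(g, grad_g, beta0, lambda, pf, max_iter = 20000,
                       tol = 1e-10) {
  beta <- beta0
  L <- 1
  obj_old <- g(beta) + lambda * sum(pf * abs(beta))
  for (it in seq_len(max_iter)) {
    gr <- grad_g(beta)
    repeat {
      cand <- sign(beta - gr / L) * pmax(abs(beta - gr / L) - lambda * pf / L, 0)
      # backtracking: majorization condition
      dv <- cand - beta
      if (g(cand) <= g(beta) + sum(gr * dv) + L / 2 * sum(dv^2) + 1e-14) break
      L <- L * 2
    }
    obj <- g(cand) + lambda * sum(pf * abs(cand))
    if (abs(obj_old - obj) < tol * (abs(obj_old) + 1)) {
      beta <- cand
      break
    }
    beta <- cand
    obj_old <- obj
    L <- L / 1.5  # allow the step to grow again
  }
  beta
}

# penalized positive-row least squares: objective and ISTA solution
normal_pen_objective <- function(beta2, data, lambda2, omega2) {
  pos <- data$y == 1
  r <- data$x[pos] - drop(data$Z2[pos, , drop = FALSE] %*% beta2)
  sum(r^2) + lambda2 * sum(omega2 * abs(beta2[-1]))
}

ista_normal <- function(data, lambda2, omega2) {
  pos <- data$y == 1
  Z <- data$Z2[pos, , drop = FALSE]
  xp <- data$x[pos]
  g <- function(b) sum((xp - drop(Z %*% b))^2)
  grad_g <- function(b) -2 * drop(crossprod(Z, xp - drop(Z %*% b)))
  ista_solve(g, grad_g, numeric(ncol(Z)), lambda2, c(0, omega2))
}

# penalized logistic (doubled scale): objective and ISTA solution
logistic_pen_objective <- function(beta1, data, lambda1, omega1) {
  eta <- drop(data$Z1 %*% beta1)
  2 * sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - data$y * eta) +
    lambda1 * sum(omega1 * abs(beta1[-1]))
}

ista_logistic <- function(data, lambda1, omega1) {
  Z <- data$Z1
  y <- data$y
  g <- function(b) {
    eta <- drop(Z %*% b)
    2 * sum(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) - y * eta)
  }
  grad_g <- function(b) -2 * drop(crossprod(Z, y - plogis(drop(Z %*% b))))
  ista_solve(g, grad_g, numeric(ncol(Z)), lambda1, c(0, omega1))
}

# small random semicontinuous dataset for property tests
random_bnt_data <- function(n = 40, q = 3, seed = NULL, rho = 0,
                            beta1 = NULL, beta2 = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(beta1)) beta1 <- c(0.3, stats::rnorm(q, 0, 0.8))
  if (is.null(beta2)) beta2 <- c(0.2, stats::rnorm(q, 0, 0.8))
  Z <- if (rho == 0) matrix(stats::rnorm(n * q), n, q) else
    simulate_covariates(n, q, rho)
  repeat {
    d <- simulate_bnt_data(Z = Z, beta1 = beta1, beta2 = beta2, sigma = 1)
    if (sum(d$y) >= q + 2 && sum(1 - d$y) >= 2) return(d)
  }
}
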