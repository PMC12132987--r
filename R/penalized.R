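# Lasso / adaptive-Lasso penalized estimation of the two parts. The
# continuous part minimizes
#   sum_{y=1} (x_i - z2_i' beta2)^2 + lambda2 * sum_s omega2_s |beta2_s|
# by cyclic coordinate descent with soft-thresholding; the binomial part
# minimizes the penalized negative log-likelihood (on the doubled working
# scale, matching the weighted least-squares quadratic)
#   2 * [-l1(beta1)] + lambda1 * sum_j omega1_j |beta1_j|
# by a nested loop: an outer IRLS quadratic approximation (work response
# gamma_i, weights w_i = p_i(1-p_i)) and an inner coordinate descent on the
# penalized weighted least squares. Intercepts and sigma are never penalized.
# The heavy loops live in src/cd_solvers.cpp; the single-coordinate updates
# are also exposed in R for testing and teaching.

#' Soft-thresholding operator
#'
#' `S(a, b) = sign(a) * max(|a| - b, 0)`, the one-dimensional lasso solution.
#' Vectorized in `a`.
#'
#' @param a Numeric vector.
#' @param b Non-negative threshold.
#' @return `sign(a) * pmax(abs(a) - b, 0)`.
#' @examples
#' soft_threshold(3, 1)   #  2
#' soft_threshold(-3, 1)  # -2
#' soft_threshold(1, 2)   #  0
#' @export
soft_threshold <- function(a, b) {
  if (any(b < 0)) stop("threshold b must be >= 0", call. = FALSE)
  sign(a) * pmax(abs(a) - b, 0)
}

# weights w_i are clamped below to keep the quadratic well conditioned at
# extreme fitted probabilities
W_MIN <- 1e-5

#' IRLS quadratic approximation of the binomial log-likelihood
#'
#' Second-order expansion of `l1(beta1)` at `beta1_old`: work response
#' `gamma_i = eta_i + (y_i - p_i) / w_i` and weight `w_i = p_i (1 - p_i)`
#' (clamped below at 1e-5), so that maximizing the quadratic is the weighted
#' least-squares problem `min sum_i w_i (gamma_i - z1_i' beta1)^2`.
#'
#' @param beta1_old Expansion point, length `q1 + 1`.
#' @param data A [bnt_data()] object.
#' @return A list of class `"irls_state"` with `gamma`, `w`, `p` and
#'   `beta1_old`.
#' @export
irls_quadratic <- function(beta1_old, data) {
  check_beta_dim(beta1_old, data$Z1, "binomial-part")
  eta <- clamp_eta(drop(data$Z1 %*% beta1_old))
  p <- plogis(eta)
  w <- pmax(p * (1 - p), W_MIN)
  structure(list(gamma = eta + (data$y - p) / w, w = w, p = p,
                 beta1_old = beta1_old),
            class = "irls_state")
}

#' Single coordinate-descent update, continuous part
#'
#' The minimizer of the penalized positive-row least squares in coordinate
#' `k`, holding the other coordinates fixed:
#' `S(2 * sum I(y=1) z_k * r_partial, lambda2 * omega2k) / (2 * sum I(y=1) z_k^2)`
#' where `r_partial` is the residual excluding coordinate `k`. The intercept
#' (`k = 1`) is updated with a zero penalty.
#'
#' @param k Column index into `beta2` (1 = intercept).
#' @param beta2 Current coefficient vector.
#' @param data A [bnt_data()] object.
#' @param lambda2 Non-negative penalty level.
#' @param omega2k Positive penalty weight for coordinate `k` (ignored for the
#'   intercept).
#' @return The updated value of `beta2[k]`.
#' @export
cd_update_normal <- function(k, beta2, data, lambda2, omega2k = 1) {
  check_beta_dim(beta2, data$Z2, "continuous-part")
  pos <- data$y == 1
  Z <- data$Z2[pos, , drop = FALSE]
  zk <- Z[, k]
  den <- 2 * sum(zk^2)
  if (den <= 0) {
    stop(sprintf("degenerate covariate: column %d of Z2 is identically zero on the positive rows", k),
         call. = FALSE)
  }
  r_partial <- data$x[pos] - drop(Z[, -k, drop = FALSE] %*% beta2[-k])
  pen <- if (k == 1) 0 else lambda2 * omega2k
  soft_threshold(2 * sum(zk * r_partial), pen) / den
}

#' Single coordinate-descent update, binomial part
#'
#' The minimizer of the penalized weighted least squares (IRLS quadratic) in
#' coordinate `k`:
#' `S(2 * sum w_i z_k (gamma_i - partial fit), lambda1 * omega1k) / (2 * sum w_i z_k^2)`.
#' The denominator carries the IRLS weights `w_i` (the true curvature of the
#' quadratic in coordinate `k`). The intercept (`k = 1`) is unpenalized.
#'
#' @param k Column index into `beta1` (1 = intercept).
#' @param beta1 Current coefficient vector.
#' @param state An [irls_quadratic()] state.
#' @param data A [bnt_data()] object.
#' @param lambda1 Non-negative penalty level.
#' @param omega1k Positive penalty weight for coordinate `k`.
#' @return The updated value of `beta1[k]`.
#' @export
cd_update_logistic <- function(k, beta1, state, data, lambda1, omega1k = 1) {
  check_beta_dim(beta1, data$Z1, "binomial-part")
  zk <- data$Z1[, k]
  den <- 2 * sum(state$w * zk^2)
  if (den <= 0) {
    stop(sprintf("degenerate covariate: column %d of Z1 has zero weighted norm", k),
         call. = FALSE)
  }
  r_partial <- state$gamma - drop(data$Z1[, -k, drop = FALSE] %*% beta1[-k])
  pen <- if (k == 1) 0 else lambda1 * omega1k
  soft_threshold(2 * sum(state$w * zk * r_partial), pen) / den
}

active_set <- function(beta) which(beta[-1] != 0)

#' Penalized fit of the continuous part by coordinate descent
#'
#' Solves `min sum_{y=1} (x - z2' beta2)^2 + lambda2 sum_s omega2_s |beta2_s|`
#' by cyclic coordinate descent (intercept unpenalized), then computes the ML
#' scale from the residuals of the penalized solution (sigma itself is never
#' penalized).
#'
#' @param data A [bnt_data()] object with at least one positive row.
#' @param lambda2 Non-negative penalty level.
#' @param omega2 Positive penalty weights, length `q2` (default all 1 =
#'   plain Lasso).
#' @param tol Convergence tolerance on the max coordinate change per sweep.
#' @param max_iter Maximum number of full sweeps.
#' @param beta_init Optional warm start, length `q2 + 1`.
#' @return A list with `beta2`, `sigma`, `active_set` (indices of nonzero
#'   non-intercept coefficients, counted within `1..q2`), `n_iter`,
#'   `converged`.
#' @export
fit_cd_normal <- function(data, lambda2, omega2 = rep(1, data$q2),
                          tol = 1e-7, max_iter = 10000, beta_init = NULL) {
  if (lambda2 < 0) stop("lambda2 must be >= 0", call. = FALSE)
  if (length(omega2) != data$q2 || any(omega2 <= 0)) {
    stop("omega2 must be a positive vector of length q2", call. = FALSE)
  }
  pos <- data$y == 1
  if (!any(pos)) stop("no positive rows: continuous part cannot be fitted", call. = FALSE)
  Z <- data$Z2[pos, , drop = FALSE]
  xp <- data$x[pos]
  css <- colSums(Z^2)
  if (any(css <= 0)) {
    stop(sprintf("degenerate covariate: column %d of Z2 is identically zero on the positive rows",
                 which(css <= 0)[1]), call. = FALSE)
  }
  if (is.null(beta_init)) beta_init <- numeric(ncol(Z))
  res <- cd_wls_lasso_cpp(Z, xp, rep(1, nrow(Z)), beta_init, lambda2,
                          c(0, omega2), tol, max_iter)
  if (!res$converged) {
    stop(sprintf("continuous-part coordinate descent did not converge in %d sweeps",
                 max_iter), call. = FALSE)
  }
  beta2 <- res$beta
  r <- xp - drop(Z %*% beta2)
  list(beta2 = beta2, sigma = sqrt(mean(r^2)), active_set = active_set(beta2),
       n_iter = res$n_iter, converged = res$converged)
}

#' Penalized fit of the binomial part by IRLS + coordinate descent
#'
#' Solves `min 2*[-l1(beta1)] + lambda1 sum_j omega1_j |beta1_j|` by the
#' nested loop: external IRLS quadratic approximation, internal cyclic
#' coordinate descent on the penalized weighted least squares, with a
#' step-halving safeguard that keeps the penalized objective non-increasing.
#'
#' @param data A [bnt_data()] object with both outcome classes present.
#' @param lambda1 Non-negative penalty level.
#' @param omega1 Positive penalty weights, length `q1` (default all 1).
#' @param tol_outer Convergence tolerance on the max coefficient change
#'   between outer (IRLS) iterations.
#' @param max_outer Maximum outer iterations.
#' @param tol_inner Convergence tolerance of the inner coordinate descent.
#' @param max_inner Maximum inner sweeps per outer iteration.
#' @param beta_init Optional warm start, length `q1 + 1`.
#' @return A list with `beta1`, `active_set`, `n_outer`, `n_inner`,
#'   `converged`, `objective` (the final penalized objective on the doubled
#'   scale).
#' @export
fit_cd_logistic <- function(data, lambda1, omega1 = rep(1, data$q1),
                            tol_outer = 1e-6, max_outer = 50,
                            tol_inner = 1e-7, max_inner = 10000,
                            beta_init = NULL) {
  if (lambda1 < 0) stop("lambda1 must be >= 0", call. = FALSE)
  if (length(omega1) != data$q1 || any(omega1 <= 0)) {
    stop("omega1 must be a positive vector of length q1", call. = FALSE)
  }
  check_both_classes(data)
  if (is.null(beta_init)) beta_init <- numeric(ncol(data$Z1))
  res <- cd_logistic_lasso_cpp(data$Z1, data$y, beta_init, lambda1,
                               c(0, omega1), tol_outer, max_outer,
                               tol_inner, max_inner, W_MIN)
  if (!res$converged) {
    stop(sprintf("binomial-part coordinate descent did not converge in %d outer iterations",
                 max_outer), call. = FALSE)
  }
  beta1 <- res$beta
  pi <- plogis(clamp_eta(drop(data$Z1 %*% beta1)))
  if (any(pmin(pi, 1 - pi) < 1e-8) && sqrt(sum(beta1^2)) > 10) {
    warning("fitted probabilities numerically 0 or 1 in the penalized binomial part: ",
            "quasi-separation suspected", call. = FALSE)
  }
  list(beta1 = beta1, active_set = active_set(beta1),
       n_outer = res$n_outer, n_inner = res$n_inner,
       converged = res$converged, objective = res$objective)
}

#' Adaptive-Lasso penalty weights from the unpenalized MLE
#'
#' `omega_j = 1 / |beta_hat_j,ml|` for each non-intercept coefficient (the
#' oracle-motivated choice with exponent gamma = 1), capped at `cap` when the
#' MLE component is numerically zero.
#'
#' @param data A [bnt_data()] object.
#' @param cap Upper cap on a weight (default 1e6, reached when
#'   `|beta_hat| < 1e-6`).
#' @return A list with positive weight vectors `omega1` (length `q1`),
#'   `omega2` (length `q2`) and the underlying `mle` fits.
#' @export
adaptive_weights <- function(data, cap = 1e6) {
  fb <- fit_mle_binomial(data)
  fc <- fit_mle_continuous(data)
  list(omega1 = pmin(1 / abs(fb$beta1[-1]), cap),
       omega2 = pmin(1 / abs(fc$beta2[-1]), cap),
       mle = list(beta1 = fb$beta1, beta2 = fc$beta2, sigma = fc$sigma))
}

#' Smallest penalty levels with an empty model
#'
#' `lambda_max` per part: the smallest penalty for which every penalized
#' (non-intercept) coefficient is zero. For the continuous part this is
#' `max_j |2 sum_{y=1} z_j (x - xbar_+)| / omega_j`; for the binomial part it
#' is evaluated at the intercept-only fit, `max_j |2 sum_i z_j (y - ybar)| / omega_j`.
#'
#' @param data A [bnt_data()] object.
#' @param omega1,omega2 Penalty weight vectors (default all 1).
#' @return A list with `lambda1_max` and `lambda2_max`.
#' @export
lambda_max_bnt <- function(data, omega1 = rep(1, data$q1),
                           omega2 = rep(1, data$q2)) {
  pos <- data$y == 1
  Zp <- data$Z2[pos, -1, drop = FALSE]
  rp <- data$x[pos] - mean(data$x[pos])
  l2 <- if (data$q2 > 0) max(abs(2 * drop(crossprod(Zp, rp))) / omega2) else 0
  r1 <- data$y - mean(data$y)
  l1 <- if (data$q1 > 0) max(abs(2 * drop(crossprod(data$Z1[, -1, drop = FALSE], r1))) / omega1) else 0
  list(lambda1_max = l1, lambda2_max = l2)
}

# descending log-spaced grid from lambda_max to ratio * lambda_max
lambda_grid <- function(lambda_max, nlambda = 100, lambda_min_ratio = 1e-3) {
  if (lambda_max <= 0) return(rep(0, nlambda))
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio), length.out = nlambda))
}

# Warm-started coefficient path for one part, computed entirely in compiled
# code. Returns a (nlambda x p) matrix, one row per (descending) lambda.
path_part <- function(data, part = c("binomial", "continuous"), lambdas,
                      omega, tol_outer = 1e-6, max_outer = 50,
                      tol_inner = 1e-7, max_inner = 10000) {
  part <- match.arg(part)
  if (part == "binomial") {
    cd_logistic_lasso_path_cpp(data$Z1, data$y, lambdas, c(0, omega),
                               tol_outer, max_outer, tol_inner, max_inner,
                               W_MIN)
  } else {
    pos <- data$y == 1
    Z <- data$Z2[pos, , drop = FALSE]
    cd_wls_lasso_path_cpp(Z, data$x[pos], rep(1, nrow(Z)), lambdas,
                          c(0, omega), tol_inner, max_inner)
  }
}

#' Lasso / adaptive-Lasso penalized fit of the two-part model
#'
#' Fits both parts at fixed penalty levels. The two sub-problems are
#' independent: `lambda1` only affects the binomial part and `lambda2` only
#' the continuous part. For `penalty = "alasso"` the weights default to
#' `1/|beta_hat_ml|` computed by [adaptive_weights()]; for `penalty = "lasso"`
#' all weights are 1.
#'
#' @param object A model formula (`x ~ z1 + z2` or `x ~ a + b | c + d` for
#'   part-specific covariates) or a [bnt_data()] object.
#' @param data A data frame (when `object` is a formula).
#' @param penalty `"lasso"` or `"alasso"`.
#' @param lambda1,lambda2 Non-negative penalty levels for the binomial and
#'   continuous parts.
#' @param omega1,omega2 Optional penalty weight vectors overriding the
#'   defaults.
#' @param log_positives Passed to [bnt_data()] when `object` is a formula.
#' @param ... Further arguments passed to [fit_cd_logistic()] and
#'   [fit_cd_normal()] (tolerances, iteration caps).
#' @return An object of class `c("bnt_pen", "bnt")`; see [bnt()] for the
#'   shared fields. Adds `penalty`, `lambda1`, `lambda2`, `omega1`, `omega2`,
#'   `active1`, `active2` and convergence counters.
#' @examples
#' d <- simulate_bnt_data(bnt_scenario("s1", n = 200), seed = 1)
#' fit <- bnt_penalized(d, penalty = "lasso", lambda1 = 20, lambda2 = 20)
#' fit$active1
#' @export
bnt_penalized <- function(object, data = NULL, penalty = c("lasso", "alasso"),
                          lambda1 = 0, lambda2 = 0, omega1 = NULL,
                          omega2 = NULL, log_positives = FALSE, ...) {
  penalty <- match.arg(penalty)
  inp <- resolve_bnt_input(object, data, log_positives)
  d <- inp$data
  check_both_classes(d)
  if (penalty == "alasso" && (is.null(omega1) || is.null(omega2))) {
    w <- adaptive_weights(d)
    if (is.null(omega1)) omega1 <- w$omega1
    if (is.null(omega2)) omega2 <- w$omega2
  }
  if (is.null(omega1)) omega1 <- rep(1, d$q1)
  if (is.null(omega2)) omega2 <- rep(1, d$q2)
  f1 <- fit_cd_logistic(d, lambda1, omega1, ...)
  f2 <- fit_cd_normal(d, lambda2, omega2, ...)
  out <- new_bnt(beta1 = f1$beta1, beta2 = f2$beta2, sigma = f2$sigma,
                 data = d, formula1 = inp$formula1, formula2 = inp$formula2,
                 call = match.call())
  out$method <- penalty
  out$penalty <- penalty
  out$lambda1 <- lambda1
  out$lambda2 <- lambda2
  out$omega1 <- omega1
  out$omega2 <- omega2
  out$active1 <- f1$active_set
  out$active2 <- f2$active_set
  out$n_outer <- f1$n_outer
  out$n_inner <- f1$n_inner + f2$n_iter
  out$converged <- f1$converged && f2$converged
  class(out) <- c("bnt_pen", "bnt")
  out
}
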