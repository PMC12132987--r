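# Unpenalized maximum likelihood for the two parts. The binomial part is
# fitted by Newton iteration beta <- beta + I(beta)^{-1} U(beta) with a
# step-halving safeguard; the continuous part has an exact solution (least
# squares on the positive rows, then the ML variance), which is what the
# Newton iteration on (beta2, sigma) converges to, so we use the closed form
# and record a short trace for API parity.

#' Score vector of the binomial part
#'
#' The gradient of [loglik_binomial()]: `U(beta1) = sum_i (y_i - pi_i) z1_i`.
#'
#' @inheritParams loglik_binomial
#' @return Numeric vector of length `q1 + 1`.
#' @export
score_binomial <- function(beta1, data) {
  check_beta_dim(beta1, data$Z1, "binomial-part")
  pi <- plogis(clamp_eta(drop(data$Z1 %*% beta1)))
  drop(crossprod(data$Z1, data$y - pi))
}

#' Observed information matrix of the binomial part
#'
#' `I(beta1) = sum_i pi_i (1 - pi_i) z1_i z1_i'`, the negative Hessian of
#' [loglik_binomial()]; symmetric positive semi-definite (it equals the Fisher
#' information for the logistic link).
#'
#' @inheritParams loglik_binomial
#' @return A `(q1+1) x (q1+1)` matrix.
#' @export
info_binomial <- function(beta1, data) {
  check_beta_dim(beta1, data$Z1, "binomial-part")
  pi <- plogis(clamp_eta(drop(data$Z1 %*% beta1)))
  w <- pi * (1 - pi)
  crossprod(data$Z1 * w, data$Z1)
}

#' Score vector of the continuous part
#'
#' Concatenated gradient of [loglik_continuous()] in `(beta2, sigma)`:
#' `U_beta2 = sum_{y=1} (x - mu) z2 / sigma^2` and
#' `U_sigma = sum_{y=1} ((x - mu)^2 - sigma^2) / sigma^3`.
#'
#' @inheritParams loglik_continuous
#' @return Numeric vector of length `q2 + 2` (the last entry is the sigma
#'   component).
#' @export
score_continuous <- function(beta2, sigma, data) {
  check_beta_dim(beta2, data$Z2, "continuous-part")
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  pos <- data$y == 1
  Z <- data$Z2[pos, , drop = FALSE]
  r <- data$x[pos] - drop(Z %*% beta2)
  c(drop(crossprod(Z, r)) / sigma^2, sum(r^2 - sigma^2) / sigma^3)
}

#' Observed information matrix of the continuous part
#'
#' The negative Hessian of [loglik_continuous()] in `(beta2, sigma)`, with
#' blocks `sum I(y=1) z z'/sigma^2`, cross block `sum I(y=1) 2 r z / sigma^3`
#' and sigma-sigma entry `sum I(y=1) (3 r^2/sigma^4 - 1/sigma^2)`, where `r`
#' is the residual.
#'
#' @inheritParams loglik_continuous
#' @return A `(q2+2) x (q2+2)` symmetric matrix.
#' @export
info_continuous <- function(beta2, sigma, data) {
  check_beta_dim(beta2, data$Z2, "continuous-part")
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  pos <- data$y == 1
  if (!any(pos)) stop("no positive rows: continuous-part information undefined",
                      call. = FALSE)
  Z <- data$Z2[pos, , drop = FALSE]
  r <- data$x[pos] - drop(Z %*% beta2)
  bb <- crossprod(Z) / sigma^2
  bs <- drop(crossprod(Z, 2 * r)) / sigma^3
  ss <- sum(3 * r^2 / sigma^4 - 1 / sigma^2)
  rbind(cbind(bb, bs), c(bs, ss))
}

new_newton_trace <- function(iterates, loglik_values, converged) {
  structure(list(iterates = iterates, loglik_values = loglik_values,
                 converged = converged, n_iter = length(loglik_values) - 1L),
            class = "newton_trace")
}

#' Maximum-likelihood fit of the binomial part by Newton iteration
#'
#' Iterates `beta <- beta + solve(I(beta), U(beta))` from zero, halving the
#' step (up to 20 times) whenever the log-likelihood would decrease, until the
#' max-norm of the update falls below `tol`.
#'
#' @param data A [bnt_data()] object with both outcome classes present.
#' @param tol Convergence tolerance on the max-norm of the Newton update.
#' @param max_iter Maximum number of Newton iterations.
#' @return A list with `beta1` (the MLE) and `trace` (a `newton_trace` with
#'   iterates, log-likelihood values, convergence flag).
#' @export
fit_mle_binomial <- function(data, tol = 1e-8, max_iter = 100) {
  check_both_classes(data)
  p <- ncol(data$Z1)
  if (qr(data$Z1)$rank < p) {
    stop("binomial-part design matrix is rank deficient", call. = FALSE)
  }
  beta <- numeric(p)
  ll <- loglik_binomial(beta, data)
  iterates <- list(beta)
  lls <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- score_binomial(beta, data)
    I <- info_binomial(beta, data)
    step <- tryCatch(solve(I, U), error = function(e) {
      stop("singular information matrix in binomial-part Newton iteration",
           call. = FALSE)
    })
    # step halving: never accept a likelihood decrease
    s <- 1
    repeat {
      cand <- beta + s * step
      llc <- loglik_binomial(cand, data)
      if (llc >= ll - 1e-12 || s < 2^-20) break
      s <- s / 2
    }
    beta <- cand
    ll <- llc
    iterates[[length(iterates) + 1L]] <- beta
    lls <- c(lls, ll)
    if (max(abs(s * step)) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    cond <- structure(
      list(message = sprintf(
             "binomial-part Newton iteration did not converge in %d iterations",
             max_iter),
           call = sys.call(-1),
           trace = new_newton_trace(do.call(rbind, iterates), lls, FALSE)),
      class = c("bnt_no_convergence", "error", "condition"))
    stop(cond)
  }
  pi <- plogis(clamp_eta(drop(data$Z1 %*% beta)))
  if (any(pmin(pi, 1 - pi) < 1e-8) && sqrt(sum(beta^2)) > 10) {
    warning("fitted probabilities numerically 0 or 1: quasi-separation suspected; ",
            "estimates clamped at the current iterate", call. = FALSE)
  }
  list(beta1 = beta, trace = new_newton_trace(do.call(rbind, iterates), lls, TRUE))
}

#' Maximum-likelihood fit of the continuous part
#'
#' The positive-part normal regression has an exact maximizer: `beta2` is the
#' least-squares solution on the positive rows and `sigma^2` is the mean
#' squared residual (ML, divisor `n+`). A short trace is recorded for API
#' parity with the binomial part.
#'
#' @param data A [bnt_data()] object with at least `q2 + 2` positive rows.
#' @param tol Tolerance used to stamp the trace convergence flag (the solution
#'   is exact).
#' @param max_iter Unused; kept for interface symmetry.
#' @return A list with `beta2`, `sigma` and `trace`.
#' @export
fit_mle_continuous <- function(data, tol = 1e-8, max_iter = 100) {
  pos <- data$y == 1
  npos <- sum(pos)
  p <- ncol(data$Z2)
  if (npos < p + 1) {
    stop(sprintf("too few positive rows (%d) for %d continuous-part parameters",
                 npos, p + 1L), call. = FALSE)
  }
  Z <- data$Z2[pos, , drop = FALSE]
  if (qr(Z)$rank < p) {
    stop("continuous-part design matrix is rank deficient on the positive rows",
         call. = FALSE)
  }
  xp <- data$x[pos]
  fit <- lm.fit(Z, xp)
  beta2 <- fit$coefficients
  sigma <- sqrt(mean(fit$residuals^2))
  ll0 <- loglik_continuous(numeric(p), 1, data)
  ll1 <- loglik_continuous(beta2, sigma, data)
  trace <- new_newton_trace(rbind(c(numeric(p), 1), c(beta2, sigma)),
                            c(ll0, ll1), TRUE)
  list(beta2 = unname(beta2), sigma = sigma, trace = trace)
}
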