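# Log-likelihood of the Bernoulli-Normal two-part model. The joint
# log-likelihood factorizes as l(theta) = l1(beta1) + l2(beta2, sigma):
#   l1(beta1)        = sum_i { y_i eta1_i - ln(1 + exp(eta1_i)) }
#   l2(beta2, sigma) = sum_{i: y_i = 1} { -(x_i - mu_i)^2 / (2 sigma^2)
#                                          - ln(sigma) - ln(2 pi) / 2 }
# with eta1_i = z1_i' beta1 (logit of the mixing proportion) and
# mu_i = z2_i' beta2 (conditional mean of the positive part).

ETA_CLAMP <- 30

clamp_eta <- function(eta) pmin(pmax(eta, -ETA_CLAMP), ETA_CLAMP)

# stable log(1 + exp(eta))
log1pexp <- function(eta) ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))

check_beta_dim <- function(beta, Z, part) {
  if (length(beta) != ncol(Z)) {
    stop(sprintf("%s coefficient length %d does not match design matrix with %d columns",
                 part, length(beta), ncol(Z)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Log-likelihood of the binomial (zero/nonzero) part
#'
#' Computes `l1(beta1) = sum_i { y_i * eta_i - ln(1 + exp(eta_i)) }` with
#' `eta_i = z1_i' beta1`. Linear predictors are clamped at `|eta| = 30` before
#' exponentiation; beyond that the mixing proportion differs from 0/1 by less
#' than 1e-13, so the clamp is numerically inert.
#'
#' @param beta1 Coefficient vector of length `q1 + 1` (intercept first).
#' @param data A [bnt_data()] object.
#' @return The scalar log-likelihood of the binomial part.
#' @export
loglik_binomial <- function(beta1, data) {
  check_beta_dim(beta1, data$Z1, "binomial-part")
  eta <- clamp_eta(drop(data$Z1 %*% beta1))
  sum(data$y * eta - log1pexp(eta))
}

#' Log-likelihood of the continuous (positive) part
#'
#' Computes the normal log-likelihood over the positive rows only:
#' `l2(beta2, sigma) = sum_{y_i = 1} { -(x_i - mu_i)^2/(2 sigma^2) - ln sigma
#' - ln(2 pi)/2 }`. Rows with a zero outcome contribute exactly 0.
#'
#' @param beta2 Coefficient vector of length `q2 + 1` (intercept first).
#' @param sigma Positive scale of the continuous part.
#' @param data A [bnt_data()] object.
#' @return The scalar log-likelihood of the continuous part.
#' @export
loglik_continuous <- function(beta2, sigma, data) {
  check_beta_dim(beta2, data$Z2, "continuous-part")
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  pos <- data$y == 1
  if (!any(pos)) return(0)
  r <- data$x[pos] - drop(data$Z2[pos, , drop = FALSE] %*% beta2)
  sum(-r^2 / (2 * sigma^2) - log(sigma) - 0.5 * log(2 * pi))
}

#' Total log-likelihood of the two-part model
#'
#' The joint log-likelihood is exactly the sum of the binomial and continuous
#' part log-likelihoods; the two parts share no parameters.
#'
#' @param params A list with elements `beta1`, `beta2`, `sigma` (see
#'   [bnt()] for the fitted version).
#' @param data A [bnt_data()] object.
#' @return The scalar total log-likelihood.
#' @export
loglik_bnt <- function(params, data) {
  loglik_binomial(params$beta1, data) +
    loglik_continuous(params$beta2, params$sigma, data)
}

#' Expected semicontinuous outcome
#'
#' The standard two-part predictor `x_hat_i = pi_i * mu_i`: the probability of
#' a nonzero outcome times the conditional mean of the positive part.
#'
#' @param params A list with elements `beta1`, `beta2` (a `sigma` element is
#'   allowed and ignored).
#' @param Z1,Z2 Design matrices (intercept column first) with equal row counts.
#' @return Numeric vector of expected outcomes.
#' @export
predict_expected <- function(params, Z1, Z2) {
  Z1 <- as.matrix(Z1); Z2 <- as.matrix(Z2)
  if (nrow(Z1) != nrow(Z2)) {
    stop(sprintf("row mismatch: nrow(Z1) = %d, nrow(Z2) = %d", nrow(Z1), nrow(Z2)),
         call. = FALSE)
  }
  check_beta_dim(params$beta1, Z1, "binomial-part")
  check_beta_dim(params$beta2, Z2, "continuous-part")
  pi <- plogis(clamp_eta(drop(Z1 %*% params$beta1)))
  mu <- drop(Z2 %*% params$beta2)
  pi * mu
}
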