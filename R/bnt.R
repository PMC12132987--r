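# User-facing model fitting front end and S3 methods.

new_bnt <- function(beta1, beta2, sigma, data, formula1 = NULL, formula2 = NULL,
                    call = NULL, trace1 = NULL, trace2 = NULL) {
  default_nm <- function(p) c("(Intercept)",
                              if (p > 1) paste0("z", seq_len(p - 1)) else character(0))
  nm1 <- colnames(data$Z1)
  nm2 <- colnames(data$Z2)
  names(beta1) <- if (is.null(nm1)) default_nm(length(beta1)) else nm1
  names(beta2) <- if (is.null(nm2)) default_nm(length(beta2)) else nm2
  structure(
    list(beta1 = beta1, beta2 = beta2, sigma = sigma,
         loglik = c(binomial = loglik_binomial(beta1, data),
                    continuous = loglik_continuous(beta2, sigma, data)),
         data = data, formula1 = formula1, formula2 = formula2,
         trace1 = trace1, trace2 = trace2, method = "mle", call = call),
    class = "bnt")
}

#' Fit a Bernoulli-Normal two-part regression model by maximum likelihood
#'
#' The model is `f(x_i) = (1 - pi_i)^(1-y_i) * [pi_i N(x_i; mu_i, sigma^2)]^(y_i)`
#' with `y_i = I(x_i > 0)`, `logit(pi_i) = z1_i' beta1` and
#' `mu_i = z2_i' beta2`. The log-likelihood separates into a logistic part for
#' `beta1` (maximized by Newton iteration with step-halving) and a normal part
#' for `(beta2, sigma)` (maximized exactly by least squares on the positive
#' rows with the ML variance).
#'
#' @param object A model formula (`x ~ z1 + z2`, or `x ~ a + b | c + d` to
#'   give the two parts different covariates) or a [bnt_data()] object.
#' @param data A data frame (when `object` is a formula).
#' @param log_positives Logical; log-transform the positive outcomes at load
#'   (see [bnt_data()]).
#' @param tol,max_iter Newton convergence controls for the binomial part.
#' @return An object of class `"bnt"`: a list with coefficient vectors
#'   `beta1`, `beta2`, scale `sigma`, per-part `loglik`, the `data`, Newton
#'   `trace1`/`trace2`, and the matched `call`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `logLik`, `sigma`, `simulate`.
#' @examples
#' d <- simulate_bnt_data(bnt_scenario("s1", n = 300), seed = 1)
#' fit <- bnt(d)
#' coef(fit, part = "binomial")
#' @export
bnt <- function(object, data = NULL, log_positives = FALSE,
                tol = 1e-8, max_iter = 100) {
  inp <- resolve_bnt_input(object, data, log_positives)
  d <- inp$data
  check_both_classes(d)
  fb <- fit_mle_binomial(d, tol = tol, max_iter = max_iter)
  fc <- fit_mle_continuous(d, tol = tol, max_iter = max_iter)
  new_bnt(beta1 = fb$beta1, beta2 = fc$beta2, sigma = fc$sigma, data = d,
          formula1 = inp$formula1, formula2 = inp$formula2,
          call = match.call(), trace1 = fb$trace, trace2 = fc$trace)
}

n_parameters <- function(object) {
  if (inherits(object, "bnt_pen")) {
    # post-selection count: intercepts + active coefficients + sigma
    length(object$active1) + length(object$active2) + 3L
  } else {
    length(object$beta1) + length(object$beta2) + 1L
  }
}

#' @export
print.bnt <- function(x, digits = 4, ...) {
  cat("Bernoulli-Normal two-part regression",
      if (inherits(x, "bnt_pen")) sprintf("(%s penalty)", x$penalty) else "(maximum likelihood)",
      "\n")
  cat(sprintf("n = %d (%d zero / %d positive)\n",
              x$data$n, sum(x$data$y == 0), sum(x$data$y == 1)))
  cat("\nBinomial part (logit of Pr(X > 0)):\n")
  print(round(x$beta1, digits))
  cat("\nContinuous part (mean of positive outcomes):\n")
  print(round(x$beta2, digits))
  cat(sprintf("\nsigma = %.*f   log-likelihood = %.*f\n",
              digits, x$sigma, digits, sum(x$loglik)))
  if (inherits(x, "bnt_pen")) {
    cat(sprintf("lambda1 = %.4g, lambda2 = %.4g; active: %d of %d (binomial), %d of %d (continuous)\n",
                x$lambda1, x$lambda2, length(x$active1), x$data$q1,
                length(x$active2), x$data$q2))
  }
  invisible(x)
}

#' @export
summary.bnt <- function(object, ...) {
  ll <- sum(object$loglik)
  k <- n_parameters(object)
  out <- list(fit = object, loglik = object$loglik, k = k,
              aic = -2 * ll + 2 * k,
              bic = -2 * ll + k * log(object$data$n))
  class(out) <- "summary.bnt"
  out
}

#' @export
print.summary.bnt <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("\nk = %d parameters, AIC = %.*f, BIC = %.*f\n",
              x$k, digits, x$aic, digits, x$bic))
  invisible(x)
}

#' Extract coefficients from a two-part fit
#'
#' @param object A fitted [bnt()] / [bnt_penalized()] object.
#' @param part `"both"` (named concatenation with `bin_`/`con_` prefixes),
#'   `"binomial"` or `"continuous"`.
#' @param ... Unused.
#' @return A named numeric vector.
#' @export
coef.bnt <- function(object, part = c("both", "binomial", "continuous"), ...) {
  part <- match.arg(part)
  switch(part,
         binomial = object$beta1,
         continuous = object$beta2,
         both = c(stats::setNames(object$beta1, paste0("bin_", names(object$beta1))),
                  stats::setNames(object$beta2, paste0("con_", names(object$beta2)))))
}

#' @export
sigma.bnt <- function(object, ...) object$sigma

#' @export
logLik.bnt <- function(object, ...) {
  structure(sum(object$loglik), df = n_parameters(object),
            nobs = object$data$n, class = "logLik")
}

#' Predict from a two-part fit
#'
#' @param object A fitted [bnt()] / [bnt_penalized()] object.
#' @param newdata Optional data frame (formula fits) or list/`bnt_data` with
#'   elements `Z1`, `Z2`. Defaults to the training data.
#' @param type `"response"` for the expected outcome `pi * mu`, `"pi"` for
#'   the nonzero probability, `"mu"` for the conditional positive mean.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.bnt <- function(object, newdata = NULL,
                        type = c("response", "pi", "mu"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    Z1 <- object$data$Z1
    Z2 <- object$data$Z2
  } else if (is.list(newdata) && !is.null(newdata$Z1)) {
    Z1 <- as.matrix(newdata$Z1)
    Z2 <- as.matrix(if (is.null(newdata$Z2)) newdata$Z1 else newdata$Z2)
  } else if (!is.null(object$formula1)) {
    f1 <- stats::delete.response(stats::terms(object$formula1))
    Z1 <- stats::model.matrix(f1, stats::model.frame(f1, newdata))
    if (is.null(object$formula2)) {
      Z2 <- Z1
    } else {
      Z2 <- stats::model.matrix(object$formula2,
                                stats::model.frame(object$formula2, newdata))
    }
  } else {
    stop("newdata must carry Z1/Z2 design matrices for matrix-interface fits",
         call. = FALSE)
  }
  switch(type,
         pi = plogis(clamp_eta(drop(Z1 %*% object$beta1))),
         mu = drop(Z2 %*% object$beta2),
         response = predict_expected(object, Z1, Z2))
}

#' @export
fitted.bnt <- function(object, ...) predict(object, type = "response")

#' Residuals of a two-part fit
#'
#' `"response"` residuals are `x - pi_hat * mu_hat` over all rows;
#' `"binomial"` residuals are `y - pi_hat`; `"continuous"` residuals are
#' `x - mu_hat` on the positive rows only.
#'
#' @param object A fitted [bnt()] object.
#' @param type One of `"response"`, `"binomial"`, `"continuous"`.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
residuals.bnt <- function(object, type = c("response", "binomial", "continuous"),
                          ...) {
  type <- match.arg(type)
  d <- object$data
  switch(type,
         response = d$x - predict(object, type = "response"),
         binomial = d$y - predict(object, type = "pi"),
         continuous = {
           pos <- d$y == 1
           d$x[pos] - predict(object, type = "mu")[pos]
         })
}

#' Simulate semicontinuous outcomes from a fitted two-part model
#'
#' Draws `y_i ~ Bernoulli(pi_hat_i)` and, where `y_i = 1`, a
#' `Normal(mu_hat_i, sigma_hat)` positive part, on the training design.
#'
#' @param object A fitted [bnt()] object.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional seed for a private RNG stream.
#' @param ... Unused.
#' @return A data frame with `nsim` columns, each a simulated outcome vector
#'   of length `n`.
#' @export
simulate.bnt <- function(object, nsim = 1, seed = NULL, ...) {
  pi <- predict(object, type = "pi")
  mu <- predict(object, type = "mu")
  n <- length(pi)
  sims <- with_seed(seed, {
    replicate(nsim, {
      y <- rbinom(n, 1, pi)
      ifelse(y == 1, rnorm(n, mu, object$sigma), 0)
    })
  })
  as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
}
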