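# Model-comparison reporting and the normality precheck used before fitting
# a normal positive part to real data.

#' Fit-quality report: -2LogLik, AIC, BIC and cross-validated error
#'
#' For each part and their combination, reports `-2 * loglik`,
#' `AIC = -2 l + 2 k` and `BIC = -2 l + k ln(n_eff)`, where `k` counts the
#' nonzero coefficients of the (possibly penalized) fit -- intercepts always,
#' plus one for `sigma` in the continuous part -- and `n_eff` is `n` for the
#' binomial part and the number of positive rows for the continuous part
#' (their sum for the combined row). `ME` is the K-fold cross-validated
#' prediction error of the selected model: the active set is refitted
#' unpenalized on each training split and scored on the held-out rows with
#' the same part conventions as the MPSE ((y - pi)^2 binomial, (x - mu)^2 on
#' positive rows, (x - pi mu)^2 combined).
#'
#' @param fit A fitted [bnt()] / [bnt_penalized()] object.
#' @param K Folds for the ME computation (default 10).
#' @param seed Fold seed.
#' @return A data frame with rows `binomial`, `normal`, `two_parts` and
#'   columns `neg2loglik`, `k`, `AIC`, `BIC`, `ME`.
#' @export
bnt_report <- function(fit, K = 10, seed = NULL) {
  d <- fit$data
  npos <- sum(d$y == 1)
  if (inherits(fit, "bnt_pen")) {
    k1 <- 1L + length(fit$active1)
    k2 <- 2L + length(fit$active2)  # intercept + sigma
    keep1 <- c(1L, fit$active1 + 1L)
    keep2 <- c(1L, fit$active2 + 1L)
  } else {
    k1 <- length(fit$beta1)
    k2 <- length(fit$beta2) + 1L
    keep1 <- seq_along(fit$beta1)
    keep2 <- seq_along(fit$beta2)
  }
  l1 <- fit$loglik[["binomial"]]
  l2 <- fit$loglik[["continuous"]]

  folds <- make_folds(d$n, K, seed)
  me <- matrix(NA_real_, K, 3)
  for (J in seq_len(K)) {
    test <- folds == J
    train <- subset_bnt_data(d, !test)
    sub <- bnt_data(train$x, train$Z1[, keep1, drop = FALSE],
                    train$Z2[, keep2, drop = FALSE], y = train$y)
    refit <- bnt(sub)
    Z1t <- d$Z1[test, keep1, drop = FALSE]
    Z2t <- d$Z2[test, keep2, drop = FALSE]
    pi <- plogis(clamp_eta(drop(Z1t %*% refit$beta1)))
    mu <- drop(Z2t %*% refit$beta2)
    xt <- d$x[test]
    yt <- d$y[test]
    pos <- yt == 1
    me[J, 1] <- mean((yt - pi)^2)
    me[J, 2] <- if (any(pos)) mean((xt[pos] - mu[pos])^2) else NA_real_
    me[J, 3] <- mean((xt - pi * mu)^2)
  }
  me_mean <- colMeans(me, na.rm = TRUE)

  data.frame(
    part = c("binomial", "normal", "two_parts"),
    neg2loglik = c(-2 * l1, -2 * l2, -2 * (l1 + l2)),
    k = c(k1, k2, k1 + k2),
    AIC = c(-2 * l1 + 2 * k1, -2 * l2 + 2 * k2, -2 * (l1 + l2) + 2 * (k1 + k2)),
    BIC = c(-2 * l1 + k1 * log(d$n), -2 * l2 + k2 * log(npos),
            -2 * (l1 + l2) + (k1 + k2) * log(d$n + npos)),
    ME = me_mean)
}

#' Shapiro-Wilk normality precheck of the positive part
#'
#' Advisory test run before assuming a normal continuous part: applies
#' [stats::shapiro.test()] to the positive outcomes (after any log transform
#' applied at load). Never blocks fitting.
#'
#' @param data A [bnt_data()] object with at least 3 positive rows.
#' @return The Shapiro-Wilk p-value.
#' @export
shapiro_precheck <- function(data) {
  xp <- data$x[data$y == 1]
  if (length(xp) < 3) stop("at least 3 positive outcomes required", call. = FALSE)
  if (stats::sd(xp) == 0) stop("positive outcomes are constant; test degenerate",
                               call. = FALSE)
  if (length(xp) > 5000) xp <- xp[seq_len(5000)]
  stats::shapiro.test(xp)$p.value
}

#' Serialize a fitted two-part model to JSON
#'
#' Writes coefficients, scale, penalty configuration and log-likelihood with
#' full double precision so that a reloaded fit predicts bitwise identically.
#'
#' @param fit A fitted [bnt()] / [bnt_penalized()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
bnt_write_json <- function(fit, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for JSON serialization", call. = FALSE)
  }
  obj <- list(
    beta1 = unname(fit$beta1), beta2 = unname(fit$beta2), sigma = fit$sigma,
    names1 = names(fit$beta1), names2 = names(fit$beta2),
    loglik = as.list(fit$loglik), method = fit$method,
    penalty = fit$penalty, lambda1 = fit$lambda1, lambda2 = fit$lambda2,
    omega1 = fit$omega1, omega2 = fit$omega2,
    log_positives = fit$data$log_positives,
    call = paste(deparse(fit$call), collapse = " "))
  # I(17) significant digits: exact double round trip
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Reload a serialized two-part model
#'
#' @param path A file written by [bnt_write_json()].
#' @return A list of class `"bnt_coef"` with `beta1`, `beta2`, `sigma` and the
#'   stored metadata; usable with [predict_expected()] and
#'   `predict(..., newdata = )` via its own `predict` method.
#' @export
bnt_read_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for JSON serialization", call. = FALSE)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$beta1 <- stats::setNames(as.numeric(obj$beta1), obj$names1)
  obj$beta2 <- stats::setNames(as.numeric(obj$beta2), obj$names2)
  class(obj) <- "bnt_coef"
  obj
}

#' @export
predict.bnt_coef <- function(object, newdata, type = c("response", "pi", "mu"),
                             ...) {
  type <- match.arg(type)
  Z1 <- as.matrix(newdata$Z1)
  Z2 <- as.matrix(if (is.null(newdata$Z2)) newdata$Z1 else newdata$Z2)
  switch(type,
         pi = plogis(clamp_eta(drop(Z1 %*% object$beta1))),
         mu = drop(Z2 %*% object$beta2),
         response = predict_expected(object, Z1, Z2))
}
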