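# K-fold cross-validation tuning of the two penalty levels. The whole sample
# is split into K near-equal folds; each fold in turn is held out, the
# penalized model is fitted on the remainder over a descending warm-started
# lambda grid, and the held-out loss is averaged: CV(lambda) = mean_J CV_J.
# The two penalties are tuned separately by default, each with its own
# part-specific loss (binomial deviance on y for lambda1; squared error on
# positive-row outcomes for lambda2); the likelihood and the penalized
# estimators are separable, so nothing couples the two grids. A joint mode
# scoring (x - pi*mu)^2 on the 2-D grid is available for comparison.

#' Assign observations to K cross-validation folds
#'
#' A random permutation split into `K` parts whose sizes differ by at most 1,
#' reproducible from `seed` without disturbing the session RNG.
#'
#' @param n Number of observations.
#' @param K Number of folds, `2 <= K <= n`.
#' @param seed Optional integer seed for a private RNG stream.
#' @return Integer vector of length `n` with values in `1..K`.
#' @export
make_folds <- function(n, K, seed = NULL) {
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (K > n) stop(sprintf("K = %d exceeds n = %d", K, n), call. = FALSE)
  with_seed(seed, sample(rep_len(seq_len(K), n)))
}

subset_bnt_data <- function(data, idx) {
  bnt_data(data$x[idx], data$Z1[idx, , drop = FALSE],
           data$Z2[idx, , drop = FALSE], y = data$y[idx])
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * (y * log(p) + (1 - y) * log(1 - p))
}

# Held-out loss matrices for one part over a lambda grid.
# Returns a (K x nlambda) matrix of per-fold mean losses (normal-part rows
# with no held-out positives are NA and dropped from the average).
cv_loss_part <- function(data, part, lambdas, omega, folds, ...) {
  K <- max(folds)
  loss <- matrix(NA_real_, K, length(lambdas))
  for (J in seq_len(K)) {
    test <- folds == J
    train <- subset_bnt_data(data, !test)
    if (all(train$y == 0) || all(train$y == 1)) {
      stop("a training split contains a single outcome class; ",
           "use fewer folds or a different fold seed", call. = FALSE)
    }
    path <- path_part(train, part, lambdas, omega, ...)
    if (part == "binomial") {
      Zt <- data$Z1[test, , drop = FALSE]
      yt <- data$y[test]
      p <- plogis(clamp_eta(Zt %*% t(path)))
      loss[J, ] <- colMeans(binomial_deviance(yt, p))
    } else {
      pos <- test & data$y == 1
      if (!any(pos)) next
      Zt <- data$Z2[pos, , drop = FALSE]
      xt <- data$x[pos]
      loss[J, ] <- colMeans((xt - Zt %*% t(path))^2)
    }
  }
  loss
}

#' Cross-validation error of one part at a single penalty level
#'
#' Trains on `K - 1` folds and scores the held-out fold, for each fold in
#' turn. The binomial part is scored by mean deviance on the held-out
#' indicators; the continuous part by mean squared error on the held-out
#' positive-row outcomes.
#'
#' @param data A [bnt_data()] object.
#' @param lambda Non-negative penalty level.
#' @param fold_assignment Integer fold labels from [make_folds()].
#' @param part `"binomial"` or `"continuous"`.
#' @param omega Penalty weights for the part (default all 1).
#' @param ... Passed to the part solver.
#' @return A list with `mean_error` and `per_fold_errors` (the mean is the
#'   plain average of the per-fold errors).
#' @export
cv_error <- function(data, lambda, fold_assignment,
                     part = c("binomial", "continuous"),
                     omega = NULL, ...) {
  part <- match.arg(part)
  if (is.null(omega)) omega <- rep(1, if (part == "binomial") data$q1 else data$q2)
  loss <- cv_loss_part(data, part, lambda, omega, fold_assignment, ...)
  per_fold <- drop(loss)
  list(mean_error = mean(per_fold, na.rm = TRUE), per_fold_errors = per_fold)
}

# argmin with ties broken toward larger lambda; grids are descending, so take
# the first index attaining the minimum.
select_from_curve <- function(lambdas, cv_mean, cv_se, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  i_min <- which(cv_mean <= min(cv_mean))[1]
  if (rule == "min") return(lambdas[i_min])
  thresh <- cv_mean[i_min] + cv_se[i_min]
  lambdas[which(cv_mean <= thresh)[1]]
}

#' Select a penalty level by K-fold cross-validation over a grid
#'
#' @param data A [bnt_data()] object.
#' @param grid Non-empty descending vector of candidate penalty levels.
#' @param part `"binomial"` or `"continuous"`.
#' @param K Number of folds.
#' @param seed Fold seed (private RNG stream).
#' @param rule `"min"` (grid minimizer, ties toward larger lambda) or
#'   `"1se"` (largest lambda within one standard error of the minimum).
#' @param omega Penalty weights for the part.
#' @param ... Passed to the part solver.
#' @return A list of class `"bnt_cv_part"`: `lambda_grid`, `cv_errors`,
#'   `cv_se`, `lambda_selected`, `fold_assignment`, `K`.
#' @export
select_lambda <- function(data, grid, part = c("binomial", "continuous"),
                          K = 10, seed = NULL, rule = c("min", "1se"),
                          omega = NULL, ...) {
  part <- match.arg(part)
  rule <- match.arg(rule)
  if (length(grid) < 1) stop("empty lambda grid", call. = FALSE)
  grid <- sort(grid, decreasing = TRUE)
  if (is.null(omega)) omega <- rep(1, if (part == "binomial") data$q1 else data$q2)
  folds <- make_folds(data$n, K, seed)
  loss <- cv_loss_part(data, part, grid, omega, folds, ...)
  cv_mean <- colMeans(loss, na.rm = TRUE)
  nf <- colSums(!is.na(loss))
  cv_se <- apply(loss, 2, stats::sd, na.rm = TRUE) / sqrt(nf)
  structure(list(lambda_grid = grid, cv_errors = cv_mean, cv_se = cv_se,
                 lambda_selected = select_from_curve(grid, cv_mean, cv_se, rule),
                 fold_assignment = folds, K = K),
            class = "bnt_cv_part")
}

#' Cross-validated Lasso / adaptive-Lasso two-part fit
#'
#' Tunes `lambda1` and `lambda2` by K-fold cross-validation and refits the
#' penalized model on the full data at the selected pair. Both parts share
#' one fold assignment. For the adaptive Lasso, the weights are computed once
#' from the full-data MLE and held fixed across folds.
#'
#' @param object A model formula or [bnt_data()] object.
#' @param data A data frame (when `object` is a formula).
#' @param penalty `"lasso"` or `"alasso"`.
#' @param K Number of folds (default 10).
#' @param seed Fold seed (private RNG stream).
#' @param rule `"min"` or `"1se"` selection rule.
#' @param nlambda,lambda_min_ratio Grid size and span: `nlambda` log-spaced
#'   values descending from `lambda_max` to `lambda_min_ratio * lambda_max`.
#' @param joint Logical; if `TRUE`, select `(lambda1, lambda2)` jointly by the
#'   combined two-part loss `(x - pi*mu)^2` on the 2-D grid (the parts are
#'   still fitted independently, so the 2-D search costs the same as two 1-D
#'   searches).
#' @param log_positives Passed to [bnt_data()] for formula input.
#' @param ... Passed to the part solvers.
#' @return An object of class `"cv_bnt"`: per-part `"bnt_cv_part"` results
#'   (`cv1`, `cv2`), the selected `lambda1`/`lambda2`, and `fit`, the refitted
#'   [bnt_penalized()] model.
#' @examples
#' d <- simulate_bnt_data(bnt_scenario("s1", n = 300), seed = 7)
#' cvf <- cv_bnt(d, penalty = "alasso", seed = 7)
#' cvf$lambda1; cvf$fit$active1
#' @export
cv_bnt <- function(object, data = NULL, penalty = c("lasso", "alasso"),
                   K = 10, seed = NULL, rule = c("min", "1se"),
                   nlambda = 100, lambda_min_ratio = 1e-3, joint = FALSE,
                   log_positives = FALSE, ...) {
  penalty <- match.arg(penalty)
  rule <- match.arg(rule)
  inp <- resolve_bnt_input(object, data, log_positives)
  d <- inp$data
  check_both_classes(d)
  if (penalty == "alasso") {
    w <- adaptive_weights(d)
    omega1 <- w$omega1
    omega2 <- w$omega2
  } else {
    omega1 <- rep(1, d$q1)
    omega2 <- rep(1, d$q2)
  }
  lmax <- lambda_max_bnt(d, omega1, omega2)
  grid1 <- lambda_grid(lmax$lambda1_max, nlambda, lambda_min_ratio)
  grid2 <- lambda_grid(lmax$lambda2_max, nlambda, lambda_min_ratio)
  folds <- make_folds(d$n, K, seed)

  if (!joint) {
    loss1 <- cv_loss_part(d, "binomial", grid1, omega1, folds, ...)
    loss2 <- cv_loss_part(d, "continuous", grid2, omega2, folds, ...)
    cv1 <- colMeans(loss1, na.rm = TRUE)
    cv2 <- colMeans(loss2, na.rm = TRUE)
    se1 <- apply(loss1, 2, stats::sd, na.rm = TRUE) / sqrt(colSums(!is.na(loss1)))
    se2 <- apply(loss2, 2, stats::sd, na.rm = TRUE) / sqrt(colSums(!is.na(loss2)))
    lambda1 <- select_from_curve(grid1, cv1, se1, rule)
    lambda2 <- select_from_curve(grid2, cv2, se2, rule)
  } else {
    # fit per-part paths per fold once; combine predictions multiplicatively
    Kf <- max(folds)
    tot <- matrix(0, length(grid1), length(grid2))
    cnt <- 0
    for (J in seq_len(Kf)) {
      test <- folds == J
      train <- subset_bnt_data(d, !test)
      if (all(train$y == 0) || all(train$y == 1)) {
        stop("a training split contains a single outcome class; ",
             "use fewer folds or a different fold seed", call. = FALSE)
      }
      p1 <- path_part(train, "binomial", grid1, omega1, ...)
      p2 <- path_part(train, "continuous", grid2, omega2, ...)
      Pi <- plogis(clamp_eta(d$Z1[test, , drop = FALSE] %*% t(p1)))  # ntest x L1
      Mu <- d$Z2[test, , drop = FALSE] %*% t(p2)                     # ntest x L2
      xt <- d$x[test]
      for (a in seq_along(grid1)) {
        err <- (xt - Pi[, a] * Mu)^2
        tot[a, ] <- tot[a, ] + colSums(err)
      }
      cnt <- cnt + sum(test)
    }
    cvm <- tot / cnt
    idx <- which(cvm == min(cvm), arr.ind = TRUE)[1, ]
    lambda1 <- grid1[idx[1]]
    lambda2 <- grid2[idx[2]]
    cv1 <- cvm
    cv2 <- NULL
    se1 <- se2 <- NULL
  }

  fit <- bnt_penalized(d, penalty = penalty, lambda1 = lambda1,
                       lambda2 = lambda2, omega1 = omega1, omega2 = omega2, ...)
  fit$formula1 <- inp$formula1
  fit$formula2 <- inp$formula2
  structure(list(
    cv1 = list(lambda_grid = grid1, cv_errors = cv1, cv_se = se1,
               lambda_selected = lambda1, fold_assignment = folds, K = K),
    cv2 = list(lambda_grid = grid2, cv_errors = cv2, cv_se = se2,
               lambda_selected = lambda2, fold_assignment = folds, K = K),
    lambda1 = lambda1, lambda2 = lambda2, penalty = penalty,
    rule = rule, joint = joint, K = K, seed = seed, fit = fit),
    class = "cv_bnt")
}

#' @export
print.cv_bnt <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated %s two-part fit (%s rule%s)\n",
              x$K, x$penalty, x$rule, if (x$joint) ", joint grid" else ""))
  cat(sprintf("selected lambda1 = %.4g, lambda2 = %.4g\n", x$lambda1, x$lambda2))
  print(x$fit)
  invisible(x)
}

#' Plot cross-validation curves of a tuned two-part fit
#'
#' Draws the per-part CV error against `log(lambda)` with +/- 1 SE bars and
#' marks the selected penalty. Not available for joint-grid fits.
#'
#' @param x A [cv_bnt()] object.
#' @param ... Passed to [plot()].
#' @export
plot.cv_bnt <- function(x, ...) {
  if (x$joint) stop("no curve plot for joint 2-D tuning", call. = FALSE)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (part in 1:2) {
    cv <- if (part == 1) x$cv1 else x$cv2
    lab <- if (part == 1) "binomial part (deviance)" else "continuous part (MSE)"
    plot(log(cv$lambda_grid), cv$cv_errors, type = "b", pch = 20,
         xlab = expression(log(lambda)), ylab = "CV error", main = lab, ...)
    graphics::arrows(log(cv$lambda_grid), cv$cv_errors - cv$cv_se,
                     log(cv$lambda_grid), cv$cv_errors + cv$cv_se,
                     angle = 90, code = 3, length = 0.02, col = "grey60")
    graphics::abline(v = log(cv$lambda_selected), lty = 2, col = "red")
  }
  invisible(x)
}
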