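# Synthetic-data generator and Monte-Carlo evaluation harness. Covariates are
# drawn from N_q(0, Sigma) with AR(1)-type covariance Sigma_ij = rho^|i-j|;
# the outcome is the product construction
#   x_i = Bernoulli(pi_i) * Normal(mu_i, 1),
#   logit(pi_i) = z_i' beta1,  mu_i = z_i' beta2,  z1 = z2.
# The zero/nonzero indicator y is the Bernoulli draw itself (the Normal
# factor is unbounded and can be negative, so I(x > 0) would mislabel a few
# rows); the fitting code receives y explicitly.

#' Named simulation scenarios for the selection study
#'
#' Three preset coefficient configurations at q = 10, 15, 25 covariates. The
#' binomial-part and continuous-part coefficient vectors (intercept first)
#' mix a handful of nonzero signals with exact zeros; `sigma` is fixed at 1.
#'
#' @param scenario `"s1"` (q = 10), `"s2"` (q = 15) or `"s3"` (q = 25).
#' @param rho AR(1) covariate correlation, `|rho| < 1` (study values 0, 0.6).
#' @param n Sample size (study values 150, 300).
#' @param n_reps Number of Monte-Carlo replicates (study value 500).
#' @param seed Base seed for the study.
#' @return An object of class `"bnt_scenario"`: a list with `q`, `rho`, `n`,
#'   `beta1`, `beta2`, `sigma`, `n_reps`, `seed`, `name`.
#' @export
bnt_scenario <- function(scenario = c("s1", "s2", "s3"), rho = 0, n = 300,
                         n_reps = 500, seed = 1) {
  scenario <- match.arg(scenario)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  presets <- list(
    s1 = list(
      beta1 = c(0.2, 0.30, 1, 0.8, 0.4, -0.2, 0, 0, 0, 0, 0),
      beta2 = c(0.1, 1.10, 1, -0.36, 0.6, 0, 0, 0, 0, 0, 0)),
    s2 = list(
      beta1 = c(0.2, 0.30, 1, 0.8, 0.4, -0.2, 0, 0, 0.6, 0, 0, 0, 0, 0, 0, 0),
      beta2 = c(0.1, 1.10, 1, -0.36, 0.6, 0, 0, 0, 0.8, 0, 0, 0, 0, 0, 0, 0)),
    s3 = list(
      beta1 = c(0.2, 0.30, 1, 0.8, 0.4, -0.2, 0, 0, 0.6, 0, 0, 0, 0, 0, 0, 0,
                1.1, -0.2, 0, 0, 0, 0, 0, 0.6, 0, 0),
      beta2 = c(0.1, 1.10, 1, -0.36, 0.6, 0, 0, 0, 0.8, 0, 0, 0, 0, 0, 0, 0,
                0.9, 0.7, 0, 0, 0, 0, 0, 1.2, 0, 0))
  )
  p <- presets[[scenario]]
  structure(list(name = scenario, q = length(p$beta1) - 1L, rho = rho, n = n,
                 beta1 = p$beta1, beta2 = p$beta2, sigma = 1,
                 n_reps = n_reps, seed = seed),
            class = "bnt_scenario")
}

#' @export
print.bnt_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario %s: q = %d, rho = %.2f, n = %d, %d replicates (seed %d)\n",
              x$name, x$q, x$rho, x$n, x$n_reps, x$seed))
  cat(sprintf("  binomial part: %d nonzero / %d zero coefficients\n",
              sum(x$beta1[-1] != 0), sum(x$beta1[-1] == 0)))
  cat(sprintf("  continuous part: %d nonzero / %d zero coefficients\n",
              sum(x$beta2[-1] != 0), sum(x$beta2[-1] == 0)))
  invisible(x)
}

#' Draw AR(1)-correlated multivariate-normal covariates
#'
#' `n` rows from `N_q(0, Sigma)` with `Sigma_ij = rho^|i-j|` (unit variances;
#' geometrically decaying cross-correlations).
#'
#' @param n Number of rows.
#' @param q Number of covariates.
#' @param rho Correlation parameter, `|rho| < 1`.
#' @param seed Optional seed (private RNG stream).
#' @return An `n x q` matrix (no intercept column).
#' @export
simulate_covariates <- function(n, q, rho, seed = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  Sigma <- rho^abs(outer(seq_len(q), seq_len(q), "-"))
  with_seed(seed, MASS::mvrnorm(n, mu = rep(0, q), Sigma = Sigma))
}

#' Generate a semicontinuous dataset from the two-part model
#'
#' Given a scenario (or explicit coefficients and covariates), draws
#' `y_i ~ Bernoulli(pi_i)` and `x_i = y_i * Normal(mu_i, sigma)`. The
#' indicator stored in the dataset is the Bernoulli draw, so occasional
#' negative draws of the Normal factor are kept as generated and still count
#' as "nonzero" outcomes.
#'
#' @param scenario A [bnt_scenario()] object, or `NULL` when `Z`, `beta1`,
#'   `beta2` are given directly.
#' @param Z Optional `n x q` covariate matrix (generated from the scenario
#'   when missing).
#' @param beta1,beta2 Coefficient vectors (intercept first); default from the
#'   scenario.
#' @param sigma Positive-part scale; default from the scenario (1).
#' @param n Number of rows when `Z` is generated here.
#' @param rho Covariate correlation when `Z` is generated here.
#' @param seed Optional seed (private RNG stream) covering both the covariate
#'   and outcome draws.
#' @return A [bnt_data()] object with the true parameters attached as
#'   attribute `"truth"` (a list `beta1`, `beta2`, `sigma`).
#' @export
simulate_bnt_data <- function(scenario = NULL, Z = NULL, beta1 = NULL,
                              beta2 = NULL, sigma = NULL, n = NULL,
                              rho = NULL, seed = NULL) {
  if (!is.null(scenario)) {
    if (is.null(beta1)) beta1 <- scenario$beta1
    if (is.null(beta2)) beta2 <- scenario$beta2
    if (is.null(sigma)) sigma <- scenario$sigma
    if (is.null(n)) n <- scenario$n
    if (is.null(rho)) rho <- scenario$rho
  }
  if (is.null(sigma)) sigma <- 1
  if (length(beta1) != length(beta2)) {
    stop("beta1 and beta2 must have equal length (shared covariates z1 = z2)",
         call. = FALSE)
  }
  q <- length(beta1) - 1L
  with_seed(seed, {
    if (is.null(Z)) Z <- simulate_covariates(n, q, rho)
    if (ncol(Z) != q) {
      stop(sprintf("Z has %d columns but beta implies q = %d", ncol(Z), q),
           call. = FALSE)
    }
    Zi <- cbind(rep(1, nrow(Z)), Z)  # robust to q = 0
    pi <- plogis(clamp_eta(drop(Zi %*% beta1)))
    mu <- drop(Zi %*% beta2)
    y <- rbinom(nrow(Z), 1, pi)
    x <- ifelse(y == 1, rnorm(nrow(Z), mu, sigma), 0)
    colnames(Zi) <- c("(Intercept)",
                      if (q > 0) paste0("z", seq_len(q)) else character(0))
    d <- bnt_data(x, Zi, Zi, y = y)
    attr(d, "truth") <- list(beta1 = beta1, beta2 = beta2, sigma = sigma)
    d
  })
}

selection_counts <- function(beta_true, beta_hat) {
  bt <- beta_true[-1]
  bh <- beta_hat[-1]
  list(tp = sum(bt != 0 & bh != 0), nnz = sum(bt != 0),
       tn = sum(bt == 0 & bh == 0), nz = sum(bt == 0))
}

#' Score a fitted two-part model against the generating truth
#'
#' Computes the five evaluation statistics per part and combined:
#' \itemize{
#'   \item MPSE, mean squared prediction error on an independent test set:
#'     two-part rows score `(x - pi_hat * mu_hat)^2`; the binomial part scores
#'     `(y - pi_hat)^2` and the continuous part `(x - mu_hat)^2` over positive
#'     test rows (the part-specific conventions are this package's; the
#'     combined two-part MPSE is the standard one).
#'   \item MSE, `sum_{j=0..q} (beta_j - beta_hat_j)^2 / (q + 1)` per part
#'     (intercept included).
#'   \item Sensitivity (`#\{true nonzero kept\} / #\{true nonzero\}`),
#'     Specificity (`#\{true zero dropped\} / #\{true zero\}`) and Accuracy
#'     (`(kept + dropped) / q`), over non-intercept coefficients; combined
#'     metrics pool the counts of both parts.
#' }
#'
#' @param fit A fitted [bnt_penalized()] (or [bnt()]) object.
#' @param truth A list with `beta1`, `beta2` (e.g. `attr(data, "truth")` or a
#'   [bnt_scenario()]).
#' @param test_data Optional independent [bnt_data()] test set for the MPSE
#'   rows (omitted -> MPSE entries are `NA`).
#' @return A one-row data frame with columns `mpse_*`, `mse_*`, `sens*`,
#'   `spec*`, `acc*` for parts 1 (binomial), 2 (continuous) and `_two`.
#' @export
evaluate_fit <- function(fit, truth, test_data = NULL) {
  c1 <- selection_counts(truth$beta1, fit$beta1)
  c2 <- selection_counts(truth$beta2, fit$beta2)
  q1 <- c1$nnz + c1$nz
  q2 <- c2$nnz + c2$nz
  mse1 <- mean((truth$beta1 - fit$beta1)^2)
  mse2 <- mean((truth$beta2 - fit$beta2)^2)
  mpse1 <- mpse2 <- mpse_two <- NA_real_
  if (!is.null(test_data)) {
    pi <- predict(fit, newdata = test_data, type = "pi")
    mu <- predict(fit, newdata = test_data, type = "mu")
    mpse1 <- mean((test_data$y - pi)^2)
    pos <- test_data$y == 1
    mpse2 <- mean((test_data$x[pos] - mu[pos])^2)
    mpse_two <- mean((test_data$x - pi * mu)^2)
  }
  data.frame(
    mpse_binomial = mpse1, mpse_normal = mpse2, mpse_two = mpse_two,
    mse_beta1 = mse1, mse_beta2 = mse2,
    sens1 = c1$tp / c1$nnz, spec1 = c1$tn / c1$nz,
    acc1 = (c1$tp + c1$tn) / q1,
    sens2 = c2$tp / c2$nnz, spec2 = c2$tn / c2$nz,
    acc2 = (c2$tp + c2$tn) / q2,
    sens_two = (c1$tp + c2$tp) / (c1$nnz + c2$nnz),
    spec_two = (c1$tn + c2$tn) / (c1$nz + c2$nz),
    acc_two = (c1$tp + c1$tn + c2$tp + c2$tn) / (q1 + q2))
}

fit_one_method <- function(train, method, K, fold_seed, nlambda,
                           lambda_min_ratio) {
  cv_bnt(train, penalty = method, K = K, seed = fold_seed,
         nlambda = nlambda, lambda_min_ratio = lambda_min_ratio)$fit
}

#' Monte-Carlo selection study over a scenario
#'
#' Repeats, `n_reps` times: generate a training set from the scenario, tune
#' and fit each requested method by K-fold cross-validation, generate an
#' independent test set of the same size, and score the fit with
#' [evaluate_fit()]. Replicate `r` uses the RNG stream seeded by `seed + r`
#' (folds use an offset stream), so results are independent of scheduling and
#' both methods see identical data. Replicates whose data defeat fitting
#' (a single-class training split, too few positives) are redrawn with a
#' shifted seed and counted.
#'
#' @param scenario A [bnt_scenario()] object.
#' @param methods Character subset of `c("lasso", "alasso")`.
#' @param K Number of CV folds (default 10).
#' @param n_reps Number of replicates (default from the scenario).
#' @param seed Base seed (default from the scenario).
#' @param nlambda,lambda_min_ratio Penalty grid controls.
#' @param verbose Print a progress line every 50 replicates.
#' @return An object of class `"bnt_study"`: a list with `means` (a data
#'   frame of per-method mean statistics), `reps` (a named list of per-method
#'   per-replicate data frames, for paired comparisons), `n_reps_done`,
#'   `n_redrawn`, `scenario`.
#' @export
run_bnt_study <- function(scenario, methods = c("lasso", "alasso"), K = 10,
                          n_reps = scenario$n_reps, seed = scenario$seed,
                          nlambda = 100, lambda_min_ratio = 1e-3,
                          verbose = FALSE) {
  methods <- match.arg(methods, c("lasso", "alasso"), several.ok = TRUE)
  reps <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) reps[[m]] <- vector("list", n_reps)
  truth <- list(beta1 = scenario$beta1, beta2 = scenario$beta2)
  n_redrawn <- 0L
  for (r in seq_len(n_reps)) {
    attempt <- 0L
    repeat {
      rep_seed <- seed + r + attempt * 9000000L
      res <- tryCatch({
        train <- simulate_bnt_data(scenario, seed = rep_seed)
        test <- simulate_bnt_data(scenario, seed = rep_seed + 4000000L)
        lapply(stats::setNames(methods, methods), function(m) {
          fit <- fit_one_method(train, m, K, rep_seed + 1000000L,
                                nlambda, lambda_min_ratio)
          evaluate_fit(fit, truth, test)
        })
      }, error = function(e) e)
      if (!inherits(res, "error")) break
      attempt <- attempt + 1L
      n_redrawn <- n_redrawn + 1L
      if (attempt > 10L) stop("replicate ", r, " failed repeatedly: ",
                              conditionMessage(res), call. = FALSE)
    }
    for (m in methods) reps[[m]][[r]] <- res[[m]]
    if (verbose && r %% 50 == 0) {
      message(sprintf("  replicate %d / %d", r, n_reps))
    }
  }
  per_method <- lapply(reps, function(lst) do.call(rbind, lst))
  means <- do.call(rbind, lapply(methods, function(m) {
    cbind(data.frame(method = m), as.data.frame(t(colMeans(per_method[[m]]))))
  }))
  rownames(means) <- NULL
  structure(list(means = means, reps = per_method, n_reps_done = n_reps,
                 n_redrawn = n_redrawn, scenario = scenario, K = K,
                 seed = seed),
            class = "bnt_study")
}

#' @export
print.bnt_study <- function(x, digits = 4, ...) {
  s <- x$scenario
  cat(sprintf("Monte-Carlo selection study: scenario %s (q = %d, rho = %.1f, n = %d), %d replicates\n",
              s$name, s$q, s$rho, s$n, x$n_reps_done))
  if (x$n_redrawn > 0) cat(sprintf("  (%d degenerate replicate draws redrawn)\n", x$n_redrawn))
  m <- x$means
  num <- vapply(m, is.numeric, logical(1))
  m[num] <- lapply(m[num], round, digits)
  print(m, row.names = FALSE)
  invisible(x)
}
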