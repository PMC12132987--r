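# bntreg

Variable selection for **semicontinuous outcomes** — non-negative
measurements with a point mass at zero and a continuous distribution on the
positives (dietary intake of occasionally eaten foods, health-care
expenditures, insurance claims, rainfall). The package is written for
biostatisticians and epidemiologists who need to know *which* covariates
drive (a) whether the outcome occurs at all and (b) how large it is when it
does.

## The model and the methods

The Bernoulli-Normal two-part (BNT) regression model, with
$y_i = I(x_i > 0)$:

$$f(x_i) = (1-\pi_i)^{1-y_i}\bigl[\pi_i\,N(x_i;\mu_i,\sigma^2)\bigr]^{y_i},
\qquad \operatorname{logit}(\pi_i) = z_{1i}^\top\beta_1, \qquad
\mu_i = z_{2i}^\top\beta_2 .$$

The log-likelihood separates as $l(\theta)=l_1(\beta_1)+l_2(\beta_2,\sigma)$,
so the logistic part and the positive-part normal regression are estimated
independently. On top of the maximum-likelihood fit, the package provides
$\ell_1$-penalized variable selection per part,

$$-l_1(\beta_1) + \lambda_1\sum_j \omega_{1j}|\beta_{1j}|, \qquad
\sum_{y_i=1}(x_i-z_{2i}^\top\beta_2)^2 + \lambda_2\sum_s \omega_{2s}|\beta_{2s}|,$$

with unit weights (**Lasso**) or weights $\omega_j = 1/|\hat\beta_{j,\rm ml}|$
(**adaptive Lasso**, which has the oracle property). Both problems are solved
by cyclic coordinate descent with soft-thresholding — the binomial part
through a nested IRLS quadratic approximation — with compiled (Rcpp) inner
loops, warm-started regularization paths, and K-fold cross-validation tuning
of $(\lambda_1,\lambda_2)$. A Monte-Carlo harness reproduces the
selection-accuracy study design: AR(1)-correlated Gaussian covariates
($\Sigma_{ij}=\rho^{|i-j|}$), sparse true coefficient vectors at
$q \in \{10,15,25\}$, and Sensitivity / Specificity / Accuracy of the
selected models.

## Worked example

```r
library(bntreg)

sc  <- bnt_scenario("s1", rho = 0, n = 300)   # q = 10, 5 + 4 true signals
d   <- simulate_bnt_data(sc, seed = 1)

fit <- bnt(d)                                 # maximum likelihood
fit
#> Bernoulli-Normal two-part regression (maximum likelihood)
#> n = 300 (145 zero / 155 positive)
#> Binomial part (logit of Pr(X > 0)):
#> (Intercept)    z1    z2    z3    z4     z5     z6     z7     z8    z9   z10
#>       0.051 0.247 0.917 0.800 0.380 -0.273 -0.220 -0.150 -0.106 0.098 -0.020
#> Continuous part (mean of positive outcomes):
#> (Intercept)    z1    z2     z3    z4     z5    z6    z7    z8    z9   z10
#>       0.175 1.183 0.938 -0.378 0.599 -0.006 0.057 0.067 0.091 0.048 0.003
#> sigma = 1.007   log-likelihood = -383.289

cvf <- cv_bnt(d, penalty = "alasso", seed = 1) # 10-fold CV tuned adaptive lasso
cvf$fit$active2
#> [1] 1 2 3 4
```

The MLE estimates every coefficient (the five true binomial signals
z1–z5 and four continuous signals z1–z4 stand out, but the noise covariates
get small nonzero estimates too); the CV-tuned adaptive Lasso recovers the
continuous part's true support {z1, z2, z3, z4} exactly and zeroes the rest.
A 50-replicate study of the same scenario:

```r
st <- run_bnt_study(bnt_scenario("s1", n = 300, n_reps = 50, seed = 1))
st$means[, c("method", "sens1", "spec1", "acc1", "sens2", "spec2", "acc2")]
#>   method sens1 spec1  acc1 sens2 spec2  acc2
#> 1  lasso 0.968 0.396 0.682 0.995 0.423 0.652
#> 2 alasso 0.860 0.740 0.800 0.995 0.840 0.902
```

Read: the Lasso keeps nearly every true signal (`sens`) but also keeps most
noise covariates (low `spec`); the adaptive Lasso trades a little sensitivity
in the binomial part for far better exclusion of noise, and wins on overall
selection accuracy in both parts — the study's headline comparison.

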