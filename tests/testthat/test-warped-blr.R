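test_that("identity-warp NLML equals the direct n-space Gaussian evidence", {
  set.seed(12)
  n <- 40
  X <- cbind(1, rnorm(n), runif(n))
  y <- drop(X %*% c(1, 0.5, -2)) + rnorm(n)
  ys <- (y - mean(y)) / sd(y)
  for (pars in list(c(1, 1), c(0.3, 4), c(5, 0.2))) {
    hyper <- blr_hyperparams(pars[1], pars[2])
    nlml <- neg_log_marginal_likelihood(hyper, ys, bare_design(X))
    direct <- -blr_log_evidence_direct(ys, X, pars[1], pars[2])
    expect_equal(nlml, direct, tolerance = 1e-8)
  }
})

test_that("single-point evidence matches 1-D quadrature over the weight", {
  # n = 1, p = 1, Phi = [1], z = 0, alpha = beta = 1
  ev_quad <- integrate(function(w) dnorm(0, w, 1) * dnorm(w, 0, 1),
                       -Inf, Inf, rel.tol = 1e-12)$value
  nlml <- neg_log_marginal_likelihood(
    blr_hyperparams(1, 1), 0, bare_design(matrix(1, 1, 1))
  )
  expect_equal(nlml, -log(ev_quad), tolerance = 1e-8)
})

test_that("NLML varies smoothly in the warp and the analytic gradient matches finite differences", {
  set.seed(13)
  n <- 120
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(0.3, 0.8)) + rnorm(n, 0, 0.5)
  ys <- (y - mean(y)) / sd(y)
  f <- function(th) {
    hyper <- blr_hyperparams(exp(th[1]), exp(th[2]),
                             shash_params(th[3], exp(th[4])))
    neg_log_marginal_likelihood(hyper, ys, bare_design(X))
  }
  th0 <- c(0.2, -0.1, 0.15, 0.1)
  core <- neuronorm:::nlml_core(th0, ys, X, crossprod(X))
  g <- neuronorm:::nlml_grad(core, ys)
  h <- 1e-6
  for (j in 1:4) {
    e <- replace(rep(0, 4), j, h)
    fd <- (f(th0 + e) - f(th0 - e)) / (2 * h)
    expect_equal(g[j], fd, tolerance = 1e-4)
  }
})

test_that("with the warp fixed at identity the fit matches an independent evidence optimum", {
  set.seed(14)
  n <- 500
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(X %*% c(0.5, 1, -0.7)) + rnorm(n, 0, 0.8)
  ys <- (y - mean(y)) / sd(y)
  fit <- fit_roi(ys, bare_design(X), fix_warp = TRUE, standardize = FALSE,
                 n_restarts = 1, pgtol = 1e-10, factr = 1e1)
  oracle <- em_blr(ys, X)
  expect_lt(max(abs(fit$weight_mean - oracle$m)), 1e-8)
  expect_equal(fit$hyper$alpha, oracle$alpha, tolerance = 1e-6)
  expect_equal(fit$hyper$beta, oracle$beta, tolerance = 1e-6)
  expect_equal(fit$hyper$warp$a, 0)
  expect_equal(fit$hyper$warp$b, 1)
})

test_that("near-Gaussian data yields a near-identity fitted warp", {
  errs <- t(sapply(1:10, function(k) {
    set.seed(200 + k)
    n <- 5000
    x <- runif(n, 2, 100)
    X <- cbind(1, x / 50)
    y <- drop(X %*% c(2.5, -0.3)) + rnorm(n, 0, 0.2)
    fit <- fit_roi(y, bare_design(X), n_restarts = 0, seed = k)
    c(a = fit$hyper$warp$a, b = fit$hyper$warp$b)
  }))
  expect_lt(abs(mean(errs[, "a"])), 0.05)
  expect_lt(abs(mean(errs[, "b"]) - 1), 0.05)
})

test_that("duplicating every observation leaves the weight posterior mean unchanged", {
  set.seed(15)
  n <- 300
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(0.2, 1.1)) + rnorm(n, 0, 0.6)
  fit1 <- fit_roi(y, bare_design(X), n_restarts = 0, pgtol = 1e-9, factr = 1e2)
  fit2 <- fit_roi(rep(y, 2), bare_design(X[rep(1:n, 2), ]), n_restarts = 0,
                  pgtol = 1e-9, factr = 1e2)
  # the evidence optimum drifts by O(1/n) as the prior weakens relatively,
  # so agreement is to that order, not bit-exact
  expect_lt(max(abs(fit1$weight_mean - fit2$weight_mean)), 5e-3)
  expect_equal(fit1$hyper$beta, fit2$hyper$beta, tolerance = 0.02)
  expect_equal(fit1$hyper$warp$a, fit2$hyper$warp$a, tolerance = 0.05)
})

test_that("no fitted hyperparameter can be perturbed +-10% to a lower NLML", {
  co <- tiny_cohort(400, 1, 2, seed = 17)
  spec <- make_design_spec(co)
  dm <- build_design_matrix(co, spec)
  y <- roi_matrix(co)[, 1]
  fit <- fit_roi(y, dm, n_restarts = 1, pgtol = 1e-8, factr = 1e2)
  ys <- (y - fit$response_center) / fit$response_scale
  at <- function(al, be, a, b) {
    neg_log_marginal_likelihood(blr_hyperparams(al, be, shash_params(a, b)),
                                ys, dm)
  }
  h <- fit$hyper
  base <- at(h$alpha, h$beta, h$warp$a, h$warp$b)
  for (e in c(-1, 1)) {
    expect_gte(at(h$alpha * (1 + 0.1 * e), h$beta, h$warp$a, h$warp$b), base - 1e-6)
    expect_gte(at(h$alpha, h$beta * (1 + 0.1 * e), h$warp$a, h$warp$b), base - 1e-6)
    expect_gte(at(h$alpha, h$beta, h$warp$a + 0.05 * e, h$warp$b), base - 1e-6)
    expect_gte(at(h$alpha, h$beta, h$warp$a, h$warp$b * (1 + 0.1 * e)), base - 1e-6)
  }
})

test_that("prediction is row-wise, shrinks to zero under a huge prior, and model_var falls with replication", {
  set.seed(18)
  n <- 80
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(0.5, 1)) + rnorm(n, 0, 0.5)
  fit <- fit_roi(y, bare_design(X), n_restarts = 0)
  perm <- sample(n)
  p1 <- predict(fit, bare_design(X))
  p2 <- predict(fit, bare_design(X[perm, ]))
  expect_equal(p2$latent_mean, p1$latent_mean[perm])
  expect_equal(p2$model_var, p1$model_var[perm])
  # prior-dominated limit: posterior mean at alpha -> large shrinks to zero
  fitL <- fit_roi(y, bare_design(X), fix_warp = TRUE, n_restarts = 0)
  z <- (y - fitL$response_center) / fitL$response_scale
  fitL$weight_mean[] <- drop(
    fitL$hyper$beta * solve(1e12 * diag(2) + fitL$hyper$beta * crossprod(X),
                            crossprod(X, z))
  )
  expect_lt(max(abs(predict(fitL, bare_design(X))$latent_mean)), 1e-6)
  # replicating a design row shrinks its modeling uncertainty
  Xr <- rbind(X, X[rep(1, 20), ])
  yr <- c(y, rep(y[1], 20))
  fit_rep <- fit_roi(yr, bare_design(Xr), n_restarts = 0)
  expect_lt(predict(fit_rep, bare_design(X[1, , drop = FALSE]))$model_var,
            predict(fit, bare_design(X[1, , drop = FALSE]))$model_var)
})

test_that("degenerate inputs are rejected or warned about", {
  X <- cbind(1, rnorm(10))
  expect_error(fit_roi(rep(2, 10), bare_design(X)), "zero-variance")
  expect_error(fit_roi(c(rnorm(9), NA), bare_design(X)), "finite")
  expect_warning(fit_roi(rnorm(3), bare_design(cbind(1, rnorm(3), rnorm(3))),
                         n_restarts = 0), "fewer observations")
  expect_error(neg_log_marginal_likelihood(blr_hyperparams(), rnorm(5),
                                           bare_design(X)), "length")
})
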