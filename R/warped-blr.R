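#' Hyperparameters of the warped Bayesian linear regression
#'
#' @param alpha Prior precision on the weight vector (> 0).
#' @param beta Noise precision in the latent Gaussian space (> 0).
#' @param warp A [shash_params()] object.
#' @return An object of class `blr_hyperparams`.
#' @export
blr_hyperparams <- function(alpha = 1, beta = 1, warp = shash_params()) {
  check_positive_scalar(alpha, "alpha")
  check_positive_scalar(beta, "beta")
  structure(list(alpha = alpha, beta = beta, warp = as_shash_params(warp)),
            class = "blr_hyperparams")
}

# Evidence core at fixed hyperparameters. y_std is the standardized response.
# Returns the negative log marginal likelihood of the warped model
#   -log evidence(z | alpha, beta) - sum(log Jacobian of y -> z)
# together with the posterior (m, A) and the pieces the gradient needs.
# A = alpha I + beta Phi'Phi;  m = beta A^{-1} Phi' z.
nlml_core <- function(theta, y_std, X, XtX, fix_warp = FALSE, jitter = 0) {
  n <- length(y_std)
  p <- ncol(X)
  alpha <- exp(theta[1L])
  beta <- exp(theta[2L])
  if (fix_warp) {
    a <- 0; b <- 1
    z <- y_std
    lj_sum <- 0
  } else {
    a <- theta[3L]; b <- exp(theta[4L])
    u <- b * asinh(y_std) - a
    z <- sinh(u)
    lj_sum <- sum(log(b) + log_cosh(u) - 0.5 * log1p(y_std^2))
  }
  A <- alpha * diag(p) + beta * XtX
  if (jitter > 0) diag(A) <- diag(A) + jitter
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    if (jitter == 0) {
      return(nlml_core(theta, y_std, X, XtX, fix_warp, jitter = 1e-8))
    }
    nn_stop("posterior precision matrix not positive definite; ",
            "try increasing the jitter")
  }
  Xtz <- crossprod(X, z)
  m <- beta * backsolve(R, forwardsolve(t(R), Xtz))
  resid <- z - drop(X %*% m)
  rss <- sum(resid^2)
  mtm <- sum(m^2)
  logdetA <- 2 * sum(log(diag(R)))
  logev <- p / 2 * log(alpha) + n / 2 * log(beta) - beta / 2 * rss -
    alpha / 2 * mtm - logdetA / 2 - n / 2 * log(2 * pi)
  value <- -logev - lj_sum
  list(value = value, m = m, R = R, resid = resid, rss = rss, mtm = mtm,
       alpha = alpha, beta = beta, a = a, b = b, n = n, p = p,
       jitter = jitter, z = z)
}

# Analytic gradient of the NLML in (log alpha, log beta, a, log b).
# Envelope identities: d logev/d alpha = p/(2 alpha) - m'm/2 - tr(A^-1)/2;
# d logev/d beta = n/(2 beta) - rss/2 - tr(A^-1 Phi'Phi)/2 with
# tr(A^-1 Phi'Phi) = (p - alpha tr(A^-1))/beta; d NLML/dz = beta (z - Phi m).
nlml_grad <- function(core, y_std, fix_warp = FALSE) {
  Ainv <- chol2inv(core$R)
  trAinv <- sum(diag(Ainv))
  g_la <- -(core$p / 2 - core$alpha * core$mtm / 2 - core$alpha * trAinv / 2)
  tr_AiS <- (core$p - core$alpha * trAinv) / core$beta
  g_lb <- -(core$n / 2 - core$beta * core$rss / 2 - core$beta * tr_AiS / 2)
  if (fix_warp) return(c(g_la, g_lb))
  s <- asinh(y_std)
  u <- core$b * s - core$a
  ch <- cosh(u); th <- tanh(u)
  dz_da <- -ch
  dz_db <- s * ch
  dlj_da <- -th
  dlj_db <- 1 / core$b + s * th
  w <- core$beta * core$resid
  g_a <- sum(w * dz_da) - sum(dlj_da)
  g_b <- sum(w * dz_db) - sum(dlj_db)
  c(g_la, g_lb, g_a, core$b * g_b)
}

#' Negative log marginal likelihood of the warped BLR
#'
#' The objective minimized during hyperparameter optimisation: the negative
#' log evidence of a Gaussian Bayesian linear regression computed on the
#' warped responses `z = W(y)`, minus the summed log-Jacobian of the warp
#' (which converts the latent density into a response-space density).
#'
#' @param hyper A [blr_hyperparams()].
#' @param y Standardized response vector.
#' @param design A `design_matrix` (or bare numeric matrix).
#' @return Scalar negative log marginal likelihood.
#' @export
neg_log_marginal_likelihood <- function(hyper, y, design) {
  stopifnot(inherits(hyper, "blr_hyperparams"))
  X <- if (inherits(design, "design_matrix")) design$values else as.matrix(design)
  check_finite(y, "y")
  if (length(y) != nrow(X)) nn_stop("length(y) must equal nrow(design)")
  theta <- c(log(hyper$alpha), log(hyper$beta), hyper$warp$a, log(hyper$warp$b))
  nlml_core(theta, y, X, crossprod(X))$value
}

#' Fit a normative model for one ROI
#'
#' Type-II maximum likelihood: minimizes the warped-evidence negative log
#' marginal likelihood over `(log alpha, log beta, a, log b)` by bounded
#' quasi-Newton (L-BFGS-B) with analytic gradients, from a default start plus
#' seeded random restarts. The closed-form posterior over weights at the
#' optimum is stored together with the warp, the design specification and the
#' training standardization of the response.
#'
#' @param y Numeric response vector (one ROI, training subjects).
#' @param design A `design_matrix` from [build_design_matrix()].
#' @param roi_name Name recorded in the fitted model.
#' @param fix_warp If `TRUE`, the warp is held at the identity and the model
#'   is an ordinary Gaussian Bayesian linear regression.
#' @param standardize Center/scale `y` by its training mean/SD before warping
#'   (default). Disable only when the response is already in standardized
#'   units.
#' @param n_restarts Number of random restarts beyond the default start.
#' @param max_iter,pgtol,factr L-BFGS-B controls.
#' @param seed Seed for the restart perturbations.
#' @return An object of class `normative_model`.
#' @export
fit_roi <- function(y, design, roi_name = "roi", fix_warp = FALSE,
                    standardize = TRUE, n_restarts = 3L,
                    max_iter = 500L, pgtol = 1e-5, factr = 1e7, seed = 1L) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$values
  check_finite(y, "y")
  if (length(y) != nrow(X)) nn_stop("length(y) must equal nrow(design)")
  if (sd(y) == 0) nn_stop("zero-variance response for ROI ", roi_name)
  if (length(y) <= ncol(X)) {
    warning("fewer observations than design columns for ROI ", roi_name,
            call. = FALSE)
  }
  center <- if (standardize) mean(y) else 0
  scale <- if (standardize) sd(y) else 1
  y_std <- (y - center) / scale
  XtX <- crossprod(X)
  n_par <- if (fix_warp) 2L else 4L
  lower <- c(-20, -20, -5, -3)[seq_len(n_par)]
  upper <- c(20, 20, 5, 3)[seq_len(n_par)]
  starts <- list(rep(0, n_par))
  if (n_restarts > 0) {
    with_seed(derive_seed(seed, "restarts"), {
      for (k in seq_len(n_restarts)) {
        starts[[k + 1L]] <- rnorm(n_par) * c(1, 1, 0.3, 0.3)[seq_len(n_par)]
      }
    })
  }
  fn <- function(th) {
    v <- nlml_core(th, y_std, X, XtX, fix_warp)$value
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(th) {
    core <- nlml_core(th, y_std, X, XtX, fix_warp)
    g <- nlml_grad(core, y_std, fix_warp)
    if (any(!is.finite(g))) rep(0, n_par) else g
  }
  best <- NULL
  conv <- integer(0)
  for (st in starts) {
    fit <- tryCatch(
      optim(pmin(pmax(st, lower), upper), fn, gr, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = max_iter, pgtol = pgtol, factr = factr)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    conv <- c(conv, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) nn_stop("optimisation failed for ROI ", roi_name)
  theta <- best$par
  core <- nlml_core(theta, y_std, X, XtX, fix_warp)
  weight_cov <- chol2inv(core$R)
  hyper <- blr_hyperparams(core$alpha, core$beta,
                           shash_params(core$a, core$b))
  structure(
    list(
      roi_name = roi_name,
      weight_mean = setNames(drop(core$m), colnames(X)),
      weight_cov = weight_cov,
      hyper = hyper,
      design_spec = design$spec,
      response_center = center,
      response_scale = scale,
      fit_report = list(
        converged = any(conv == 0L),
        final_objective = best$value,
        n_restarts = n_restarts,
        convergence_codes = conv,
        jitter_used = core$jitter
      )
    ),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf(
    "<normative_model> %s: p=%d, alpha=%.4g, beta=%.4g, warp(a=%.3f, b=%.3f)%s\n",
    x$roi_name, length(x$weight_mean), x$hyper$alpha, x$hyper$beta,
    x$hyper$warp$a, x$hyper$warp$b,
    if (isTRUE(x$fit_report$converged)) "" else " [not converged]"
  ))
  invisible(x)
}

check_spec_match <- function(model, design) {
  s1 <- model$design_spec; s2 <- design$spec
  same <- identical(s1$column_names, s2$column_names) &&
    isTRUE(all.equal(s1$knot_positions, s2$knot_positions)) &&
    identical(s1$site_levels, s2$site_levels)
  if (!same) nn_stop("design was not built from this model's design_spec")
  invisible(TRUE)
}

#' Latent-space predictive distribution
#'
#' For each row of the design: the latent predictive mean `mu = phi' m`, the
#' (scalar) noise variance `1/beta`, and the per-row modeling-uncertainty
#' variance `phi' Sigma phi` from the weight posterior.
#'
#' @param object A `normative_model`.
#' @param design A `design_matrix` built from the model's `design_spec`.
#' @param ... Unused.
#' @return An object of class `predictive`: list with `latent_mean`,
#'   `noise_var`, `model_var`, `row_ids`.
#' @export
predict.normative_model <- function(object, design, ...) {
  stopifnot(inherits(design, "design_matrix"))
  check_spec_match(object, design)
  X <- design$values
  mu <- drop(X %*% object$weight_mean)
  mv <- rowSums((X %*% object$weight_cov) * X)
  structure(
    list(latent_mean = mu, noise_var = 1 / object$hyper$beta,
         model_var = pmax(mv, 0), row_ids = design$row_ids),
    class = "predictive"
  )
}

#' Simulate responses from a fitted model's predictive law
#'
#' Draws latent values `z ~ N(mu, sigma_d^2 + sigma_*^2)` per design row and
#' returns them inverse-warped and de-standardized to measurement space.
#' Used to generate held-out data that is exactly in the fitted model class
#' (calibration and coverage checks).
#'
#' @param model A `normative_model`.
#' @param design A `design_matrix` built from the model's spec.
#' @param seed Integer seed.
#' @param include_model_var Include modeling uncertainty in the draw variance
#'   (default `TRUE`, the full predictive).
#' @param latent_shift Optional constant added in latent space (used to
#'   emulate unseen-site offsets).
#' @return Numeric vector of simulated responses in measurement units.
#' @export
simulate_from_model <- function(model, design, seed = 1L,
                                include_model_var = TRUE, latent_shift = 0) {
  pred <- predict(model, design)
  v <- pred$noise_var + if (include_model_var) pred$model_var else 0
  z <- with_seed(seed, rnorm(length(pred$latent_mean),
                             pred$latent_mean + latent_shift, sqrt(v)))
  y_std <- warp_inverse(z, model$hyper$warp)
  y_std * model$response_scale + model$response_center
}

#' Fit normative models for every ROI of a cohort
#'
#' One independent warped BLR per ROI (embarrassingly parallel in principle;
#' fitted sequentially here), sharing a single design specification built from
#' the training cohort.
#'
#' @param train_cohort A [cohort_table()] of training subjects.
#' @param ... Passed to [fit_roi()].
#' @return An object of class `model_bundle`: list of `normative_model`s
#'   keyed by ROI name plus metadata.
#' @export
fit_normative_models <- function(train_cohort, ...) {
  spec <- make_design_spec(train_cohort)
  design <- build_design_matrix(train_cohort, spec)
  Y <- roi_matrix(train_cohort)
  models <- lapply(colnames(Y), function(r) {
    fit_roi(Y[, r], design, roi_name = r, ...)
  })
  names(models) <- colnames(Y)
  structure(
    list(format_version = "1.0",
         models = models,
         calibrations = list(),
         metadata = list(
           n_train = nrow(train_cohort),
           # content hash (design + ROI set + size); deliberately path-free
           config_hash = config_hash(list(n = nrow(train_cohort),
                                          rois = names(models),
                                          spec = unclass(spec))),
           created = "neuronorm"
         )),
    class = "model_bundle"
  )
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle v%s> %d ROI models, %d site calibrations\n",
              x$format_version, length(x$models), length(x$calibrations)))
  invisible(x)
}
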