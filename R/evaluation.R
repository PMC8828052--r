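#' Site-stratified train/test split
#'
#' Splits a cohort into equal-sized halves (by default) within each site, so
#' train and test have the same site composition. A site with a single
#' subject goes to the training half with a warning.
#'
#' @param cohort A [cohort_table()].
#' @param fraction Training fraction within each site (default 0.5).
#' @param seed Integer seed.
#' @return List with `train` and `test` cohort tables.
#' @export
split_train_test <- function(cohort, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) nn_stop("`fraction` must be in (0, 1)")
  sites <- unique(as.character(cohort$site))
  train_idx <- integer(0)
  with_seed(derive_seed(seed, "split"), {
    for (s in sites) {
      idx <- which(cohort$site == s)
      if (length(idx) == 1L) {
        warning("site ", s, " has a single subject; assigned to train",
                call. = FALSE)
        train_idx <- c(train_idx, idx)
        next
      }
      n_train <- round(fraction * length(idx))
      n_train <- min(max(n_train, 1L), length(idx) - 1L)
      train_idx <- c(train_idx, sample(idx, n_train))
    }
  })
  train_idx <- sort(train_idx)
  list(train = cohort_subset(cohort, train_idx),
       test = cohort_subset(cohort, setdiff(seq_len(nrow(cohort)), train_idx)))
}

#' Explained variance
#'
#' `EV = 1 - Var(y_true - y_point) / Var(y_true)`, computed in measurement
#' space with the predictive median as point prediction.
#'
#' @param y_true Observed responses.
#' @param y_point Point predictions.
#' @return Scalar explained variance (at most 1).
#' @export
explained_variance <- function(y_true, y_point) {
  check_finite(y_true, "y_true")
  check_finite(y_point, "y_point")
  if (length(y_true) < 2L) nn_stop("need at least 2 observations")
  v <- var(y_true)
  if (v == 0) nn_stop("zero-variance truth")
  1 - var(y_true - y_point) / v
}

#' Training baseline for the standardized log-loss
#'
#' Mean and variance of the warped, training-standardized responses — the
#' trivial Gaussian reference the MSLL compares against.
#'
#' @param model A `normative_model`.
#' @param y_train Raw training responses for this ROI.
#' @return List with `mean` and `var` in latent space.
#' @export
train_baseline <- function(model, y_train) {
  z <- warp_forward((y_train - model$response_center) / model$response_scale,
                    model$hyper$warp)
  list(mean = mean(z), var = var(z))
}

#' Per-point standardized log-loss
#'
#' `-log p_model(y) + log p_baseline(y)` where the model density is the latent
#' Gaussian predictive evaluated at `W(y_std)` corrected by the warp
#' log-Jacobian, and the baseline is the Gaussian with the training mean and
#' variance of the warped-standardized responses, corrected by the same
#' Jacobian. Negative values mean the model beats the trivial baseline.
#'
#' @param model A `normative_model`.
#' @param design A `design_matrix` for the test subjects.
#' @param y Raw test responses.
#' @param baseline A [train_baseline()] list.
#' @return Numeric vector of per-point losses.
#' @export
standardized_log_loss <- function(model, design, y, baseline) {
  if (baseline$var <= 0) nn_stop("baseline variance must be positive")
  pred <- predict(model, design)
  y_std <- (y - model$response_center) / model$response_scale
  z <- warp_forward(y_std, model$hyper$warp)
  lj <- warp_log_jacobian(y_std, model$hyper$warp)
  lp_model <- dnorm(z, pred$latent_mean,
                    sqrt(pred$noise_var + pred$model_var), log = TRUE) + lj
  lp_base <- dnorm(z, baseline$mean, sqrt(baseline$var), log = TRUE) + lj
  -lp_model + lp_base
}

#' Mean standardized log-loss
#'
#' @inheritParams standardized_log_loss
#' @return Scalar MSLL (mean of [standardized_log_loss()]).
#' @export
msll <- function(model, design, y, baseline) {
  mean(standardized_log_loss(model, design, y, baseline))
}

#' Skew and excess kurtosis of deviation scores
#'
#' Third and fourth standardized central moments (Fisher convention;
#' excess kurtosis = kurtosis - 3). For a well-specified model both are
#' around zero on held-out data.
#'
#' @param z Numeric vector of deviations.
#' @return List with `skew` and `excess_kurtosis`.
#' @export
moments <- function(z) {
  check_finite(z, "z")
  n <- length(z)
  if (n < 4L) nn_stop("need at least 4 observations")
  m <- mean(z)
  m2 <- mean((z - m)^2)
  if (m2 == 0) nn_stop("zero-variance input")
  list(skew = mean((z - m)^3) / m2^1.5,
       excess_kurtosis = mean((z - m)^4) / m2^2 - 3)
}

# metrics for every ROI of a fitted bundle against a test cohort
evaluate_bundle <- function(bundle, train_cohort, test_cohort) {
  spec <- bundle$models[[1L]]$design_spec
  design <- build_design_matrix(test_cohort, spec)
  Y_test <- roi_matrix(test_cohort)
  Y_train <- roi_matrix(train_cohort)
  dev <- deviation_map(bundle, test_cohort)
  rows <- lapply(names(bundle$models), function(r) {
    model <- bundle$models[[r]]
    y_point <- predict_median(model, design)
    base <- train_baseline(model, Y_train[, r])
    mom <- moments(dev[, r])
    data.frame(
      roi = r,
      explained_variance = explained_variance(Y_test[, r], y_point),
      msll = msll(model, design, Y_test[, r], base),
      skew = mom$skew,
      excess_kurtosis = mom$excess_kurtosis,
      n_test = nrow(Y_test)
    )
  })
  do.call(rbind, rows)
}

#' Evaluate normative models on a held-out test set
#'
#' Per-ROI explained variance (measurement space, predictive median), mean
#' standardized log-loss against the training baseline, and skew / excess
#' kurtosis of the test-set deviation scores.
#'
#' @param bundle A `model_bundle`.
#' @param train_cohort Training cohort (for the MSLL baseline).
#' @param test_cohort Held-out cohort.
#' @return An `evaluation_report` data.frame: one row per ROI with columns
#'   `roi`, `explained_variance`, `msll`, `skew`, `excess_kurtosis`, `n_test`.
#' @export
evaluation_report <- function(bundle, train_cohort, test_cohort) {
  out <- evaluate_bundle(bundle, train_cohort, test_cohort)
  out$replicate <- 1L
  structure(out, class = c("evaluation_report", "data.frame"))
}

#' Test-set resampling of the evaluation metrics
#'
#' Assesses the stability of the evaluation metrics by repeating the
#' resampling with distinct derived seeds. By default the models are fitted
#' once on the training half and the *test* half is randomly resampled
#' (site-stratified subsets, no training subjects involved) on each replicate
#' after the first, which evaluates the full test half. `refit = TRUE`
#' instead repeats the whole split + fit + evaluate cycle per replicate.
#'
#' @param cohort A [cohort_table()].
#' @param n_replicates Number of resampled replicates (default 10).
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param test_fraction Fraction of the test half used per resample
#'   (`refit = FALSE` replicates after the first; default 0.5).
#' @param refit Refit models per replicate?
#' @param ... Passed to [fit_roi()] via [fit_normative_models()].
#' @return An `evaluation_report` with a `replicate` column.
#' @export
resampled_evaluation <- function(cohort, n_replicates = 10L, seed = 1L,
                                 test_fraction = 0.5, refit = FALSE, ...) {
  if (n_replicates < 1L) nn_stop("`n_replicates` must be >= 1")
  base_split <- split_train_test(cohort, seed = derive_seed(seed, "rep1"))
  bundle <- fit_normative_models(base_split$train, ...)
  out <- list()
  for (k in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, paste0("rep", k))
    if (refit && k > 1L) {
      split_k <- split_train_test(cohort, seed = rep_seed)
      bundle_k <- fit_normative_models(split_k$train, ...)
      res <- evaluate_bundle(bundle_k, split_k$train, split_k$test)
    } else {
      test_k <- if (k == 1L) base_split$test else {
        split_train_test(base_split$test, fraction = test_fraction,
                         seed = rep_seed)$train
      }
      res <- evaluate_bundle(bundle, base_split$train, test_k)
    }
    res$replicate <- k
    out[[k]] <- res
  }
  structure(do.call(rbind, out),
            class = c("evaluation_report", "data.frame"))
}
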