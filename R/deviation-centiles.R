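#' Deviation Z-scores for one ROI
#'
#' `Z = (W(y_std) - mu) / sqrt(sigma_d^2 + sigma_*^2)`: the standardized
#' distance of each subject's warped, training-standardized response from the
#' latent predictive mean, with the denominator combining the estimated noise
#' variance and the modeling-uncertainty variance. Under the model, Z is
#' standard normal.
#'
#' @param model A `normative_model`.
#' @param design A `design_matrix` for the scored subjects.
#' @param y Raw responses (measurement units) aligned with the design rows.
#' @return Numeric vector of Z-scores.
#' @export
deviation_scores <- function(model, design, y) {
  check_finite(y, "y")
  pred <- predict(model, design)
  if (length(y) != length(pred$latent_mean)) {
    nn_stop("length(y) must match the number of design rows")
  }
  y_std <- (y - model$response_center) / model$response_scale
  z <- warp_forward(y_std, model$hyper$warp)
  (z - pred$latent_mean) / sqrt(pred$noise_var + pred$model_var)
}

#' Deviation map for a cohort
#'
#' Applies [deviation_scores()] for every ROI model in a bundle.
#'
#' @param bundle A `model_bundle`.
#' @param cohort A [cohort_table()] containing every modelled ROI.
#' @return An object of class `deviation_map`: subjects x ROIs numeric matrix
#'   with subject ids as row names.
#' @export
deviation_map <- function(bundle, cohort) {
  stopifnot(inherits(bundle, "model_bundle"))
  spec <- bundle$models[[1L]]$design_spec
  design <- build_design_matrix(cohort, spec)
  Y <- roi_matrix(cohort)
  rois <- names(bundle$models)
  missing_rois <- setdiff(rois, colnames(Y))
  if (length(missing_rois)) {
    nn_stop("cohort lacks modelled ROI(s): ", paste(missing_rois, collapse = ", "))
  }
  Z <- vapply(rois, function(r) {
    deviation_scores(bundle$models[[r]], design, Y[, r])
  }, numeric(nrow(Y)))
  Z <- matrix(Z, nrow = nrow(Y), dimnames = list(rownames(Y), rois))
  structure(Z, class = c("deviation_map", "matrix", "array"))
}

#' Classify extreme deviations
#'
#' Strict inequalities: `Z > threshold` is a positive extreme (larger/thicker
#' than expected), `Z < -threshold` a negative extreme; a score exactly at the
#' threshold is typical.
#'
#' @param z Numeric vector or matrix of deviation scores.
#' @param threshold Positive threshold (default 2).
#' @return Character object of the same shape with values
#'   `"positive_extreme"`, `"negative_extreme"`, `"typical"`.
#' @export
classify_extreme <- function(z, threshold = 2) {
  check_positive_scalar(threshold, "threshold")
  lab <- ifelse(z > threshold, "positive_extreme",
                ifelse(z < -threshold, "negative_extreme", "typical"))
  if (is.matrix(z)) dimnames(lab) <- dimnames(z)
  lab
}

#' Centile curves in measurement space
#'
#' For each age on the grid, the level-`c` centile is
#' `unstandardize(Winv(mu + q_c * sqrt(sigma_d^2 + sigma_*^2)))` with `q_c`
#' the standard-normal quantile. The 0.5 curve is the inverse-warped latent
#' mean — the predictive median, which is the model's point prediction in
#' measurement space. `total_variance = FALSE` uses the noise variance alone.
#'
#' @param model A `normative_model`.
#' @param ages Numeric age grid (years); out-of-range ages are clamped with a
#'   warning.
#' @param sex 0 (female) or 1 (male).
#' @param site Site id, or `NA` for the reference/unseen-site baseline.
#' @param levels Centile fractions in (0, 1).
#' @param total_variance Use noise + modeling variance (default) or noise only.
#' @return An object of class `centile_curves`: data.frame with columns
#'   `roi`, `age`, `sex`, `site`, `level`, `value`.
#' @export
centile_curves <- function(model, ages, sex = 0, site = NA,
                           levels = c(0.05, 0.25, 0.5, 0.75, 0.95),
                           total_variance = TRUE) {
  if (any(levels <= 0 | levels >= 1)) nn_stop("`levels` must lie in (0, 1)")
  design <- design_for_grid(model$design_spec, ages, sex, site)
  pred <- predict(model, design)
  v <- pred$noise_var + if (total_variance) pred$model_var else 0
  out <- do.call(rbind, lapply(sort(levels), function(cl) {
    zc <- pred$latent_mean + qnorm(cl) * sqrt(v)
    data.frame(
      roi = model$roi_name, age = ages, sex = sex,
      site = ifelse(is.na(site), "<reference>", site), level = cl,
      value = warp_inverse(zc, model$hyper$warp) * model$response_scale +
        model$response_center
    )
  }))
  structure(out, class = c("centile_curves", "data.frame"))
}

#' Point predictions in measurement space
#'
#' The predictive median: inverse-warped latent mean, de-standardized.
#'
#' @param model A `normative_model`.
#' @param design A `design_matrix`.
#' @return Numeric vector of predicted responses.
#' @export
predict_median <- function(model, design) {
  pred <- predict(model, design)
  warp_inverse(pred$latent_mean, model$hyper$warp) * model$response_scale +
    model$response_center
}

#' Plot centile curves
#'
#' Minimal ggplot helper for a single ROI's centile fan, optionally overlaying
#' observed subjects.
#'
#' @param curves A `centile_curves` object.
#' @param observed Optional data.frame with `age` and `value` columns.
#' @return A ggplot object.
#' @export
plot_centiles <- function(curves, observed = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    nn_stop("plot_centiles() needs the ggplot2 package")
  }
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$age, y = .data$value,
                                            group = .data$level)) +
    ggplot2::geom_line(ggplot2::aes(linewidth = .data$level == 0.5),
                       colour = "steelblue", show.legend = FALSE) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.4, `TRUE` = 1)) +
    ggplot2::labs(x = "age (years)", y = curves$roi[1]) +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(
      data = observed, ggplot2::aes(x = .data$age, y = .data$value),
      inherit.aes = FALSE, alpha = 0.25, size = 0.5
    )
  }
  p
}
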