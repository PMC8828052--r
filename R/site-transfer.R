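#' Calibrate a trained model bundle to an unseen site
#'
#' Moment-matching in the latent Gaussian space: for each ROI, latent
#' residuals `r = W(y_std) - mu0` are computed against the zero-site-dummy
#' baseline prediction `mu0`; the site offset is `mean(r)` and the scale is
#' `SD(r) / sqrt(sigma_d^2 + mean(sigma_*^2))` — the ratio of observed to
#' expected residual spread. With fewer than `min_n_scale` calibration
#' subjects the scale is fixed at 1 (offset-only calibration) with a warning.
#'
#' @param bundle A `model_bundle`.
#' @param calibration_cohort A [cohort_table()] from a single site that was
#'   not in training.
#' @param min_n_scale Minimum calibration size for estimating the variance
#'   scale (default 25).
#' @return An object of class `site_calibration`.
#' @export
calibrate_new_site <- function(bundle, calibration_cohort, min_n_scale = 25L) {
  stopifnot(inherits(bundle, "model_bundle"))
  site <- unique(as.character(calibration_cohort$site))
  if (length(site) != 1L) {
    nn_stop("calibration cohort must come from a single site")
  }
  spec <- bundle$models[[1L]]$design_spec
  if (site %in% spec$site_levels) {
    nn_stop("site ", site, " was present in training; transfer calibration ",
            "is for unseen sites only")
  }
  n <- nrow(calibration_cohort)
  if (n == 0L) nn_stop("empty calibration cohort")
  offset_only <- n < min_n_scale
  if (offset_only) {
    warning("only ", n, " calibration subjects (< ", min_n_scale,
            "): variance scale fixed at 1", call. = FALSE)
  }
  design <- build_design_matrix(calibration_cohort, spec)
  Y <- roi_matrix(calibration_cohort)
  per_roi <- do.call(rbind, lapply(names(bundle$models), function(r) {
    model <- bundle$models[[r]]
    pred <- predict(model, design)
    y_std <- (Y[, r] - model$response_center) / model$response_scale
    res <- warp_forward(y_std, model$hyper$warp) - pred$latent_mean
    sc <- if (offset_only || n < 2L) 1 else {
      sd(res) / sqrt(pred$noise_var + mean(pred$model_var))
    }
    data.frame(roi = r, latent_offset = mean(res),
               latent_scale = max(sc, .Machine$double.eps))
  }))
  structure(
    list(site_id = site, per_roi = per_roi, n_calibration = n,
         offset_only = offset_only,
         calibration_subjects = as.character(calibration_cohort$subject_id)),
    class = "site_calibration"
  )
}

#' @export
print.site_calibration <- function(x, ...) {
  cat(sprintf("<site_calibration> site %s, n=%d%s, %d ROIs\n",
              x$site_id, x$n_calibration,
              if (x$offset_only) " (offset-only)" else "",
              nrow(x$per_roi)))
  invisible(x)
}

#' Deviation scores for a transferred (unseen) site
#'
#' Applies a [calibrate_new_site()] adjustment:
#' `Z = (W(y_std) - mu0 - mu_s) / (s_s * sqrt(sigma_d^2 + sigma_*^2))`.
#' A zero-offset, unit-scale calibration reproduces the uncalibrated scores
#' exactly. By default subjects that were used to estimate the calibration
#' are rejected (leakage guard).
#'
#' @param bundle A `model_bundle`.
#' @param calibration A `site_calibration` for the cohort's site.
#' @param new_cohort A [cohort_table()] from the calibrated site.
#' @param allow_overlap Permit scoring the calibration subjects themselves
#'   (default `FALSE`).
#' @return A `deviation_map` (subjects x ROIs).
#' @export
predict_transferred <- function(bundle, calibration, new_cohort,
                                allow_overlap = FALSE) {
  stopifnot(inherits(bundle, "model_bundle"),
            inherits(calibration, "site_calibration"))
  site <- unique(as.character(new_cohort$site))
  if (!identical(site, calibration$site_id)) {
    nn_stop("cohort site(s) [", paste(site, collapse = ", "),
            "] do not match calibration site ", calibration$site_id)
  }
  overlap <- intersect(as.character(new_cohort$subject_id),
                       calibration$calibration_subjects)
  if (length(overlap) && !allow_overlap) {
    nn_stop(length(overlap), " subject(s) appear in both the calibration and ",
            "scoring sets; evaluate on held-out subjects or set ",
            "allow_overlap = TRUE")
  }
  spec <- bundle$models[[1L]]$design_spec
  design <- build_design_matrix(new_cohort, spec)
  Y <- roi_matrix(new_cohort)
  Z <- vapply(names(bundle$models), function(r) {
    model <- bundle$models[[r]]
    pred <- predict(model, design)
    cal <- calibration$per_roi[match(r, calibration$per_roi$roi), ]
    if (anyNA(cal)) nn_stop("calibration lacks ROI ", r)
    y_std <- (Y[, r] - model$response_center) / model$response_scale
    z <- warp_forward(y_std, model$hyper$warp)
    (z - pred$latent_mean - cal$latent_offset) /
      (cal$latent_scale * sqrt(pred$noise_var + pred$model_var))
  }, numeric(nrow(Y)))
  Z <- matrix(Z, nrow = nrow(Y),
              dimnames = list(rownames(Y), names(bundle$models)))
  structure(Z, class = c("deviation_map", "matrix", "array"))
}

#' Attach a site calibration to a model bundle
#'
#' Stored additively, keyed by site id, and preserved through serialization.
#'
#' @param bundle A `model_bundle`.
#' @param calibration A `site_calibration`.
#' @return The bundle with the calibration attached.
#' @export
attach_calibration <- function(bundle, calibration) {
  stopifnot(inherits(bundle, "model_bundle"),
            inherits(calibration, "site_calibration"))
  bundle$calibrations[[calibration$site_id]] <- calibration
  bundle
}
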