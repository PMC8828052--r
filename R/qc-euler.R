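#' Per-site standardization of the Euler characteristic
#'
#' The Freesurfer Euler characteristic (EC) is a strong proxy for scan
#' quality: more negative values mean more topological defects. Because EC
#' distributions differ across scanners, each subject's mean EC (average of
#' the two hemispheres) is centred and scaled within its site:
#' `q = (mean_euler - center_site) / scale_site`, with median and normalized
#' IQR (`IQR / 1.349`) by default (robust to the heavy lower tail), or
#' mean/SD with `robust = FALSE`. Sites with fewer than 5 subjects are
#' flagged and standardized against pooled statistics with a warning; a site
#' with zero spread is flagged and its scores set to 0 (all subjects pass).
#'
#' @param cohort A [cohort_table()] with `euler_lh` and `euler_rh` columns.
#' @param robust Use median/IQR (default) instead of mean/SD.
#' @return A `qc_scores` data.frame: `subject_id`, `site`, `mean_euler`, `q`,
#'   `site_flagged`.
#' @export
standardize_euler <- function(cohort, robust = TRUE) {
  if (!all(c("euler_lh", "euler_rh") %in% names(cohort))) {
    nn_stop("cohort lacks `euler_lh`/`euler_rh` columns ",
            "(see simulate_euler_numbers() or read_cohort())")
  }
  mean_ec <- (cohort$euler_lh + cohort$euler_rh) / 2
  site <- as.character(cohort$site)
  center_fn <- if (robust) median else mean
  scale_fn <- if (robust) function(x) diff(quantile(x, c(0.25, 0.75),
                                                    names = FALSE)) / 1.349
              else sd
  q <- numeric(length(mean_ec))
  flagged <- logical(length(mean_ec))
  small_sites <- character(0)
  for (s in unique(site)) {
    idx <- which(site == s)
    if (length(idx) < 5L) {
      small_sites <- c(small_sites, s)
      ctr <- center_fn(mean_ec)
      scl <- scale_fn(mean_ec)
      flagged[idx] <- TRUE
    } else {
      ctr <- center_fn(mean_ec[idx])
      scl <- scale_fn(mean_ec[idx])
    }
    if (!is.finite(scl) || scl == 0) {
      q[idx] <- 0
      flagged[idx] <- TRUE
    } else {
      q[idx] <- (mean_ec[idx] - ctr) / scl
    }
  }
  if (length(small_sites)) {
    warning("site(s) with < 5 subjects standardized against pooled EC: ",
            paste(small_sites, collapse = ", "), call. = FALSE)
  }
  structure(
    data.frame(subject_id = as.character(cohort$subject_id), site = site,
               mean_euler = mean_ec, q = q, site_flagged = flagged,
               stringsAsFactors = FALSE),
    class = c("qc_scores", "data.frame")
  )
}

#' Apply the QC inclusion threshold
#'
#' One-sided, conservative exclusion: a subject is excluded iff
#' `q < -threshold`, i.e. only scans well into the bad (negative) tail of the
#' site-standardized EC distribution are removed. High EC indicates good
#' topology and is never a reason for exclusion.
#'
#' @param scores A `qc_scores` data.frame from [standardize_euler()].
#' @param threshold Positive threshold in robust-SD units (default 5).
#' @return The scores with logical `include` and `threshold_used` columns.
#' @export
apply_qc_threshold <- function(scores, threshold = 5) {
  check_positive_scalar(threshold, "threshold")
  scores$include <- !(scores$q < -threshold)
  scores$threshold_used <- threshold
  scores
}

#' Euler-characteristic quality control
#'
#' Convenience wrapper: [standardize_euler()] then [apply_qc_threshold()].
#'
#' @inheritParams standardize_euler
#' @inheritParams apply_qc_threshold
#' @return A QC report data.frame (subject, site, EC, q, include).
#' @export
euler_qc <- function(cohort, robust = TRUE, threshold = 5) {
  apply_qc_threshold(standardize_euler(cohort, robust = robust), threshold)
}
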