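#' Extreme-deviation proportion maps per clinical group
#'
#' For each group and ROI: the percentage of group subjects with a positive
#' extreme deviation (`Z > threshold`) and, separately, a negative extreme
#' (`Z < -threshold`). Controls drawn from the same sites as the group are
#' summarized identically for comparison.
#'
#' @param dev A `deviation_map` (subjects x ROIs).
#' @param labels Character vector of group labels aligned with the rows of
#'   `dev`.
#' @param sites Character vector of site ids aligned with the rows of `dev`
#'   (used to restrict controls to the group's sites).
#' @param control_label Label identifying control subjects.
#' @param threshold Extreme-deviation threshold (default 2).
#' @return A `group_deviation_summary` data.frame: `group`, `roi`, `group_n`,
#'   `pct_positive_extreme`, `pct_negative_extreme`, and the matched-control
#'   counterparts (`control_n`, `ctrl_pct_positive_extreme`,
#'   `ctrl_pct_negative_extreme`).
#' @export
group_extreme_proportion <- function(dev, labels, sites,
                                     control_label = "control",
                                     threshold = 2) {
  stopifnot(nrow(dev) == length(labels), nrow(dev) == length(sites))
  groups <- setdiff(unique(labels), control_label)
  if (!length(groups)) nn_stop("no non-control groups in `labels`")
  pct <- function(Z) {
    data.frame(pos = 100 * colMeans(Z > threshold),
               neg = 100 * colMeans(Z < -threshold))
  }
  out <- lapply(groups, function(g) {
    gi <- which(labels == g)
    if (!length(gi)) nn_stop("empty group ", g)
    ci <- which(labels == control_label & sites %in% unique(sites[gi]))
    gp <- pct(dev[gi, , drop = FALSE])
    cp <- if (length(ci)) pct(dev[ci, , drop = FALSE]) else
      data.frame(pos = NA_real_, neg = NA_real_)
    data.frame(
      group = g, roi = colnames(dev), group_n = length(gi),
      pct_positive_extreme = gp$pos, pct_negative_extreme = gp$neg,
      control_n = length(ci),
      ctrl_pct_positive_extreme = cp$pos, ctrl_pct_negative_extreme = cp$neg,
      row.names = NULL
    )
  })
  structure(do.call(rbind, out),
            class = c("group_deviation_summary", "data.frame"))
}

#' Mass-univariate case-control tests
#'
#' Welch's unequal-variance two-sample t-test per ROI, with
#' Benjamini-Hochberg FDR control across ROIs. Run it once on raw measures
#' and once on deviation scores to compare the two inference routes. ROIs
#' with degenerate variance in either arm are flagged, their p-value set
#' missing and excluded from the FDR correction.
#'
#' @param values Numeric subjects x ROIs matrix (raw measures or deviations).
#' @param case_idx,control_idx Row indices (or logical masks) of the two arms.
#' @param q FDR level (default 0.05).
#' @param input_space Label recorded in the result (`"raw"` or
#'   `"deviation"`).
#' @return A `case_control_result` data.frame: `roi`, `t_statistic`,
#'   `p_value`, `fdr_significant`, `degenerate`, `input_space`.
#' @export
case_control_tests <- function(values, case_idx, control_idx, q = 0.05,
                               input_space = "raw") {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("roi", seq_len(ncol(values)))
  }
  A <- values[case_idx, , drop = FALSE]
  B <- values[control_idx, , drop = FALSE]
  if (nrow(A) < 2L || nrow(B) < 2L) {
    nn_stop("need at least 2 subjects per arm")
  }
  res <- lapply(seq_len(ncol(values)), function(j) {
    tt <- tryCatch(t.test(A[, j], B[, j], var.equal = FALSE),
                   error = function(e) NULL)
    if (is.null(tt)) {
      data.frame(t_statistic = NA_real_, p_value = NA_real_, degenerate = TRUE)
    } else {
      data.frame(t_statistic = unname(tt$statistic),
                 p_value = tt$p.value, degenerate = FALSE)
    }
  })
  res <- do.call(rbind, res)
  res <- cbind(roi = colnames(values), res)
  res$fdr_significant <- bh_fdr(res$p_value, q = q)
  res$input_space <- input_space
  structure(res, class = c("case_control_result", "data.frame"))
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Step-up procedure at level `q`: with the ordered p-values, find the
#' largest rank `k` with `p_(k) <= k q / m` and reject ranks `1..k`.
#' Implemented through `stats::p.adjust(method = "BH")`; missing p-values are
#' excluded from the correction and flagged `NA`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @param q FDR level (default 0.05).
#' @return Logical vector of rejection flags (`NA` where `p` was missing).
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    nn_stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH") <= q
}

#' Transdiagnostic clinical summary
#'
#' Per clinical group: extreme-deviation proportion maps and case-control
#' Welch tests against matched (same-site) controls, run both on the raw ROI
#' measures and on the deviation scores, each FDR-corrected per map.
#'
#' @param dev A `deviation_map` for a cohort containing controls and groups.
#' @param cohort The matching [cohort_table()] (provides `group`, `site`, and
#'   raw ROI measures).
#' @param control_label Label identifying controls.
#' @param threshold Extreme-deviation threshold.
#' @param q FDR level.
#' @return A `clinical_summary` data.frame, one row per group x ROI:
#'   extreme-deviation percentages plus `t_raw`, `p_raw`, `sig_raw`, `t_dev`,
#'   `p_dev`, `sig_dev`.
#' @export
clinical_summary <- function(dev, cohort, control_label = "control",
                             threshold = 2, q = 0.05) {
  stopifnot(nrow(dev) == nrow(cohort))
  labels <- as.character(cohort$group)
  sites <- as.character(cohort$site)
  props <- group_extreme_proportion(dev, labels, sites,
                                    control_label = control_label,
                                    threshold = threshold)
  raw <- roi_matrix(cohort)[, colnames(dev), drop = FALSE]
  out <- lapply(unique(props$group), function(g) {
    gi <- which(labels == g)
    ci <- which(labels == control_label & sites %in% unique(sites[gi]))
    tr <- case_control_tests(raw, gi, ci, q = q, input_space = "raw")
    td <- case_control_tests(dev, gi, ci, q = q, input_space = "deviation")
    pr <- props[props$group == g, ]
    cbind(pr,
          data.frame(t_raw = tr$t_statistic, p_raw = tr$p_value,
                     sig_raw = tr$fdr_significant,
                     t_dev = td$t_statistic, p_dev = td$p_value,
                     sig_dev = td$fdr_significant))
  })
  structure(do.call(rbind, out),
            class = c("clinical_summary", "data.frame"))
}
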