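#' Cohort table
#'
#' Container holding one row per subject: demographic covariates (`subject_id`,
#' `age` in years, `sex` coded 0 = female / 1 = male, `site`, `group`), one
#' column per region of interest (cortical thickness in mm or subcortical
#' volume in mm³), and optionally per-hemisphere Euler characteristics
#' (`euler_lh`, `euler_rh`) for quality control.
#'
#' @param data A data.frame with the columns above.
#' @param roi_names Character vector naming the ROI measure columns of `data`.
#' @param provenance Arbitrary list recording how the table was produced
#'   (simulation config, file paths, ...).
#' @return An object of class `cohort_table` (a data.frame subclass).
#' @export
cohort_table <- function(data, roi_names, provenance = list()) {
  stopifnot(is.data.frame(data))
  required <- c("subject_id", "age", "sex", "site", "group")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    nn_stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(roi_names %in% names(data))) {
    nn_stop("roi_names not all present in data: ",
            paste(setdiff(roi_names, names(data)), collapse = ", "))
  }
  if (anyDuplicated(data$subject_id)) {
    dup <- unique(data$subject_id[duplicated(data$subject_id)])
    nn_stop("duplicate subject ids: ", paste(head(dup, 5), collapse = ", "))
  }
  roi_block <- as.matrix(data[roi_names])
  if (anyNA(roi_block) || any(!is.finite(roi_block))) {
    nn_stop("cohort ROI measures must be complete and finite ",
            "(drop incomplete rows at ingest)")
  }
  if (!all(data$sex %in% c(0, 1))) {
    nn_stop("cohort `sex` must be coded 0 (female) / 1 (male)")
  }
  structure(
    as.data.frame(data),
    roi_names = as.character(roi_names),
    provenance = provenance,
    class = c("cohort_table", "data.frame")
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_table> %d subjects, %d ROIs, %d sites, groups: %s\n",
    nrow(x), length(roi_names(x)), length(unique(x$site)),
    paste(unique(x$group), collapse = ", ")
  ))
  invisible(x)
}

#' ROI names of a cohort
#' @param cohort A [cohort_table()].
#' @return Character vector of ROI column names.
#' @export
roi_names <- function(cohort) attr(cohort, "roi_names")

#' Extract the subjects-by-ROI measurement matrix
#' @param cohort A [cohort_table()].
#' @return Numeric matrix with subject ids as row names.
#' @export
roi_matrix <- function(cohort) {
  m <- as.matrix(as.data.frame(cohort)[roi_names(cohort)])
  rownames(m) <- cohort$subject_id
  m
}

#' Subset a cohort by row index, keeping attributes
#'
#' @param cohort A [cohort_table()].
#' @param idx Integer or logical row index.
#' @return A [cohort_table()] with the selected subjects.
#' @export
cohort_subset <- function(cohort, idx) {
  cohort_table(as.data.frame(cohort)[idx, , drop = FALSE],
               roi_names = roi_names(cohort),
               provenance = attr(cohort, "provenance"))
}
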