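#' Design specification for the normative covariate basis
#'
#' Captures everything needed to rebuild the design matrix at prediction time:
#' the cubic B-spline age basis (five evenly spaced knots spanning the training
#' age range, boundary knots included among the five), the training age range,
#' the ordered site levels with the first training site as reference, and the
#' resulting column names. Serialized with every fitted model so prediction
#' reproduces the training-time basis exactly.
#'
#' @param train_cohort A [cohort_table()] of training subjects.
#' @return An object of class `design_spec`.
#' @export
make_design_spec <- function(train_cohort) {
  ages <- train_cohort$age
  if (length(unique(ages)) < 2L) {
    nn_stop("degenerate design: need at least 2 distinct training ages")
  }
  age_min <- min(ages)
  age_max <- max(ages)
  knots <- seq(age_min, age_max, length.out = 5L)
  site_levels <- as.character(unique(train_cohort$site))
  n_basis <- length(knots) + 3L - 1L  # clamped cubic: nknots + degree - 1
  cols <- c("intercept", paste0("age_bs", seq_len(n_basis)), "sex")
  if (length(site_levels) > 1L) {
    cols <- c(cols, paste0("site_", site_levels[-1L]))
  }
  structure(
    list(
      knot_positions = knots,
      spline_degree = 3L,
      age_min = age_min,
      age_max = age_max,
      site_levels = site_levels,
      reference_site = site_levels[1L],
      column_names = cols
    ),
    class = "design_spec"
  )
}

# Full clamped knot vector: boundary knots replicated degree extra times.
full_knot_vector <- function(spec) {
  k <- spec$knot_positions
  d <- spec$spline_degree
  c(rep(k[1L], d), k, rep(k[length(k)], d))
}

#' Build the normative design matrix
#'
#' Columns: intercept, cubic B-spline basis of age evaluated from the spec's
#' clamped knot vector, a 0/1 sex column, and fixed-effect site dummies against
#' the reference site. Ages outside the training range are clamped to the
#' boundary (with a warning); subjects from sites not present in the spec
#' receive all-zero site dummies and are flagged — this is the pathway used
#' when transferring a trained model to unseen sites.
#'
#' @param cohort A [cohort_table()].
#' @param spec A `design_spec` from [make_design_spec()].
#' @return An object of class `design_matrix`: list with `values` (n x p
#'   matrix), `spec`, `row_ids`, and `unknown_site_rows` (integer indices).
#' @export
build_design_matrix <- function(cohort, spec) {
  stopifnot(inherits(spec, "design_spec"))
  ages <- cohort$age
  clamped <- ages < spec$age_min | ages > spec$age_max
  if (any(clamped)) {
    warning(sprintf("%d age(s) outside training range [%g, %g] clamped to boundary",
                    sum(clamped), spec$age_min, spec$age_max), call. = FALSE)
    ages <- pmin(pmax(ages, spec$age_min), spec$age_max)
  }
  B <- splines::splineDesign(full_knot_vector(spec), ages,
                             ord = spec$spline_degree + 1L)
  site <- as.character(cohort$site)
  unknown <- which(!site %in% spec$site_levels)
  n_sites <- length(spec$site_levels)
  dummies <- matrix(0, nrow(cohort), max(n_sites - 1L, 0L))
  if (n_sites > 1L) {
    for (j in seq_len(n_sites - 1L)) {
      dummies[, j] <- as.numeric(site == spec$site_levels[j + 1L])
    }
  }
  X <- cbind(1, B, cohort$sex, dummies)
  colnames(X) <- spec$column_names
  structure(
    list(values = X, spec = spec,
         row_ids = as.character(cohort$subject_id),
         unknown_site_rows = unknown),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d x %d (%d unknown-site rows)\n",
              nrow(x$values), ncol(x$values), length(x$unknown_site_rows)))
  invisible(x)
}

# Minimal design for a prediction grid (age, sex, site); site = NA gives the
# all-zero site coding (reference-site / unseen-site baseline).
design_for_grid <- function(spec, ages, sex, site = NA) {
  df <- data.frame(
    subject_id = paste0("grid", seq_along(ages)),
    age = ages, sex = sex,
    site = ifelse(is.na(site), "<none>", site),
    group = "grid"
  )
  roi <- "dummy_roi"
  df[[roi]] <- 0
  build_design_matrix(cohort_table(df, roi), spec)
}
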