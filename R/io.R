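read_table_auto <- function(path) {
  if (!file.exists(path)) nn_stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
}

normalize_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(key))
  out[key %in% c("0", "f", "female")] <- 0
  out[key %in% c("1", "m", "male")] <- 1
  out
}

#' Read a cohort from demographic and ROI tables
#'
#' Reads one demographics table (`subject_id, age, sex, site[, group,
#' euler_lh, euler_rh]`) and one or more ROI tables in the Freesurfer
#' `aparcstats2table`/`asegstats2table` layout (subject identifier in the
#' first column, one ROI per subsequent column; comma- or tab-delimited,
#' auto-detected). Tables are inner-joined on subject id; any row with a
#' missing value in any retained column is dropped with a logged count, as
#' are rows whose sex code cannot be interpreted (accepted codes: 0/1, M/F,
#' male/female).
#'
#' @param roi_table_paths Character vector of ROI table paths.
#' @param demographics_path Path to the demographics table.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(roi_table_paths, demographics_path) {
  demo <- read_table_auto(demographics_path)
  names(demo)[1L] <- "subject_id"
  needed <- c("age", "sex", "site")
  if (!all(needed %in% names(demo))) {
    nn_stop("demographics table needs columns: ",
            paste(setdiff(needed, names(demo)), collapse = ", "))
  }
  if (!"group" %in% names(demo)) demo$group <- "control"
  demo$subject_id <- as.character(demo$subject_id)
  if (anyDuplicated(demo$subject_id)) {
    dup <- unique(demo$subject_id[duplicated(demo$subject_id)])
    nn_stop("duplicate subject ids in demographics: ",
            paste(head(dup, 5), collapse = ", "))
  }
  sex <- normalize_sex(demo$sex)
  n_bad_sex <- sum(is.na(sex) & !is.na(demo$sex))
  demo$sex <- sex
  demo$age <- as.numeric(demo$age)
  merged <- demo
  rois <- character(0)
  for (path in roi_table_paths) {
    tab <- read_table_auto(path)
    names(tab)[1L] <- "subject_id"
    tab$subject_id <- as.character(tab$subject_id)
    if (anyDuplicated(tab$subject_id)) {
      dup <- unique(tab$subject_id[duplicated(tab$subject_id)])
      nn_stop("duplicate subject ids in ", path, ": ",
              paste(head(dup, 5), collapse = ", "))
    }
    rois <- c(rois, setdiff(names(tab), "subject_id"))
    merged <- merge(merged, tab, by = "subject_id", sort = TRUE)
  }
  if (!nrow(merged)) nn_stop("no overlapping subject ids across tables")
  keep <- complete.cases(merged[c("subject_id", "age", "sex", "site",
                                  "group", rois)])
  n_dropped <- sum(!keep)
  if (n_dropped > 0 || n_bad_sex > 0) {
    message("read_cohort: dropped ", n_dropped, " incomplete row(s)",
            if (n_bad_sex) paste0(" (", n_bad_sex, " with unrecognized sex codes)"))
  }
  merged <- merged[keep, , drop = FALSE]
  rownames(merged) <- NULL
  cohort_table(merged, rois,
               provenance = list(demographics = demographics_path,
                                 roi_tables = roi_table_paths))
}

#' Write a cohort to demographic + ROI tables
#'
#' Writes the same CSV layout [read_cohort()] reads, so synthetic cohorts
#' exercise the real ingest path.
#'
#' @param cohort A [cohort_table()].
#' @param demographics_path,roi_table_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, demographics_path, roi_table_path) {
  df <- as.data.frame(cohort)
  demo_cols <- intersect(
    c("subject_id", "age", "sex", "site", "group", "euler_lh", "euler_rh",
      "planted", "ec_outlier"),
    names(df)
  )
  write.csv(df[demo_cols], demographics_path, row.names = FALSE)
  write.csv(df[c("subject_id", roi_names(cohort))], roi_table_path,
            row.names = FALSE)
  invisible(c(demographics_path, roi_table_path))
}

MODEL_FORMAT_VERSION <- "1.0"

serialize_model <- function(m) {
  list(
    roi_name = m$roi_name,
    weight_mean = as.list(m$weight_mean),
    weight_cov = m$weight_cov,
    hyper = list(alpha = m$hyper$alpha, beta = m$hyper$beta,
                 warp = list(a = m$hyper$warp$a, b = m$hyper$warp$b)),
    design_spec = unclass(m$design_spec),
    response_center = m$response_center,
    response_scale = m$response_scale,
    fit_report = m$fit_report
  )
}

deserialize_model <- function(x) {
  spec <- x$design_spec
  spec$spline_degree <- as.integer(spec$spline_degree)
  class(spec) <- "design_spec"
  wm <- unlist(x$weight_mean)
  structure(
    list(
      roi_name = x$roi_name,
      weight_mean = wm,
      weight_cov = matrix(unlist(x$weight_cov), length(wm), length(wm)),
      hyper = blr_hyperparams(x$hyper$alpha, x$hyper$beta,
                              shash_params(x$hyper$warp$a, x$hyper$warp$b)),
      design_spec = spec,
      response_center = x$response_center,
      response_scale = x$response_scale,
      fit_report = x$fit_report
    ),
    class = "normative_model"
  )
}

#' Write a model bundle to a versioned JSON file
#'
#' Structured-text serialization at 17 significant digits, which round-trips
#' IEEE doubles exactly: save, load and predict reproduces predictions
#' bit-identically. Site calibrations attached to the bundle are preserved.
#'
#' @param bundle A `model_bundle`.
#' @param path Output path (conventionally `.json`).
#' @return Invisibly, `path`.
#' @export
write_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  payload <- list(
    format_version = bundle$format_version,
    metadata = bundle$metadata,
    models = lapply(bundle$models, serialize_model),
    calibrations = lapply(bundle$calibrations, function(cal) {
      list(site_id = cal$site_id,
           per_roi = cal$per_roi,
           n_calibration = cal$n_calibration,
           offset_only = cal$offset_only,
           calibration_subjects = cal$calibration_subjects)
    })
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a model bundle from a JSON file
#'
#' @param path Path written by [write_model()].
#' @return A `model_bundle`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) nn_stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  payload <- tryCatch(
    jsonlite::fromJSON(txt, simplifyDataFrame = FALSE, simplifyMatrix = TRUE),
    error = function(e) {
      nn_stop("failed to parse model file '", path, "' (", nchar(txt, "bytes"),
              " bytes read): ", conditionMessage(e))
    }
  )
  if (!identical(payload$format_version, MODEL_FORMAT_VERSION)) {
    nn_stop("model file version ", payload$format_version,
            " does not match supported version ", MODEL_FORMAT_VERSION,
            "; no migration path available")
  }
  models <- lapply(payload$models, deserialize_model)
  cals <- lapply(payload$calibrations, function(x) {
    structure(
      list(site_id = x$site_id,
           per_roi = data.frame(
             roi = vapply(x$per_roi, `[[`, "", "roi"),
             latent_offset = vapply(x$per_roi, `[[`, 0, "latent_offset"),
             latent_scale = vapply(x$per_roi, `[[`, 0, "latent_scale")
           ),
           n_calibration = as.integer(x$n_calibration),
           offset_only = isTRUE(x$offset_only),
           calibration_subjects = as.character(unlist(x$calibration_subjects))),
      class = "site_calibration"
    )
  })
  structure(
    list(format_version = payload$format_version,
         models = models,
         calibrations = cals,
         metadata = payload$metadata),
    class = "model_bundle"
  )
}
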