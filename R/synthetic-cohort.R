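#' Simulation configuration for synthetic lifespan cohorts
#'
#' Defines a multi-site lifespan cohort with known ground truth. Each ROI
#' follows a smooth lifespan trajectory
#' `f(age) = c0 + c1 * exp(-age / tau) + c2 * age`
#' (decaying-exponential childhood phase plus linear adult decline), shifted by
#' a per-ROI sex offset and per-site mean offsets, with sinh-arcsinh (SHASH)
#' distributed noise: `y = f(age) + sex_offset*sex + site_offset +
#' site_scale * base_scale * roi_scale * Winv(eps; a, b)`, `eps ~ N(0,1)`.
#'
#' @param n_subjects Total number of reference subjects.
#' @param site_sizes Integer vector of per-site subject counts; must sum to
#'   `n_subjects`. Names (or `site` prefix) give site ids.
#' @param age_range Length-2 vector `(min, max)` in years, within `[2, 100]`.
#' @param trajectory_params Data.frame with one row per ROI and columns
#'   `roi`, `c0`, `c1`, `tau`, `c2`, `scale` (per-ROI noise scale multiplier,
#'   1 for thickness-like ROIs).
#' @param sex_offset Numeric per-ROI mean shift added for `sex == 1` (male).
#' @param site_offsets Numeric matrix (`n_sites` x `n_rois`) of per-site mean
#'   shifts in measurement units.
#' @param site_scales Positive numeric per-site noise multipliers.
#' @param noise_params List with SHASH skew `a`, tailweight `b > 0`, and
#'   `base_scale > 0` (noise scale in measurement units for unit `scale` ROIs).
#' @param clinical_effects Optional named list: one entry per clinical group,
#'   each `list(rois =, shift =, prevalence =, n =)` with `shift` a signed
#'   mean shift in noise-SD units applied to a `prevalence` fraction of the
#'   group's subjects in the listed ROIs only.
#' @param site_age_ranges Optional list of per-site `(min, max)` age ranges.
#' @param seed Integer seed; all randomness in the generators flows from it.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_subjects,
                              site_sizes,
                              age_range = c(2, 100),
                              trajectory_params,
                              sex_offset,
                              site_offsets,
                              site_scales,
                              noise_params = list(a = 0, b = 1, base_scale = 0.1),
                              clinical_effects = NULL,
                              site_age_ranges = NULL,
                              seed = 1L) {
  check_positive_scalar(n_subjects, "n_subjects")
  if (sum(site_sizes) != n_subjects) {
    nn_stop("`site_sizes` must sum to `n_subjects`")
  }
  if (any(site_sizes <= 0)) nn_stop("`site_sizes` must be positive")
  if (length(age_range) != 2L || age_range[1] >= age_range[2]) {
    nn_stop("`age_range` must be an ordered (min, max) pair")
  }
  if (age_range[1] < 2 || age_range[2] > 100) {
    nn_stop("`age_range` must lie within [2, 100] years")
  }
  stopifnot(is.data.frame(trajectory_params))
  needed <- c("roi", "c0", "c1", "tau", "c2", "scale")
  if (!all(needed %in% names(trajectory_params))) {
    nn_stop("`trajectory_params` needs columns: ", paste(needed, collapse = ", "))
  }
  n_rois <- nrow(trajectory_params)
  n_sites <- length(site_sizes)
  if (length(sex_offset) == 1L) sex_offset <- rep(sex_offset, n_rois)
  if (length(sex_offset) != n_rois) {
    nn_stop("`sex_offset` must have one value per ROI")
  }
  site_offsets <- as.matrix(site_offsets)
  if (!all(dim(site_offsets) == c(n_sites, n_rois))) {
    nn_stop("`site_offsets` must be an n_sites x n_rois matrix")
  }
  if (length(site_scales) != n_sites || any(site_scales <= 0)) {
    nn_stop("`site_scales` must be positive, one per site")
  }
  if (is.null(noise_params$a) || is.null(noise_params$b) ||
      is.null(noise_params$base_scale)) {
    nn_stop("`noise_params` needs fields a, b, base_scale")
  }
  if (noise_params$b <= 0) nn_stop("`noise_params$b` must be > 0")
  if (noise_params$base_scale < 0) nn_stop("`noise_params$base_scale` must be >= 0")
  if (!is.null(clinical_effects)) {
    for (g in names(clinical_effects)) {
      eff <- clinical_effects[[g]]
      bad <- setdiff(eff$rois, trajectory_params$roi)
      if (length(bad)) {
        nn_stop("clinical effect for group `", g,
                "` references unknown ROI(s): ", paste(bad, collapse = ", "))
      }
      if (eff$prevalence < 0 || eff$prevalence > 1) {
        nn_stop("clinical `prevalence` must be in [0, 1]")
      }
      if (is.null(eff$n) || eff$n < 1) nn_stop("clinical group `", g, "` needs n >= 1")
    }
  }
  site_ids <- names(site_sizes)
  if (is.null(site_ids)) site_ids <- sprintf("site%02d", seq_len(n_sites))
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_sites = n_sites,
      site_ids = site_ids,
      site_sizes = as.integer(site_sizes),
      age_range = age_range,
      trajectory_params = trajectory_params,
      sex_offset = sex_offset,
      site_offsets = site_offsets,
      site_scales = site_scales,
      noise_params = noise_params,
      clinical_effects = clinical_effects,
      site_age_ranges = site_age_ranges,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default simulation configuration
#'
#' A scaled-down analogue of a large multi-site lifespan reference cohort:
#' by default 2,000 subjects across 10 unequally sized sites spanning ages
#' 2–100, 16 cortical-thickness-like ROIs (mm scale) and 4 subcortical-volume
#' -like ROIs (mm³ scale), mildly skewed heavy-ish SHASH noise
#' (`a = 0.1`, `b = 1.05`), per-site mean offsets and noise-scale
#' heterogeneity. All per-ROI/per-site parameters are drawn reproducibly from
#' `seed`.
#'
#' @param n_subjects,n_rois,n_sites Cohort dimensions.
#' @param seed Integer seed.
#' @param noise_params SHASH noise specification (see [simulation_config()]).
#' @param clinical_effects Optional clinical group definitions.
#' @return A `sim_config`.
#' @export
default_sim_config <- function(n_subjects = 2000L, n_rois = 20L, n_sites = 10L,
                               seed = 1L,
                               noise_params = list(a = 0.1, b = 1.05,
                                                   base_scale = 0.12),
                               clinical_effects = NULL) {
  par_seed <- derive_seed(seed, "config-params")
  with_seed(par_seed, {
    n_thick <- max(n_rois - floor(n_rois / 5), 1L)
    n_vol <- n_rois - n_thick
    thick <- data.frame(
      roi = sprintf("ctx_roi%02d_thickness", seq_len(n_thick)),
      c0 = runif(n_thick, 2.0, 2.9),
      c1 = runif(n_thick, 0.4, 1.1),     # thicker cortex in childhood
      tau = runif(n_thick, 8, 25),
      c2 = runif(n_thick, -0.008, -0.002),  # linear adult thinning, mm/year
      scale = 1
    )
    traj <- thick
    if (n_vol > 0) {
      vol <- data.frame(
        roi = sprintf("subctx_roi%02d_volume", seq_len(n_vol)),
        c0 = runif(n_vol, 3500, 8000),
        c1 = runif(n_vol, -2500, -800),  # volumes rise through childhood
        tau = runif(n_vol, 5, 12),
        c2 = runif(n_vol, -18, -6),      # adult volume loss, mm^3/year
        scale = runif(n_vol, 1500, 3500) # noise ~ hundreds of mm^3
      )
      traj <- rbind(thick, vol)
    }
    w <- rexp(n_sites) + 0.3            # unequal site sizes, as in pooled cohorts
    sizes <- pmax(20L, as.integer(round(n_subjects * w / sum(w))))
    sizes[1] <- sizes[1] + (n_subjects - sum(sizes))
    if (sizes[1] < 1L) {  # pathological tiny-n corner
      sizes <- rep(n_subjects %/% n_sites, n_sites)
      sizes[1] <- sizes[1] + n_subjects - sum(sizes)
    }
    names(sizes) <- sprintf("site%02d", seq_len(n_sites))
    sex_off <- c(runif(n_thick, -0.02, 0.05),
                 if (n_vol > 0) runif(n_vol, 100, 400))  # males slightly larger
    site_off <- matrix(rnorm(n_sites * nrow(traj)), n_sites) *
      rep(0.5 * noise_params$base_scale * traj$scale, each = n_sites)
    site_sc <- runif(n_sites, 0.8, 1.25)
  })
  simulation_config(
    n_subjects = n_subjects,
    site_sizes = sizes,
    age_range = c(2, 100),
    trajectory_params = traj,
    sex_offset = sex_off,
    site_offsets = site_off,
    site_scales = site_sc,
    noise_params = noise_params,
    clinical_effects = clinical_effects,
    seed = seed
  )
}

# ground-truth trajectory
trajectory_mean <- function(traj_row, age) {
  traj_row$c0 + traj_row$c1 * exp(-age / traj_row$tau) + traj_row$c2 * age
}

# generate n subjects' covariates + ROI block for given site indices
simulate_block <- function(config, site_idx, id_prefix, group) {
  n <- length(site_idx)
  traj <- config$trajectory_params
  n_rois <- nrow(traj)
  ranges <- lapply(seq_len(config$n_sites), function(s) {
    if (!is.null(config$site_age_ranges)) config$site_age_ranges[[s]]
    else config$age_range
  })
  age <- vapply(site_idx, function(s) runif(1, ranges[[s]][1], ranges[[s]][2]),
                numeric(1))
  sex <- rbinom(n, 1L, 0.5)
  wp <- shash_params(config$noise_params$a, config$noise_params$b)
  eps <- matrix(rnorm(n * n_rois), n, n_rois)
  noise <- warp_inverse(eps, wp)
  Y <- matrix(0, n, n_rois)
  for (r in seq_len(n_rois)) {
    Y[, r] <- trajectory_mean(traj[r, ], age) +
      config$sex_offset[r] * sex +
      config$site_offsets[site_idx, r] +
      config$site_scales[site_idx] * config$noise_params$base_scale *
        traj$scale[r] * noise[, r]
  }
  colnames(Y) <- traj$roi
  df <- data.frame(
    subject_id = sprintf("%s%05d", id_prefix, seq_len(n)),
    age = age, sex = sex,
    site = config$site_ids[site_idx],
    group = group,
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(Y))
}

#' Simulate a reference cohort
#'
#' Draws the control (reference) cohort defined by a [simulation_config()].
#' Deterministic given the config's seed: the same config yields a
#' byte-identical cohort.
#'
#' @param config A `sim_config`.
#' @return A [cohort_table()] with `group == "control"` throughout.
#' @export
simulate_reference_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "reference"), {
    site_idx <- rep(seq_len(config$n_sites), times = config$site_sizes)
    df <- simulate_block(config, site_idx, "sub", "control")
  })
  cohort_table(df, config$trajectory_params$roi,
               provenance = list(config_hash = config_hash(config),
                                 seed = config$seed, kind = "reference"))
}

#' Simulate clinical groups alongside controls
#'
#' Returns the reference controls plus one labelled block per clinical group.
#' Within a group, a `prevalence` fraction of subjects (the "planted"
#' subjects, recorded in the hidden `planted` column) receives the signed mean
#' shift — expressed in noise-SD units and converted through the SHASH noise
#' SD — in the affected ROI subset only. Group subjects are drawn from the
#' same sites as controls.
#'
#' @param config A `sim_config` with non-empty `clinical_effects`.
#' @return A [cohort_table()] with a logical `planted` column.
#' @export
simulate_clinical_groups <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$clinical_effects) || !length(config$clinical_effects)) {
    nn_stop("`config$clinical_effects` is empty")
  }
  controls <- as.data.frame(simulate_reference_cohort(config))
  controls$planted <- FALSE
  noise_sd_unit <- shash_noise_moments(
    shash_params(config$noise_params$a, config$noise_params$b))$sd
  traj <- config$trajectory_params
  blocks <- list(controls)
  for (g in names(config$clinical_effects)) {
    eff <- config$clinical_effects[[g]]
    with_seed(derive_seed(config$seed, paste0("clinical-", g)), {
      site_idx <- sample(rep(seq_len(config$n_sites), length.out = eff$n))
      df <- simulate_block(config, site_idx, paste0(gsub("[^a-zA-Z0-9]", "", g), "-"), g)
      planted <- runif(eff$n) < eff$prevalence
      for (roi in eff$rois) {
        r <- match(roi, traj$roi)
        shift_abs <- eff$shift * noise_sd_unit *
          config$site_scales[site_idx] * config$noise_params$base_scale *
          traj$scale[r]
        df[[roi]] <- df[[roi]] + ifelse(planted, shift_abs, 0)
      }
      df$planted <- planted
    })
    blocks[[length(blocks) + 1L]] <- df
  }
  out <- do.call(rbind, blocks)
  cohort_table(out, traj$roi,
               provenance = list(config_hash = config_hash(config),
                                 seed = config$seed, kind = "clinical"))
}

#' Simulate per-subject Euler characteristics
#'
#' Adds integer left/right-hemisphere Euler characteristics with per-site
#' locations and scales (EC distributions differ across scanners), plus a
#' planted fraction of strongly more-negative outliers per site emulating
#' low-quality reconstructions. The planted flags are kept in the hidden
#' `ec_outlier` column as ground truth for QC evaluation.
#'
#' @param cohort A [cohort_table()].
#' @param site_ec_params Optional data.frame (`site`, `mean`, `sd`); defaults
#'   are drawn reproducibly from `seed` with means in `[-150, -20]` and SDs in
#'   `[15, 40]`.
#' @param outlier_fraction Fraction in `[0, 0.5)` of subjects per site planted
#'   as outliers.
#' @param outlier_shift Outlier location shift in per-site SD units
#'   (default -10).
#' @param seed Integer seed.
#' @return The cohort with `euler_lh`, `euler_rh`, `ec_outlier` columns.
#' @export
simulate_euler_numbers <- function(cohort, site_ec_params = NULL,
                                   outlier_fraction = 0, outlier_shift = -10,
                                   seed = 1L) {
  if (outlier_fraction < 0 || outlier_fraction >= 0.5) {
    nn_stop("`outlier_fraction` must be in [0, 0.5)")
  }
  sites <- unique(as.character(cohort$site))
  with_seed(derive_seed(seed, "euler"), {
    if (is.null(site_ec_params)) {
      site_ec_params <- data.frame(
        site = sites,
        mean = runif(length(sites), -150, -20),
        sd = runif(length(sites), 15, 40)
      )
    }
    df <- as.data.frame(cohort)
    df$euler_lh <- NA_integer_
    df$euler_rh <- NA_integer_
    df$ec_outlier <- FALSE
    for (s in sites) {
      idx <- which(df$site == s)
      p <- site_ec_params[match(s, site_ec_params$site), ]
      if (anyNA(p)) nn_stop("no EC parameters for site ", s)
      n_out <- round(outlier_fraction * length(idx))
      out_idx <- if (n_out > 0) sample(idx, n_out) else integer(0)
      mu <- rep(p$mean, length(idx))
      mu[match(out_idx, idx)] <- p$mean + outlier_shift * p$sd
      df$euler_lh[idx] <- as.integer(round(rnorm(length(idx), mu, p$sd)))
      df$euler_rh[idx] <- as.integer(round(rnorm(length(idx), mu, p$sd)))
      df$ec_outlier[out_idx] <- TRUE
    }
  })
  cohort_table(df, roi_names(cohort), provenance = attr(cohort, "provenance"))
}
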