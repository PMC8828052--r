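test_that("config validation names the offending field", {
  traj <- data.frame(roi = "r1", c0 = 1, c1 = 1, tau = 10, c2 = 0, scale = 1)
  ok <- list(n_subjects = 10, site_sizes = c(a = 5, b = 5),
             trajectory_params = traj, sex_offset = 0,
             site_offsets = matrix(0, 2, 1), site_scales = c(1, 1))
  expect_s3_class(do.call(simulation_config, ok), "sim_config")
  bad <- ok; bad$site_sizes <- c(a = 4, b = 5)
  expect_error(do.call(simulation_config, bad), "site_sizes")
  bad <- ok; bad$site_scales <- c(1, -1)
  expect_error(do.call(simulation_config, bad), "site_scales")
  bad <- ok; bad$age_range <- c(50, 20)
  expect_error(do.call(simulation_config, bad), "age_range")
  bad <- ok; bad$noise_params <- list(a = 0, b = -1, base_scale = 1)
  expect_error(do.call(simulation_config, bad), "b")
  bad <- ok
  bad$clinical_effects <- list(g = list(rois = "nope", shift = 1,
                                        prevalence = 1, n = 5))
  expect_error(do.call(simulation_config, bad), "unknown ROI")
})

test_that("zero-noise limit reproduces the ground-truth trajectory exactly", {
  cfg <- default_sim_config(100, 3, 2, seed = 21,
                            noise_params = list(a = 0, b = 1, base_scale = 0))
  co <- simulate_reference_cohort(cfg)
  traj <- cfg$trajectory_params
  for (r in seq_len(3)) {
    expected <- traj$c0[r] + traj$c1[r] * exp(-co$age / traj$tau[r]) +
      traj$c2[r] * co$age + cfg$sex_offset[r] * co$sex +
      cfg$site_offsets[match(co$site, cfg$site_ids), r]
    expect_equal(unname(roi_matrix(co)[, r]), expected, tolerance = 1e-12)
  }
})

test_that("identical seed and config give byte-identical cohorts", {
  cfg <- default_sim_config(150, 3, 3, seed = 33)
  expect_identical(simulate_reference_cohort(cfg),
                   simulate_reference_cohort(cfg))
  cfg2 <- default_sim_config(150, 3, 3, seed = 34)
  expect_false(identical(simulate_reference_cohort(cfg)$age,
                         simulate_reference_cohort(cfg2)$age))
})

test_that("residual skewness matches a direct Monte-Carlo of the inverse warp", {
  n <- 20000
  traj <- data.frame(roi = "r1", c0 = 2.5, c1 = 0.8, tau = 15, c2 = -0.004,
                     scale = 1)
  cfg <- simulation_config(
    n_subjects = n, site_sizes = c(only = n), trajectory_params = traj,
    sex_offset = 0, site_offsets = matrix(0, 1, 1), site_scales = 1,
    noise_params = list(a = 0.8, b = 0.7, base_scale = 0.1), seed = 77
  )
  co <- simulate_reference_cohort(cfg)
  f <- traj$c0 + traj$c1 * exp(-co$age / traj$tau) + traj$c2 * co$age
  resid <- roi_matrix(co)[, 1] - f
  set.seed(101)
  mc <- warp_inverse(rnorm(n), shash_params(0.8, 0.7))
  expect_equal(sample_skewness(resid), sample_skewness(mc), tolerance = 0.15)
  expect_gt(sample_skewness(resid), 1)  # strongly right-skewed by construction
})

test_that("Gaussian noise setting passes a normality test and recovers site offsets", {
  cfg <- default_sim_config(5000, 2, 4, seed = 55,
                            noise_params = list(a = 0, b = 1, base_scale = 0.12))
  co <- simulate_reference_cohort(cfg)
  traj <- cfg$trajectory_params
  r <- 1
  f <- traj$c0[r] + traj$c1[r] * exp(-co$age / traj$tau[r]) +
    traj$c2[r] * co$age + cfg$sex_offset[r] * co$sex
  resid <- roi_matrix(co)[, r] - f
  site_idx <- match(co$site, cfg$site_ids)
  # per-site noise scales differ, so normality holds only after rescaling
  # each site's residuals (a pooled variance mixture is correctly non-normal)
  pure <- (resid - cfg$site_offsets[site_idx, r]) / cfg$site_scales[site_idx]
  expect_gt(jarque_bera_p(pure), 0.01)
  for (s in seq_len(4)) {
    rs <- resid[site_idx == s]
    se <- sd(rs) / sqrt(length(rs))
    expect_lt(abs(mean(rs) - cfg$site_offsets[s, r]), 3 * se)
  }
})

test_that("null clinical shift is indistinguishable from controls", {
  rejections <- 0
  for (k in 1:40) {
    traj <- data.frame(roi = "r1", c0 = 2.5, c1 = 0.5, tau = 12, c2 = -0.003,
                       scale = 1)
    cfg <- simulation_config(
      n_subjects = 400, site_sizes = c(s1 = 200, s2 = 200),
      trajectory_params = traj, sex_offset = 0,
      site_offsets = matrix(0, 2, 1), site_scales = c(1, 1),
      noise_params = list(a = 0.2, b = 1, base_scale = 0.1),
      clinical_effects = list(null_grp = list(rois = "r1", shift = 0,
                                              prevalence = 1, n = 200)),
      seed = 1000 + k
    )
    co <- simulate_clinical_groups(cfg)
    # compare age-detrended residuals so only the (absent) shift matters
    f <- traj$c0 + traj$c1 * exp(-co$age / traj$tau) + traj$c2 * co$age
    resid <- roi_matrix(co)[, 1] - f
    p <- t.test(resid[co$group == "null_grp"], resid[co$group == "control"])$p.value
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 3)  # ~0.4 expected under the null
})

test_that("planted clinical shifts have the configured size, localization and prevalence", {
  traj <- data.frame(roi = c("hit", "spared"), c0 = c(2.5, 2.7),
                     c1 = c(0.5, 0.6), tau = c(12, 14), c2 = c(-0.003, -0.004),
                     scale = c(1, 1))
  cfg <- simulation_config(
    n_subjects = 4000, site_sizes = c(s1 = 4000), trajectory_params = traj,
    sex_offset = c(0, 0), site_offsets = matrix(0, 1, 2), site_scales = 1,
    noise_params = list(a = 0, b = 1, base_scale = 0.1),
    clinical_effects = list(
      grp = list(rois = "hit", shift = -3, prevalence = 1, n = 4000),
      half = list(rois = "hit", shift = -3, prevalence = 0.5, n = 2000)
    ),
    seed = 91
  )
  co <- simulate_clinical_groups(cfg)
  f <- function(r, age) traj$c0[r] + traj$c1[r] * exp(-age / traj$tau[r]) +
    traj$c2[r] * age
  resid_hit <- roi_matrix(co)[, "hit"] - f(1, co$age)
  resid_sp <- roi_matrix(co)[, "spared"] - f(2, co$age)
  ctrl <- co$group == "control"; grp <- co$group == "grp"; half <- co$group == "half"
  # -3 noise-SD shift in the affected ROI only (noise SD = base_scale here)
  shift_hat <- mean(resid_hit[grp]) - mean(resid_hit[ctrl])
  expect_equal(shift_hat / 0.1, -3, tolerance = 0.15)
  expect_lt(abs(mean(resid_sp[grp]) - mean(resid_sp[ctrl])), 0.01)
  # prevalence respected within binomial error
  frac <- mean(co$planted[half])
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / sum(half)))
  expect_error(simulate_clinical_groups(default_sim_config(50, 2, 2)), "empty")
})

test_that("Euler characteristics have per-site locations and planted outliers", {
  co <- tiny_cohort(2000, 2, 2, seed = 8)
  params <- data.frame(site = c("site01", "site02"), mean = c(-20, -120),
                       sd = c(10, 10))
  clean <- simulate_euler_numbers(co, params, outlier_fraction = 0, seed = 2)
  expect_false(any(clean$ec_outlier))
  for (s in params$site) {
    ec <- (clean$euler_lh + clean$euler_rh)[clean$site == s] / 2
    se <- sd(ec) / sqrt(length(ec))
    expect_lt(abs(mean(ec) - params$mean[params$site == s]), 2 * se)
  }
  dirty <- simulate_euler_numbers(co, params, outlier_fraction = 0.05, seed = 2)
  for (s in params$site) {
    n_s <- sum(co$site == s)
    expect_equal(sum(dirty$ec_outlier[dirty$site == s]), round(0.05 * n_s))
  }
  expect_error(simulate_euler_numbers(co, params, outlier_fraction = 0.6),
               "outlier_fraction")
  expect_identical(simulate_euler_numbers(co, params, 0.05, seed = 2),
                   simulate_euler_numbers(co, params, 0.05, seed = 2))
})
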