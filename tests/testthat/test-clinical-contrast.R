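test_that("null extreme-deviation maps sit at the 2.28% normal tail", {
  set.seed(51)
  Z <- matrix(rnorm(10000 * 10), 10000, 10,
              dimnames = list(NULL, paste0("roi", 1:10)))
  labels <- rep(c("grp", "control"), each = 5000)
  sites <- rep("s1", 10000)
  gs <- group_extreme_proportion(Z, labels, sites)
  se_pct <- 100 * sqrt(0.0228 * 0.9772 / 5000)
  expect_true(all(abs(gs$pct_positive_extreme - 2.28) < 4 * se_pct))
  expect_true(all(abs(gs$pct_negative_extreme - 2.28) < 4 * se_pct))
  expect_lt(abs(mean(gs$pct_positive_extreme) - 2.28), 3 * se_pct / sqrt(10))
  expect_equal(unique(gs$group_n), 5000)
})

test_that("proportion maps localize planted shifts and count single subjects correctly", {
  set.seed(52)
  n <- 400
  Z <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("roi", 1:20)))
  labels <- rep(c("grp", "control"), each = n / 2)
  Z[labels == "grp", 1:10] <- Z[labels == "grp", 1:10] - 3
  gs <- group_extreme_proportion(Z, labels, rep("s1", n))
  expect_true(all(gs$pct_negative_extreme[1:10] > 50))
  expect_true(all(gs$pct_negative_extreme[11:20] < 10))
  # single-subject group
  Z1 <- matrix(c(3, 0.5), 1, 2, dimnames = list(NULL, c("rA", "rB")))
  Zc <- rbind(Z1, matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("rA", "rB"))))
  g1 <- group_extreme_proportion(Zc, c("g", rep("control", 10)), rep("s", 11))
  expect_equal(g1$pct_positive_extreme[g1$roi == "rA"], 100)
  expect_equal(g1$pct_positive_extreme[g1$roi == "rB"], 0)
  expect_error(group_extreme_proportion(Z, rep("control", n), rep("s1", n)),
               "no non-control")
})

test_that("Welch statistics match the direct formula and identical arms give t = 0", {
  x <- c(2.1, 2.5, 2.3, 2.8, 2.2, 2.6)
  y <- c(2.0, 2.4, 2.9, 2.1, 2.2, 2.35)
  vals <- cbind(roiA = c(x, y), roiB = c(y, x))
  res <- case_control_tests(vals, 1:6, 7:12)
  o <- welch_oracle(x, y)
  expect_equal(res$t_statistic[1], o$t, tolerance = 1e-10)
  expect_equal(res$p_value[1], o$p, tolerance = 1e-10)
  same <- case_control_tests(cbind(r = c(x, x)), 1:6, 7:12)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  # degenerate variance is flagged and excluded from FDR
  degen <- case_control_tests(cbind(r1 = rep(1, 12), r2 = c(x, y)), 1:6, 7:12)
  expect_true(degen$degenerate[1])
  expect_true(is.na(degen$p_value[1]) && is.na(degen$fdr_significant[1]))
  expect_false(is.na(degen$p_value[2]))
})

test_that("type-I error of the per-ROI tests is near nominal under the null", {
  set.seed(53)
  vals <- matrix(rnorm(60 * 1000), 60, 1000)
  res <- case_control_tests(vals, 1:30, 31:60)
  frac <- mean(res$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("BH flags equal brute-force step-up enumeration", {
  expect_equal(bh_fdr(rep(1, 7)), rep(FALSE, 7))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  expect_equal(bh_fdr(p, 0.05), bh_brute(p, 0.05))
  expect_equal(which(bh_fdr(p, 0.05)), 1:2)  # p_(3)=0.039 > 3q/m=0.03
  set.seed(54)
  for (k in 1:200) {
    m <- sample(1:40, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    if (k %% 5 == 0) p[sample(m, 1)] <- NA
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(bh_fdr(p, q), as.logical(bh_brute(p, q)))
  }
  # rejection set is a down-set in p-order
  set.seed(55)
  p <- runif(50)^2
  rej <- bh_fdr(p, 0.1)
  if (any(rej)) expect_true(all(p[rej] <= min(p[!rej])) ||
                              max(p[rej]) <= min(p[!rej]))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("expected false discovery proportion stays at or below q under a global null", {
  set.seed(56)
  fdp <- replicate(500, {
    p <- runif(20)
    mean(bh_fdr(p, 0.05))
  })
  expect_lte(mean(fdp), 0.05 + 3 * sd(fdp) / sqrt(500))
})

test_that("deviation-space tests beat raw-space tests when site offsets dominate", {
  # constructed scenario: large between-site mean offsets inflate raw-space
  # variance; deviations remove the site means, concentrating power
  set.seed(57)
  n_sites <- 6; per_site <- 40; n <- n_sites * per_site
  n_rois <- 20; planted <- 1:5
  site <- rep(seq_len(n_sites), each = per_site)
  site_off <- rnorm(n_sites, 0, 3)
  sens <- function() {
    hits_dev <- 0; hits_raw <- 0
    for (rep in 1:10) {
      raw <- matrix(rnorm(2 * n * n_rois), 2 * n, n_rois) +
        site_off[rep(site, 2)]
      lab <- rep(c("case", "control"), each = n)
      raw[lab == "case", planted] <- raw[lab == "case", planted] + 0.4
      dev <- raw
      for (s in seq_len(n_sites)) {  # site-centred analogue of deviations
        idx <- rep(site, 2) == s & lab == "control"
        all_idx <- rep(site, 2) == s
        dev[all_idx, ] <- sweep(raw[all_idx, ], 2, colMeans(raw[idx, ]))
      }
      r_raw <- case_control_tests(raw, which(lab == "case"),
                                  which(lab == "control"))
      r_dev <- case_control_tests(dev, which(lab == "case"),
                                  which(lab == "control"))
      hits_raw <- hits_raw + sum(r_raw$fdr_significant[planted])
      hits_dev <- hits_dev + sum(r_dev$fdr_significant[planted])
    }
    c(raw = hits_raw, dev = hits_dev)
  }
  h <- sens()
  expect_gte(h["dev"], h["raw"])
  expect_gt(h["dev"], 0)
})

test_that("clinical summary combines proportions with dual-space tests per group", {
  co <- tiny_cohort(600, 2, 2, seed = 59)
  b <- quick_bundle(co)
  df <- as.data.frame(co)
  df$group[1:80] <- "patientA"
  co2 <- cohort_table(df, roi_names(co))
  dev <- deviation_map(b, co2)
  # plant a strong negative shift in ROI 1 for the patient group
  summ0 <- clinical_summary(dev, co2)
  expect_setequal(unique(summ0$group), "patientA")
  expect_equal(nrow(summ0), 2)
  dev[1:80, 1] <- dev[1:80, 1] - 3
  summ <- clinical_summary(dev, co2)
  r1 <- summ[summ$roi == roi_names(co)[1], ]
  r2 <- summ[summ$roi == roi_names(co)[2], ]
  expect_gt(r1$pct_negative_extreme, 50)
  expect_lt(r2$pct_negative_extreme, 15)
  expect_true(r1$sig_dev)
  expect_true(all(c("t_raw", "p_raw", "sig_raw", "t_dev", "p_dev", "sig_dev")
                  %in% names(summ)))
})
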