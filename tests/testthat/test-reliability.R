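test_that("inter-subject ICC maps honour the consistency trivial cases", {
  set.seed(2)
  r1 <- matrix(rnorm(50 * 6), 50, 6)
  m_same <- inter_subject_icc_map(r1, r1)
  expect_true(all(m_same$icc[m_same$defined] == 1))
  m_shift <- inter_subject_icc_map(r1, r1 + 5)
  expect_equal(m_shift$icc[m_shift$defined], rep(1, sum(m_shift$defined)),
               tolerance = 1e-10)
  # a constant-across-subjects voxel is flagged undefined, not zero-filled
  r1[3, ] <- 7
  r2 <- r1
  expect_message(m <- inter_subject_icc_map(r1, r2), "undefined")
  expect_true(is.na(m$icc[3]))
  expect_false(m$defined[3])
  expect_equal(m$n_undefined, 1)
})

test_that("vectorised voxelwise ICC equals the scalar ICC(3,1) route", {
  set.seed(9)
  r1 <- matrix(rnorm(20 * 8), 20, 8)
  r2 <- matrix(rnorm(20 * 8), 20, 8)
  map <- inter_subject_icc_map(r1, r2)
  for (v in c(1, 7, 20)) {
    expect_equal(map$icc[v], icc_31(cbind(r1[v, ], r2[v, ]))$icc,
                 tolerance = 1e-12)
  }
})

test_that("the post-state ICC map converges to the variance-component oracle", {
  # sigma_b2 + sigma_g2 = 9, sigma_e2 = 1 -> expected post-state ICC 0.9
  vc <- variance_components(grand_mean = 50, sigma_b2 = 8, sigma_s2 = 1,
                            sigma_g2 = 1, sigma_w2 = 0, delta = 4)
  ds <- simulate_study(study_design(200, 2, c(10, 10, 4)), vc, seed = 41,
                       network_frac = 1, keep_latent = FALSE)
  sm <- session_means(ds)
  expect_lt(abs(median_icc(state_icc_map(sm, "post"), ds$network_mask) - 0.9),
            0.03)
  expect_lt(abs(median_icc(state_icc_map(sm, "pre"), ds$network_mask) - 8 / 9),
            0.03)
})

test_that("median ICC summarises defined voxels per stratum", {
  map <- structure(list(icc = c(0.2, 0.5, 0.8, NA), defined = c(TRUE, TRUE, TRUE, FALSE),
                        mask = rep(TRUE, 4), n_targets = 10L, k = 2L,
                        n_undefined = 1L), class = "icc_map")
  expect_equal(median_icc(map), 0.5)
  expect_equal(median_icc(map, c(FALSE, TRUE, TRUE, TRUE)), 0.65)
  expect_error(median_icc(map, c(FALSE, FALSE, FALSE, TRUE)), "Empty stratum")
})

test_that("ICC distributions normalise, locate the median and sign the skew", {
  set.seed(4)
  vals <- runif(1e4, 0, 1) # symmetric around 0.5
  map <- structure(list(icc = vals, defined = rep(TRUE, 1e4),
                        mask = rep(TRUE, 1e4), n_targets = 10L, k = 2L,
                        n_undefined = 0L), class = "icc_map")
  d <- icc_distribution(map, bins = 40, stratum = "gm")
  expect_equal(sum(d$bins$fraction), 1)
  expect_lt(abs(d$skewness), 0.05)
  expect_gte(d$median, min(vals))
  expect_lte(d$median, max(vals))
  # mass piled against 1 gives a negative skew
  vals2 <- c(0.5, 0.9, 0.95, 1.0)
  map2 <- structure(list(icc = vals2, defined = rep(TRUE, 4),
                         mask = rep(TRUE, 4), n_targets = 10L, k = 2L,
                         n_undefined = 0L), class = "icc_map")
  d2 <- icc_distribution(map2, bins = 50)
  expect_lt(d2$skewness, 0)
  # matches a direct computation of the sample skew
  g1 <- mean((vals2 - mean(vals2))^3) / mean((vals2 - mean(vals2))^2)^1.5
  expect_equal(d2$skewness, g1)
  expect_error(icc_distribution(map2, c(TRUE, FALSE, FALSE, FALSE)), "2 defined")
})

test_that("intra-voxel ICC follows the variance-ratio oracle", {
  a0 <- rep(c(1, 5, 9), length.out = 12)
  expect_equal(within_subject_iccv(a0, a0)$icc, 1)
  expect_equal(within_subject_iccv(a0, a0)$sem, 0)
  expect_equal(within_subject_iccv(a0, a0 + 3)$icc, 1, tolerance = 1e-12)
  set.seed(6)
  mu <- rnorm(1e4, 50, 10) # between-voxel SD 10
  va <- mu + rnorm(1e4) # iid measurement noise SD 1
  vb <- mu + rnorm(1e4)
  expect_equal(within_subject_iccv(va, vb)$icc, 100 / 101, tolerance = 0.01)
  r <- within_subject_iccv(rep(2, 10), rep(2, 10))
  expect_true(r$undefined)
  expect_error(within_subject_iccv(1, 2), "2 voxels")
})

test_that("intra-session scan pairs are exchangeable and beat inter-session ICC_v", {
  # one big ROI; session effects shared within a session, so (1,3) and (1,6)
  # have the same expected ICC_v while session means differ more
  vc <- variance_components(grand_mean = 50, sigma_b2 = 25, sigma_s2 = 9,
                            sigma_g2 = 0, sigma_w2 = 4, delta = 0)
  d <- study_design(4, 6, c(25, 20, 20))
  big_roi <- list(ALL = array(TRUE, d$vol_dim))
  ds <- simulate_study(d, vc, seed = 19, roi_masks = big_roi,
                       keep_latent = FALSE)
  intra <- intra_session_iccv(ds, roi_masks = big_roi)
  by_pair <- summarise_iccv(intra, by = "pair")
  expect_lt(abs(by_pair$icc[by_pair$pair == "1v3"] -
                  by_pair$icc[by_pair$pair == "1v6"]), 0.02)
  inter <- inter_session_iccv(ds, "post", roi_masks = big_roi)
  expect_gt(mean(intra$icc), mean(inter$icc))
  # analytic check: intra ~ (25+9)/38, inter ~ 25/(25+9+4/6)
  expect_equal(mean(intra$icc), 34 / 38, tolerance = 0.02)
  expect_equal(mean(inter$icc), 25 / (25 + 9 + 4 / 6), tolerance = 0.02)
})

test_that("median state ICC decreases as session error variance grows", {
  set.seed(55)
  med_at <- function(s2) {
    vals <- replicate(100, {
      vc <- variance_components(grand_mean = 50, sigma_b2 = 4, sigma_s2 = s2,
                                sigma_g2 = 1, sigma_w2 = 0, delta = 2)
      ds <- simulate_study(study_design(16, 2, c(5, 5, 2)), vc,
                           seed = sample.int(1e6, 1), network_frac = 1,
                           keep_latent = FALSE)
      median_icc(state_icc_map(session_means(ds), "post"), ds$network_mask)
    })
    mean(vals)
  }
  meds <- vapply(c(0.5, 1, 2), med_at, numeric(1))
  expect_true(all(diff(meds) < 0))
})

test_that("run_reliability produces a well-formed, reproducible report", {
  d <- study_design(8, 3, c(6, 6, 3))
  make <- function() {
    ds <- simulate_study(d, seed = 77)
    vas <- simulate_vas(d, seed = 78)
    quietly(run_reliability(ds, vas, scan_pairs = list(c(1, 3))))
  }
  rep1 <- make()
  expect_s3_class(rep1, "reliability_report")
  expect_equal(nrow(rep1$med_icc), 6 * (2 + 10)) # 6 analyses x (gm, network, 10 ROIs)
  # stratum nesting: the network stratum uses only GM voxels
  gm_n <- rep1$med_icc$n_voxels[rep1$med_icc$stratum == "gm"]
  nw_n <- rep1$med_icc$n_voxels[rep1$med_icc$stratum == "network"]
  expect_true(all(nw_n <= gm_n))
  # state reliability beats delta-pair reliability (sigma_b2 > sigma_g2)
  med <- rep1$med_icc
  expect_gt(med$med_icc[med$analysis == "post" & med$stratum == "gm"],
            med$med_icc[med$analysis == "delta_pairs" & med$stratum == "gm"])
  # byte-identical serialization under a fixed seed
  t1 <- file.path(tempfile(), "a"); t2 <- file.path(tempfile(), "b")
  write_report(rep1, t1, volumes = FALSE)
  write_report(make(), t2, volumes = FALSE)
  for (f in list.files(t1)) {
    expect_identical(readLines(file.path(t1, f)), readLines(file.path(t2, f)))
  }
  expect_gt(length(list.files(t1)), 4)
})

test_that("a noise-free dataset yields perfect or undefined ICCs but a valid report", {
  vc <- variance_components(grand_mean = 40, sigma_b2 = 4, sigma_s2 = 0,
                            sigma_g2 = 1, sigma_w2 = 0, delta = 5)
  ds <- simulate_study(study_design(6, 2, c(4, 4, 2)), vc, seed = 9)
  rep0 <- quietly(run_reliability(ds))
  expect_s3_class(rep0$med_icc, "tbl_df")
  ok <- !is.na(rep0$med_icc$med_icc)
  expect_true(all(abs(rep0$med_icc$med_icc[ok] - 1) < 1e-8))
})
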