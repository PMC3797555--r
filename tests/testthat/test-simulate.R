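test_that("degenerate components give a flat dataset equal to the grand mean", {
  vc <- variance_components(grand_mean = 42, sigma_b2 = 0, sigma_s2 = 0,
                            sigma_g2 = 0, sigma_w2 = 0, delta = 0)
  ds <- simulate_study(study_design(4, 2, c(3, 3, 2)), vc, seed = 1)
  expect_true(all(ds$cbf == 42))
})

test_that("identical seeds reproduce datasets and VAS tables bit-identically", {
  d <- study_design(4, 3, c(3, 3, 2))
  a <- simulate_study(d, seed = 99)
  b <- simulate_study(d, seed = 99)
  expect_identical(a$cbf, b$cbf)
  expect_identical(a$network_mask, b$network_mask)
  va <- simulate_vas(d, seed = 99)
  vb <- simulate_vas(d, seed = 99)
  expect_identical(va, vb)
  # a different seed changes the data
  expect_false(identical(simulate_study(d, seed = 100)$cbf, a$cbf))
})

test_that("empirical variance components match the generator inputs", {
  # law of total variance: var of a subject's session mean = sigma_b2 + sigma_s2
  vc <- variance_components(grand_mean = 0, sigma_b2 = 9, sigma_s2 = 1,
                            sigma_g2 = 0, sigma_w2 = 0, delta = 0)
  ds <- simulate_study(study_design(2000, 2, c(2, 1, 1)), vc, seed = 3,
                       keep_latent = FALSE)
  sm <- session_means(ds)
  v <- var(as.vector(sm$values[1, , ]))
  expect_equal(v, 10, tolerance = 0.05)
  # within-session scan variance after removing the session level
  vc2 <- variance_components(grand_mean = 0, sigma_b2 = 0, sigma_s2 = 0,
                             sigma_g2 = 0, sigma_w2 = 4, delta = 0)
  ds2 <- simulate_study(study_design(500, 6, c(2, 1, 1)), vc2, seed = 4,
                        keep_latent = FALSE)
  expect_equal(var(as.vector(ds2$cbf)), 4, tolerance = 0.05)
})

test_that("masks obey the grid and nesting contracts", {
  ds <- simulate_study(study_design(4, 2, c(4, 4, 3)), seed = 1)
  expect_identical(dim(ds$gm_mask), c(4L, 4L, 3L))
  expect_true(all(!(ds$network_mask & !ds$gm_mask))) # network inside GM
  expect_equal(sum(ds$network_mask), round(0.1 * sum(ds$gm_mask)))
  expect_length(ds$roi_masks, 10)
  # ROI masks are disjoint by construction
  expect_lte(max(Reduce(`+`, lapply(ds$roi_masks, as.numeric))), 1)
  # grid violations are hard errors
  expect_error(simulate_study(study_design(4, 2, c(4, 4, 3)),
                              gm_mask = array(TRUE, c(2, 2, 2))), "grid")
  bad_net <- array(FALSE, c(4, 4, 3)); bad_net[1] <- TRUE
  gm <- array(TRUE, c(4, 4, 3)); gm[1] <- FALSE
  expect_error(simulate_study(study_design(4, 2, c(4, 4, 3)),
                              gm_mask = gm, network_mask = bad_net), "subset")
  expect_error(variance_components(sigma_b2 = -1), ">= 0")
  expect_error(study_design(vol_dim = c(0, 4, 4)), "positive")
})

test_that("closed-form expected ICCs match their defining ratios", {
  vc <- variance_components(sigma_b2 = 2, sigma_s2 = 1, sigma_g2 = 1,
                            sigma_w2 = 0)
  out <- expected_icc(vc)
  expect_equal(unname(out["delta_pair"]), 1 / 3)
  expect_equal(unname(out["delta_mean"]), 0.6)
  expect_equal(unname(out["delta_single"]), 2 / 3)
  expect_equal(unname(out["pre_state"]), 2 / 3)
  expect_equal(unname(out["post_state"]), 3 / 4)
  # no error variance: every level is 1
  vc0 <- variance_components(sigma_s2 = 0, sigma_w2 = 0)
  expect_true(all(expected_icc(vc0) == 1))
  # scan noise folds into the effective session error
  vc6 <- variance_components(sigma_b2 = 2, sigma_s2 = 0.5, sigma_g2 = 1,
                             sigma_w2 = 3)
  e <- 0.5 + 3 / 6
  expect_equal(unname(expected_icc(vc6, "delta_pair")), 1 / (1 + 2 * e))
  expect_error(expected_icc(vc, "delta_s2"), "Unknown ICC level")
})

test_that("delta-scheme expected ICCs are ordered pair < mean < single for any error", {
  set.seed(13)
  for (rep in 1:20) {
    vc <- variance_components(sigma_b2 = runif(1, 0, 10),
                              sigma_s2 = runif(1, 0.1, 5),
                              sigma_g2 = runif(1, 0.1, 5),
                              sigma_w2 = runif(1, 0, 5))
    icc <- expected_icc(vc)
    expect_lt(icc["delta_pair"], icc["delta_mean"])
    expect_lt(icc["delta_mean"], icc["delta_single"])
  }
})

test_that("Monte-Carlo difference scores reproduce the closed forms", {
  # direct session-level simulation, independent of the study generator:
  # shared-baseline error migrates into the between-target variance
  set.seed(31)
  n <- 1e5
  g <- rnorm(n)
  e22 <- rnorm(n); e24 <- rnorm(n); e23 <- rnorm(n); e25 <- rnorm(n)
  icc_of <- function(d1, d2) icc_31(cbind(d1, d2))$icc
  expect_lt(abs(icc_of(g + e23 - e22, g + e25 - e24) - 1 / 3), 0.015)
  b <- (e22 + e24) / 2
  expect_lt(abs(icc_of(g + e23 - b, g + e25 - b) - 0.6), 0.015)
  expect_lt(abs(icc_of(g + e23 - e22, g + e25 - e22) - 2 / 3), 0.015)
})

test_that("VAS generator honours the floor effect and the scanning criterion", {
  d <- study_design(8)
  vas <- simulate_vas(d, seed = 2)
  expect_true(all(vas$pain[vas$state == "pre"] == 0))
  expect_true(all(vas$pain >= 0 & vas$pain <= 100))
  expect_true(all(vas$alertness >= 0 & vas$alertness <= 100))
  # side labels attach to post sessions only, balanced across subjects
  expect_true(all(is.na(vas$side[vas$state == "pre"])))
  expect_true(all(vas$side[vas$state == "post"] %in% c("left", "right")))
  # zero noise: every post-surgical pain rating equals the mean
  v0 <- simulate_vas(d, pain = vas_params(50, 0, 0, 0), seed = 1)
  expect_true(all(v0$pain[v0$state == "post"] == 50))
  # normal tail: with mean 60 and SD 5, >99% of post ratings exceed 30 mm
  big <- simulate_vas(study_design(840), pain = vas_params(60, 25, 0, 0),
                      seed = 5)
  post_pain <- big$pain[big$state == "post"]
  expect_gte(length(post_pain), 1e4)
  expect_gt(mean(post_pain > 30), 0.99)
  # clipping is tracked
  hot <- simulate_vas(d, pain = vas_params(99, 225, 0, 0), seed = 6)
  expect_gt(attr(hot, "clipped")["pain"], 0)
  expect_true(all(hot$pain <= 100))
})

test_that("side order must be balanced and sessions follow the pre/post pattern", {
  d <- study_design(6)
  expect_equal(sum(d$side_order == "left_first"), 3)
  expect_error(study_design(6, side_order = rep("left_first", 6)), "balanced")
  expect_equal(d$sessions$state, c("pre", "post", "pre", "post"))
  sides <- session_sides(d)
  expect_equal(nrow(sides), 12)
  # each subject gets one left and one right post session
  per_subj <- table(sides$subject, sides$side)
  expect_true(all(per_subj == 1))
})
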