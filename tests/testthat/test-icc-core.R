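test_that("two-way mean squares match hand-computed tables", {
  ms <- two_way_mean_squares(matrix(c(1, 3, 5, 2, 4, 6), ncol = 2))
  expect_equal(ms$bms, 8)
  expect_equal(ms$jms, 1.5)
  expect_equal(ms$ems, 0)

  ms2 <- two_way_mean_squares(matrix(c(1, 3, 5, 2, 3, 6), ncol = 2))
  expect_equal(round(ms2$bms, 4), 8.1667)
  expect_equal(round(ms2$ems, 4), 0.1667)
  expect_equal(icc_31(ms2)$icc, 0.96, tolerance = 1e-12)

  ms0 <- two_way_mean_squares(matrix(7, 4, 3))
  expect_equal(ms0$bms, 0)
  expect_equal(ms0$jms, 0)
  expect_equal(ms0$ems, 0)
})

test_that("mean squares agree with the aov decomposition on random tables", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    k <- sample(2:6, 1)
    m <- rand_table(n, k)
    ms <- two_way_mean_squares(m)
    df <- data.frame(value = as.vector(m),
                     target = factor(rep(seq_len(n), times = k)),
                     rater = factor(rep(seq_len(k), each = n)))
    a <- anova(stats::aov(value ~ target + rater, data = df))
    expect_equal(ms$bms, a["target", "Mean Sq"], tolerance = 1e-10)
    expect_equal(ms$jms, a["rater", "Mean Sq"], tolerance = 1e-10)
    expect_equal(ms$ems, a["Residuals", "Mean Sq"], tolerance = 1e-10)
  }
})

test_that("ICC via mean squares equals brute-force sum-of-squares computation", {
  set.seed(7)
  for (rep in 1:200) {
    m <- rand_table(8, 2)
    expect_equal(icc_31(m)$icc, brute_icc31(m), tolerance = 1e-12)
  }
})

test_that("ICC(3,1) is a consistency coefficient: rater shifts do not change it", {
  set.seed(5)
  for (rep in 1:20) {
    m <- rand_table(10, 3)
    shifted <- m
    shifted[, 2] <- shifted[, 2] + runif(1, -50, 50)
    expect_equal(icc_31(shifted)$icc, icc_31(m)$icc, tolerance = 1e-10)
  }
  # at k = 2 the formula reduces to (BMS - EMS)/(BMS + EMS)
  m <- rand_table(9, 2)
  ms <- two_way_mean_squares(m)
  expect_equal(icc_31(m)$icc, (ms$bms - ms$ems) / (ms$bms + ms$ems))
})

test_that("degenerate and boundary ICC inputs behave as specified", {
  # zero error variance
  expect_equal(icc_31(matrix(c(1, 3, 5, 1, 3, 5), ncol = 2))$icc, 1)
  # BMS == EMS gives 0 via a synthetic mean-squares object
  ms <- two_way_mean_squares(rand_table(6, 2))
  ms$bms <- 2; ms$ems <- 2
  expect_equal(icc_31(ms)$icc, 0)
  # all-constant data: undefined signal, not a number
  r <- icc_31(matrix(4, 5, 2))
  expect_true(r$undefined)
  expect_true(is.na(r$icc))
  expect_match(r$reason, "constant")
  # input validation
  expect_error(two_way_mean_squares(matrix(1:2, 1, 2)), "2 targets")
  expect_error(two_way_mean_squares(matrix(1:3, 3, 1)), "2 raters")
  expect_error(two_way_mean_squares(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("data-frame input reproduces the matrix route and rejects bad tables", {
  m <- rand_table(6, 3)
  df <- data.frame(target = rep(1:6, 3), rater = rep(1:3, each = 6),
                   value = as.vector(m))
  expect_equal(icc_31(df)$icc, icc_31(m)$icc)
  expect_error(icc_31(df[-1, ]), "Missing cells")
  expect_error(icc_31(rbind(df, df[1, ])), "Duplicated")
})

test_that("CV is sample sd over mean with an undefined signal at zero mean", {
  expect_equal(cv(c(3, 3, 3)), 0)
  expect_equal(round(cv(c(2, 4)), 4), 0.4714)
  expect_warning(out <- cv(c(0, 0)), "zero")
  expect_true(is.na(out))
  expect_error(cv(3), "n >= 2")
})

test_that("reliability bands reproduce the printed qualitative labels", {
  expect_equal(as.character(classify_icc_band(0.456)), "fair")
  expect_equal(as.character(classify_icc_band(0.664)), "good")
  expect_equal(as.character(classify_icc_band(-0.1)), "poor")
  # half-open boundaries: each value maps to exactly one band
  expect_equal(as.character(classify_icc_band(c(0.4, 0.6, 0.75, 0.3999))),
               c("fair", "good", "excellent", "poor"))
  expect_error(classify_icc_band(1.2), "<= 1")
})

test_that("SEM follows pooled_sd * sqrt(1 - ICC)", {
  expect_equal(sem_from_icc(3, 1), 0)
  expect_equal(sem_from_icc(3, 0), 3)
  expect_equal(sem_from_icc(2, 0.75), 1)
  expect_gt(sem_from_icc(1, -0.5), 1) # negative ICC allowed
  expect_error(sem_from_icc(-1, 0.5), ">= 0")
})

test_that("tidy and glance summarise an ICC result", {
  r <- icc_31(rand_table(8, 2))
  td <- tidy(r)
  expect_equal(td$term, c("between_targets", "between_raters", "error"))
  expect_equal(td$df, c(7, 1, 7))
  expect_equal(sum(td$sumsq),
               r$ms$ss_targets + r$ms$ss_raters + r$ms$ss_error)
  g <- glance(r)
  expect_equal(g$icc, r$icc)
  expect_equal(g$n_targets, 8)
})

test_that("ICC estimates recover the true reliability and are centred under the null", {
  set.seed(21)
  n <- 100
  n_tables <- 2000
  for (true_icc in c(0.3, 0.6, 0.9)) {
    sb <- sqrt(true_icc)
    se <- sqrt(1 - true_icc)
    b <- matrix(rnorm(n_tables * n, sd = sb), n_tables, n)
    r1 <- b + matrix(rnorm(n_tables * n, sd = se), n_tables, n)
    r2 <- b + matrix(rnorm(n_tables * n, sd = se), n_tables, n)
    map <- inter_subject_icc_map(r1, r2)
    expect_equal(mean(map$icc), true_icc, tolerance = 0.02)
  }
  # null: no between-target variance
  r1 <- matrix(rnorm(1000 * n), 1000, n)
  r2 <- matrix(rnorm(1000 * n), 1000, n)
  expect_lt(abs(median(inter_subject_icc_map(r1, r2)$icc)), 0.05)
})
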