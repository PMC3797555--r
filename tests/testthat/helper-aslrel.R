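# Brute-force ICC(3,1) from explicit sum-of-squares loops: independent of
# the package's mean-squares route.
brute_icc31 <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- sum(m) / (n * k)
  ss_t <- 0
  for (i in seq_len(n)) ss_t <- ss_t + k * (sum(m[i, ]) / k - grand)^2
  ss_e <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ss_e <- ss_e + (m[i, j] - sum(m[i, ]) / k - sum(m[, j]) / n + grand)^2
    }
  }
  bms <- ss_t / (n - 1)
  ems <- ss_e / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems)
}

# Random targets x raters table with a target effect and iid noise.
rand_table <- function(n, k, sd_target = 1, sd_noise = 1) {
  matrix(rnorm(n, sd = sd_target), n, k) + matrix(rnorm(n * k, sd = sd_noise), n, k)
}

# Deterministic VAS table: rating is a function of subject only, so every
# reliability level should be perfect.
const_vas <- function(n_subjects = 8) {
  d <- study_design(n_subjects = n_subjects)
  vas <- simulate_vas(d, pain = vas_params(50, 0, 0, 0),
                      alertness = vas_params(50, 0, 0, 0),
                      floor_effect = FALSE, seed = 1)
  vas$pain <- 20 + 3 * vas$subject
  vas$alertness <- 30 + 2 * vas$subject
  vas
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

quietly <- function(expr) suppressMessages(expr)
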