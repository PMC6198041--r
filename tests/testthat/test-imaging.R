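make_trace <- function(f, rate = 5.92) {
  tibble::tibble(time_s = (seq_along(f) - 1) / rate, f = f)
}

test_that("dF/F0 follows the selected baseline convention", {
  # constant trace -> all zeros under both conventions
  tr <- make_trace(rep(100, 120))
  d1 <- compute_dff(tr, "first_9s")
  expect_true(all(d1$dff == 0))
  d2 <- compute_dff(tr, "pre_odor_2s", onset_s = 10)
  expect_true(all(d2$dff == 0))

  # baseline 100, plateau 200 -> plateau dF/F0 = 1
  f <- c(rep(100, 60), rep(200, 60))
  tr2 <- make_trace(f)
  d3 <- compute_dff(tr2, "pre_odor_2s", onset_s = 60 / 5.92)
  expect_equal(d3$dff[61], 1.0)
  expect_equal(d3$f_over_f0[61], 2.0)

  # element-wise oracle on an arbitrary synthetic trace
  set.seed(5)
  f4 <- 100 + cumsum(rnorm(80))
  tr4 <- make_trace(f4)
  d4 <- compute_dff(tr4, "first_9s")
  f0 <- mean(f4[tr4$time_s < 9])
  expect_equal(d4$dff, (f4 - f0) / f0)

  expect_error(compute_dff(make_trace(rep(-1, 50)), "first_9s"),
               "non-positive baseline")
  expect_error(compute_dff(tr, "pre_odor_2s"), "onset_s required")
})

test_that("odor AUC integrates the 5-s window trapezoidally", {
  rate <- 10
  tr <- tibble::tibble(time_s = seq(0, 20, by = 1 / rate))
  tr$dff <- 0
  tr$f_over_f0 <- as.numeric(tr$time_s >= 5 & tr$time_s <= 10) # unit boxcar
  expect_equal(odor_response_auc(tr, 5, 5), 5.0)
  expect_equal(odor_response_auc(tr, 5, 5, integrand = "dff"), 0)
  expect_error(odor_response_auc(tr, 18, 5), "exceeds record")

  # smooth response vs fine-grid reference
  resp <- function(t) 1 + 0.8 * pmax(0, 1 - exp(-(t - 5) / 0.4)) * exp(-pmax(0, t - 5) / 3)
  coarse <- tibble::tibble(time_s = seq(0, 15, by = 1 / 5.92))
  coarse$f_over_f0 <- resp(coarse$time_s)
  fine <- tibble::tibble(time_s = seq(0, 15, by = 1e-3))
  fine$f_over_f0 <- resp(fine$time_s)
  t_on <- round(5 * 5.92) / 5.92 # the sample the coarse grid snaps onset to
  a_coarse <- odor_response_auc(coarse, 5, 5)
  a_fine <- odor_response_auc(fine, t_on, 5)
  expect_lt(abs(a_coarse - a_fine) / a_fine, 0.01)
})

test_that("AUC is linear in the integrand", {
  set.seed(2)
  t <- seq(0, 12, by = 0.1)
  x <- tibble::tibble(time_s = t, f_over_f0 = runif(length(t)))
  y <- tibble::tibble(time_s = t, f_over_f0 = runif(length(t)))
  z <- tibble::tibble(time_s = t, f_over_f0 = 2 * x$f_over_f0 + 3 * y$f_over_f0)
  expect_equal(odor_response_auc(z, 1, 5),
               2 * odor_response_auc(x, 1, 5) + 3 * odor_response_auc(y, 1, 5))
})

test_that("normalization to the novel odor behaves per definition", {
  expect_equal(normalize_to_novel(1.2, 1.2), 1.0)
  expect_equal(normalize_to_novel(2.4, 1.2), 2.0)
  expect_warning(out <- normalize_to_novel(c(1, 2), c(1, 0)), "excluded")
  expect_equal(out, c(1, NA))
})

test_that("multiplying raw F by a constant leaves dF/F0 and AUC ratios unchanged", {
  g <- gen_imaging_cohort(n_flies = 1, cs_plus_multiplier = 0.8, noise_sd = 0,
                          seed = 4)
  tr <- g$traces
  scaled <- tr
  scaled$f <- tr$f * 3.7
  for (i in seq_len(nrow(g$epochs))) {
    a <- compute_dff(tr, "pre_odor_2s", onset_s = g$epochs$onset_s[i])
    b <- compute_dff(scaled, "pre_odor_2s", onset_s = g$epochs$onset_s[i])
    expect_equal(a$dff, b$dff, tolerance = 1e-12)
  }
  t1 <- odor_response_table(tr, g$epochs)
  t2 <- odor_response_table(scaled, g$epochs)
  expect_equal(t1$normalized_auc, t2$normalized_auc, tolerance = 1e-12)
})

test_that("a planted 30% CS+ depression yields ~0.7 normalized ratio (dff mode)", {
  g <- gen_imaging_cohort(n_flies = 12, cs_plus_multiplier = 0.7, seed = 31)
  tab <- odor_response_table(g$traces, g$epochs, integrand = "dff")
  wide <- tidyr::pivot_wider(tab[, c("fly_id", "odor", "normalized_auc")],
                             names_from = "odor", values_from = "normalized_auc")
  ratio <- mean(wide$`CS+` / wide$`CS-`)
  expect_equal(ratio, 0.7, tolerance = 0.05)
})

test_that("paired_group_test gates on normality and handles edge cases", {
  v <- c(1, 2, 3, 4, 5, 6)
  res <- paired_group_test(v, v)
  expect_equal(res$p_value, 1)
  expect_equal(res$test_used, "degenerate")
  expect_error(paired_group_test(1:3, 1:3), "at least 5")

  set.seed(8)
  a <- rnorm(20); b <- a - 1 + rnorm(20, 0, 0.3) # normal differences
  expect_equal(paired_group_test(a, b)$test_used, "paired t")
  skewed <- a + exp(rnorm(20, 0, 1.5)) # heavy-tailed differences
  res2 <- paired_group_test(skewed, a)
  expect_equal(res2$test_used, "Wilcoxon signed-rank")

  # boxplot summary consistent with data
  s <- res2$summary[res2$summary$condition == "CS+", ]
  expect_equal(s$median, stats::median(skewed))
  expect_equal(s$min, min(skewed))
  expect_equal(s$max, max(skewed))
})

test_that("paired test has power ~1 at d = 1 sd and calibrated null size", {
  set.seed(123)
  rejections <- 0
  n_sims <- 400
  for (i in seq_len(n_sims)) {
    base <- rnorm(20)
    res <- paired_group_test(base + 1 + rnorm(20), base)
    rejections <- rejections + (res$p_value < 0.05)
  }
  expect_gte(rejections / n_sims, 0.8)

  null_rej <- 0
  for (i in seq_len(1000)) {
    res <- paired_group_test(rnorm(15), rnorm(15))
    null_rej <- null_rej + (res$p_value < 0.05)
  }
  expect_gte(null_rej / 1000, 0.035)
  expect_lte(null_rej / 1000, 0.065)
})

test_that("optogenetic pre/post comparison detects a planted step", {
  rate <- 5.92
  t <- seq(0, 12, by = 1 / rate)
  flat <- dplyr::bind_rows(lapply(1:6, function(id) {
    tibble::tibble(fly_id = id, time_s = t, dff = 0)
  }))
  res0 <- optogenetic_response(flat, stim_onset_s = 6)
  expect_equal(res0$p_value, 1)
  expect_equal(res0$per_preparation$pre_mean, res0$per_preparation$post_mean)

  set.seed(6)
  step <- dplyr::bind_rows(lapply(1:10, function(id) {
    tibble::tibble(fly_id = id, time_s = t,
                   dff = ifelse(t >= 6, 0.5, 0) + rnorm(length(t), 0, 0.05))
  }))
  res1 <- optogenetic_response(step, stim_onset_s = 6)
  expect_lt(res1$p_value, 0.05)
  expect_gt(mean(res1$per_preparation$post_mean - res1$per_preparation$pre_mean), 0.4)

  expect_error(optogenetic_response(flat, stim_onset_s = 0.5), "1 s of record")
})

test_that("odor_response_table requires a novel epoch", {
  g <- gen_imaging_cohort(n_flies = 2, seed = 9)
  ep <- g$epochs[g$epochs$label != "novel", ]
  expect_error(odor_response_table(g$traces, ep), "novel")
})
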