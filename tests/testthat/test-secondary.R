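test_that("the log-RT model recovers a known trial-type effect", {
  # lognormal RTs with a multiplicative test-vs-easy effect of exp(0.5)
  set.seed(27)
  n_per <- 80
  types <- rep(c("baseline_easy", "baseline_difficult", "test"),
               each = n_per)
  logs <- lapply(1:5, function(p) {
    lg <- mini_log(types, participant = sprintf("P%d", p))
    eff <- c(baseline_easy = 0, baseline_difficult = 0.2, test = 0.5)
    lg$rt_ms <- exp(log(800) + rnorm(1, 0, 0.1) + eff[lg$trial_type] +
                      rnorm(nrow(lg), 0, 0.1))
    lg
  })
  fit <- log_rt_mixed_model(do.call(rbind, logs))
  est <- fit$contrasts
  easy_test <- est$estimate[est$contrast == "easy - test"]
  expect_lt(abs(easy_test - (-0.5)), 0.05)
  easy_diff <- est$estimate[est$contrast == "easy - difficult"]
  expect_lt(abs(easy_diff - (-0.2)), 0.05)
  expect_true(all(est$lower <= est$estimate & est$estimate <= est$upper))
})

test_that("constant RTs yield zero contrasts and corrections are excluded", {
  lg <- mini_log(rep(c("baseline_easy", "baseline_difficult", "test",
                       "correction"), each = 30),
                 rt_ms = 700)
  lg$is_correction <- lg$trial_type == "correction"
  # constant response: lm warns about a perfect fit, which is the point
  expect_message(fit <- suppressWarnings(log_rt_mixed_model(lg)),
                 "single participant")
  expect_equal(fit$n_excluded_corrections, 30)
  expect_true(all(abs(fit$contrasts$estimate) < 1e-12))
})

test_that("position-bias chi-square matches the closed formula", {
  # all 300 choices in one cell: (300-50)^2/50 + 5 * 50 = 1500
  one_cell <- mini_log(rep("test", 300), chosen_cell = 3L)
  expect_equal(position_bias_chisq(one_cell)$chi_square, 1500)
  # perfectly uniform choices: 0
  uniform <- mini_log(rep("test", 300), chosen_cell = rep(0:5, 50))
  expect_equal(position_bias_chisq(uniform)$chi_square, 0)
  # random fixtures against the brute-force loop
  set.seed(9)
  for (r in 1:5) {
    cells <- sample(0:5, 120, replace = TRUE, prob = runif(6))
    lg <- mini_log(rep("test", 120), chosen_cell = cells)
    chi <- 0
    for (cell in 0:5) chi <- chi + (sum(cells == cell) - 20)^2 / 20
    expect_equal(position_bias_chisq(lg)$chi_square, chi)
  }
  expect_error(position_bias_chisq(mini_log("baseline_easy")), "test trials")
})

test_that("spearman_corr handles monotone data, ties and one-tailed tests", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_corr(x, rev(x))$rho, -1)
  expect_equal(spearman_corr(x, x^3)$rho, 1)
  # midrank oracle on a 6-point fixture with ties
  y <- c(2, 2, 1, 5, 5, 4)
  got <- spearman_corr(x, y)
  expect_equal(got$rho, cor(rank(x), rank(y)))
  # one-tailed p for a negative association is half the two-sided one
  neg <- spearman_corr(x, c(6, 5, 4, 3, 2, 1) + c(0.1, 0, 0, 0, 0, 0),
                       alternative = "less")
  expect_lt(neg$p, spearman_corr(x, rev(x) + c(0.1, 0, 0, 0, 0, 0))$p + 1e-12)
  expect_error(spearman_corr(x, rep(1, 6)), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})

test_that("the RT median split partitions per-participant test trials", {
  m <- matrix(0L, 2, 2)
  ds <- mini_dataset(lapply(1:10, function(i) {
    v <- matrix(as.integer(i), 2, 2)
    list(v, m, m)
  }), chosen = rep(1L, 10), rt_ms = 1:10 * 100)
  sp <- rt_median_split(ds)
  expect_equal(n_trials(sp$faster), 5)
  expect_equal(n_trials(sp$slower), 5)
  expect_true(all(sp$faster$trials$rt_ms <= 500))
  # union is the original dataset, disjoint
  expect_setequal(c(sp$faster$trials$trial, sp$slower$trials$trial), 1:10)
  # fully tied RTs leave the slower half empty, with a warning
  ds_tied <- mini_dataset(lapply(1:4, function(i) list(m, m, m)),
                          chosen = rep(1L, 4), rt_ms = rep(400, 4))
  expect_warning(sp2 <- rt_median_split(ds_tied), "degenerate")
  expect_equal(n_trials(sp2$faster), 4)
  expect_equal(n_trials(sp2$slower), 0)
})

test_that("brightness contrasts equal closed-form mean differences", {
  set.seed(5)
  a <- matrix(rnorm(200, -1.6, 1), 10, 20)
  planes <- list(chimp = a, human = a)
  same <- brightness_difference_model(planes)
  expect_equal(same$contrasts$estimate, 0, tolerance = 1e-12)
  # constant offset: contrast equals the offset
  planes2 <- list(chimp = a, letter = a - 1.4)
  offs <- brightness_difference_model(planes2)
  expect_equal(offs$contrasts$estimate, 1.4, tolerance = 1e-12)
  expect_equal(offs$summary$mean, c(mean(a), mean(a) - 1.4))
  expect_equal(offs$summary$se,
               rep(sd(a) / sqrt(length(a)), 2), tolerance = 1e-12)
  # generic fixture against the two-sample formula
  b <- matrix(rnorm(200, -3, 0.7), 10, 20)
  two <- brightness_difference_model(list(x = a, y = b))
  expect_equal(two$contrasts$estimate, mean(a) - mean(b), tolerance = 1e-12)
  # row/column random-intercept variant reports the same contrast
  rc <- brightness_difference_model(list(x = a, y = b), variant = "rowcol")
  expect_equal(rc$contrasts$estimate, mean(a) - mean(b), tolerance = 1e-6)
  expect_error(brightness_difference_model(list(x = a, y = b[1:5, ])),
               "mismatched")
})

test_that("radial spectra localize frequencies and correlate sensibly", {
  h <- 64; w <- 80
  # pure horizontal sinusoid with 9 cycles -> energy in radial bin 9
  sinus <- matrix(rep(sin(2 * pi * 9 * (0:(w - 1)) / w), each = h), h, w)
  prof <- radial_amplitude_spectrum(sinus)
  expect_length(prof, 32)
  expect_equal(which.max(prof), 9)
  expect_gt(prof[9] / (sum(prof) - prof[9] + 1e-12), 100)
  # self-correlation of any image is exactly 1
  set.seed(2)
  img <- matrix(rnorm(h * w), h, w)
  expect_equal(spectrum_correlation(img, img), 1)
  expect_error(radial_amplitude_spectrum(1:10), "2D")
})

test_that("euclidean image distance is a metric on planes", {
  a <- matrix(rnorm(44000), 220, 200)
  expect_equal(euclidean_image_distance(a, a), 0)
  expect_equal(euclidean_image_distance(a, a + 1), sqrt(44000))
  b <- matrix(rnorm(44000), 220, 200)
  expect_equal(euclidean_image_distance(a, b),
               euclidean_image_distance(b, a))
  expect_error(euclidean_image_distance(a, b[1:10, ]), "mismatched")
})
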