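test_that("zero-CV biodistribution lies exactly on the truth curves", {
  truth <- default_biodist_truth(cv = 0)
  bio <- gen_biodistribution(truth, seed = 3, scale = "uncorrected")
  for (org in c("blood", "gut")) {
    row <- truth[truth$organ == org, ]
    sub <- bio[bio$organ == org, ]
    expected <- tac_eval(row$model, tatdose:::truth_params(row), sub$time_h)
    expect_equal(sub$value, expected, tolerance = 1e-12)
  }
})

test_that("generators are pure functions of (truth, seed)", {
  b1 <- gen_biodistribution(seed = 10); b2 <- gen_biodistribution(seed = 10)
  expect_identical(b1, b2)
  b3 <- gen_biodistribution(seed = 11)
  expect_false(identical(b1$value, b3$value))

  s1 <- gen_survival(seed = 10); s2 <- gen_survival(seed = 10)
  expect_identical(s1, s2)

  h1 <- gen_hematology(seed = 10); h2 <- gen_hematology(seed = 10)
  expect_identical(h1, h2)

  # caller RNG state is not disturbed
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(gen_biodistribution(seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("biodistribution calibration reproduces the headline group means", {
  # blood ~14.9 %ID/g at 21 h and liver ~33.0 at 15 min on the corrected scale
  means <- sapply(1:50, function(s) {
    bio <- gen_biodistribution(seed = s)
    c(blood = mean(bio$value[bio$organ == "blood" & bio$time_h == 21]),
      liver = mean(bio$value[bio$organ == "liver" & bio$time_h == 0.25]))
  })
  expect_equal(unname(rowMeans(means)["blood"]), 14.9, tolerance = 0.05)
  expect_equal(unname(rowMeans(means)["liver"]), 33.0, tolerance = 0.05)
})

test_that("survival generator honors cure fractions and censoring", {
  truth_all_cured <- data.frame(group = "g", n = 12L, cure_fraction = 1,
                                median_days = 45, log_sd = 0.3,
                                censor_day = 160)
  rec <- gen_survival(truth_all_cured, seed = 1)
  expect_true(all(rec$event == 0))
  expect_true(all(rec$time == 160))

  # degenerate point-mass: all events at the median
  truth_point <- data.frame(group = "g", n = 8L, cure_fraction = 0,
                            median_days = 45, log_sd = 0, censor_day = 160)
  rec2 <- gen_survival(truth_point, seed = 1)
  expect_true(all(rec2$event == 1))
  expect_equal(rec2$time, rep(45, 8))
  expect_equal(median_survival(km_curve(rec2)), 45)
})

test_that("control-arm KM median is calibrated to 45 days", {
  truth <- default_survival_truth()
  medians <- sapply(1:200, function(s) {
    rec <- gen_survival(truth, seed = s)
    median_survival(km_curve(rec[rec$group == "control", ]))
  })
  expect_equal(mean(medians), 45, tolerance = 5 / 45)
})

test_that("empirical cure fraction converges to truth at large n", {
  truth <- data.frame(group = "g", n = 4000L, cure_fraction = 11 / 17,
                      median_days = 90, log_sd = 0.3, censor_day = 160)
  rec <- gen_survival(truth, seed = 8)
  p_hat <- mean(rec$event == 0 & rec$time == 160)
  p <- 11 / 17
  # events censored administratively (t_raw > censor) inflate p_hat slightly
  se <- sqrt(p * (1 - p) / 4000)
  expect_lt(abs(p_hat - p), 4 * se + 0.03)
})

test_that("hematology trajectories yield the designed nadir decreases", {
  truth <- default_hematology_truth()
  truth$cv <- 0; truth$baseline_sd <- 0
  hem <- gen_hematology(truth, n_per_group = 2, seed = 1)
  g740 <- hem[hem$group == "740kBq" & hem$analyte == "wbc" &
                hem$animal == "740kBq_01", ]
  nd <- nadir_percent_decrease(g740$day, g740$value, window = c(1, 7))
  expect_equal(nd$percent_decrease, 100 * (1 - 0.301), tolerance = 1e-10)
  expect_equal(nd$nadir_day, 3)

  flat <- truth; flat$nadir_fraction <- 1
  hem_flat <- gen_hematology(flat, n_per_group = 1, seed = 1)
  one <- hem_flat[hem_flat$animal == "control_01" &
                    hem_flat$analyte == "wbc", ]
  expect_equal(nadir_percent_decrease(one$day, one$value,
                                      c(1, 7))$percent_decrease, 0)
})

test_that("740 kBq WBC cohort mean decrease is calibrated to ~69.9%", {
  means <- sapply(1:50, function(s) {
    hem <- gen_hematology(seed = s)
    sub <- hem[hem$group == "740kBq", ]
    group_decrease_summary(sub, "wbc")$summary$mean
  })
  expect_equal(mean(means), 69.9, tolerance = 5 / 69.9)
})
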