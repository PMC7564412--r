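test_that("product-limit curve matches hand calculations", {
  # 4 deaths, no censoring
  k <- km_curve(data.frame(time = c(10, 20, 30, 40), event = 1))
  expect_equal(k$survival, c(0.75, 0.5, 0.25, 0))

  # all censored: S stays at 1
  k2 <- km_curve(data.frame(time = c(5, 10, 15), event = 0))
  expect_true(all(k2$survival == 1))

  # mixed 6-record example, frozen from the hand product-limit calculation:
  # deaths at 8 (2 of 5 at risk) and 20 (1 of 2) -> S = 0.6 then 0.3
  k3 <- km_curve(six_record_example())
  expect_equal(k3$survival, c(1, 0.6, 0.6, 0.3, 0.3))
  expect_equal(k3$n_risk, c(6, 5, 3, 2, 1))
})

test_that("KM equals 1 - ECDF when nothing is censored", {
  set.seed(61)
  for (i in 1:10) {
    tt <- sample(1:40, 12, replace = TRUE)
    k <- km_curve(data.frame(time = tt, event = 1))
    ecdf_fn <- ecdf(tt)
    expect_equal(k$survival, 1 - ecdf_fn(k$time))
  }
})

test_that("KM curve agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(62)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    rec <- data.frame(time = sample(1:30, n, replace = TRUE),
                      event = rbinom(n, 1, 0.7))
    if (!any(rec$event == 1)) rec$event[1] <- 1
    k <- km_curve(rec)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
    expect_equal(k$survival, summary(sf, times = k$time)$surv,
                 tolerance = 1e-12)
  }
})

test_that("median survival uses the first time S falls to 0.5 or below", {
  k <- km_curve(data.frame(time = c(10, 20, 30, 40), event = 1))
  expect_equal(median_survival(k), 20)

  # S never reaches 0.5: undefined, flagged as NA not an error
  k2 <- km_curve(data.frame(time = c(5, 8, 100, 100, 100),
                            event = c(1, 1, 0, 0, 0)))
  expect_true(is.na(median_survival(k2)))

  # invariant to record ordering
  rec <- six_record_example()
  m1 <- median_survival(km_curve(rec))
  m2 <- median_survival(km_curve(rec[sample(nrow(rec)), ]))
  expect_identical(m1, m2)
  expect_equal(m1, 20)
})

test_that("log-rank matches the hand-computed 6-record example", {
  A <- data.frame(time = c(3, 6, 9), event = c(1, 1, 0))
  B <- data.frame(time = c(5, 10, 12), event = c(1, 1, 0))
  lr <- logrank_test(A, B)
  # frozen hand calculation: sum(O-E) = 0.6, sum(V) = 0.74
  expect_equal(lr$chisq, 0.6^2 / 0.74, tolerance = 1e-12)
  expect_equal(lr$p_value, pchisq(0.6^2 / 0.74, 1, lower.tail = FALSE))

  # symmetric in group labels
  lr_swap <- logrank_test(B, A)
  expect_equal(lr_swap$chisq, lr$chisq)
})

test_that("log-rank agrees with the survival package on random cases", {
  skip_if_not_installed("survival")
  set.seed(63)
  for (i in 1:10) {
    nA <- sample(4:10, 1); nB <- sample(4:10, 1)
    A <- data.frame(time = sample(1:25, nA, replace = TRUE),
                    event = rbinom(nA, 1, 0.8))
    B <- data.frame(time = sample(5:30, nB, replace = TRUE),
                    event = rbinom(nB, 1, 0.8))
    if (sum(A$event) + sum(B$event) == 0) A$event[1] <- 1
    lr <- logrank_test(A, B)
    sd_ref <- survival::survdiff(
      survival::Surv(c(A$time, B$time), c(A$event, B$event)) ~
        rep(1:2, c(nA, nB)))
    expect_equal(lr$chisq, sd_ref$chisq, tolerance = 1e-10)
  }
})

test_that("identical groups give statistic 0 and p = 1", {
  g <- data.frame(time = c(4, 9, 15, 20), event = c(1, 1, 0, 1))
  lr <- logrank_test(g, g)
  expect_equal(lr$chisq, 0)
  expect_equal(lr$p_value, 1)
})

test_that("fully separated large groups are highly significant", {
  A <- data.frame(time = 1:10, event = 1)
  B <- data.frame(time = 11:20, event = 1)
  lr <- logrank_test(A, B)
  expect_lt(lr$p_value, 0.001)
})

test_that("log-rank with zero events is flagged undefined", {
  A <- data.frame(time = c(5, 6), event = 0)
  B <- data.frame(time = c(7, 8), event = 0)
  lr <- logrank_test(A, B)
  expect_false(lr$defined)
  expect_true(is.na(lr$p_value))
})

test_that("survival percentage matches the reported convention", {
  expect_equal(survival_percent(11, 17), 100 * 11 / 17)
  expect_equal(survival_percent(11, 17, digits = 0), 65)
  expect_equal(survival_percent(0, 8), 0)
  expect_equal(survival_percent(8, 8), 100)
  expect_error(survival_percent(1, 0), "total")
  expect_error(survival_percent(9, 8), "alive")
})

test_that("group summaries report n, events, median and percent surviving", {
  rec <- gen_survival(seed = 2)
  s <- survival_summary(rec)
  expect_setequal(s$group, default_survival_truth()$group)
  expect_equal(s$n[s$group == "740kBq"], 17)
  expect_equal(s$n, s$events + s$censored)
  expect_true(all(s$percent_surviving >= 0 & s$percent_surviving <= 100))
})
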