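test_that("dose conversion follows the dimensional-analysis constant chain", {
  expect_equal(dose_per_unit_activity(0, 6.79), 0)
  # (100/100) ID.h/g x 3.6e9 decays/(MBq.h) x 6.79 MeV x 1.602e-13 J/MeV x 1e3 g/kg
  expect_equal(dose_per_unit_activity(100, 6.79), 3.916, tolerance = 1e-3)
  expect_error(dose_per_unit_activity(-1, 6.79), "auc")
  expect_error(dose_per_unit_activity(10, 0), "energy")
})

test_that("dose is linear in AUC, energy and injected activity", {
  set.seed(31)
  auc <- runif(20, 0, 400); e <- runif(20, 1, 10); act <- runif(20, 0, 2)
  expect_equal(dose_per_unit_activity(2 * auc, e),
               2 * dose_per_unit_activity(auc, e))
  expect_equal(dose_per_unit_activity(auc, 3 * e),
               3 * dose_per_unit_activity(auc, e))
  expect_equal(dose_at_activity(dose_per_unit_activity(auc, e), 2 * act),
               2 * dose_at_activity(dose_per_unit_activity(auc, e), act))
})

test_that("whole-organ (%ID + mass) route equals the per-gram route", {
  set.seed(32)
  for (i in 1:10) {
    auc_pg <- runif(1, 1, 300)      # %ID.h/g
    mass <- runif(1, 0.05, 2)       # g
    expect_equal(dose_from_whole_organ(auc_pg * mass, mass, 6.79),
                 dose_per_unit_activity(auc_pg, 6.79))
  }
})

test_that("dose at activity multiplies then rounds report-style", {
  expect_equal(dose_at_activity(8.2, 0.740, digits = 1), 6.1)
  expect_equal(dose_at_activity(3.6, 0.740, digits = 1), 2.7)
  expect_equal(dose_at_activity(8.0, 0.740), 5.92)
  expect_equal(dose_at_activity(5, 0), 0)
  expect_error(dose_at_activity(5, -1), "injected")
})

test_that("RBE weighting is a guarded product", {
  expect_equal(apply_rbe(8.0, 4), 32)
  expect_equal(apply_rbe(7.3, 1), 7.3)
  expect_equal(apply_rbe(0, 5), 0)
  expect_error(apply_rbe(1, 0), "rbe")
})

test_that("delta SE is zero for zero covariance and linear in energy", {
  f <- fit_tac(study_tps, tac_eval("monoexp", c(A0 = 30, lambda = 0.1),
                                   study_tps), "monoexp")
  f$covariance <- matrix(0, 2, 2, dimnames = list(names(f$estimates),
                                                  names(f$estimates)))
  expect_equal(dose_uncertainty(f, 6.79, "delta"), 0)

  set.seed(41)
  t_all <- rep(study_tps, each = 3)
  y <- tac_eval("monoexp", c(A0 = 30, lambda = 0.1296), t_all) *
    rlnorm(length(t_all), -cv15_sdlog^2 / 2, cv15_sdlog)
  fn <- fit_tac(t_all, y, "monoexp")
  expect_equal(dose_uncertainty(fn, 2 * 6.79, "delta"),
               2 * dose_uncertainty(fn, 6.79, "delta"))
})

test_that("delta SE agrees with a parametric bootstrap oracle", {
  set.seed(3)
  t_all <- rep(study_tps, each = 3)
  truth <- c(A0 = 30, lambda = 0.1296)
  y <- tac_eval("monoexp", truth, t_all) *
    rlnorm(length(t_all), -cv15_sdlog^2 / 2, cv15_sdlog)
  f <- fit_tac(t_all, y, "monoexp")
  se_delta <- dose_uncertainty(f, 6.79, "delta")

  # oracle: simulate gaussian data from the fitted curve and refit
  sig <- sqrt(sum((y - tac_eval("monoexp", f$estimates, t_all))^2) /
                (length(y) - 2))
  set.seed(11)
  doses <- replicate(2000, {
    ystar <- pmax(tac_eval("monoexp", f$estimates, t_all) +
                    rnorm(length(y), 0, sig), 0)
    dose_per_unit_activity(
      fit_tac(t_all, ystar, "monoexp", init = f$estimates)$auc, 6.79)
  })
  expect_equal(se_delta, sd(doses), tolerance = 0.15)
})

test_that("residual bootstrap SE is seeded and reproducible", {
  set.seed(43)
  t_all <- rep(study_tps, each = 3)
  y <- tac_eval("monoexp", c(A0 = 30, lambda = 0.1296), t_all) *
    rlnorm(length(t_all), -cv15_sdlog^2 / 2, cv15_sdlog)
  f <- fit_tac(t_all, y, "monoexp")
  b1 <- dose_uncertainty(f, 6.79, "bootstrap", n_boot = 200, seed = 7)
  b2 <- dose_uncertainty(f, 6.79, "bootstrap", n_boot = 200, seed = 7)
  expect_identical(b1, b2)
  se_delta <- dose_uncertainty(f, 6.79, "delta")
  expect_equal(b1, se_delta, tolerance = 0.5)  # same order of magnitude
})

test_that("noiseless synthetic study reproduces truth-implied doses exactly", {
  bio <- gen_biodistribution(default_biodist_truth(cv = 0), seed = 1)
  dt <- suppressMessages(build_dose_table(bio))
  truth <- truth_dose_table()
  m <- merge(as.data.frame(dt), truth, by = "organ")
  expect_equal(nrow(m), 13L)  # neck excluded from per-gram dosimetry
  expect_true(all(m$converged))
  expect_equal(m$dose_gy_per_mbq.x, m$dose_gy_per_mbq.y, tolerance = 1e-6)
})

test_that("single-organ tables produce single-entry dose tables", {
  df <- make_biodist_df(
    animal = rep(sprintf("m%d", 1:3), times = 6),
    organ = "brain",
    time_h = rep(study_tps, each = 3),
    value = tac_eval("monoexp", c(A0 = 0.65, lambda = 0.125),
                     rep(study_tps, each = 3)),
    decay_corrected = FALSE)
  dt <- build_dose_table(tatdose:::new_biodist_table(df))
  expect_equal(nrow(dt), 1L)
  expect_identical(dt$organ, "brain")
  expect_identical(dt$model, "monoexp")
})

test_that("dose table export is byte-identical across reruns", {
  bio <- gen_biodistribution(seed = 12)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  dt1 <- suppressMessages(build_dose_table(bio, seed = 5))
  dt2 <- suppressMessages(build_dose_table(bio, seed = 5))
  utils::write.csv(as.data.frame(dt1), f1, row.names = FALSE)
  utils::write.csv(as.data.frame(dt2), f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})
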