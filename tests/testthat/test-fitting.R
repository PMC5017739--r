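# ROI prediction, relative-variance fitting and Akaike model comparison.

test_that("time_activity_dataset enforces its invariants", {
  expect_error(time_activity_dataset("kidneys", c(30, 20, 60, 90), rep(0.1, 4)),
               "strictly increasing")
  expect_error(time_activity_dataset("kidneys", c(30, 60, 90), rep(0.1, 3)),
               "at least 4")
  expect_error(time_activity_dataset("kidneys", c(30, 60, 90, 120),
                                     c(0.1, 0.2, 1.5, 0.1)), "\\[0, 1.2\\]")
  d <- time_activity_dataset("total_body", c(30, 60, 90, 120),
                             c(1.1, 1.0, 0.9, 0.8))
  expect_s3_class(d, "time_activity_dataset")
})

test_that("predict_roi adds the muscle background linearly", {
  sim <- median_sim()
  base <- predict_roi(sim, "kidneys", 0)
  expect_equal(base$value, activity_fraction(sim, "kidneys")$value)
  musc <- activity_fraction(sim, "muscle")$value
  for (cc in c(0.05, 0.1, 0.2)) {
    p <- predict_roi(sim, "kidneys", cc)
    expect_equal(p$value - base$value, cc * musc, tolerance = 1e-12)
  }
  # strictly increasing in the background fraction wherever muscle signal is
  # non-negligible
  p1 <- predict_roi(sim, "tumor_1", 0.01)$value
  p2 <- predict_roi(sim, "tumor_1", 0.02)$value
  expect_true(all(p2[musc > 1e-9] > p1[musc > 1e-9]))
  # total-body ROI ignores the background fraction
  expect_equal(predict_roi(sim, "total_body", 0.5)$value,
               activity_fraction(sim, "total_body")$value)
  expect_error(predict_roi(sim, "kidneys", -0.1), "background_fraction")
})

test_that("noise-free data are recovered within 1% with near-zero CVs", {
  vp <- noisefree_patient(42)
  ds <- simulate_measurements(vp)
  f <- fit_patient(ds, quick_spec(), vp, seed = 1)
  tr <- vp$truth[f$spec$free]
  expect_true(all(abs(f$estimates / tr - 1) < 0.01))
  expect_true(all(f$r2 > 0.9999))
  expect_true(all(f$cv_pct < 1))
})

test_that("the generating parameters are a local optimum of the objective on exact data", {
  vp <- noisefree_patient(3)
  ds <- simulate_measurements(vp)
  spec <- quick_spec(rtol = 1e-8, atol = 1e-12)
  factory <- psmaplan:::default_model_factory(vp, spec)
  times_all <- sort(unique(unlist(lapply(ds, `[[`, "time_min"))))
  y <- unlist(lapply(ds, `[[`, "value"), use.names = FALSE)
  ssq <- function(theta)
    sum(((y - psmaplan:::fit_predict(theta, ds, factory, times_all,
                                     spec$control)) / y)^2)
  f0 <- ssq(vp$truth[spec$free])
  expect_lt(f0, 1e-12) # residuals vanish at the truth
  for (j in seq_along(spec$free)) {
    for (s in c(0.98, 1.02)) {
      th <- vp$truth[spec$free]
      th[j] <- th[j] * s
      expect_gt(ssq(th), f0)
    }
  }
})

test_that("objective is invariant to dataset ordering", {
  vp <- sample_virtual_patient(5)
  ds <- simulate_measurements(vp)
  spec <- quick_spec()
  factory <- psmaplan:::default_model_factory(vp, spec)
  objective_of <- function(dl) {
    times_all <- sort(unique(unlist(lapply(dl, `[[`, "time_min"))))
    y <- unlist(lapply(dl, `[[`, "value"), use.names = FALSE)
    ridx <- rep(seq_along(dl), vapply(dl, nrow, 0L))
    nr <- tabulate(ridx)
    p <- psmaplan:::fit_predict(vp$truth[spec$free], dl, factory, times_all,
                                spec$control)
    ssr <- rowsum((y - p)^2 / y^2, ridx)[, 1]
    sum(nr * log(ssr / nr))
  }
  expect_equal(objective_of(ds), objective_of(rev(ds)), tolerance = 1e-10)
})

test_that("fit result structure: correlations, bounds flags, AIC bookkeeping", {
  vp <- sample_virtual_patient(11)
  ds <- simulate_measurements(vp)
  f <- fit_patient(ds, fit_spec(), vp, seed = 2) # default multistart
  expect_equal(dim(f$correlation), c(10, 10))
  expect_equal(unname(diag(f$correlation)), rep(1, 10))
  expect_equal(f$correlation, t(f$correlation), tolerance = 1e-12)
  expect_true(all(f$cv_pct >= 0, na.rm = TRUE))
  expect_true(all(f$r2 <= 1))
  expect_equal(f$n_obs, 25)
  expect_equal(f$k, 10 + 5) # 10 free parameters + one variance per region
  expect_equal(f$aic, f$objective + 2 * f$k)
  # fractional SDs live on the scale of the generator noise envelope
  expect_true(all(f$fractional_sd > 0.001 & f$fractional_sd < 0.5))
})

fake_fit <- function(obj, k, koff = 0.046, data) {
  structure(list(objective = obj, aic = obj + 2 * k, k = k, n_obs = 25,
                 k_off = koff, data = data), class = "fit_result")
}

test_that("Akaike weights: closed forms", {
  vp <- sample_virtual_patient(8)
  ds <- simulate_measurements(vp)
  # equal objective and k -> equal weights
  w <- aic_compare(list(fake_fit(-50, 15, 0.046, ds),
                        fake_fit(-50, 15, 0.46, ds)))
  expect_equal(w$weight, c(0.5, 0.5))
  # delta AIC of 2 -> weight ratio exp(-1)
  w2 <- aic_compare(list(fake_fit(-52, 15, 0.046, ds),
                         fake_fit(-50, 15, 0.46, ds)))
  expect_equal(w2$weight[2] / w2$weight[1], exp(-1), tolerance = 1e-12)
  expect_equal(sum(w2$weight), 1, tolerance = 1e-12)
  # four equal fits -> 0.25 each
  w4 <- aic_compare(rep(list(fake_fit(-10, 15, 0.046, ds)), 4))
  expect_equal(w4$weight, rep(0.25, 4))
  # mismatched data is rejected
  ds2 <- simulate_measurements(sample_virtual_patient(9))
  expect_error(aic_compare(list(fake_fit(-50, 15, 0.046, ds),
                                fake_fit(-50, 15, 0.46, ds2))),
               "different data")
  # AICc correction increases the penalty of the larger model
  w5 <- aic_compare(list(fake_fit(-50, 15, 0.046, ds),
                         fake_fit(-54, 17, 0.46, ds)), correct = TRUE)
  expect_lt(w5$weight[2], aic_compare(list(
    fake_fit(-50, 15, 0.046, ds), fake_fit(-54, 17, 0.46, ds)))$weight[2])
})

test_that("the generating dissociation-rate model wins the Akaike comparison", {
  vp <- sample_virtual_patient(21)
  ds <- simulate_measurements(vp, k_off = 0.046)
  f1 <- fit_patient(ds, quick_spec(k_off = 0.046), vp, seed = 3)
  f2 <- fit_patient(ds, quick_spec(k_off = 0.46), vp, seed = 3)
  w <- aic_compare(list(f1, f2))
  expect_gt(w$weight[1], 0.9)
})
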