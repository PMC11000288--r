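test_that("fit metrics reproduce hand calculations and perfect-fit limits", {
  m <- fit_metrics(c(1, 2, 4), c(1, 2, 5))
  expect_equal(m$RMSE, sqrt(1 / 3), tolerance = 1e-4)
  expect_equal(m$MAPE, 100 / 12, tolerance = 1e-4)
  expect_equal(m$R2, m$R^2, tolerance = 1e-9)
  perfect <- fit_metrics(1:5, 1:5)
  expect_equal(perfect[c("R", "RMSE", "MAPE")],
               tibble::tibble(R = 1, RMSE = 0, MAPE = 0))
  # R is symmetric under swapping arguments; MAPE is not
  obs <- c(1, 2, 4); pred <- c(1.1, 1.9, 5)
  expect_equal(fit_metrics(obs, pred)$R, fit_metrics(pred, obs)$R)
  expect_false(isTRUE(all.equal(fit_metrics(obs, pred)$MAPE,
                                fit_metrics(pred, obs)$MAPE)))
  expect_warning(z <- fit_metrics(c(0, 1, 2), c(0, 1, 2)), "MAPE")
  expect_true(is.na(z$MAPE))
  expect_error(fit_metrics(1:3, 1:4), class = "protodoe_metric_error")
})

test_that("the refit quadratic's yield metrics are internally consistent", {
  fy <- fit_quadratic(study$design, study$response$yield)
  m <- fit_metrics(study$response$yield, fy$fitted)
  expect_equal(m$R, 0.996, tolerance = 0.001)
  # R^2 of the Pearson R equals the ANOVA R2 for OLS with intercept
  expect_equal(m$R2, anova(fy)$R2, tolerance = 1e-9)
})

test_that("coefficient of variation matches the study's printed dispersion values", {
  expect_equal(cv_percent(study$response$viability), 3.428, tolerance = 0.01 / 3.428)
  expect_equal(cv_percent(c(0.955, 0.945, 1.035, 1.090, 1.010)), 5.92,
               tolerance = 0.05 / 5.92)
  expect_equal(cv_percent(rep(3, 5)), 0)
  expect_warning(out <- cv_percent(c(-1, 1)), "mean is zero")
  expect_true(is.na(out))
})

test_that("viable cells reproduce every derived entry of the packaged study", {
  expect_equal(viable_cells(1.566, 87.27), 1.367, tolerance = 5e-4 / 1.367)
  expect_equal(viable_cells(0.575, 85.78), 0.493, tolerance = 5e-4 / 0.493)
  expect_equal(viable_cells(2.5, 100), 2.5)
  derived <- viable_cells(study$response$yield, study$response$viability)
  expect_true(all(abs(derived - study$response$viable_cells) <= 0.001))
  expect_error(viable_cells(-1, 50), class = "protodoe_range_error")
  expect_error(viable_cells(1, 101), class = "protodoe_range_error")
})

test_that("relative error reproduces the validation-table entries", {
  # (predicted, experimental, printed relative error %) rows of the
  # optimum-validation table: yield, viability and viable-cell triples for
  # the four optimization routes
  rows <- rbind(
    c(1.464, 1.470, 0.41), c(90.81, 89.73, 1.20), c(1.329, 1.319, 0.76),
    c(1.625, 1.550, 4.84), c(90.16, 90.65, 0.54), c(1.337, 1.405, 4.83),
    c(0.565, 0.563, 0.36), c(90.18, 90.81, 0.69), c(0.510, 0.508, 0.39),
    c(1.574, 1.566, 0.51), c(87.12, 87.27, 0.17), c(1.342, 1.367, 1.83)
  )
  expect_true(all(abs(relative_error(rows[, 1], rows[, 2]) - rows[, 3]) <= 0.01))
  expect_equal(relative_error(2.5, 2.5), 0)
  expect_warning(out <- relative_error(1, 0), "observed is zero")
  expect_true(is.na(out))
})

test_that("the comparison report flags the best model with first-wins ties", {
  rep2 <- comparison_report(list(
    good = list(observed = c(1, 2, 4), predicted = c(1, 2, 4.1)),
    bad = list(observed = c(1, 2, 4), predicted = c(1.5, 1.5, 5))
  ))
  expect_equal(nrow(rep2), 2)
  expect_true(rep2$best_r2[1] && rep2$best_rmse[1] && rep2$best_mape[1])
  solo <- comparison_report(list(only = list(observed = 1:4, predicted = 1:4)))
  expect_true(all(unlist(solo[c("best_r2", "best_rmse", "best_mape")])))
  tie <- comparison_report(list(
    first = list(observed = 1:4, predicted = 1:4),
    second = list(observed = 1:4, predicted = 1:4)
  ))
  expect_equal(tie$best_r2, c(TRUE, FALSE))
  expect_error(comparison_report(list()), class = "protodoe_metric_error")
})
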