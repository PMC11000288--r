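test_that("split sizes follow floor-plus-remainder with train first", {
  s17 <- split_data(17, c(0.70, 0.15, 0.15), seed = 1)
  expect_equal(lengths(s17), c(train = 12L, validation = 3L, test = 2L))
  s20 <- split_data(20, c(0.70, 0.15, 0.15), seed = 1)
  expect_equal(lengths(s20), c(train = 14L, validation = 3L, test = 3L))
  all_train <- split_data(9, c(1, 0, 0), seed = 1)
  expect_equal(all_train$train, 1:9)
  # disjoint cover, reproducible from the seed
  expect_equal(sort(unlist(s17)), 1:17, ignore_attr = TRUE)
  expect_identical(s17, split_data(17, c(0.70, 0.15, 0.15), seed = 1))
  expect_false(identical(s17, split_data(17, c(0.70, 0.15, 0.15), seed = 2)))
  expect_error(split_data(4, c(0, 0.5, 0.5)), class = "protodoe_split_error")
})

test_that("a realizable linear map is learned to near-zero training error", {
  X <- cbind(seq(0, 1, length.out = 10), 0.5, 0.5)
  y <- 2 * X[, 1]
  fit <- train_bpnn(X, y, n_hidden = 2, split = c(1, 0, 0),
                    max_epochs = 300, seed = 1)
  expect_lt(tail(fit$history$train_mse, 1), 1e-6)
})

test_that("both algorithms learn a noiseless quadratic surface out of sample", {
  truth <- random_quadratic(seed = 5)
  Xall <- coded_to_actual(withr::with_seed(6, matrix(runif(150) * 2 - 1, ncol = 3)),
                          paper_factors)
  yall <- predict(truth, Xall)
  train <- 1:30; test <- 31:50
  fit_lm <- train_bpnn(Xall[train, ], yall[train], n_hidden = 10,
                       algorithm = "lm", split = c(0.85, 0.15, 0),
                       max_epochs = 2000, patience = 50, seed = 2, restarts = 3)
  expect_gt(cor(yall[test], predict(fit_lm, Xall[test, ]))^2, 0.99)
  # SCG needs its full epoch budget on noiseless data, so no validation holdout
  fit_scg <- train_bpnn(Xall[train, ], yall[train], n_hidden = 10,
                        algorithm = "scg", split = c(1, 0, 0),
                        max_epochs = 1000, seed = 2)
  expect_gt(cor(yall[test], predict(fit_scg, Xall[test, ]))^2, 0.99)
})

test_that("the analytic Jacobian matches finite differences", {
  n_hidden <- 4
  X <- withr::with_seed(3, matrix(runif(15, -1, 1), ncol = 3))
  w <- withr::with_seed(4, runif(n_hidden * 3 + 2 * n_hidden + 1, -0.5, 0.5))
  J <- protodoe:::net_jacobian(w, X, n_hidden)
  h <- 1e-6
  J_fd <- sapply(seq_along(w), function(j) {
    wp <- w; wp[j] <- wp[j] + h
    wm <- w; wm[j] <- wm[j] - h
    (protodoe:::net_forward(wp, X, n_hidden)$yhat -
       protodoe:::net_forward(wm, X, n_hidden)$yhat) / (2 * h)
  })
  expect_equal(J, J_fd, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("training is bitwise reproducible from the seed", {
  X <- actual_inputs()
  y <- study$response$yield
  a <- train_bpnn(X, y, n_hidden = 6, seed = 42, max_epochs = 100)
  b <- train_bpnn(X, y, n_hidden = 6, seed = 42, max_epochs = 100)
  expect_identical(a$net$weights, b$net$weights)
  expect_identical(a$history, b$history)
})

test_that("accepted LM steps never increase training error", {
  X <- actual_inputs()
  fit <- train_bpnn(X, study$response$viability, n_hidden = 8, seed = 5,
                    max_epochs = 200, patience = 1000)
  expect_true(all(diff(fit$history$train_mse) <= 1e-12))
})

test_that("returned weights correspond to the minimum-validation-MSE epoch", {
  X <- actual_inputs()
  for (alg in c("lm", "scg")) {
    fit <- train_bpnn(X, study$response$yield, n_hidden = 12, algorithm = alg,
                      seed = 9, max_epochs = 200)
    expect_equal(fit$best_epoch,
                 fit$history$epoch[which.min(fit$history$val_mse)])
    best_mse <- mean((study$response$yield[fit$split$validation] -
                        predict(fit, X[fit$split$validation, , drop = FALSE]))^2)
    # recompute in original units: scaled best val MSE times the output half-range^2
    scale2 <- fit$net$output_scaling$half^2
    expect_equal(best_mse, min(fit$history$val_mse) * scale2, tolerance = 1e-8)
  }
})

test_that("prediction is deterministic, batch-consistent, and descales correctly", {
  X <- actual_inputs()
  fit <- train_bpnn(X, study$response$yield, n_hidden = 5, seed = 1, max_epochs = 50)
  batch <- predict(fit, X)
  single <- sapply(seq_len(nrow(X)), function(i) predict(fit, X[i, ]))
  expect_equal(batch, single, tolerance = 1e-12)
  # zero weights produce the descaled zero (the mid-range response)
  net0 <- fit$net
  net0$weights <- rep(0, length(net0$weights))
  expect_equal(predict_net(net0, X), rep(net0$output_scaling$center, nrow(X)),
               ignore_attr = TRUE)
})

test_that("wide networks can memorize the study within 50 restarts", {
  X <- actual_inputs()
  cases <- list(yield = 18, viability = 17,
                viable_cells = 14)
  for (resp in names(cases)) {
    y <- study$response[[resp]]
    best <- max(vapply(1:50, function(s) {
      f <- train_bpnn(X, y, n_hidden = cases[[resp]], seed = s)
      cor(y, predict(f, X))
    }, 1))
    expect_gte(best, 0.95)
  }
})

test_that("degenerate inputs are rejected", {
  X <- actual_inputs()
  expect_error(train_bpnn(X[1:3, ], study$response$yield[1:3]),
               class = "protodoe_train_error")
  expect_error(train_bpnn(X, c(NA, study$response$yield[-1])),
               class = "protodoe_train_error")
})
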