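test_that("quadratic fit equals the normal-equations oracle", {
  y <- withr::with_seed(11, rnorm(17))
  fit <- fit_quadratic(study$design, y)
  Xc <- as.matrix(study$design[paste0(paper_factors$symbol, "_coded")])
  M <- oracle_model_matrix(Xc)
  beta <- solve(crossprod(M), crossprod(M, y))  # explicit Gram-matrix solve
  expect_equal(unname(coef(fit, "coded")), as.numeric(beta), tolerance = 1e-8)
})

test_that("a noiseless quadratic is recovered to numerical precision", {
  truth <- random_quadratic(seed = 7)
  y <- predict(truth, actual_inputs())
  fit <- fit_quadratic(study$design, y)
  expect_equal(coef(fit, "actual"), coef(truth, "actual"), tolerance = 1e-9)
  expect_equal(fit$fitted, y, tolerance = 1e-9)
})

test_that("coefficient unit conversion round-trips and preserves predictions", {
  m <- random_quadratic(seed = 3, space = "actual")
  back <- quadratic_model(coef(m, "coded"), paper_factors, unit_space = "coded")
  expect_equal(coef(back, "actual"), coef(m, "actual"), tolerance = 1e-10)
  pts <- coded_to_actual(withr::with_seed(8, matrix(runif(60) * 2 - 1, ncol = 3)),
                         paper_factors)
  agree <- predict(m, pts, units = "actual") -
    predict(m, actual_to_coded(pts, paper_factors), units = "coded")
  expect_lt(max(abs(agree)), 1e-10)
})

test_that("underdetermined and singular designs are rejected", {
  small <- study$design[1:9, ]
  attr(small, "factors") <- paper_factors
  expect_error(fit_quadratic(small, study$response$yield[1:9]),
               class = "protodoe_underdetermined")
  degenerate <- study$design
  degenerate$C_coded <- degenerate$B_coded
  degenerate$C_actual <- degenerate$B_actual
  expect_error(fit_quadratic(degenerate, study$response$yield),
               class = "protodoe_singular_design")
})

test_that("study predictions at the reported optimum match the printed values", {
  fy <- fit_quadratic(study$design, study$response$yield, response_name = "yield")
  fv <- fit_quadratic(study$design, study$response$viability, response_name = "viability")
  expect_equal(predict(fy, c(1.86, 1.00, 0.50)), 1.464, tolerance = 0.01 / 1.464)
  expect_equal(predict(fv, c(1.86, 1.00, 0.50)), 90.81, tolerance = 0.2 / 90.81)
  # evaluating at the design rows reproduces the stored fitted values
  expect_equal(predict(fy, actual_inputs()), fy$fitted, tolerance = 1e-10)
})

test_that("ANOVA decomposition satisfies its additivity and R2 identities", {
  for (resp in c("yield", "viability")) {
    fit <- fit_quadratic(study$design, study$response[[resp]])
    an <- anova(fit)
    tab <- tidy(an)
    ss <- setNames(tab$sum_sq, tab$source)
    df <- setNames(tab$df, tab$source)
    expect_equal(ss[["model"]] + ss[["residual"]], ss[["total"]],
                 tolerance = 1e-8)
    expect_equal(ss[["lack_of_fit"]] + ss[["pure_error"]], ss[["residual"]],
                 tolerance = 1e-8)
    expect_equal(df[["model"]] + df[["residual"]], df[["total"]])
    expect_equal(df[["lack_of_fit"]] + df[["pure_error"]], df[["residual"]])
    expect_equal(df[["model"]], 9)
    n <- an$n
    expect_equal(an$R2_adjusted,
                 1 - (ss[["residual"]] / df[["residual"]]) / (ss[["total"]] / (n - 1)))
    expect_true(an$R2_adjusted <= an$R2)
    expect_true(an$R2_predicted <= an$R2)
    expect_true(an$R2 >= 0 && an$R2 <= 1)
  }
})

test_that("PRESS equals the literal leave-one-out refit error sum", {
  sim <- simulate_bbd_responses(protoplast_surface_preset("yield", seed = 21))
  y <- sim$response$yield
  fit <- fit_quadratic(sim$design, y)
  an <- anova(fit)
  X <- actual_inputs(sim$design)
  press_loo <- sum(sapply(seq_along(y), function(i) {
    d_i <- sim$design[-i, ]
    attr(d_i, "factors") <- paper_factors
    f_i <- fit_quadratic(d_i, y[-i])
    (y[i] - predict(f_i, X[i, , drop = FALSE]))^2
  }))
  expect_equal(an$PRESS, press_loo, tolerance = 1e-6)
})

test_that("a perfect fit is flagged with infinite F and zero p", {
  truth <- random_quadratic(seed = 9)
  y <- predict(truth, actual_inputs())
  an <- anova(fit_quadratic(study$design, y))
  expect_identical(an$F_model, Inf)
  expect_identical(an$p_model, 0)
  expect_equal(an$R2, 1)
})

test_that("surface grids agree with pointwise prediction and locate the optimum", {
  fy <- fit_quadratic(study$design, study$response$yield, response_name = "yield")
  g <- surface_grid(fy, c("A", "B"), fixed = c(C = 0.50), resolution = 201)
  i <- which.max(g$value)
  step <- c(diff(sort(unique(g$x)))[1], diff(sort(unique(g$y)))[1])
  # independent box-constrained oracle for the slice maximum
  oracle <- optim(c(2, 0.75), function(p) -predict(fy, c(p, 0.50)),
                  method = "L-BFGS-B", lower = c(1, 0.5), upper = c(3, 1))
  expect_lt(abs(g$x[i] - oracle$par[1]), step[1] + 1e-9)
  expect_lt(abs(g$y[i] - oracle$par[2]), step[2] + 1e-9)
  # grid values equal predict() at the nodes
  pts <- cbind(g$x[1:20], g$y[1:20], 0.50)
  expect_equal(g$value[1:20], predict(fy, pts), tolerance = 1e-12)
  flat <- quadratic_model(c(5, rep(0, 9)), paper_factors, unit_space = "actual")
  expect_true(all(surface_grid(flat, c("A", "C"), resolution = 11)$value == 5))
})

test_that("main-effect spans match a dense sweep oracle and rank A > B > C for yield", {
  fy <- fit_quadratic(study$design, study$response$yield, response_name = "yield")
  spans <- main_effect_spans(fy)
  expect_equal(spans$symbol, c("A", "B", "C"))
  # dense 1-D sweep oracle
  sweep_span <- function(i) {
    grid <- seq(paper_factors$low[i], paper_factors$high[i], length.out = 2001)
    mid <- (paper_factors$low + paper_factors$high) / 2
    X <- matrix(rep(mid, each = length(grid)), ncol = 3)
    X[, i] <- grid
    diff(range(predict(fy, X)))
  }
  oracle <- sapply(1:3, sweep_span)
  expect_equal(sort(spans$span, decreasing = TRUE), sort(oracle, decreasing = TRUE),
               tolerance = 1e-6)
  # additive coded model with equal linear terms has equal spans
  add <- quadratic_model(c(0, 1, 1, 1, rep(0, 6)), paper_factors, unit_space = "coded")
  expect_equal(main_effect_spans(add)$span, rep(2, 3))
  expect_equal(main_effect_spans(add)$symbol, c("A", "B", "C"))
  # a factor absent from every term has zero span
  only_a <- quadratic_model(c(0, 1, 0, 0, rep(0, 6)), paper_factors, unit_space = "coded")
  expect_equal(main_effect_spans(only_a)$span[2:3], c(0, 0))
})

test_that("desirability optimum matches analytic and grid oracles", {
  # single concave coded quadratic: analytic interior vertex
  m <- quadratic_model(c(1, 0.2, -0.1, 0, 0, 0, 0, -1, -1, -1),
                       paper_factors, unit_space = "coded")
  opt <- optimize_desirability(list(resp = m),
                               goals = list(resp = list(goal = "maximize",
                                                        low = 0, high = 2)))
  vertex_coded <- c(0.1, -0.05, 0)
  expect_equal(unname(opt$settings),
               unname(coded_to_actual(vertex_coded, paper_factors)),
               tolerance = 1e-3)
  # two-response study optimum vs an exhaustive lattice oracle
  fy <- fit_quadratic(study$design, study$response$yield, response_name = "yield")
  fv <- fit_quadratic(study$design, study$response$viability, response_name = "viability")
  models <- list(yield = fy, viability = fv)
  opt2 <- optimize_desirability(models)
  axes <- lapply(1:3, function(i) seq(paper_factors$low[i], paper_factors$high[i],
                                      length.out = 101))
  lattice <- as.matrix(expand.grid(axes))
  anchors <- lapply(models, function(m) range(m$data$y))
  dvals <- exp(rowMeans(log(pmax(sapply(names(models), function(nm) {
    y <- predict(models[[nm]], lattice)
    pmin(1, pmax(0, (y - anchors[[nm]][1]) / diff(anchors[[nm]])))
  }), 0))))
  expect_gte(opt2$desirability, max(dvals) - 1e-6)
  step <- sapply(axes, function(a) diff(a[1:2]))
  expect_true(all(abs(opt2$settings - lattice[which.max(dvals), ]) <= step + 1e-9))
})

test_that("desirability is zero at the lower anchor of a maximize goal", {
  m <- quadratic_model(c(5, rep(0, 9)), paper_factors, unit_space = "actual")
  expect_warning(
    opt <- optimize_desirability(list(r = m),
                                 goals = list(r = list(goal = "maximize",
                                                       low = 5, high = 6))),
    "degenerate")
  expect_true(opt$degenerate)
  expect_equal(opt$desirability, 0)
  expect_error(optimize_desirability(list()), class = "protodoe_goal_error")
})
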