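#' Evaluate a fitted surface on a two-factor lattice
#'
#' Builds a `resolution` x `resolution` lattice over the actual-unit ranges
#' of two factors, holds the remaining factors at supplied values (default:
#' range midpoints), and evaluates the model at every node. The long-format
#' result feeds [ggplot2::autoplot()] or external 3-D plotting.
#'
#' @param model A `quadratic_model` (or any object with a compatible
#'   `predict` method and `factors` element).
#' @param vary Character vector of two distinct factor symbols to sweep.
#' @param fixed Named numeric vector of actual-unit settings for the
#'   remaining factors; defaults to their midpoints.
#' @param resolution Nodes per axis (default 101).
#' @return A tibble with columns `x`, `y`, `value` (and the vary symbols as
#'   attributes), class `surface_grid`.
#' @export
#' @examples
#' study <- load_protoplast_study()
#' fit <- fit_quadratic(study$design, study$response$yield)
#' surface_grid(fit, c("A", "B"), fixed = c(C = 0.5), resolution = 21)
surface_grid <- function(model, vary, fixed = NULL, resolution = 101) {
  factors <- model$factors
  if (length(vary) != 2 || anyDuplicated(vary) ||
      !all(vary %in% factors$symbol)) {
    rlang::abort("`vary` must name two distinct factors of the model",
                 class = "protodoe_factor_error")
  }
  iv <- match(vary, factors$symbol)
  others <- setdiff(seq_len(nrow(factors)), iv)
  mid <- (factors$high + factors$low) / 2
  fix <- mid[others]
  names(fix) <- factors$symbol[others]
  if (!is.null(fixed)) {
    unknown <- setdiff(names(fixed), names(fix))
    if (length(unknown)) {
      rlang::abort(paste("`fixed` names factors not held constant:",
                         paste(unknown, collapse = ", ")),
                   class = "protodoe_factor_error")
    }
    fix[names(fixed)] <- fixed
  }
  gx <- seq(factors$low[iv[1]], factors$high[iv[1]], length.out = resolution)
  gy <- seq(factors$low[iv[2]], factors$high[iv[2]], length.out = resolution)
  grid <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  X <- matrix(NA_real_, nrow = nrow(grid), ncol = nrow(factors))
  X[, iv[1]] <- grid$x
  X[, iv[2]] <- grid$y
  for (o in others) X[, o] <- fix[factors$symbol[o]]
  out <- tibble::tibble(x = grid$x, y = grid$y,
                        value = predict(model, X, units = "actual"))
  attr(out, "vary") <- vary
  attr(out, "fixed") <- fix
  attr(out, "response_name") <- model$response_name
  class(out) <- c("surface_grid", class(out))
  out
}

#' @method autoplot surface_grid
#' @export
autoplot.surface_grid <- function(object, ...) {
  vary <- attr(object, "vary")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$value, z = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(colour = "white", linewidth = 0.25) +
    ggplot2::scale_fill_viridis_c(name = attr(object, "response_name")) +
    ggplot2::labs(x = vary[1], y = vary[2]) +
    ggplot2::theme_minimal()
}

# extremes of a + b*x + c*x^2 on [lo, hi]: endpoints plus interior vertex
quad_1d_range <- function(a, b, cc, lo, hi) {
  xs <- c(lo, hi)
  if (cc != 0) {
    v <- -b / (2 * cc)
    if (v > lo && v < hi) xs <- c(xs, v)
  }
  vals <- a + b * xs + cc * xs^2
  range(vals)
}

#' Rank factors by main-effect span
#'
#' For each factor, sweeps it over its actual-unit range with every other
#' factor held at its midpoint and records the span (max - min) of the
#' predicted response along that slice — the "steepness" reading used to
#' order factor influence on response-surface plots. Extremes are located
#' analytically (endpoints plus the interior vertex of the 1-D quadratic).
#'
#' @param model A fitted `quadratic_model`.
#' @return A tibble (`symbol`, `name`, `span`) sorted by decreasing span;
#'   ties keep factor order.
#' @export
#' @examples
#' study <- load_protoplast_study()
#' fit <- fit_quadratic(study$design, study$response$yield)
#' main_effect_spans(fit)
main_effect_spans <- function(model) {
  factors <- model$factors
  k <- nrow(factors)
  co <- model$coef_actual
  pairs <- utils::combn(k, 2)
  mid <- (factors$high + factors$low) / 2
  spans <- vapply(seq_len(k), function(i) {
    others <- setdiff(seq_len(k), i)
    a <- co[1] + sum(co[1 + others] * mid[others]) +
      sum(co[1 + k + ncol(pairs) + others] * mid[others]^2)
    b <- co[1 + i]
    for (p in seq_len(ncol(pairs))) {
      pi <- pairs[1, p]; pj <- pairs[2, p]
      cij <- co[1 + k + p]
      if (pi == i) b <- b + cij * mid[pj]
      else if (pj == i) b <- b + cij * mid[pi]
      else a <- a + cij * mid[pi] * mid[pj]
    }
    d <- co[1 + k + ncol(pairs) + i]
    diff(quad_1d_range(a, b, d, factors$low[i], factors$high[i]))
  }, numeric(1))
  out <- tibble::tibble(symbol = factors$symbol, name = factors$name, span = spans)
  out[order(-out$span), ]
}

# Derringer one-sided / two-sided desirability transform
desirability_d <- function(y, goal) {
  w <- goal$weight %||% 1
  lo <- goal$low; hi <- goal$high
  d <- switch(goal$goal,
    maximize = pmin(1, pmax(0, (y - lo) / (hi - lo)))^w,
    minimize = pmin(1, pmax(0, (hi - y) / (hi - lo)))^w,
    target = {
      tg <- goal$target
      d <- ifelse(y <= tg,
                  pmax(0, (y - lo) / (tg - lo)),
                  pmax(0, (hi - y) / (hi - tg)))
      pmin(1, d)^w
    },
    rlang::abort(sprintf("unknown goal '%s'", goal$goal),
                 class = "protodoe_goal_error")
  )
  d
}

#' Multi-response optimization by Derringer desirability
#'
#' Transforms each response onto a 0-1 desirability scale (linear ramp
#' between its anchors) and maximizes the geometric mean over the factor box.
#' A coarse lattice scan seeds multiple L-BFGS-B polishing runs, so the
#' reported optimum is a verified global maximum up to lattice resolution.
#'
#' @param models Named list of fitted `quadratic_model` objects (names are
#'   response labels).
#' @param goals Optional named list, one entry per response:
#'   `list(goal = "maximize"|"minimize"|"target", low =, high =, target =,
#'   weight = 1)`. Anchors default to the observed response range and the
#'   goal defaults to maximize.
#' @param n_starts Number of polishing starts (default 32: the best lattice
#'   nodes plus seeded random starts).
#' @param grid_resolution Nodes per axis of the seeding lattice (default 21).
#' @param seed Integer seed for the random starts (default 0).
#' @return An `optim_result`: list with `settings` (named actual-unit
#'   vector), `predicted` (named responses), `desirability`, and `degenerate`
#'   flag (TRUE when no point in the box has positive desirability).
#' @export
#' @examples
#' study <- load_protoplast_study()
#' fits <- list(
#'   yield = fit_quadratic(study$design, study$response$yield, response_name = "yield"),
#'   viability = fit_quadratic(study$design, study$response$viability,
#'                             response_name = "viability")
#' )
#' optimize_desirability(fits)
optimize_desirability <- function(models, goals = NULL, n_starts = 32,
                                  grid_resolution = 21, seed = 0) {
  if (!length(models)) {
    rlang::abort("`models` must contain at least one fitted model",
                 class = "protodoe_goal_error")
  }
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    rlang::abort("`models` must be a named list", class = "protodoe_goal_error")
  }
  factors <- models[[1]]$factors
  k <- nrow(factors)
  goals <- goals %||% list()
  for (nm in names(models)) {
    g <- goals[[nm]] %||% list()
    g$goal <- g$goal %||% "maximize"
    if (is.null(g$low) || is.null(g$high)) {
      y <- models[[nm]]$data$y
      if (is.null(y)) {
        rlang::abort(sprintf("response '%s': supply goal anchors for a coefficient-built model", nm),
                     class = "protodoe_goal_error")
      }
      g$low <- g$low %||% min(y)
      g$high <- g$high %||% max(y)
    }
    goals[[nm]] <- g
  }
  D <- function(X) {
    X <- as_settings_matrix(X, k)
    ds <- vapply(names(models), function(nm) {
      desirability_d(predict(models[[nm]], X, units = "actual"), goals[[nm]])
    }, numeric(nrow(X)))
    if (nrow(X) == 1) ds <- matrix(ds, nrow = 1)
    ws <- vapply(names(models), function(nm) goals[[nm]]$weight %||% 1, 1)
    exp(as.vector(log(pmax(ds, 0)) %*% ws) / sum(ws))
  }
  # lattice scan seeds the local polish
  axes <- lapply(seq_len(k), function(i) {
    seq(factors$low[i], factors$high[i], length.out = grid_resolution)
  })
  lattice <- as.matrix(do.call(expand.grid, axes))
  dvals <- D(lattice)
  ord <- order(-dvals)
  n_seed <- min(ceiling(n_starts / 2), nrow(lattice))
  starts <- lattice[ord[seq_len(n_seed)], , drop = FALSE]
  n_rand <- max(0, n_starts - n_seed)
  if (n_rand > 0) {
    rand <- withr::with_seed(seed, matrix(stats::runif(n_rand * k), ncol = k))
    rand <- sweep(sweep(rand, 2, factors$high - factors$low, `*`), 2, factors$low, `+`)
    starts <- rbind(starts, rand)
  }
  best <- list(par = starts[1, ], value = dvals[ord[1]])
  for (s in seq_len(nrow(starts))) {
    res <- stats::optim(starts[s, ], function(x) -D(x), method = "L-BFGS-B",
                        lower = factors$low, upper = factors$high,
                        control = list(factr = 1e4))
    if (-res$value > best$value) best <- list(par = res$par, value = -res$value)
  }
  settings <- stats::setNames(as.numeric(best$par), factors$symbol)
  predicted <- vapply(models, function(m) predict(m, settings, units = "actual"), 1)
  degenerate <- !is.finite(best$value) || best$value <= 0
  if (degenerate) {
    rlang::warn("desirability is zero everywhere in the box; result is degenerate")
  }
  structure(list(settings = settings, predicted = predicted,
                 desirability = max(best$value, 0), degenerate = degenerate,
                 goals = goals, method = "desirability"),
            class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat(sprintf("Optimum (%s)\n", x$method))
  cat("  settings:  ", paste(sprintf("%s = %.4g", names(x$settings), x$settings),
                             collapse = ", "), "\n")
  cat("  predicted: ", paste(sprintf("%s = %.4g", names(x$predicted), x$predicted),
                             collapse = ", "), "\n")
  if (!is.null(x$desirability)) cat(sprintf("  desirability: %.4f\n", x$desirability))
  invisible(x)
}
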