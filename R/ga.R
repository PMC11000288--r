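as_bounds_matrix <- function(bounds) {
  if (is.data.frame(bounds) && all(c("low", "high") %in% names(bounds))) {
    out <- cbind(low = bounds$low, high = bounds$high)
    rownames(out) <- if ("symbol" %in% names(bounds)) bounds$symbol else NULL
    bounds <- out
  }
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2 || !all(is.finite(bounds)) || any(bounds[, 1] >= bounds[, 2])) {
    rlang::abort("`bounds` must be a k x 2 matrix of finite low < high pairs",
                 class = "protodoe_ga_error")
  }
  bounds
}

#' Maximize an objective over a factor box with a real-coded genetic algorithm
#'
#' Tournament selection (size 2), blend (BLX-0.5) crossover, Gaussian
#' mutation with standard deviation `mutation_scale` times each factor's
#' range (clipped to the box), and elitism. The best-ever individual is
#' returned, so the per-generation best trace is non-decreasing.
#'
#' @param objective Function taking a settings vector, returning a finite
#'   scalar to maximize. Minimize by negating.
#' @param bounds k x 2 matrix (or factor tibble / data frame with `low` and
#'   `high` columns) of box constraints.
#' @param population,generations GA size controls (population >= 4).
#' @param crossover_rate,mutation_rate,mutation_scale,elitism Operator
#'   controls.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return A `ga_result`: list with `par` (best settings), `value`, and
#'   `trace` (tibble of per-generation best objective).
#' @export
#' @examples
#' ga_optimize(function(x) -sum((x - 1)^2), cbind(low = c(0, 0), high = c(2, 2)),
#'             generations = 50, seed = 1)
ga_optimize <- function(objective, bounds, population = 50, generations = 200,
                        crossover_rate = 0.8, mutation_rate = 0.1,
                        mutation_scale = 0.1, elitism = 2, seed = 0) {
  bounds <- as_bounds_matrix(bounds)
  if (population < 4) {
    rlang::abort("population must be >= 4", class = "protodoe_ga_error")
  }
  k <- nrow(bounds)
  lo <- bounds[, 1]; hi <- bounds[, 2]; range <- hi - lo
  evaluate <- function(P) {
    v <- vapply(seq_len(nrow(P)), function(i) objective(P[i, ]), numeric(1))
    if (any(!is.finite(v))) {
      bad <- P[which(!is.finite(v))[1], ]
      rlang::abort(paste("objective is non-finite at settings",
                         paste(signif(bad, 6), collapse = ", ")),
                   class = "protodoe_ga_error")
    }
    v
  }
  withr::with_seed(seed, {
    P <- sweep(sweep(matrix(stats::runif(population * k), ncol = k),
                     2, range, `*`), 2, lo, `+`)
    fit <- evaluate(P)
    best <- list(par = P[which.max(fit), ], value = max(fit))
    trace <- numeric(generations)
    for (gen in seq_len(generations)) {
      ord <- order(-fit)
      elite <- P[ord[seq_len(min(elitism, population))], , drop = FALSE]
      tournament <- function() {
        c1 <- sample.int(population, 2)
        P[c1[which.max(fit[c1])], ]
      }
      children <- matrix(NA_real_, population - nrow(elite), k)
      for (i in seq_len(nrow(children))) {
        p1 <- tournament(); p2 <- tournament()
        if (stats::runif(1) < crossover_rate) {
          # BLX-alpha: sample uniformly in the interval stretched by alpha = 0.5
          cmin <- pmin(p1, p2); cmax <- pmax(p1, p2); d <- cmax - cmin
          child <- stats::runif(k, cmin - 0.5 * d, cmax + 0.5 * d)
        } else {
          child <- p1
        }
        mutate <- stats::runif(k) < mutation_rate
        child[mutate] <- child[mutate] +
          stats::rnorm(sum(mutate), 0, mutation_scale * range[mutate])
        children[i, ] <- pmin(pmax(child, lo), hi)
      }
      P <- rbind(elite, children)
      fit <- evaluate(P)
      if (max(fit) > best$value) {
        best <- list(par = P[which.max(fit), ], value = max(fit))
      }
      trace[gen] <- best$value
    }
    par <- stats::setNames(as.numeric(best$par),
                           rownames(bounds) %||% paste0("x", seq_len(k)))
    structure(list(par = par, value = best$value,
                   trace = tibble::tibble(generation = seq_len(generations),
                                          best_value = trace)),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat("Genetic-algorithm optimum\n")
  cat("  settings:", paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "), "\n")
  cat(sprintf("  value: %.6g\n", x$value))
  invisible(x)
}

#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$generation, y = .data$best_value)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "best objective") +
    ggplot2::theme_minimal()
}
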