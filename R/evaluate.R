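#' Goodness-of-fit panel for observed vs predicted responses
#'
#' Computes the Pearson correlation R, the coefficient of determination
#' (taken as R squared, the convention of model-comparison tables), the root
#' mean square error `sqrt(mean((obs - pred)^2))` and the mean absolute
#' percentage error `100 * mean(|obs - pred| / |obs|)`.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return A one-row tibble with `R`, `R2`, `RMSE`, `MAPE`, `n`. `MAPE` is
#'   `NA` (with a warning) when any observed value is zero.
#' @export
#' @examples
#' fit_metrics(c(1, 2, 4), c(1, 2, 5))
fit_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    rlang::abort("`observed` and `predicted` must be equal-length vectors (n >= 2)",
                 class = "protodoe_metric_error")
  }
  obs <- as.numeric(observed); pred <- as.numeric(predicted)
  r <- stats::cor(obs, pred)
  rmse <- sqrt(mean((obs - pred)^2))
  if (any(obs == 0)) {
    rlang::warn("MAPE undefined: an observed value is zero")
    mape <- NA_real_
  } else {
    mape <- 100 * mean(abs(obs - pred) / abs(obs))
  }
  tibble::tibble(R = r, R2 = r^2, RMSE = rmse, MAPE = mape, n = length(obs))
}

#' Coefficient of variation of a data series
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation — the
#' data-dispersion reading of C.V.%. (The ANOVA adequacy C.V.% reported by
#' [anova.quadratic_model()] uses `sqrt(MS_residual)` instead.)
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return Percent coefficient of variation (`NA` with a warning for a zero
#'   mean).
#' @export
#' @examples
#' cv_percent(c(0.955, 0.945, 1.035, 1.090, 1.010))
cv_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    rlang::abort("need at least 2 values", class = "protodoe_metric_error")
  }
  m <- mean(values)
  if (m == 0) {
    rlang::warn("C.V.% undefined: mean is zero")
    return(NA_real_)
  }
  100 * stats::sd(values) / m
}

#' Number of viable cells
#'
#' The combined evaluation index for protoplast preparations:
#' yield x viability / 100, in the same 1e6-per-100-mg units as yield.
#'
#' @param yield Nonnegative protoplast yield(s).
#' @param viability Viability percentage(s) in `[0, 100]`.
#' @return Numeric vector of viable-cell counts.
#' @export
#' @examples
#' viable_cells(1.566, 87.27)
viable_cells <- function(yield, viability) {
  yield <- as.numeric(yield); viability <- as.numeric(viability)
  if (any(yield < 0)) {
    rlang::abort("yield must be >= 0", class = "protodoe_range_error")
  }
  if (any(viability < 0 | viability > 100)) {
    rlang::abort("viability must be between 0 and 100 percent",
                 class = "protodoe_range_error")
  }
  yield * viability / 100
}

#' Relative prediction error
#'
#' `100 * |predicted - observed| / |observed|`, the validation statistic used
#' to judge whether a model's optimum prediction is credible (conventionally,
#' below 5 percent).
#'
#' @param predicted,observed Numeric vectors; `observed` must be nonzero.
#' @return Percent relative error (`NA` with a warning where observed is 0).
#' @export
#' @examples
#' relative_error(1.464, 1.470)
relative_error <- function(predicted, observed) {
  predicted <- as.numeric(predicted); observed <- as.numeric(observed)
  out <- 100 * abs(predicted - observed) / abs(observed)
  if (any(observed == 0)) {
    rlang::warn("relative error undefined where observed is zero")
    out[observed == 0] <- NA_real_
  }
  out
}

#' Side-by-side model comparison report
#'
#' One [fit_metrics()] row per model, with flags for the highest R-squared
#' and the lowest RMSE and MAPE. Ties keep the first model in input order.
#'
#' @param models Named list; each element is a list with `observed` and
#'   `predicted` vectors.
#' @return A tibble with one row per model: the metric panel plus logical
#'   `best_r2`, `best_rmse`, `best_mape` columns.
#' @export
#' @examples
#' comparison_report(list(
#'   perfect = list(observed = 1:5, predicted = 1:5),
#'   noisy = list(observed = 1:5, predicted = c(1, 2.2, 2.9, 4, 5.3))
#' ))
comparison_report <- function(models) {
  if (!length(models)) {
    rlang::abort("`models` must be nonempty", class = "protodoe_metric_error")
  }
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    rlang::abort("`models` must be a named list", class = "protodoe_metric_error")
  }
  rows <- purrr::imap(models, function(m, nm) {
    dplyr::bind_cols(tibble::tibble(model = nm),
                     fit_metrics(m$observed, m$predicted))
  })
  out <- dplyr::bind_rows(rows)
  flag_best <- function(x, highest) {
    best <- if (highest) which.max(x) else which.min(x)
    seq_along(x) == best
  }
  out$best_r2 <- flag_best(out$R2, highest = TRUE)
  out$best_rmse <- flag_best(out$RMSE, highest = FALSE)
  out$best_mape <- if (all(is.na(out$MAPE))) NA else flag_best(out$MAPE, highest = FALSE)
  out
}
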