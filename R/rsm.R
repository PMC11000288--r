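quad_term_names <- function(symbols) {
  k <- length(symbols)
  pairs <- utils::combn(k, 2)
  c("(Intercept)", symbols,
    paste0(symbols[pairs[1, ]], ":", symbols[pairs[2, ]]),
    paste0(symbols, "^2"))
}

# full second-order model matrix: [1, x_i, x_i x_j (i<j), x_i^2]
quad_model_matrix <- function(X) {
  k <- ncol(X)
  pairs <- utils::combn(k, 2)
  inter <- vapply(seq_len(ncol(pairs)),
                  function(p) X[, pairs[1, p]] * X[, pairs[2, p]],
                  numeric(nrow(X)))
  if (nrow(X) == 1) inter <- matrix(inter, nrow = 1)
  cbind(1, X, inter, X^2)
}

# re-express a full quadratic under the affine substitution x_old = s*x_new + t
affine_requad <- function(coef, s, t) {
  k <- length(s)
  pairs <- utils::combn(k, 2)
  a <- coef[1]
  b <- coef[1 + seq_len(k)]
  cc <- coef[1 + k + seq_len(ncol(pairs))]
  d <- coef[1 + k + ncol(pairs) + seq_len(k)]
  new_a <- a + sum(b * t) + sum(d * t^2)
  new_b <- b * s + 2 * d * s * t
  new_c <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    new_a <- new_a + cc[p] * t[i] * t[j]
    new_b[i] <- new_b[i] + cc[p] * s[i] * t[j]
    new_b[j] <- new_b[j] + cc[p] * s[j] * t[i]
    new_c[p] <- cc[p] * s[i] * s[j]
  }
  out <- c(new_a, new_b, new_c, d * s^2)
  names(out) <- names(coef)
  out
}

coef_coded_to_actual <- function(coef, factors) {
  half <- (factors$high - factors$low) / 2
  mid <- (factors$high + factors$low) / 2
  # coded model evaluated at x_c = (x_a - mid)/half
  affine_requad(coef, s = 1 / half, t = -mid / half)
}

coef_actual_to_coded <- function(coef, factors) {
  half <- (factors$high - factors$low) / 2
  mid <- (factors$high + factors$low) / 2
  # actual model evaluated at x_a = mid + half * x_c
  affine_requad(coef, s = half, t = mid)
}

#' Construct a quadratic response-surface model from known coefficients
#'
#' Builds the same object [fit_quadratic()] returns, from a coefficient
#' vector. Used for known ground-truth surfaces (see [surface_spec()]) and
#' for models imported from published equations.
#'
#' @param coefficients Numeric vector of length `1 + 2k + choose(k,2)` in the
#'   fixed term order: intercept, linear terms, pairwise interactions
#'   (factor-pair order), pure quadratics.
#' @param factors Factor tibble (see [bbd_factor()]).
#' @param unit_space `"coded"` or `"actual"`: the space the coefficients are
#'   expressed in.
#' @param response_name Label for the modelled response.
#' @return A `quadratic_model` object.
#' @export
quadratic_model <- function(coefficients, factors,
                            unit_space = c("actual", "coded"),
                            response_name = "response") {
  check_factors(factors)
  unit_space <- match.arg(unit_space)
  k <- nrow(factors)
  p <- 1 + 2 * k + choose(k, 2)
  if (length(coefficients) != p) {
    rlang::abort(sprintf("expected %d coefficients for %d factors, got %d",
                         p, k, length(coefficients)),
                 class = "protodoe_dimension_error")
  }
  coefficients <- stats::setNames(as.numeric(coefficients),
                                  quad_term_names(factors$symbol))
  coef_coded <- if (unit_space == "coded") coefficients
                else coef_actual_to_coded(coefficients, factors)
  coef_actual <- if (unit_space == "actual") coefficients
                 else coef_coded_to_actual(coefficients, factors)
  structure(list(factors = factors,
                 unit_space = unit_space,
                 response_name = response_name,
                 coef_coded = coef_coded,
                 coef_actual = coef_actual),
            class = "quadratic_model")
}

#' Fit the full second-order response-surface model
#'
#' Ordinary least squares on the complete 10-term (for three factors)
#' quadratic: intercept, linear, pairwise-interaction and pure-quadratic
#' terms. The fit is carried out on coded (-1..+1) levels, which keeps the
#' normal equations well conditioned, and coefficients are stored in both
#' coded and actual units.
#'
#' @param design A `bbd_design` tibble from [generate_bbd()] or
#'   [load_protoplast_study()].
#' @param response Numeric vector of per-run responses (design order), or the
#'   name of a column of `design`.
#' @param unit_space Which coefficient space [coef()], [tidy()] and `print()`
#'   report by default; both spaces are always available.
#' @param response_name Label for the response; defaults to the column name
#'   when `response` is one.
#'
#' @return A `quadratic_model`; see [quadratic_model()]. Fit context (design
#'   matrices, observed response, fitted values, leverages) is kept so that
#'   [anova()][anova.quadratic_model] and [optimize_desirability()] can reuse
#'   it.
#' @export
#' @examples
#' study <- load_protoplast_study()
#' fit <- fit_quadratic(study$design, study$response$yield, response_name = "yield")
#' coef(fit)
fit_quadratic <- function(design, response, unit_space = c("coded", "actual"),
                          response_name = NULL) {
  unit_space <- match.arg(unit_space)
  factors <- design_factors(design)
  if (is.character(response) && length(response) == 1) {
    response_name <- response_name %||% response
    response <- design[[response]]
    if (is.null(response)) {
      rlang::abort("response column not found in design", class = "protodoe_fit_error")
    }
  }
  response_name <- response_name %||% "response"
  y <- as.numeric(response)
  Xc <- design_coded_matrix(design)
  n <- nrow(Xc)
  k <- ncol(Xc)
  p <- 1 + 2 * k + choose(k, 2)
  if (length(y) != n) {
    rlang::abort("response length does not match the number of runs",
                 class = "protodoe_dimension_error")
  }
  if (n <= p) {
    rlang::abort(sprintf("need more runs (%d) than model terms (%d)", n, p),
                 class = "protodoe_underdetermined")
  }
  M <- quad_model_matrix(Xc)
  ls <- stats::lm.fit(M, y)
  if (ls$rank < p) {
    rlang::abort("design is singular for the full second-order model",
                 class = "protodoe_singular_design")
  }
  coefs <- stats::setNames(ls$coefficients, quad_term_names(factors$symbol))
  fit <- quadratic_model(coefs, factors, unit_space = "coded",
                         response_name = response_name)
  fit$unit_space <- unit_space
  fit$data <- list(coded = Xc, actual = design_actual_matrix(design), y = y)
  fit$fitted <- as.numeric(M %*% coefs)
  fit$residuals <- y - fit$fitted
  fit$leverage <- stats::hat(M, intercept = FALSE)
  fit
}

#' @export
coef.quadratic_model <- function(object, units = object$unit_space, ...) {
  if (units == "coded") object$coef_coded else object$coef_actual
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("Second-order response-surface model for '%s' (%s units)\n",
              x$response_name, x$unit_space))
  print(round(coef(x), 6))
  invisible(x)
}

#' Evaluate a quadratic response-surface model
#'
#' @param object A `quadratic_model`.
#' @param newdata Settings to predict at: a numeric vector (one setting), a
#'   matrix, or a data frame with one column per factor. Actual units by
#'   default.
#' @param units `"actual"` (default) or `"coded"`, the units of `newdata`.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
#' @examples
#' study <- load_protoplast_study()
#' fit <- fit_quadratic(study$design, study$response$yield)
#' predict(fit, c(1.86, 1.00, 0.50))
predict.quadratic_model <- function(object, newdata,
                                    units = c("actual", "coded"), ...) {
  units <- match.arg(units)
  X <- as_settings_matrix(newdata, nrow(object$factors))
  co <- if (units == "actual") object$coef_actual else object$coef_coded
  as.numeric(quad_model_matrix(X) %*% co)
}

#' @method tidy quadratic_model
#' @export
tidy.quadratic_model <- function(x, units = x$unit_space, ...) {
  tibble::tibble(term = names(coef(x, units)),
                 estimate = unname(coef(x, units)),
                 unit_space = units)
}

#' @method glance quadratic_model
#' @export
glance.quadratic_model <- function(x, ...) {
  if (is.null(x$data)) {
    rlang::abort("model was built from coefficients, not fitted to data",
                 class = "protodoe_fit_error")
  }
  an <- stats::anova(x)
  glance(an)
}

#' ANOVA adequacy panel for a fitted response-surface model
#'
#' Decomposes the total (mean-corrected) sum of squares into model and
#' residual, splits the residual into lack-of-fit and pure-error components
#' using replicated design points, and reports the standard adequacy
#' statistics: the model F test, R-squared, adjusted R-squared, PRESS-based
#' predicted R-squared, the coefficient of variation
#' (100 * sqrt(MS_residual) / mean response) and the adequate-precision
#' signal-to-noise ratio, (max fitted - min fitted) / sqrt(p * MS_residual / n).
#' PRESS is computed from leverages as sum((e_i / (1 - h_ii))^2), which equals
#' the literal leave-one-out refit error sum for OLS.
#'
#' @param object A `quadratic_model` fitted with [fit_quadratic()].
#' @param ... Unused.
#' @return An `rsm_anova` object; `tidy()` gives the source table, `glance()`
#'   the adequacy scalars.
#' @export
#' @examples
#' study <- load_protoplast_study()
#' fit <- fit_quadratic(study$design, study$response$yield)
#' anova(fit)
anova.quadratic_model <- function(object, ...) {
  if (is.null(object$data)) {
    rlang::abort("model was built from coefficients, not fitted to data",
                 class = "protodoe_fit_error")
  }
  y <- object$data$y
  yhat <- object$fitted
  e <- object$residuals
  n <- length(y)
  k <- nrow(object$factors)
  p <- 1 + 2 * k + choose(k, 2)

  ss_total <- sum((y - mean(y))^2)
  ss_res <- sum(e^2)
  ss_model <- ss_total - ss_res
  df_model <- p - 1
  df_res <- n - p

  # pure error from replicated design points (identical coded rows)
  key <- apply(object$data$coded, 1, paste, collapse = "/")
  groups <- split(y, key)
  reps <- groups[vapply(groups, length, 1L) > 1]
  df_pe <- sum(vapply(reps, length, 1L) - 1L)
  ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), 1))
  has_pe <- df_pe > 0
  df_lof <- df_res - df_pe
  ss_lof <- ss_res - ss_pe

  ms_model <- ss_model / df_model
  ms_res <- if (df_res > 0) ss_res / df_res else NA_real_
  zero_resid <- isTRUE(ss_res <= 1e-12 * max(ss_total, 1))
  f_model <- if (zero_resid) Inf else ms_model / ms_res
  p_model <- if (zero_resid) 0 else stats::pf(f_model, df_model, df_res, lower.tail = FALSE)

  if (has_pe && df_lof > 0 && ss_pe > 0) {
    f_lof <- (ss_lof / df_lof) / (ss_pe / df_pe)
    p_lof <- stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
  } else {
    f_lof <- NA_real_
    p_lof <- NA_real_
  }

  press <- sum((e / (1 - object$leverage))^2)
  r2 <- 1 - ss_res / ss_total
  r2_adj <- 1 - (ss_res / df_res) / (ss_total / (n - 1))
  r2_pred <- 1 - press / ss_total
  cv <- 100 * sqrt(ms_res) / mean(y)
  adeq <- (max(yhat) - min(yhat)) / sqrt(p * ms_res / n)

  tab <- tibble::tibble(
    source = c("model", "residual", "lack_of_fit", "pure_error", "total"),
    df = c(df_model, df_res, if (has_pe) df_lof else NA_integer_,
           if (has_pe) df_pe else NA_integer_, n - 1),
    sum_sq = c(ss_model, ss_res, if (has_pe) ss_lof else NA_real_,
               if (has_pe) ss_pe else NA_real_, ss_total),
    mean_sq = c(ms_model, ms_res,
                if (has_pe && df_lof > 0) ss_lof / df_lof else NA_real_,
                if (has_pe) ss_pe / df_pe else NA_real_, NA_real_),
    statistic = c(f_model, NA_real_, f_lof, NA_real_, NA_real_),
    p_value = c(p_model, NA_real_, p_lof, NA_real_, NA_real_)
  )
  structure(list(table = tab,
                 response_name = object$response_name,
                 n = n, n_terms = p,
                 F_model = f_model, p_model = p_model,
                 F_lack_of_fit = f_lof, p_lack_of_fit = p_lof,
                 R2 = r2, R2_adjusted = r2_adj, R2_predicted = r2_pred,
                 PRESS = press, cv_percent = cv, adequate_precision = adeq),
            class = "rsm_anova")
}

#' @method tidy rsm_anova
#' @export
tidy.rsm_anova <- function(x, ...) x$table

#' @method glance rsm_anova
#' @export
glance.rsm_anova <- function(x, ...) {
  tibble::tibble(F_model = x$F_model, p_model = x$p_model,
                 F_lack_of_fit = x$F_lack_of_fit,
                 p_lack_of_fit = x$p_lack_of_fit,
                 R2 = x$R2, R2_adjusted = x$R2_adjusted,
                 R2_predicted = x$R2_predicted, PRESS = x$PRESS,
                 cv_percent = x$cv_percent,
                 adequate_precision = x$adequate_precision,
                 nobs = x$n)
}

format_p <- function(p) ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))

#' @export
print.rsm_anova <- function(x, ...) {
  cat(sprintf("Response-surface ANOVA for '%s'\n", x$response_name))
  print(as.data.frame(x$table), row.names = FALSE, digits = 5)
  cat(sprintf("F = %.3f (p %s)  R2 = %.4f  adj R2 = %.4f  pred R2 = %.4f\n",
              x$F_model, format_p(x$p_model), x$R2, x$R2_adjusted, x$R2_predicted))
  cat(sprintf("C.V.%% = %.3f  adequate precision = %.3f  PRESS = %.5g\n",
              x$cv_percent, x$adequate_precision, x$PRESS))
  invisible(x)
}
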