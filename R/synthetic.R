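#' Specify a synthetic response surface
#'
#' Bundles a ground-truth quadratic with a homoscedastic Gaussian replicate
#' noise level, the number of center replicates, a seed and an optional
#' response clip — everything [simulate_bbd_responses()] needs to emulate a
#' Box-Behnken study of a known surface.
#'
#' @param truth A `quadratic_model` (fitted or built with
#'   [quadratic_model()]).
#' @param noise_sd Replicate noise standard deviation in response units
#'   (>= 0).
#' @param n_center Center replicates in the generated design.
#' @param seed Integer seed; identical specs generate identical data.
#' @param clip Optional length-2 `(low, high)` response clipping range.
#' @return A `surface_spec` list.
#' @export
surface_spec <- function(truth, noise_sd, n_center = 5, seed = 0, clip = NULL) {
  if (!inherits(truth, "quadratic_model")) {
    rlang::abort("`truth` must be a quadratic_model", class = "protodoe_sim_error")
  }
  if (noise_sd < 0) {
    rlang::abort("`noise_sd` must be >= 0", class = "protodoe_sim_error")
  }
  if (!is.null(clip) && (length(clip) != 2 || clip[1] >= clip[2])) {
    rlang::abort("`clip` must be (low, high) with low < high",
                 class = "protodoe_sim_error")
  }
  structure(list(truth = truth, noise_sd = noise_sd, n_center = n_center,
                 seed = seed, clip = clip),
            class = "surface_spec")
}

#' Packaged synthetic presets for the protoplast study
#'
#' `"yield"` uses the published actual-unit yield equation as ground truth
#' with replicate noise 0.06 (the standard deviation of the five printed
#' center yields); `"viability"` refits the packaged study's viability
#' column (its published equation has an unusable intercept) and uses noise
#' 0.97, the center-replicate viability standard deviation.
#'
#' @param response `"yield"` or `"viability"`.
#' @param seed Seed stored in the returned spec.
#' @return A [surface_spec()].
#' @export
#' @examples
#' protoplast_surface_preset("yield", seed = 1)
protoplast_surface_preset <- function(response = c("yield", "viability"), seed = 0) {
  response <- match.arg(response)
  factors <- protoplast_factors()
  if (response == "yield") {
    truth <- quadratic_model(
      c(6.119, 1.815, -4.626, -18.608, 0.436, 0.580, -0.887,
        -0.633, 3.269, 15.650),
      factors, unit_space = "actual", response_name = "yield")
    surface_spec(truth, noise_sd = 0.06, n_center = 5, seed = seed,
                 clip = c(0, Inf))
  } else {
    study <- load_protoplast_study()
    truth <- fit_quadratic(study$design, study$response$viability,
                           response_name = "viability")
    surface_spec(truth, noise_sd = 0.97, n_center = 5, seed = seed,
                 clip = c(0, 100))
  }
}

#' Simulate Box-Behnken responses from a known surface
#'
#' Generates the design with [generate_bbd()], evaluates the ground truth at
#' each run and adds i.i.d. Gaussian noise (clipped if the spec requests
#' it).
#'
#' @param spec A [surface_spec()].
#' @param factors Factor tibble; defaults to the truth model's factors.
#' @return List with `design` (a `bbd_design`) and `response` (tibble with
#'   `run_id` and a column named after the truth's response).
#' @export
#' @examples
#' sim <- simulate_bbd_responses(protoplast_surface_preset("yield", seed = 2))
#' sim$response
simulate_bbd_responses <- function(spec, factors = NULL) {
  factors <- factors %||% spec$truth$factors
  design <- generate_bbd(factors, n_center = spec$n_center)
  mu <- predict(spec$truth, design_actual_matrix(design), units = "actual")
  y <- withr::with_seed(spec$seed,
                        mu + stats::rnorm(length(mu), 0, spec$noise_sd))
  if (!is.null(spec$clip)) y <- pmin(pmax(y, spec$clip[1]), spec$clip[2])
  response <- tibble::tibble(run_id = design$run_id, value = y)
  names(response)[2] <- spec$truth$response_name
  list(design = design, response = response)
}

#' Parameter-recovery study on simulated Box-Behnken data
#'
#' Repeatedly simulates a Box-Behnken dataset from the spec's ground truth
#' and refits the full quadratic, reporting per-coefficient bias and
#' empirical standard deviation next to the closed-form OLS standard errors
#' `noise_sd * sqrt(diag((X'X)^-1))` from the design's model matrix.
#'
#' @param spec A [surface_spec()]; replicate `r` uses seed `spec$seed + r`.
#' @param factors Factor tibble; defaults to the truth model's factors.
#' @param n_reps Number of simulate-fit replicates (>= 50).
#' @return Tibble with one row per model term: `term`, `truth`, `bias`,
#'   `empirical_sd`, `theoretical_sd`. All quantities are in the truth
#'   model's reporting unit space.
#' @export
parameter_recovery_trial <- function(spec, factors = NULL, n_reps = 200) {
  if (n_reps < 50) {
    rlang::abort("`n_reps` must be >= 50", class = "protodoe_sim_error")
  }
  factors <- factors %||% spec$truth$factors
  space <- spec$truth$unit_space
  truth_coef <- coef(spec$truth, units = space)
  est <- matrix(NA_real_, n_reps, length(truth_coef))
  design <- generate_bbd(factors, n_center = spec$n_center)
  for (r in seq_len(n_reps)) {
    spec_r <- spec; spec_r$seed <- spec$seed + r; spec_r$clip <- NULL
    sim <- simulate_bbd_responses(spec_r, factors)
    fit <- fit_quadratic(sim$design, sim$response[[2]])
    est[r, ] <- coef(fit, units = space)
  }
  X <- if (space == "coded") design_coded_matrix(design) else design_actual_matrix(design)
  M <- quad_model_matrix(X)
  theo <- spec$noise_sd * sqrt(diag(solve(crossprod(M))))
  tibble::tibble(term = names(truth_coef),
                 truth = unname(truth_coef),
                 bias = colMeans(est) - unname(truth_coef),
                 empirical_sd = apply(est, 2, stats::sd),
                 theoretical_sd = theo)
}
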