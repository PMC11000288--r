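#' Define an experimental factor
#'
#' A factor is a continuous experimental variable explored over a closed
#' range. Box-Behnken designs place runs at the low, mid and high levels of
#' each factor; in coded units these are -1, 0 and +1.
#'
#' @param name Descriptive name, e.g. `"cellulase R-10"`.
#' @param symbol Single-letter symbol used in model terms (`"A"`, `"B"`, ...).
#' @param low,high Range endpoints in actual units; `low < high`.
#' @param units Unit string, e.g. `"% w/v"` or `"mol/L"`.
#'
#' @return A one-row tibble; bind several with [dplyr::bind_rows()] to form a
#'   factor table.
#' @export
#' @examples
#' bbd_factor("cellulase R-10", "A", 1, 3, "% w/v")
bbd_factor <- function(name, symbol, low, high, units = "") {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.character(symbol) || nchar(symbol) != 1) {
    rlang::abort("`symbol` must be a single character", class = "protodoe_factor_error")
  }
  if (!is.numeric(low) || !is.numeric(high) || !(low < high)) {
    rlang::abort(sprintf("factor %s: need low < high", symbol),
                 class = "protodoe_factor_error")
  }
  tibble::tibble(name = name, symbol = symbol,
                 low = as.numeric(low), high = as.numeric(high), units = units)
}

#' The three protoplast-digestion factors of the packaged study
#'
#' Cellulase R-10 (1-3 % w/v), macerozyme R-10 (0.50-1.00 % w/v) and mannitol
#' (0.50-0.70 mol/L), the ranges over which the packaged 17-run Box-Behnken
#' study explored *Salsola laricifolia* protoplast yield and viability.
#'
#' @return A three-row factor tibble (columns `name`, `symbol`, `low`,
#'   `high`, `units`).
#' @export
#' @examples
#' protoplast_factors()
protoplast_factors <- function() {
  dplyr::bind_rows(
    bbd_factor("cellulase R-10",  "A", 1.00, 3.00, "% w/v"),
    bbd_factor("macerozyme R-10", "B", 0.50, 1.00, "% w/v"),
    bbd_factor("mannitol",        "C", 0.50, 0.70, "mol/L")
  )
}

check_factors <- function(factors) {
  req <- c("name", "symbol", "low", "high", "units")
  if (!is.data.frame(factors) || !all(req %in% names(factors))) {
    rlang::abort("`factors` must be a tibble with columns name, symbol, low, high, units",
                 class = "protodoe_factor_error")
  }
  if (anyDuplicated(factors$symbol)) {
    rlang::abort("factor symbols must be unique", class = "protodoe_factor_error")
  }
  if (any(factors$low >= factors$high)) {
    rlang::abort("every factor needs low < high", class = "protodoe_factor_error")
  }
  invisible(factors)
}

#' Generate a Box-Behnken design
#'
#' Places runs at the edge midpoints of the factor cube — every unordered
#' pair of factors at all four (-1, +1) combinations with the remaining
#' factors at 0 — followed by `n_center` all-zero center runs. For k factors
#' this gives 4*choose(k,2) + n_center runs. Pairs are taken in factor order
#' ((1,2), (1,3), ..., (k-1,k)) and within a pair the first factor varies
#' fastest, the block layout used by the packaged study; no randomization is
#' applied unless `shuffle_seed` is given.
#'
#' @param factors Factor tibble as built from [bbd_factor()]; 3 to 7 rows.
#' @param n_center Number of replicated center runs (>= 0).
#' @param shuffle_seed Optional integer; when supplied the run order is
#'   permuted reproducibly. Default keeps the deterministic block order.
#'
#' @return A tibble with `run_id`, one `<symbol>_coded` and one
#'   `<symbol>_actual` column per factor, carrying the factor table in the
#'   `"factors"` attribute.
#' @export
#' @examples
#' generate_bbd(protoplast_factors(), n_center = 5)
generate_bbd <- function(factors, n_center = 5, shuffle_seed = NULL) {
  check_factors(factors)
  k <- nrow(factors)
  if (k < 3 || k > 7) {
    rlang::abort("Box-Behnken designs need between 3 and 7 factors",
                 class = "protodoe_invalid_design")
  }
  if (n_center < 0) {
    rlang::abort("`n_center` must be >= 0", class = "protodoe_invalid_design")
  }
  pairs <- utils::combn(k, 2)
  edge <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    lev <- expand.grid(first = c(-1, 1), second = c(-1, 1))  # first varies fastest
    block <- matrix(0, nrow = 4, ncol = k)
    block[, i] <- lev$first
    block[, j] <- lev$second
    block
  }))
  coded <- rbind(edge, matrix(0, nrow = n_center, ncol = k))
  if (!is.null(shuffle_seed)) {
    coded <- coded[withr::with_seed(shuffle_seed, sample.int(nrow(coded))), , drop = FALSE]
  }
  actual <- coded_to_actual(coded, factors)
  out <- tibble::tibble(run_id = seq_len(nrow(coded)))
  for (f in seq_len(k)) {
    out[[paste0(factors$symbol[f], "_coded")]] <- coded[, f]
    out[[paste0(factors$symbol[f], "_actual")]] <- actual[, f]
  }
  attr(out, "factors") <- factors
  class(out) <- c("bbd_design", class(out))
  out
}

#' @export
print.bbd_design <- function(x, ...) {
  f <- attr(x, "factors")
  cat(sprintf("Box-Behnken design: %d runs, %d factors (%s)\n",
              nrow(x), nrow(f), paste(f$symbol, collapse = ", ")))
  NextMethod()
}

design_factors <- function(design) {
  f <- attr(design, "factors")
  if (is.null(f)) {
    rlang::abort("design carries no factor table; build it with generate_bbd()",
                 class = "protodoe_factor_error")
  }
  f
}

design_coded_matrix <- function(design) {
  f <- design_factors(design)
  as.matrix(design[paste0(f$symbol, "_coded")])
}

design_actual_matrix <- function(design) {
  f <- design_factors(design)
  as.matrix(design[paste0(f$symbol, "_actual")])
}

as_settings_matrix <- function(settings, k) {
  if (is.data.frame(settings)) settings <- as.matrix(settings)
  if (is.null(dim(settings))) {
    if (length(settings) != k) {
      rlang::abort(sprintf("expected %d factor settings, got %d", k, length(settings)),
                   class = "protodoe_dimension_error")
    }
    settings <- matrix(settings, nrow = 1)
  }
  if (ncol(settings) != k) {
    rlang::abort(sprintf("expected %d columns of factor settings, got %d", k, ncol(settings)),
                 class = "protodoe_dimension_error")
  }
  storage.mode(settings) <- "double"
  settings
}

#' Convert coded factor levels to actual units
#'
#' Standard design-of-experiments coding: actual = midpoint + coded *
#' half-range, applied componentwise.
#'
#' @param coded Numeric vector (one setting) or matrix / data frame (one
#'   setting per row) of coded levels.
#' @param factors Factor tibble.
#' @return Matrix of actual-unit settings (single vectors are returned as a
#'   named numeric vector).
#' @export
#' @examples
#' coded_to_actual(c(-1, -1, 0), protoplast_factors())
coded_to_actual <- function(coded, factors) {
  check_factors(factors)
  vec_in <- is.null(dim(coded)) && !is.data.frame(coded)
  x <- as_settings_matrix(coded, nrow(factors))
  mid <- (factors$high + factors$low) / 2
  half <- (factors$high - factors$low) / 2
  out <- sweep(sweep(x, 2, half, `*`), 2, mid, `+`)
  colnames(out) <- factors$symbol
  if (vec_in) out[1, ] else out
}

#' Convert actual-unit settings to coded levels
#'
#' Exact inverse of [coded_to_actual()]. Settings outside a factor's
#' `[low, high]` range raise a range error naming the factor.
#'
#' @inheritParams coded_to_actual
#' @param actual Numeric vector or matrix of actual-unit settings.
#' @return Coded levels, same shape convention as [coded_to_actual()].
#' @export
#' @examples
#' actual_to_coded(c(3, 1, 0.6), protoplast_factors())
actual_to_coded <- function(actual, factors) {
  check_factors(factors)
  vec_in <- is.null(dim(actual)) && !is.data.frame(actual)
  x <- as_settings_matrix(actual, nrow(factors))
  tol <- 1e-9
  for (f in seq_len(nrow(factors))) {
    bad <- x[, f] < factors$low[f] - tol | x[, f] > factors$high[f] + tol
    if (any(bad)) {
      rlang::abort(sprintf("factor %s: value %.4g outside [%g, %g]",
                           factors$symbol[f], x[which(bad)[1], f],
                           factors$low[f], factors$high[f]),
                   class = "protodoe_range_error")
    }
  }
  mid <- (factors$high + factors$low) / 2
  half <- (factors$high - factors$low) / 2
  out <- sweep(sweep(x, 2, mid, `-`), 2, half, `/`)
  colnames(out) <- factors$symbol
  if (vec_in) out[1, ] else out
}

# md5 of the packaged study file, pinned so silent corruption is caught
.table1_md5 <- "a64bf43be9657d45744909186303f316"

#' Load the packaged protoplast Box-Behnken study
#'
#' The 17-run, three-factor study of *Salsola laricifolia* protoplast
#' preparation: cellulase R-10 (%), macerozyme R-10 (%) and mannitol (mol/L)
#' against protoplast yield (1e6 per 100 mg leaf tissue), viability (%, Evans
#' blue exclusion) and the derived number of viable cells
#' (yield x viability / 100). Runs 1-12 are the edge midpoints in block
#' order, runs 13-17 the five center replicates.
#'
#' @return A list with elements `design` (a `bbd_design` tibble, see
#'   [generate_bbd()]) and `response` (tibble with `run_id`, `yield`,
#'   `viability`, `viable_cells`).
#' @export
#' @examples
#' study <- load_protoplast_study()
#' study$response
load_protoplast_study <- function() {
  path <- system.file("extdata", "salsola_protoplast_bbd.csv", package = "protodoe")
  if (!nzchar(path)) {
    rlang::abort("packaged study file not found", class = "protodoe_fixture_error")
  }
  if (unname(tools::md5sum(path)) != .table1_md5) {
    rlang::abort("packaged study file failed its checksum; reinstall the package",
                 class = "protodoe_fixture_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  factors <- protoplast_factors()
  design <- tibble::as_tibble(raw[c("run_id",
                                    paste0(factors$symbol, "_coded"),
                                    paste0(factors$symbol, "_actual"))])
  attr(design, "factors") <- factors
  class(design) <- c("bbd_design", class(design))
  response <- tibble::as_tibble(raw[c("run_id", "yield", "viability", "viable_cells")])
  list(design = design, response = response)
}
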