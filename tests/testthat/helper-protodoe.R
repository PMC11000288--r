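# shared fixtures: the packaged study and small random-surface builders

study <- load_protoplast_study()
paper_factors <- protoplast_factors()

actual_inputs <- function(design = study$design) {
  f <- attr(design, "factors")
  as.matrix(design[paste0(f$symbol, "_actual")])
}

# full second-order model matrix, independent of the package internals
oracle_model_matrix <- function(X) {
  k <- ncol(X)
  pairs <- combn(k, 2)
  inter <- sapply(seq_len(ncol(pairs)), function(p) X[, pairs[1, p]] * X[, pairs[2, p]])
  cbind(1, X, inter, X^2)
}

random_quadratic <- function(factors = paper_factors, seed = 1, space = "actual") {
  k <- nrow(factors)
  co <- withr::with_seed(seed, rnorm(1 + 2 * k + choose(k, 2)))
  quadratic_model(co, factors, unit_space = space)
}
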