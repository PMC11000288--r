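#' Deterministic train/validation/test split
#'
#' Sizes are `floor(n * fraction)` with the remainder assigned to training
#' first, then validation, then test; the permutation is reproducible from
#' the seed.
#'
#' @param n Number of samples (>= 3 when all three fractions are positive).
#' @param fractions Length-3 nonnegative vector `(train, validation, test)`
#'   summing to 1.
#' @param seed Integer seed controlling the permutation.
#' @return List of integer index vectors `train`, `validation`, `test`
#'   (disjoint, union = `1:n`).
#' @export
#' @examples
#' split_data(17, c(0.70, 0.15, 0.15), seed = 1)
split_data <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 0) {
  if (length(fractions) != 3 || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    rlang::abort("`fractions` must be 3 nonnegative values summing to 1",
                 class = "protodoe_split_error")
  }
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  for (i in seq_len(rem)) {
    slot <- ((i - 1) %% 3) + 1  # train first, then validation, then test
    sizes[slot] <- sizes[slot] + 1
  }
  if (sizes[1] == 0) {
    rlang::abort("training set would be empty", class = "protodoe_split_error")
  }
  perm <- withr::with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(sizes[1])]),
       validation = sort(perm[sizes[1] + seq_len(sizes[2])]),
       test = sort(perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

# --- weight vector <-> (W1, b1, W2, b2) ------------------------------------

unpack_weights <- function(w, n_hidden, n_in) {
  i <- 0
  W1 <- matrix(w[i + seq_len(n_hidden * n_in)], nrow = n_hidden); i <- i + n_hidden * n_in
  b1 <- w[i + seq_len(n_hidden)]; i <- i + n_hidden
  W2 <- w[i + seq_len(n_hidden)]; i <- i + n_hidden
  b2 <- w[i + 1]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

net_forward <- function(w, X, n_hidden) {
  p <- unpack_weights(w, n_hidden, ncol(X))
  H <- tanh(sweep(X %*% t(p$W1), 2, p$b1, `+`))
  list(yhat = as.numeric(H %*% p$W2 + p$b2), H = H, p = p)
}

# Jacobian of the network output wrt the packed weights, one row per sample
net_jacobian <- function(w, X, n_hidden) {
  fw <- net_forward(w, X, n_hidden)
  n <- nrow(X); n_in <- ncol(X)
  dH <- 1 - fw$H^2                                   # n x H
  back <- sweep(dH, 2, fw$p$W2, `*`)                 # n x H: dy/dz_j
  JW1 <- matrix(0, n, n_hidden * n_in)
  # packing order of W1 is column-major: (j, i) -> (i-1)*n_hidden + j
  for (i in seq_len(n_in)) {
    JW1[, (i - 1) * n_hidden + seq_len(n_hidden)] <- back * X[, i]
  }
  cbind(JW1, back, fw$H, 1)
}

minmax_scaling <- function(x) {
  lo <- apply(as.matrix(x), 2, min)
  hi <- apply(as.matrix(x), 2, max)
  half <- (hi - lo) / 2
  half[half == 0] <- 1  # constant column maps to 0
  list(center = (hi + lo) / 2, half = half)
}

apply_scaling <- function(x, sc) sweep(sweep(as.matrix(x), 2, sc$center, `-`), 2, sc$half, `/`)
undo_scaling <- function(x, sc) sweep(sweep(as.matrix(x), 2, sc$half, `*`), 2, sc$center, `+`)

mse_of <- function(w, X, t, n_hidden) {
  if (length(t) == 0) return(NA_real_)
  mean((t - net_forward(w, X, n_hidden)$yhat)^2)
}

# one Levenberg-Marquardt outer step; returns updated weights/damping
lm_step <- function(w, X, t, n_hidden, mu, mu_max = 1e10) {
  e <- t - net_forward(w, X, n_hidden)$yhat
  sse <- sum(e^2)
  J <- net_jacobian(w, X, n_hidden)
  g <- crossprod(J, e)
  if (max(abs(g)) < 1e-7) {
    return(list(w = w, mu = mu, sse = sse, converged = "gradient", grad = g))
  }
  JtJ <- crossprod(J)
  repeat {
    delta <- tryCatch(solve(JtJ + mu * diag(ncol(J)), g), error = function(e) NULL)
    if (!is.null(delta)) {
      w_new <- w + as.numeric(delta)
      e_new <- t - net_forward(w_new, X, n_hidden)$yhat
      if (is.finite(sum(e_new^2)) && sum(e_new^2) < sse) {
        return(list(w = w_new, mu = max(mu / 10, 1e-12), sse = sum(e_new^2),
                    converged = NULL, grad = g))
      }
    }
    mu <- mu * 10
    if (mu > mu_max) {
      return(list(w = w, mu = mu, sse = sse, converged = "max_damping", grad = g))
    }
  }
}

# Moller's scaled conjugate gradient, persistent state across epochs
scg_init <- function(w, X, t, n_hidden) {
  g <- scg_grad(w, X, t, n_hidden)
  list(w = w, r = -g, p = -g, lambda = 5e-7, lambda_bar = 0, success = TRUE,
       sigma0 = 5e-5, E = scg_error(w, X, t, n_hidden), k = 1)
}

scg_error <- function(w, X, t, n_hidden) 0.5 * sum((t - net_forward(w, X, n_hidden)$yhat)^2)

scg_grad <- function(w, X, t, n_hidden) {
  e <- t - net_forward(w, X, n_hidden)$yhat
  J <- net_jacobian(w, X, n_hidden)
  as.numeric(-crossprod(J, e))
}

scg_step <- function(st, X, t, n_hidden) {
  N <- length(st$w)
  p <- st$p; r <- st$r
  p2 <- sum(p^2)
  if (sqrt(p2) < 1e-12) return(c(st, list(converged = "gradient")))
  if (st$success) {
    sigma <- st$sigma0 / sqrt(p2)
    g1 <- scg_grad(st$w + sigma * p, X, t, n_hidden)
    g0 <- -r
    st$s <- (g1 - g0) / sigma
    st$delta <- sum(p * st$s)
  }
  delta <- st$delta + (st$lambda - st$lambda_bar) * p2
  if (delta <= 0) {                       # make the Hessian proxy positive definite
    st$lambda_bar <- 2 * (st$lambda - delta / p2)
    delta <- -delta + st$lambda * p2
    st$lambda <- st$lambda_bar
  }
  mu <- sum(p * r)
  alpha <- mu / delta
  w_new <- st$w + alpha * p
  E_new <- scg_error(w_new, X, t, n_hidden)
  Delta <- 2 * delta * (st$E - E_new) / mu^2
  if (is.finite(Delta) && Delta >= 0) {   # successful reduction
    r_new <- -scg_grad(w_new, X, t, n_hidden)
    st$lambda_bar <- 0
    st$success <- TRUE
    if (st$k %% N == 0) {
      st$p <- r_new                       # restart along steepest descent
    } else {
      beta <- (sum(r_new^2) - sum(r_new * r)) / mu
      st$p <- r_new + beta * p
    }
    st$w <- w_new; st$r <- r_new; st$E <- E_new
    if (Delta >= 0.75) st$lambda <- st$lambda / 4
  } else {
    st$lambda_bar <- st$lambda
    st$success <- FALSE
  }
  if (!is.finite(Delta) || Delta < 0.25) st$lambda <- st$lambda + delta * (1 - max(Delta, 0)) / p2
  if (!is.finite(st$lambda)) st$lambda <- 1e10
  st$k <- st$k + 1
  if (max(abs(st$r)) < 1e-7) st$converged <- "gradient" else st$converged <- NULL
  st
}

#' Train a single-hidden-layer back-propagation network
#'
#' Fits a 3-H-1 feed-forward regressor (tanh hidden layer, linear output)
#' with min-max scaling of inputs and target to `[-1, 1]`. Training
#' minimizes squared error on the training split only, by Levenberg-Marquardt
#' (damped Gauss-Newton on the full Jacobian) or Moller's scaled conjugate
#' gradient. Early stopping monitors the validation split: the returned
#' weights are those of the epoch with minimum validation MSE, and training
#' stops after `patience` consecutive epochs without improvement, at
#' `max_epochs`, or when the gradient norm falls below 1e-7. With
#' `restarts > 1` the restart with the lowest best validation MSE wins.
#'
#' @param inputs Numeric matrix (or data frame), one row per sample.
#' @param targets Numeric response vector.
#' @param n_hidden Hidden-layer width (study values: 18 for yield, 17 for
#'   viability, 14 for viable cells).
#' @param algorithm `"lm"` (Levenberg-Marquardt) or `"scg"` (scaled
#'   conjugate gradient).
#' @param split Train/validation/test fractions, see [split_data()].
#' @param max_epochs,patience Stopping controls.
#' @param seed Integer seed controlling the split and weight initialization
#'   (uniform in `[-0.5, 0.5]`).
#' @param restarts Number of random restarts (same split, fresh weights).
#' @return A `bpnn_fit`: list with `net` (scalings and weights), `history`
#'   (per-epoch train/validation/test MSE in scaled units), `best_epoch`,
#'   `stop_reason`, `split` and `config`.
#' @export
#' @examples
#' x <- matrix(runif(30), ncol = 3)
#' fit <- train_bpnn(x, x[, 1] * 2, n_hidden = 2, max_epochs = 50, seed = 1)
#' predict(fit, x)
train_bpnn <- function(inputs, targets, n_hidden = 18,
                       algorithm = c("lm", "scg"),
                       split = c(0.70, 0.15, 0.15),
                       max_epochs = 1000, patience = 6,
                       seed = 0, restarts = 1) {
  algorithm <- match.arg(algorithm)
  X_raw <- as.matrix(inputs)
  storage.mode(X_raw) <- "double"
  t_raw <- as.numeric(targets)
  n <- nrow(X_raw)
  if (n <= 3) rlang::abort("need more than 3 samples", class = "protodoe_train_error")
  if (!all(is.finite(t_raw)) || !all(is.finite(X_raw))) {
    rlang::abort("inputs and targets must be finite", class = "protodoe_train_error")
  }
  if (n_hidden < 1) rlang::abort("`n_hidden` must be >= 1", class = "protodoe_train_error")

  in_sc <- minmax_scaling(X_raw)
  out_sc <- minmax_scaling(matrix(t_raw, ncol = 1))
  X <- apply_scaling(X_raw, in_sc)
  tt <- as.numeric(apply_scaling(matrix(t_raw, ncol = 1), out_sc))

  idx <- split_data(n, split, seed)
  Xtr <- X[idx$train, , drop = FALSE]; ttr <- tt[idx$train]
  Xva <- X[idx$validation, , drop = FALSE]; tva <- tt[idx$validation]
  Xte <- X[idx$test, , drop = FALSE]; tte <- tt[idx$test]
  has_val <- length(tva) > 0
  npar <- n_hidden * ncol(X) + n_hidden + n_hidden + 1

  run_once <- function(init_seed) {
    w <- withr::with_seed(init_seed, stats::runif(npar, -0.5, 0.5))
    sel_mse <- function(w) if (has_val) mse_of(w, Xva, tva, n_hidden) else mse_of(w, Xtr, ttr, n_hidden)
    hist <- list(tibble::tibble(epoch = 0L,
                                train_mse = mse_of(w, Xtr, ttr, n_hidden),
                                val_mse = mse_of(w, Xva, tva, n_hidden),
                                test_mse = mse_of(w, Xte, tte, n_hidden)))
    best <- list(w = w, sel = sel_mse(w), epoch = 0L)
    fails <- 0L
    stop_reason <- "max_epochs"
    mu <- 1e-3
    scg_state <- if (algorithm == "scg") scg_init(w, Xtr, ttr, n_hidden) else NULL
    for (epoch in seq_len(max_epochs)) {
      if (algorithm == "lm") {
        st <- lm_step(w, Xtr, ttr, n_hidden, mu)
        w <- st$w; mu <- st$mu
        conv <- st$converged
      } else {
        scg_state <- scg_step(scg_state, Xtr, ttr, n_hidden)
        w <- scg_state$w
        conv <- scg_state$converged
      }
      row <- tibble::tibble(epoch = epoch,
                            train_mse = mse_of(w, Xtr, ttr, n_hidden),
                            val_mse = mse_of(w, Xva, tva, n_hidden),
                            test_mse = mse_of(w, Xte, tte, n_hidden))
      if (!is.finite(row$train_mse)) {
        rlang::abort(sprintf("training diverged at epoch %d", epoch),
                     class = "protodoe_training_diverged")
      }
      hist[[length(hist) + 1]] <- row
      sel <- sel_mse(w)
      if (sel < best$sel) {
        best <- list(w = w, sel = sel, epoch = epoch)
        fails <- 0L
      } else {
        fails <- fails + 1L
      }
      if (!is.null(conv)) { stop_reason <- conv; break }
      if (has_val && fails >= patience) { stop_reason <- "patience"; break }
    }
    list(history = dplyr::bind_rows(hist), best = best, stop_reason = stop_reason)
  }

  runs <- lapply(seq_len(restarts), function(r) run_once(seed + (r - 1) * 7919))
  sel <- which.min(vapply(runs, function(r) r$best$sel, 1))
  chosen <- runs[[sel]]
  pars <- unpack_weights(chosen$best$w, n_hidden, ncol(X))
  net <- structure(list(input_scaling = in_sc, output_scaling = out_sc,
                        W1 = pars$W1, b1 = pars$b1, W2 = pars$W2, b2 = pars$b2,
                        n_hidden = n_hidden, weights = chosen$best$w),
                   class = "bpnn")
  structure(list(net = net, history = chosen$history,
                 best_epoch = chosen$best$epoch,
                 stop_reason = chosen$stop_reason,
                 split = idx, restart = sel,
                 config = list(n_hidden = n_hidden, algorithm = algorithm,
                               split = split, max_epochs = max_epochs,
                               patience = patience, seed = seed,
                               restarts = restarts)),
            class = "bpnn_fit")
}

#' Feed-forward prediction from a trained network
#'
#' @param net A `bpnn` (or `bpnn_fit`) object.
#' @param inputs Matrix/data frame of samples (3 columns) or a single
#'   setting vector.
#' @return Numeric predictions in original response units.
#' @export
predict_net <- function(net, inputs) {
  if (inherits(net, "bpnn_fit")) net <- net$net
  X <- as_settings_matrix(inputs, ncol(net$W1))
  Xs <- apply_scaling(X, net$input_scaling)
  ys <- net_forward(net$weights, Xs, net$n_hidden)$yhat
  as.numeric(undo_scaling(matrix(ys, ncol = 1), net$output_scaling))
}

#' @export
predict.bpnn <- function(object, newdata, ...) predict_net(object, newdata)

#' @export
predict.bpnn_fit <- function(object, newdata, ...) predict_net(object$net, newdata)

#' @export
print.bpnn_fit <- function(x, ...) {
  cat(sprintf("3-%d-1 back-propagation network (%s), stopped by %s at best epoch %d\n",
              x$config$n_hidden, toupper(x$config$algorithm),
              x$stop_reason, x$best_epoch))
  invisible(x)
}

#' @method autoplot bpnn_fit
#' @export
autoplot.bpnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "set", values_to = "mse")
  long <- long[is.finite(long$mse), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "MSE (scaled units)", colour = NULL) +
    ggplot2::theme_minimal()
}
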