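# Conditional log-likelihood in difference form, its gradient, and the
# diagonal IRLS weights / working response, for general 1:M strata.
#
# With x_in = u_case - u_control_i and d_n = 1 + sum_l exp(-x_ln beta), the
# negative conditional log-likelihood is sum_n log d_n. The per-row
# quantities used throughout are
#   r_in = exp(-x_in beta) / d_n          (so gradient = -X^t r)
#   W_in = exp(-x_in beta) / d_n^2        (diagonal IRLS weight)
#   z_in = x_in beta + d_n                (working response)
# which satisfy -X^t W (z - X beta) = gradient identically.

# Shared per-evaluation quantities, overflow-safe. s = -X beta per row;
# log_d per stratum computed as log1p(sum exp s), with the per-stratum max
# exponent factored out once any s exceeds 30.
cl_parts <- function(x, beta) {
  if (any(!is.finite(beta))) abort("`beta` must be finite.")
  eta <- as.numeric(x$X %*% beta)
  s <- -eta
  g <- x$row_stratum
  if (max(s) <= 30) {
    es <- exp(s)
    sum_es <- as.numeric(rowsum(es, g))
    log_d <- log1p(sum_es)
    r <- es / (1 + sum_es)[g]
  } else {
    m <- vapply(split.default(s, g), max, numeric(1))
    m <- pmax(m, 0)  # keep the implicit exp(0) term of the case in range
    es <- exp(s - m[g])
    sum_es <- as.numeric(rowsum(es, g))
    log_d <- m + log(exp(-m) + sum_es)
    r <- es / (exp(-m) + sum_es)[g]
  }
  list(eta = eta, s = s, log_d = log_d, r = r)
}

#' Negative conditional log-likelihood in difference form
#'
#' Computes sum over strata of log(1 + sum_l exp(-x_l beta)), the negative
#' conditional log-likelihood of the stratified logistic model evaluated on
#' the within-stratum differences. Evaluation is overflow-safe (the largest
#' per-stratum exponent is factored out when needed), so the value is finite
#' for every finite `beta`.
#'
#' @param x A [difference_matrix()].
#' @param beta Coefficient vector, length `ncol(x$X)` (log odds ratios).
#' @return A scalar. At `beta = 0` it equals `sum(log(M_n + 1))`.
#' @export
cl_neg_loglik <- function(x, beta) {
  sum(cl_parts(x, beta)$log_d)
}

#' Gradient of the negative conditional log-likelihood
#'
#' Returns `-X^t r` with `r_in = exp(-x_in beta) / d_n` and
#' `d_n = 1 + sum_l exp(-x_ln beta)`.
#'
#' @inheritParams cl_neg_loglik
#' @return Numeric vector of length p, named by covariate.
#' @export
cl_gradient <- function(x, beta) {
  p <- cl_parts(x, beta)
  setNames(-as.numeric(crossprod(x$X, p$r)), x$variable_names)
}

#' IRLS weights and working response
#'
#' Diagonal weights `W_in = exp(-x_in beta) / d_n^2` and working response
#' `z_in = x_in beta + d_n` of the quadratic approximation to the conditional
#' log-likelihood. The identity `-X^t W (z - X beta) = ` [cl_gradient()] holds
#' exactly (up to the clamps below).
#'
#' Weights that underflow below `weight_floor` are clamped to the floor and
#' counted in `n_clamped`; `d_n` is capped at `exp(700)` so `z` stays finite
#' near separation.
#'
#' @inheritParams cl_neg_loglik
#' @param weight_floor Lower clamp for the weights (default 1e-10).
#' @return List with `w` and `z` (length = number of difference rows), `r`,
#'   `eta = X beta`, `log_d` (per stratum) and `n_clamped`.
#' @export
cl_weights <- function(x, beta, weight_floor = 1e-10) {
  p <- cl_parts(x, beta)
  g <- x$row_stratum
  log_w <- p$s - 2 * p$log_d[g]
  w <- exp(log_w)
  n_clamped <- sum(w < weight_floor) + sum(p$log_d > 700)
  w <- pmax(w, weight_floor)
  d <- exp(pmin(p$log_d, 700))
  z <- p$eta + d[g]
  list(w = w, z = z, r = p$r, eta = p$eta, log_d = p$log_d,
       n_clamped = n_clamped)
}

#' L1-penalized objective
#'
#' `cl_neg_loglik(x, beta) + lambda * sum(|beta_j|)` over penalized
#' coefficients only (forced covariates contribute no penalty).
#'
#' @inheritParams cl_neg_loglik
#' @param lambda Penalty level, >= 0.
#' @param penalty_mask Binary vector (1 = penalized); defaults to the mask
#'   stored in `x`.
#' @return A scalar.
#' @export
cl_objective <- function(x, beta, lambda, penalty_mask = x$penalty_mask) {
  if (!is.finite(lambda) || lambda < 0) abort("`lambda` must be >= 0.")
  cl_neg_loglik(x, beta) + lambda * sum(abs(beta[penalty_mask == 1L]))
}
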