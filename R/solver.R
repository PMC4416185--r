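# Fit at a fixed lambda: outer IRLS loop with Armijo backtracking, inner
# penalized weighted least squares solved by cyclic coordinate descent on the
# p x p Gram system. The inner solver sees only A = X^t W X and b = X^t W z,
# never X itself, so solver memory is O(p^2) whatever the number of subjects.

#' Solver control parameters
#'
#' @param tau Outer relative-objective convergence tolerance:
#'   stop when |f(k+1) - f(k)| / |f(k+1)| <= tau.
#' @param alpha1 Armijo slope fraction, in \[0, 0.5\].
#' @param alpha2 Backtracking shrink factor, in (0, 1).
#' @param max_outer Cap on outer IRLS iterations.
#' @param kkt_tol Subgradient (KKT) residual required, together with the
#'   `tau` criterion, before a fit is declared converged. For 1:1 strata the
#'   diagonal weights are the exact Hessian and the `tau` stop alone already
#'   lands on the optimum, but for M > 1 they understate the curvature and
#'   the objective can flatten out an order of magnitude before the
#'   subgradient conditions hold; the KKT check closes that gap.
#' @param inner_tol Inner convergence tolerance: maximum absolute coordinate
#'   change per cyclic sweep.
#' @param max_inner_sweeps Cap on cyclic sweeps; default `10 * p + 100`.
#' @param weight_floor Lower clamp on IRLS weights.
#' @param t_min Smallest admissible backtracking step before the line search
#'   declares a stall.
#' @param verbose Log one line per outer iteration.
#' @return A list of class `solver_control`.
#' @export
solver_control <- function(tau = 1e-8, alpha1 = 0.01, alpha2 = 0.5,
                           max_outer = 100L, kkt_tol = 1e-4,
                           inner_tol = 1e-9, max_inner_sweeps = NULL,
                           weight_floor = 1e-10, t_min = 1e-12,
                           verbose = FALSE) {
  stopifnot(tau > 0, alpha1 >= 0, alpha1 <= 0.5, alpha2 > 0, alpha2 < 1,
            max_outer >= 1, kkt_tol > 0, inner_tol > 0, weight_floor > 0,
            t_min > 0)
  structure(list(tau = tau, alpha1 = alpha1, alpha2 = alpha2,
                 max_outer = as.integer(max_outer), kkt_tol = kkt_tol,
                 inner_tol = inner_tol,
                 max_inner_sweeps = max_inner_sweeps,
                 weight_floor = weight_floor, t_min = t_min,
                 verbose = isTRUE(verbose)),
            class = "solver_control")
}

#' Soft-thresholding operator
#'
#' `sign(v) * max(|v| - threshold, 0)`, the scalar kernel of the Lasso
#' coordinate update. Vectorized in `v`.
#'
#' @param v Numeric.
#' @param threshold Nonnegative threshold(s).
#' @return Numeric of the same length as `v`.
#' @export
soft_threshold <- function(v, threshold) {
  if (any(threshold < 0)) abort("`threshold` must be >= 0.")
  sign(v) * pmax(abs(v) - threshold, 0)
}

#' Cyclic coordinate descent for a penalized weighted least squares problem
#'
#' Minimizes `||W^(1/2) (z - X gamma)||^2 + sum_j penalty_j |gamma_j|` given
#' only the Gram quantities `A = X^t W X` (p x p) and `b = X^t W z` (length
#' p); `X`, `W`, `z` are never read, which is what lets the fit scale with p
#' rather than the number of subjects. Coordinates are swept in fixed column
#' order; each update is `gamma_j <- S(b_j - sum_{k != j} A_jk gamma_k,
#' penalty_j) / A_jj` with `S` the soft threshold.
#'
#' A coordinate with `A_jj = 0` is frozen at zero when penalized and is an
#' error when unpenalized (a collinear forced covariate has no unique
#' solution).
#'
#' @param A Symmetric positive semidefinite p x p matrix.
#' @param b Numeric vector, length p.
#' @param penalty Per-coordinate penalties >= 0 (0 for forced covariates; a
#'   scalar is recycled).
#' @param beta_init Starting point (default zeros).
#' @param inner_tol Stop when the largest absolute coordinate change in a
#'   sweep is below this.
#' @param max_sweeps Sweep cap; default `10 * p + 100`.
#' @return The solution vector, with attribute `"sweeps"`.
#' @export
weighted_lasso_cd <- function(A, b, penalty, beta_init = NULL,
                              inner_tol = 1e-9, max_sweeps = NULL) {
  A <- as.matrix(A)
  p <- length(b)
  stopifnot(nrow(A) == p, ncol(A) == p)
  penalty <- rep_len(penalty, p)
  if (any(penalty < 0)) abort("`penalty` must be >= 0.")
  max_sweeps <- max_sweeps %||% (10L * p + 100L)
  gamma <- beta_init %||% numeric(p)
  stopifnot(length(gamma) == p)

  diagA <- diag(A)
  dead <- diagA <= 0
  if (any(dead & penalty == 0)) {
    abort("Zero curvature on an unpenalized coordinate (collinear forced covariate).")
  }
  gamma[dead] <- 0
  active <- which(!dead)

  q <- as.numeric(A %*% gamma)  # running A gamma
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    max_change <- 0
    for (j in active) {
      cj <- b[j] - q[j] + diagA[j] * gamma[j]
      new <- soft_threshold(cj, penalty[j]) / diagA[j]
      dj <- new - gamma[j]
      if (dj != 0) {
        q <- q + A[, j] * dj
        gamma[j] <- new
        max_change <- max(max_change, abs(dj))
      }
    }
    if (max_change <= inner_tol || sweeps >= max_sweeps) break
  }
  attr(gamma, "sweeps") <- sweeps
  gamma
}

#' Backtracking (Armijo) line search on the penalized objective
#'
#' Starting at `t = 1`, shrinks `t <- alpha2 * t` until
#' `f(beta + t * delta) <= f(beta) + alpha1 * t * D`, where `f` is the
#' penalized objective and `D` is the descent measure of the composite
#' (proximal-Newton) step, `D = g(beta)^t delta + lambda * (||beta +
#' delta||_1 - ||beta||_1)` over penalized coordinates, with `g` the gradient
#' of the unpenalized negative log-likelihood. Using the composite `D` rather
#' than the bare `g^t delta` matters: near the optimum the penalty's
#' directional derivative nearly cancels `g^t delta`, and a slope test on the
#' bare gradient rejects every step, stalling the outer loop short of the
#' subgradient optimum.
#'
#' @param x A [difference_matrix()].
#' @param beta Current point.
#' @param delta Search direction (inner solution minus `beta`); must be
#'   nonzero.
#' @param lambda Penalty level.
#' @param penalty_mask Binary mask, 1 = penalized.
#' @param alpha1,alpha2,t_min See [solver_control()].
#' @return List with `t`, the trial point `beta_new`, its objective `f_new`,
#'   and `stalled` (TRUE when `t` underflowed `t_min` without satisfying the
#'   criterion; the current iterate is returned unchanged).
#' @export
line_search <- function(x, beta, delta, lambda,
                        penalty_mask = x$penalty_mask,
                        alpha1 = 0.01, alpha2 = 0.5, t_min = 1e-12) {
  if (all(delta == 0)) abort("`delta` must be nonzero.")
  f0 <- cl_objective(x, beta, lambda, penalty_mask)
  pen <- penalty_mask == 1L
  slope <- sum(cl_gradient(x, beta) * delta) +
    lambda * (sum(abs((beta + delta)[pen])) - sum(abs(beta[pen])))
  t <- 1
  repeat {
    trial <- beta + t * delta
    f_trial <- cl_objective(x, trial, lambda, penalty_mask)
    if (f_trial <= f0 + alpha1 * t * slope) {
      return(list(t = t, beta_new = trial, f_new = f_trial, stalled = FALSE))
    }
    t <- alpha2 * t
    if (t < t_min) {
      return(list(t = 0, beta_new = beta, f_new = f0, stalled = TRUE))
    }
  }
}

#' Subgradient optimality residual
#'
#' Maximal violation of the Karush-Kuhn-Tucker conditions of the penalized
#' objective at `beta`: with `g` the gradient of the negative log-likelihood,
#' the residual is the maximum over coordinates of `|g_j|` (unpenalized),
#' `|g_j + lambda * sign(beta_j)|` (penalized, nonzero), and
#' `max(|g_j| - lambda, 0)` (penalized, zero). Zero iff `beta` is optimal.
#'
#' @inheritParams line_search
#' @return Nonnegative scalar.
#' @export
kkt_residual <- function(x, beta, lambda, penalty_mask = x$penalty_mask) {
  g <- as.numeric(cl_gradient(x, beta))
  pen <- penalty_mask == 1L
  res <- numeric(length(g))
  res[!pen] <- abs(g[!pen])
  nz <- pen & beta != 0
  res[nz] <- abs(g[nz] + lambda * sign(beta[nz]))
  z0 <- pen & beta == 0
  res[z0] <- pmax(abs(g[z0]) - lambda, 0)
  max(res)
}

# Form the Gram system A = X^t W X, b = X^t W z for the current weights.
# b is accumulated as X^t (w * eta + r), algebraically identical to X^t W z
# (w * d = r) but immune to overflow of d near separation. A is dense p x p;
# for sparse X the products stay sparse until the final p x p result.
gram_system <- function(x, wz) {
  X <- x$X
  if (inherits(X, "sparseMatrix")) {
    A <- as.matrix(Matrix::crossprod(X, Matrix::Diagonal(x = wz$w) %*% X))
    b <- as.numeric(Matrix::crossprod(X, wz$w * wz$eta + wz$r))
  } else {
    A <- crossprod(X, X * wz$w)
    b <- as.numeric(crossprod(X, wz$w * wz$eta + wz$r))
  }
  list(A = A, b = b)
}

#' Fit the L1-penalized conditional logistic model at one penalty level
#'
#' Outer IRLS loop: at the current `beta`, compute the diagonal weights and
#' working response, solve the penalized weighted least squares problem by
#' cyclic coordinate descent on the Gram system, take an Armijo backtracking
#' step along the resulting direction, and stop when the relative change of
#' the penalized objective falls below `control$tau`. Forced covariates carry
#' a zero per-coordinate penalty.
#'
#' @param x A [difference_matrix()] (or anything [matched_data()] accepts,
#'   coerced on the fly).
#' @param lambda Penalty level, >= 0.
#' @param beta_init Starting coefficients (default zeros; the path fitter
#'   passes warm starts).
#' @param control A [solver_control()].
#' @return An object of class `clogit_lasso_fit`: coefficients, `lambda`,
#'   penalized `objective`, `neg_log_likelihood`, `n_outer`, `converged`,
#'   `kkt_residual`, `n_nonzero` (nonzero penalized coefficients), and
#'   `n_weight_clamped`.
#'
#' @examples
#' d <- simulate_matched(n_strata = 100, n_controls = 1,
#'                       beta = c(1, 0, 0), prevalence = 0.3, seed = 3)
#' dm <- difference_matrix(matched_data(d))
#' fit <- clogit_lasso_fit(dm, lambda = 0.1 * lambda_max(dm))
#' tidy(fit)
#' @export
clogit_lasso_fit <- function(x, lambda, beta_init = NULL,
                             control = solver_control()) {
  x <- as_difference_matrix(x)
  if (!is.finite(lambda) || lambda < 0) abort("`lambda` must be >= 0.")
  p <- ncol(x$X)
  beta <- beta_init %||% numeric(p)
  stopifnot(length(beta) == p)
  pen_vec <- lambda * (x$penalty_mask == 1L)

  f_old <- cl_objective(x, beta, lambda)
  if (!is.finite(f_old)) abort("Non-finite objective at the starting point.")
  converged <- FALSE
  n_clamped <- 0L
  k <- 0L
  while (k < control$max_outer) {
    k <- k + 1L
    wz <- cl_weights(x, beta, control$weight_floor)
    n_clamped <- n_clamped + wz$n_clamped
    gr <- gram_system(x, wz)
    gamma <- weighted_lasso_cd(gr$A, gr$b, pen_vec, beta_init = beta,
                               inner_tol = control$inner_tol,
                               max_sweeps = control$max_inner_sweeps)
    delta <- as.numeric(gamma) - beta
    if (max(abs(delta)) == 0) {  # inner optimum is the current point
      converged <- TRUE
      break
    }
    ls <- line_search(x, beta, delta, lambda, x$penalty_mask,
                      alpha1 = control$alpha1, alpha2 = control$alpha2,
                      t_min = control$t_min)
    if (ls$stalled) break
    beta <- ls$beta_new
    f_new <- ls$f_new
    if (!is.finite(f_new)) {
      abort(sprintf("Non-finite objective at outer iteration %d (lambda = %g).",
                    k, lambda))
    }
    if (control$verbose) {
      inform(sprintf("outer %3d  f = %.10g  t = %.3g  sweeps = %d",
                     k, f_new, ls$t, attr(gamma, "sweeps")))
    }
    if (abs(f_new - f_old) / abs(f_new) <= control$tau &&
        kkt_residual(x, beta, lambda, x$penalty_mask) <= control$kkt_tol) {
      converged <- TRUE
      f_old <- f_new
      break
    }
    f_old <- f_new
  }

  nll <- cl_neg_loglik(x, beta)
  structure(
    list(
      beta = setNames(beta, x$variable_names),
      lambda = lambda,
      objective = nll + lambda * sum(abs(beta[x$penalty_mask == 1L])),
      neg_log_likelihood = nll,
      n_outer = k,
      converged = converged,
      kkt_residual = kkt_residual(x, beta, lambda, x$penalty_mask),
      n_nonzero = sum(beta != 0 & x$penalty_mask == 1L),
      n_weight_clamped = n_clamped,
      penalty_mask = x$penalty_mask
    ),
    class = "clogit_lasso_fit"
  )
}

#' @export
print.clogit_lasso_fit <- function(x, ...) {
  cat(sprintf("<clogit_lasso_fit> lambda = %.4g, df = %d, nll = %.4f, %s (%d outer, kkt %.2e)\n",
              x$lambda, x$n_nonzero, x$neg_log_likelihood,
              if (x$converged) "converged" else "NOT converged",
              x$n_outer, x$kkt_residual))
  invisible(x)
}
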