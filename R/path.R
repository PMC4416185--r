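# lambda_max, the lambda grid, and the warm-started path.

#' Smallest penalty that zeroes every penalized coefficient
#'
#' With no forced covariates this is the largest absolute gradient coordinate
#' of the negative conditional log-likelihood at `beta = 0`, i.e.
#' `max_j |sum_n sum_l x_lnj / (M_n + 1)|` over penalized columns: above it
#' the directional derivative of the penalty dominates the likelihood
#' gradient everywhere and 0 is the minimizer.
#'
#' With forced covariates the reference point is the unpenalized-only
#' maximum-conditional-likelihood fit (penalized coefficients clamped at
#' zero), which guarantees the first path point has zero penalized support.
#'
#' @param x A [difference_matrix()].
#' @param control [solver_control()] for the forced-only fit, if needed.
#' @return A positive scalar.
#' @export
lambda_max <- function(x, control = solver_control()) {
  x <- as_difference_matrix(x)
  pen <- x$penalty_mask == 1L
  if (!any(pen)) abort("At least one penalized column is required.")
  col_norm <- if (inherits(x$X, "sparseMatrix")) {
    as.numeric(Matrix::colSums(abs(x$X)))
  } else {
    colSums(abs(x$X))
  }
  if (all(col_norm[pen] == 0)) {
    abort("All penalized columns are identically zero.")
  }
  beta0 <- numeric(ncol(x$X))
  if (any(!pen)) {
    beta0 <- forced_only_fit(x, control)
  }
  g <- cl_gradient(x, beta0)
  max(abs(g[pen]))
}

# Maximum-conditional-likelihood fit with all penalized coefficients clamped
# at zero: fit the forced columns alone at lambda = 0 and embed.
forced_only_fit <- function(x, control = solver_control()) {
  forced <- which(x$penalty_mask == 0L)
  sub <- new_difference_matrix(
    X = x$X[, forced, drop = FALSE],
    row_stratum = x$row_stratum,
    stratum_sizes = x$stratum_sizes,
    penalty_mask = setNames(rep(0L, length(forced)), x$variable_names[forced]),
    variable_names = x$variable_names[forced]
  )
  fit <- clogit_lasso_fit(sub, lambda = 0, control = control)
  beta0 <- numeric(ncol(x$X))
  beta0[forced] <- fit$beta
  beta0
}

#' Build a decreasing lambda grid
#'
#' `n_lambda` values from `lambda_max_value` down to
#' `epsilon * lambda_max_value`, equally spaced on the log (default) or
#' linear scale; endpoints are exact.
#'
#' @param lambda_max_value Largest penalty (see [lambda_max()]).
#' @param epsilon Ratio lambda_min / lambda_max, in (0, 1). Default 0.01.
#' @param n_lambda Number of grid points, >= 2. Default 100.
#' @param scale `"log"` or `"linear"`.
#' @return Strictly decreasing numeric vector of length `n_lambda`.
#' @export
lambda_grid <- function(lambda_max_value, epsilon = 0.01, n_lambda = 100,
                        scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon >= 1) {
    abort("`epsilon` must be in (0, 1).")
  }
  if (n_lambda < 2) abort("`n_lambda` must be >= 2.")
  if (lambda_max_value <= 0) abort("`lambda_max_value` must be > 0.")
  g <- if (scale == "log") {
    exp(seq(log(lambda_max_value), log(epsilon * lambda_max_value),
            length.out = n_lambda))
  } else {
    seq(lambda_max_value, epsilon * lambda_max_value, length.out = n_lambda)
  }
  # exp(log(x)) can land one ulp off; the endpoints are exact by contract
  g[1] <- lambda_max_value
  g[n_lambda] <- epsilon * lambda_max_value
  g
}

#' Fit the Lasso conditional logistic regularization path
#'
#' The front-door fitting function. Takes long-format matched data (or a
#' prepared [matched_data()] / [difference_matrix()]), computes
#' [lambda_max()] and the [lambda_grid()] unless an explicit `lambda` vector
#' is given, and fits the model at each grid point in decreasing order with
#' warm starts: the first fit starts from zero, every later fit from the
#' previous solution.
#'
#' A fit that fails to converge at some lambda (typically near-separation at
#' tiny penalties) is flagged in `converged` and skipped by the model
#' selectors; the path continues.
#'
#' @inheritParams matched_data
#' @param data Long-format data frame, [matched_data()] or
#'   [difference_matrix()].
#' @param lambda Optional explicit penalty vector (sorted decreasing
#'   internally). Default: grid from `epsilon`, `n_lambda`, `scale`.
#' @param epsilon,n_lambda,scale Grid parameters, see [lambda_grid()].
#' @param standardize Standardize penalized columns to unit variance on the
#'   difference scale before fitting, and return coefficients on the original
#'   scale. Default `FALSE` (binary exposures are left on their own scale).
#' @param drop_concordant Drop strata with all-zero difference rows first
#'   (changes likelihood values, never the coefficients). Default `FALSE`.
#' @param sparse Use sparse storage for the difference matrix.
#' @param control A [solver_control()].
#' @return Object of class `clogit_lasso_path`: `lambda`, coefficient matrix
#'   `beta` (n_lambda x p, original scale), `df` (nonzero penalized count),
#'   `neg_log_likelihood`, `converged`, `kkt_residual`, `lambda_max`,
#'   `n_strata`, plus bookkeeping. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#'
#' @examples
#' d <- simulate_matched(n_strata = 200, n_controls = 1,
#'                       beta = c(1, -1, 0, 0), prevalence = 0.3, seed = 4)
#' path <- clogit_lasso(d, n_lambda = 20)
#' glance(path)
#' @export
clogit_lasso <- function(data, stratum = "stratum", case = "case",
                         unpenalized = NULL, lambda = NULL, epsilon = 0.01,
                         n_lambda = 100, scale = c("log", "linear"),
                         standardize = FALSE, drop_concordant = FALSE,
                         sparse = FALSE, control = solver_control()) {
  scale <- match.arg(scale)
  x <- as_difference_matrix(data, stratum = .col_arg(enquo(stratum)),
                            case = .col_arg(enquo(case)),
                            unpenalized = unpenalized, sparse = sparse)
  if (drop_concordant) x <- drop_concordant_strata(x)

  scales <- rep(1, ncol(x$X))
  if (standardize) {
    pen <- x$penalty_mask == 1L
    sds <- if (inherits(x$X, "sparseMatrix")) {
      apply(as.matrix(x$X), 2, sd)
    } else {
      apply(x$X, 2, sd)
    }
    scales[pen & sds > 0] <- sds[pen & sds > 0]
    x$X <- sweep_cols(x$X, scales)
  }

  lmax <- lambda_max(x, control)
  if (is.null(lambda)) {
    lambda <- lambda_grid(lmax, epsilon = epsilon, n_lambda = n_lambda,
                          scale = scale)
  } else {
    lambda <- sort(unique(as.numeric(lambda)), decreasing = TRUE)
  }
  fit_path(x, lambda, control = control, lambda_max_value = lmax,
           scales = scales)
}

sweep_cols <- function(X, scales) {
  if (inherits(X, "sparseMatrix")) {
    X %*% Matrix::Diagonal(x = 1 / scales)
  } else {
    sweep(X, 2, scales, "/")
  }
}

#' Fit a path on a prepared difference matrix over an explicit grid
#'
#' Lower-level engine behind [clogit_lasso()]: fits each lambda in the given
#' decreasing grid with warm starts and records per-lambda diagnostics.
#'
#' @param x A [difference_matrix()].
#' @param lambda Decreasing penalty grid.
#' @param control A [solver_control()].
#' @param lambda_max_value Value reported as the path's lambda_max (computed
#'   if missing).
#' @param scales Per-column divisors applied to `x$X` beforehand;
#'   coefficients are divided by them on output (internal use by
#'   `standardize`).
#' @return A `clogit_lasso_path`, see [clogit_lasso()].
#' @export
fit_path <- function(x, lambda, control = solver_control(),
                     lambda_max_value = NULL, scales = NULL) {
  x <- as_difference_matrix(x)
  if (is.unsorted(rev(lambda), strictly = FALSE)) {
    abort("`lambda` must be decreasing.")
  }
  p <- ncol(x$X)
  T_ <- length(lambda)
  beta <- matrix(NA_real_, T_, p, dimnames = list(NULL, x$variable_names))
  df <- integer(T_)
  nll <- numeric(T_)
  conv <- logical(T_)
  kkt <- numeric(T_)
  n_outer <- integer(T_)
  warm <- numeric(p)
  any_ok <- FALSE
  for (t in seq_len(T_)) {
    fit <- tryCatch(
      clogit_lasso_fit(x, lambda[t], beta_init = warm, control = control),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      conv[t] <- FALSE
      nll[t] <- NA_real_
      kkt[t] <- NA_real_
      next
    }
    beta[t, ] <- fit$beta
    df[t] <- fit$n_nonzero
    nll[t] <- fit$neg_log_likelihood
    conv[t] <- fit$converged
    kkt[t] <- fit$kkt_residual
    n_outer[t] <- fit$n_outer
    if (fit$converged) any_ok <- TRUE
    warm <- unname(fit$beta)
  }
  if (!any_ok) abort("No lambda value converged.")

  scales <- scales %||% rep(1, p)
  beta_orig <- sweep(beta, 2, scales, "/")

  structure(
    list(
      lambda = lambda,
      beta = beta_orig,
      df = df,
      neg_log_likelihood = nll,
      converged = conv,
      kkt_residual = kkt,
      n_outer = n_outer,
      lambda_max = lambda_max_value %||% lambda[1],
      n_strata = x$n_strata,
      stratum_sizes = x$stratum_sizes,
      penalty_mask = x$penalty_mask,
      variable_names = x$variable_names,
      scales = scales
    ),
    class = "clogit_lasso_path"
  )
}

#' @export
print.clogit_lasso_path <- function(x, ...) {
  cat(sprintf("<clogit_lasso_path> %d lambda values in [%.4g, %.4g], %d covariates, %d strata\n",
              length(x$lambda), min(x$lambda), max(x$lambda),
              length(x$variable_names), x$n_strata))
  cat(sprintf("  df range %d..%d; %d/%d fits converged\n",
              min(x$df), max(x$df), sum(x$converged), length(x$lambda)))
  invisible(x)
}

#' Export a fitted path as a tibble suitable for CSV
#'
#' One row per lambda: `lambda`, `df`, `neg_log_lik`, then one column per
#' coefficient.
#'
#' @param path A `clogit_lasso_path`.
#' @return A tibble.
#' @export
path_table <- function(path) {
  dplyr::bind_cols(
    tibble::tibble(lambda = path$lambda, df = path$df,
                   neg_log_lik = path$neg_log_likelihood,
                   converged = path$converged),
    tibble::as_tibble(path$beta)
  )
}
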