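# Choose lambda on the grid: likelihood-based K-fold cross-validation
# (folds are strata, never rows) or BIC.

#' Likelihood-based K-fold cross-validation
#'
#' Strata are shuffled by `seed` and split into `nfolds` near-equal folds.
#' For each fold the path is refitted on the remaining folds (warm starts,
#' same lambda grid, computed once on the full data) and the held-out
#' conditional log-likelihood `-sum_{n in fold} log(1 + sum_l e^{-x_ln
#' beta})` is recorded per lambda. The selected lambda maximizes the mean
#' held-out log-likelihood across folds; ties break toward the larger
#' (sparser) lambda. Lambdas that fail to converge in any fold are excluded.
#'
#' @inheritParams clogit_lasso
#' @param nfolds Number of folds K, `2 <= K <= N` strata. Default 10.
#' @param seed Integer seed for the fold shuffle (also recorded in the
#'   result). Default 1.
#' @param one_se Apply the one-standard-error rule: among lambdas whose mean
#'   criterion is within one SE of the best, pick the largest. Default
#'   `FALSE` (plain maximizer).
#' @return Object of class `cv_clogit_lasso` with the full-data path, the
#'   fold-wise and mean held-out log-likelihoods, and the selection (a
#'   `clogit_lasso_selection`). Has [tidy()], [glance()], [autoplot()].
#'
#' @examples
#' d <- simulate_matched(n_strata = 120, n_controls = 1,
#'                       beta = c(1, 0, 0), prevalence = 0.3, seed = 5)
#' cv <- cv_clogit_lasso(d, n_lambda = 15, nfolds = 4, seed = 1)
#' glance(cv)
#' @export
cv_clogit_lasso <- function(data, stratum = "stratum", case = "case",
                            unpenalized = NULL, lambda = NULL, epsilon = 0.01,
                            n_lambda = 100, scale = c("log", "linear"),
                            nfolds = 10, seed = 1, one_se = FALSE,
                            drop_concordant = FALSE, sparse = FALSE,
                            control = solver_control()) {
  scale <- match.arg(scale)
  x <- as_difference_matrix(data, stratum = .col_arg(enquo(stratum)),
                            case = .col_arg(enquo(case)),
                            unpenalized = unpenalized, sparse = sparse)
  if (drop_concordant) x <- drop_concordant_strata(x)
  N <- x$n_strata
  nfolds <- as.integer(nfolds)
  if (nfolds < 2) abort("`nfolds` must be >= 2.")
  if (N < nfolds) abort("More folds than strata.")

  lmax <- lambda_max(x, control)
  if (is.null(lambda)) {
    lambda <- lambda_grid(lmax, epsilon = epsilon, n_lambda = n_lambda,
                          scale = scale)
  } else {
    lambda <- sort(unique(as.numeric(lambda)), decreasing = TRUE)
  }

  fold_of <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    shuffled <- sample.int(N)
    f <- integer(N)
    f[shuffled] <- rep_len(seq_len(nfolds), N)
    f
  })

  T_ <- length(lambda)
  fold_ll <- matrix(NA_real_, nfolds, T_)
  fold_conv <- matrix(FALSE, nfolds, T_)
  for (k in seq_len(nfolds)) {
    train <- which(fold_of != k)
    test <- which(fold_of == k)
    x_train <- subset_strata(x, train)
    x_test <- subset_strata(x, test)
    informative <- function(d) any(as.numeric(rowSums(abs(d$X))) > 0)
    if (!informative(x_train)) {
      abort(sprintf(
        "Fold %d leaves no informative training strata; try fewer folds.", k))
    }
    pk <- fit_path(x_train, lambda, control = control, lambda_max_value = lmax)
    fold_conv[k, ] <- pk$converged
    for (t in seq_len(T_)) {
      if (pk$converged[t]) {
        fold_ll[k, t] <- -cl_neg_loglik(x_test, unname(pk$beta[t, ]))
      }
    }
  }

  usable <- apply(fold_conv, 2, all)
  if (!any(usable)) abort("No lambda converged in every fold.")
  cv_mean <- ifelse(usable, colMeans(fold_ll), NA_real_)
  cv_sd <- apply(fold_ll, 2, sd)

  best <- which(cv_mean == max(cv_mean, na.rm = TRUE))[1]  # grid decreasing: first = largest lambda
  idx <- best
  if (one_se) {
    thr <- cv_mean[best] - cv_sd[best] / sqrt(nfolds)
    idx <- which(usable & cv_mean >= thr)[1]
  }

  full_path <- fit_path(x, lambda, control = control, lambda_max_value = lmax)
  selection <- new_selection(
    criterion = "cv", path = full_path, index = idx,
    values = tibble::tibble(lambda = lambda, criterion = cv_mean,
                            sd = cv_sd, usable = usable),
    seed = seed, nfolds = nfolds
  )
  structure(
    list(lambda = lambda, fold_ll = fold_ll, cv_mean = cv_mean, cv_sd = cv_sd,
         usable = usable, fold_of = fold_of, nfolds = nfolds, seed = seed,
         path = full_path, selection = selection),
    class = "cv_clogit_lasso"
  )
}

#' @export
print.cv_clogit_lasso <- function(x, ...) {
  cat(sprintf("<cv_clogit_lasso> %d-fold, %d lambda values, seed %d\n",
              x$nfolds, length(x$lambda), x$seed))
  print(x$selection)
  invisible(x)
}

#' BIC model selection along a fitted path
#'
#' `BIC(lambda) = 2 * neg_log_likelihood + df * log(N)` with `N` the number
#' of strata (each stratum is one multinomial observation of the conditional
#' likelihood) and `df` the number of nonzero penalized coefficients plus the
#' number of forced covariates. Selects the minimizer; ties break toward the
#' larger lambda. Non-converged path entries are excluded.
#'
#' @param path A `clogit_lasso_path` from [clogit_lasso()].
#' @return A `clogit_lasso_selection`.
#' @export
bic_select <- function(path) {
  stopifnot(inherits(path, "clogit_lasso_path"))
  if (!any(path$converged)) abort("No converged path entry.")
  n_forced <- sum(path$penalty_mask == 0L)
  df_total <- path$df + n_forced
  bic <- 2 * path$neg_log_likelihood + df_total * log(path$n_strata)
  bic[!path$converged] <- NA_real_
  idx <- which(bic == min(bic, na.rm = TRUE))[1]
  new_selection(
    criterion = "bic", path = path, index = idx,
    values = tibble::tibble(lambda = path$lambda, criterion = bic,
                            df = df_total, usable = path$converged)
  )
}

#' CV selection from prepared objects
#'
#' Convenience front end choosing between criteria.
#'
#' @inheritParams cv_clogit_lasso
#' @param method `"cv"` or `"bic"`.
#' @param ... Passed through to [cv_clogit_lasso()] / [clogit_lasso()].
#' @return A `clogit_lasso_selection` (for `"cv"`, with the CV object in
#'   attribute `"cv"`).
#' @export
select_lambda <- function(data, method = c("cv", "bic"), ...) {
  method <- match.arg(method)
  if (method == "cv") {
    cv <- cv_clogit_lasso(data, ...)
    out <- cv$selection
    attr(out, "cv") <- cv
    out
  } else {
    bic_select(clogit_lasso(data, ...))
  }
}

new_selection <- function(criterion, path, index, values, seed = NULL,
                          nfolds = NULL) {
  structure(
    list(
      criterion = criterion,
      values = values,
      lambda = path$lambda[index],
      index = index,
      beta = path$beta[index, ],
      df = path$df[index],
      penalty_mask = path$penalty_mask,
      variable_names = path$variable_names,
      seed = seed,
      nfolds = nfolds,
      path = path
    ),
    class = "clogit_lasso_selection"
  )
}

#' @export
print.clogit_lasso_selection <- function(x, ...) {
  cat(sprintf("<clogit_lasso_selection> %s-selected lambda = %.4g (df = %d)\n",
              toupper(x$criterion), x$lambda, x$df))
  ors <- odds_ratios(x)
  if (nrow(ors) > 0) print(ors, n = 10)
  invisible(x)
}

#' Odds ratios of a selected model
#'
#' `exp(beta_j)` for every nonzero coefficient; penalized coefficients shrunk
#' exactly to zero are omitted, forced covariates are always reported (odds
#' ratio 1 when zero).
#'
#' @param result A `clogit_lasso_selection` or `clogit_lasso_fit`.
#' @return A tibble with `term`, `estimate` (log odds ratio), `odds_ratio`,
#'   and `penalized`.
#' @export
odds_ratios <- function(result) {
  beta <- result$beta
  mask <- result$penalty_mask
  keep <- beta != 0 | mask == 0L
  tibble::tibble(
    term = names(beta)[keep],
    estimate = unname(beta[keep]),
    odds_ratio = exp(unname(beta[keep])),
    penalized = mask[keep] == 1L
  )
}
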