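#' Build the within-stratum difference matrix
#'
#' All fitting operates on the difference representation of the conditional
#' likelihood: for each stratum the case's covariate vector u0 is subtracted
#' from each control's vector, giving one row x_i = u0 - u_i per control. A
#' stratum with one case and M controls contributes M rows; the case row
#' itself is consumed. On this scale the conditional likelihood of the
#' stratified logistic model equals a no-intercept likelihood with diagonal
#' IRLS weights, which is what makes large-N fitting cheap.
#'
#' @param data A [matched_data()] object.
#' @param sparse Store the difference matrix as a sparse `Matrix::dgCMatrix`.
#'   Worthwhile for rare binary exposures; the default keeps a dense base
#'   matrix.
#' @return An object of class `difference_matrix` with fields `X` (sum(M_n)
#'   rows by p columns, rows of a stratum contiguous), `row_stratum` (integer
#'   stratum index per row), `stratum_sizes` (M_n), `penalty_mask` and
#'   `variable_names`.
#'
#' @examples
#' d <- simulate_matched(n_strata = 5, n_controls = 2,
#'                       beta = c(1, 0), prevalence = 0.4, seed = 2)
#' dm <- difference_matrix(matched_data(d))
#' dm$X
#' @export
difference_matrix <- function(data, sparse = FALSE) {
  stopifnot(inherits(data, "matched_data"))
  strat_idx <- match(data$stratum, data$stratum_levels)
  case_rows <- which(data$case == 1L)
  # case row per stratum, in stratum order
  case_of <- integer(length(data$stratum_levels))
  case_of[strat_idx[case_rows]] <- case_rows
  ctrl_rows <- which(data$case == 0L)
  X <- data$U[case_of[strat_idx[ctrl_rows]], , drop = FALSE] -
    data$U[ctrl_rows, , drop = FALSE]
  rownames(X) <- NULL
  if (sparse) X <- methods::as(X, "CsparseMatrix")
  new_difference_matrix(
    X = X,
    row_stratum = strat_idx[ctrl_rows],
    stratum_sizes = setNames(as.integer(data$stratum_sizes) - 1L,
                             data$stratum_levels),
    penalty_mask = data$penalty_mask,
    variable_names = data$variable_names
  )
}

new_difference_matrix <- function(X, row_stratum, stratum_sizes, penalty_mask,
                                  variable_names) {
  stopifnot(nrow(X) == sum(stratum_sizes), nrow(X) == length(row_stratum))
  structure(
    list(
      X = X,
      row_stratum = as.integer(row_stratum),
      stratum_sizes = stratum_sizes,
      n_strata = length(stratum_sizes),
      penalty_mask = penalty_mask,
      variable_names = variable_names
    ),
    class = "difference_matrix"
  )
}

#' @export
print.difference_matrix <- function(x, ...) {
  cat(sprintf("<difference_matrix> %d strata, %d difference rows, %d covariates%s\n",
              x$n_strata, nrow(x$X), ncol(x$X),
              if (inherits(x$X, "sparseMatrix")) " (sparse)" else ""))
  invisible(x)
}

#' @export
dim.difference_matrix <- function(x) dim(x$X)

# Subset a difference matrix to a set of strata (indices into 1..n_strata),
# renumbering row_stratum to 1..length(keep). Used by cross-validation.
subset_strata <- function(x, keep) {
  keep <- sort(unique(as.integer(keep)))
  rows <- x$row_stratum %in% keep
  new_difference_matrix(
    X = x$X[rows, , drop = FALSE],
    row_stratum = match(x$row_stratum[rows], keep),
    stratum_sizes = x$stratum_sizes[keep],
    penalty_mask = x$penalty_mask,
    variable_names = x$variable_names
  )
}

#' Drop concordant strata
#'
#' A stratum whose difference rows are all exactly zero (case and controls
#' identical on every covariate) contributes the constant log(M_n + 1) to the
#' negative conditional log-likelihood and nothing to its gradient, so
#' removing it changes likelihood values but never the fitted coefficients.
#' Dropping is opt-in for that reason.
#'
#' @param x A [difference_matrix()].
#' @return A `difference_matrix` restricted to informative strata, with
#'   attributes `"n_dropped"` (count removed) and `"dropped_sizes"` (their
#'   M_n values).
#' @export
drop_concordant_strata <- function(x) {
  stopifnot(inherits(x, "difference_matrix"))
  row_nonzero <- as.numeric(rowSums(abs(x$X))) > 0
  informative <- as.numeric(rowsum(as.numeric(row_nonzero), x$row_stratum)) > 0
  if (!any(informative)) abort("no informative strata")
  keep <- which(informative)
  out <- subset_strata(x, keep)
  attr(out, "n_dropped") <- sum(!informative)
  attr(out, "dropped_sizes") <- unname(x$stratum_sizes[!informative])
  out
}

# Coerce user-facing inputs: data frame -> matched_data -> difference_matrix
as_difference_matrix <- function(data, stratum = "stratum", case = "case",
                                 unpenalized = NULL, sparse = FALSE) {
  if (inherits(data, "difference_matrix")) return(data)
  if (!inherits(data, "matched_data")) {
    data <- matched_data(data, stratum = stratum, case = case,
                         unpenalized = unpenalized)
  }
  difference_matrix(data, sparse = sparse)
}
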