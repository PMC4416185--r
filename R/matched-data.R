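#' Construct a validated matched dataset
#'
#' Validates and packages long-format matched case-control (or case-crossover)
#' data: one row per subject-in-stratum, a stratum identifier, a binary case
#' indicator, and one or more covariate columns. Every stratum must contain
#' exactly one case and at least one control; variable stratum sizes (1:M with
#' M differing across strata) are allowed.
#'
#' Strata are ordered by first appearance in `data` and row order within a
#' stratum is preserved. The case is identified by the indicator column, never
#' by position.
#'
#' @param data A data frame in long format.
#' @param stratum Column holding the stratum (matched-set) identifier; bare
#'   name or string. Default `"stratum"`.
#' @param case Column holding the case indicator, coded 0/1 with exactly one
#'   1 per stratum. Default `"case"`.
#' @param unpenalized Character vector of covariate names to force into the
#'   model (their coefficients are never penalized). Default none.
#' @param covariates Optional character vector naming the covariate columns;
#'   by default every column other than `stratum` and `case` is a covariate.
#'
#' @return An object of class `matched_data`: the validated long tibble plus
#'   the covariate matrix, penalty mask (1 = penalized, 0 = forced) and
#'   stratum bookkeeping.
#'
#' @examples
#' d <- simulate_matched(n_strata = 20, n_controls = 1,
#'                       beta = c(0.5, 0), prevalence = 0.3, seed = 1)
#' md <- matched_data(d)
#' md
#' @export
matched_data <- function(data, stratum = "stratum", case = "case",
                         unpenalized = NULL, covariates = NULL) {
  stratum_col <- .col_arg(enquo(stratum))
  case_col <- .col_arg(enquo(case))
  data <- tibble::as_tibble(data)
  for (col in c(stratum_col, case_col)) {
    if (!col %in% names(data)) {
      abort(sprintf("Column '%s' not found in `data`.", col))
    }
  }
  covariates <- covariates %||% setdiff(names(data), c(stratum_col, case_col))
  if (length(covariates) == 0) {
    abort("No covariate columns found.")
  }
  if (anyDuplicated(covariates)) {
    abort("Covariate names must be unique.")
  }

  y <- data[[case_col]]
  if (!all(y %in% c(0, 1))) {
    abort(sprintf("Case column '%s' must be coded 0/1.", case_col))
  }
  y <- as.integer(y)

  miss <- covariates[vapply(data[covariates], anyNA, logical(1))]
  if (length(miss) > 0) {
    abort(paste0("Missing covariate values in column(s): ",
                 paste(miss, collapse = ", ")))
  }
  non_num <- covariates[!vapply(data[covariates], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort(paste0("Non-numeric covariate column(s): ",
                 paste(non_num, collapse = ", ")))
  }

  labels <- as.character(data[[stratum_col]])
  # strata ordered by first appearance; stable sort keeps within-stratum order
  stratum_levels <- unique(labels)
  ord <- order(match(labels, stratum_levels))
  data <- data[ord, , drop = FALSE]
  labels <- labels[ord]
  y <- y[ord]

  n_cases <- tapply(y, factor(labels, levels = stratum_levels), sum)
  bad <- names(n_cases)[n_cases != 1L]
  if (length(bad) > 0) {
    abort(paste0("Each stratum must contain exactly one case; violated by: ",
                 paste(head(bad, 5), collapse = ", "),
                 if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5)))
  }
  sizes <- as.integer(table(factor(labels, levels = stratum_levels)))
  if (any(sizes < 2L)) {
    bad <- stratum_levels[sizes < 2L]
    abort(paste0("Each stratum must contain at least one control; violated by: ",
                 paste(head(bad, 5), collapse = ", ")))
  }

  unpenalized <- unpenalized %||% character(0)
  unknown <- setdiff(unpenalized, covariates)
  if (length(unknown) > 0) {
    abort(paste0("Unpenalized variable(s) not found: ",
                 paste(unknown, collapse = ", ")))
  }
  penalty_mask <- as.integer(!(covariates %in% unpenalized))
  names(penalty_mask) <- covariates

  U <- as.matrix(data[covariates])
  storage.mode(U) <- "double"

  structure(
    list(
      data = data,
      stratum = labels,
      stratum_levels = stratum_levels,
      stratum_sizes = setNames(sizes, stratum_levels),
      case = y,
      U = U,
      variable_names = covariates,
      penalty_mask = penalty_mask,
      stratum_col = stratum_col,
      case_col = case_col
    ),
    class = "matched_data"
  )
}

# Accept a column given as a string, a variable holding a string, or a bare name.
.col_arg <- function(q) {
  val <- tryCatch(rlang::eval_tidy(q), error = function(e) NULL)
  if (is.character(val) && length(val) == 1) return(val)
  rlang::as_name(rlang::quo_get_expr(q))
}

#' @export
print.matched_data <- function(x, ...) {
  m <- x$stratum_sizes - 1L
  cat(sprintf("<matched_data> %d strata, %d subjects, %d covariates\n",
              length(x$stratum_sizes), nrow(x$U), ncol(x$U)))
  cat(sprintf("  controls per case: %s\n",
              if (min(m) == max(m)) sprintf("1:%d matching", min(m))
              else sprintf("1:%d to 1:%d (variable)", min(m), max(m))))
  n_forced <- sum(x$penalty_mask == 0L)
  if (n_forced > 0) {
    cat(sprintf("  forced (unpenalized) covariates: %s\n",
                paste(x$variable_names[x$penalty_mask == 0L], collapse = ", ")))
  }
  invisible(x)
}

#' @export
glance.matched_data <- function(x, ...) {
  sizes <- x$stratum_sizes
  tibble::tibble(
    n_strata = length(sizes),
    n_subjects = nrow(x$U),
    n_covariates = ncol(x$U),
    n_forced = sum(x$penalty_mask == 0L),
    min_controls = min(sizes) - 1L,
    max_controls = max(sizes) - 1L
  )
}

#' Read long-format matched data from a delimited file
#'
#' Reads a CSV/TSV file (header row required) and validates it with
#' [matched_data()]. The delimiter is taken from the file extension
#' (`.tsv`/`.txt` read as tab, anything else as comma) unless given.
#'
#' @inheritParams matched_data
#' @param file Path to a delimited text file.
#' @param delim Field delimiter; `NULL` (default) guesses from the extension.
#' @return A [matched_data()] object.
#' @export
read_matched <- function(file, stratum = "stratum", case = "case",
                         unpenalized = NULL, covariates = NULL, delim = NULL) {
  delim <- delim %||% (if (grepl("\\.(tsv|txt)$", file, ignore.case = TRUE)) "\t" else ",")
  raw <- readr::read_delim(file, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  matched_data(raw, stratum = {{ stratum }}, case = {{ case }},
               unpenalized = unpenalized, covariates = covariates)
}

#' Read a sparse exposure matrix with a stratum/case sidecar
#'
#' For very sparse binary exposure data the covariates can be supplied as a
#' MatrixMarket file, with stratum identifiers and case indicators in an
#' aligned sidecar CSV (same row order as the matrix).
#'
#' @param mtx_file Path to a MatrixMarket (.mtx) exposure matrix
#'   (rows = subjects, columns = predictors).
#' @param meta_file Path to a CSV with the stratum and case columns, one row
#'   per subject in matrix row order.
#' @param variable_names Optional predictor names (length = ncol of matrix);
#'   defaults to `V1..Vp`.
#' @inheritParams matched_data
#' @return A [matched_data()] object (covariates stored densely after
#'   validation; fitting re-sparsifies via the Gram formulation).
#' @export
read_matched_sparse <- function(mtx_file, meta_file, stratum = "stratum",
                                case = "case", unpenalized = NULL,
                                variable_names = NULL) {
  X <- as.matrix(Matrix::readMM(mtx_file))
  storage.mode(X) <- "double"  # pattern .mtx files read back as logical
  meta <- readr::read_csv(meta_file, show_col_types = FALSE, progress = FALSE)
  if (nrow(meta) != nrow(X)) {
    abort(sprintf("Sidecar has %d rows but matrix has %d.", nrow(meta), nrow(X)))
  }
  variable_names <- variable_names %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- variable_names
  raw <- dplyr::bind_cols(meta, tibble::as_tibble(X))
  matched_data(raw, stratum = {{ stratum }}, case = {{ case }},
               unpenalized = unpenalized, covariates = variable_names)
}

#' Drop rarely observed penalized predictors
#'
#' Removes penalized covariate columns observed (nonzero) in fewer than
#' `min_subjects` subjects. Intended for binary exposure columns, where the
#' nonzero count is the number of exposed subjects. Forced (unpenalized)
#' covariates are never removed.
#'
#' @param data A [matched_data()] object.
#' @param min_subjects Minimum number of subjects with a nonzero value a
#'   penalized column needs to be retained.
#' @return A [matched_data()] object; removed column names are attached as
#'   attribute `"dropped_predictors"`.
#' @export
drop_rare_predictors <- function(data, min_subjects) {
  stopifnot(inherits(data, "matched_data"))
  if (min_subjects < 0) abort("`min_subjects` must be >= 0.")
  n_nonzero <- colSums(data$U != 0)
  drop <- data$variable_names[n_nonzero < min_subjects & data$penalty_mask == 1L]
  if (length(drop) > 0) {
    keep <- setdiff(data$variable_names, drop)
    out <- matched_data(
      data$data[, c(data$stratum_col, data$case_col, keep)],
      stratum = data$stratum_col, case = data$case_col,
      unpenalized = data$variable_names[data$penalty_mask == 0L],
      covariates = keep
    )
  } else {
    out <- data
  }
  attr(out, "dropped_predictors") <- drop
  out
}
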