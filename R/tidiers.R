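# broom-style tidiers and ggplot2 autoplot methods.

#' @export
tidy.clogit_lasso_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    odds_ratio = exp(unname(x$beta)),
    penalized = x$penalty_mask == 1L
  )
}

#' @export
glance.clogit_lasso_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    neg_log_likelihood = x$neg_log_likelihood,
    objective = x$objective,
    df = x$n_nonzero,
    n_outer = x$n_outer,
    converged = x$converged,
    kkt_residual = x$kkt_residual
  )
}

#' @export
tidy.clogit_lasso_path <- function(x, ...) {
  tibble::as_tibble(x$beta) |>
    dplyr::mutate(lambda = x$lambda, .before = 1) |>
    tidyr::pivot_longer(-"lambda", names_to = "term", values_to = "estimate")
}

#' @export
glance.clogit_lasso_path <- function(x, ...) {
  tibble::tibble(
    n_lambda = length(x$lambda),
    lambda_max = x$lambda_max,
    lambda_min = min(x$lambda),
    n_strata = x$n_strata,
    n_covariates = length(x$variable_names),
    max_df = max(x$df),
    n_converged = sum(x$converged)
  )
}

#' Coefficient trace of a regularization path
#'
#' Coefficient values against lambda (log-scaled x axis, reversed so the
#' model grows to the right). Coefficients that are zero along the entire
#' path are not drawn.
#'
#' @param object A `clogit_lasso_path`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clogit_lasso_path <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::group_by(.data$term) |>
    dplyr::filter(any(.data$estimate != 0, na.rm = TRUE)) |>
    dplyr::ungroup()
  ggplot2::ggplot(td, ggplot2::aes(x = .data$lambda, y = .data$estimate,
                                   group = .data$term, colour = .data$term)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "coefficient (log odds ratio)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
tidy.cv_clogit_lasso <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    estimate = x$cv_mean,
    std.error = x$cv_sd / sqrt(x$nfolds),
    usable = x$usable
  )
}

#' @export
glance.cv_clogit_lasso <- function(x, ...) {
  tibble::tibble(
    nfolds = x$nfolds,
    seed = x$seed,
    lambda_selected = x$selection$lambda,
    df_selected = x$selection$df,
    cv_max = max(x$cv_mean, na.rm = TRUE)
  )
}

#' Cross-validation curve
#'
#' Mean held-out conditional log-likelihood against lambda, with one-SE
#' ribbons and the selected lambda marked.
#'
#' @param object A `cv_clogit_lasso`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cv_clogit_lasso <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$lambda, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - .data$std.error,
                                      ymax = .data$estimate + .data$std.error),
                         alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$selection$lambda,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda),
                  y = "held-out conditional log-likelihood") +
    ggplot2::theme_minimal()
}

#' @export
tidy.clogit_lasso_selection <- function(x, ...) {
  odds_ratios(x)
}

#' @export
glance.clogit_lasso_selection <- function(x, ...) {
  tibble::tibble(
    criterion = x$criterion,
    lambda = x$lambda,
    df = x$df,
    n_forced = sum(x$penalty_mask == 0L),
    seed = x$seed %||% NA_integer_
  )
}

#' @importFrom rlang .data
NULL
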