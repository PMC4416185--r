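# Simulators for matched case-control and case-crossover designs with known
# sparse effects. The case within each stratum is drawn from the conditional
# model itself: P(subject i is the case) = exp(u_i beta) / sum_l exp(u_l
# beta). Stratum intercepts cancel from that probability, so the conditional
# likelihood the estimator maximizes is exactly the data-generating
# conditional model, and parameter recovery tests exercise the solver rather
# than a sampling approximation.

restore_rng <- function(seed) {
  if (is.null(seed)) return(invisible())
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

# Exact softmax draw per stratum via the Gumbel-max trick, vectorized over a
# matrix of linear predictors (strata in rows).
softmax_draw <- function(lp_matrix) {
  gumbel <- -log(-log(matrix(runif(length(lp_matrix)), nrow(lp_matrix))))
  max.col(lp_matrix + gumbel, ties.method = "first")
}

# Binary exposures with within-stratum exchangeable correlation rho via a
# shared latent draw: each subject copies the stratum-level Bernoulli with
# probability sqrt(rho), else draws independently; pairwise correlation is
# then exactly rho and the marginal prevalence is preserved.
draw_binary_block <- function(n_strata, size, prevalence, rho) {
  p <- length(prevalence)
  total <- n_strata * size
  shared <- matrix(runif(n_strata * p) < rep(prevalence, each = n_strata),
                   n_strata, p)
  own <- matrix(runif(total * p) < rep(prevalence, each = total), total, p)
  if (rho > 0) {
    copy <- matrix(runif(total * p) < sqrt(rho), total, p)
    stratum_of <- rep(seq_len(n_strata), each = size)
    out <- ifelse(copy, shared[stratum_of, , drop = FALSE], own)
  } else {
    out <- own
  }
  storage.mode(out) <- "double"
  out
}

#' Simulate a matched 1:M case-control dataset with known effects
#'
#' Each stratum gets `n_controls + 1` subjects with covariates drawn
#' independently across strata (binary with the given prevalence and optional
#' within-stratum exchangeable correlation, or standard gaussian); the case
#' is then the subject drawn with probability proportional to
#' `exp(u beta)` within the stratum. Stratum intercepts alpha_n are drawn for
#' realism but, by construction, never influence which subject is the case.
#'
#' @param n_strata Number of matched sets N.
#' @param n_controls Controls per case M (scalar, or vector of length
#'   `n_strata` for variable stratum sizes).
#' @param beta True log odds ratios (length p).
#' @param prevalence Exposure prevalence per predictor, in (0, 1); recycled
#'   to length p. Ignored for gaussian predictors.
#' @param predictor `"binary"` (default) or `"gaussian"`.
#' @param correlation Within-stratum exchangeable correlation of each
#'   predictor, in \[0, 1). Default 0.
#' @param alpha_mean,alpha_sd Distribution of the stratum intercepts
#'   (attached as attribute `"alpha"`, unused by the conditional model).
#' @param seed Integer seed; the RNG state is restored on exit.
#' @return A long-format tibble with columns `stratum`, `case`, `x1..xp`, and
#'   attributes `beta_true`, `alpha`, `design`.
#'
#' @examples
#' d <- simulate_matched(n_strata = 50, n_controls = 1,
#'                       beta = c(log(2), 0), prevalence = 0.3, seed = 7)
#' head(d)
#' @export
simulate_matched <- function(n_strata, n_controls = 1, beta,
                             prevalence = 0.2,
                             predictor = c("binary", "gaussian"),
                             correlation = 0, alpha_mean = 0, alpha_sd = 1,
                             seed = NULL) {
  predictor <- match.arg(predictor)
  p <- length(beta)
  if (any(prevalence <= 0 | prevalence >= 1)) {
    abort("`prevalence` must be in (0, 1).")
  }
  if (correlation < 0 || correlation >= 1) {
    abort("`correlation` must be in [0, 1).")
  }
  prevalence <- rep_len(prevalence, p)
  sizes <- rep_len(as.integer(n_controls), n_strata) + 1L
  if (any(sizes < 2L)) abort("`n_controls` must be >= 1.")
  cleanup <- restore_rng(seed)
  on.exit(if (is.function(cleanup)) cleanup())

  # variable sizes: pad every stratum to the maximum, mask padded slots out
  size_max <- max(sizes)
  if (predictor == "binary") {
    U <- draw_binary_block(n_strata, size_max, prevalence, correlation)
  } else {
    total <- n_strata * size_max
    shared <- matrix(rnorm(n_strata * p), n_strata, p)
    own <- matrix(rnorm(total * p), total, p)
    stratum_of <- rep(seq_len(n_strata), each = size_max)
    U <- sqrt(correlation) * shared[stratum_of, , drop = FALSE] +
      sqrt(1 - correlation) * own
  }
  stratum_of <- rep(seq_len(n_strata), each = size_max)
  pos_of <- rep(seq_len(size_max), times = n_strata)
  keep <- pos_of <= sizes[stratum_of]
  lp <- matrix(as.numeric(U %*% beta), n_strata, size_max, byrow = TRUE)
  lp[!keep_matrix(sizes, size_max)] <- -Inf  # padded slots can never be the case
  case_pos <- softmax_draw(lp)

  U <- U[keep, , drop = FALSE]
  stratum_of <- stratum_of[keep]
  pos_of <- pos_of[keep]
  y <- as.integer(pos_of == case_pos[stratum_of])

  alpha <- rnorm(n_strata, alpha_mean, alpha_sd)  # drawn last: cannot perturb the draws above

  colnames(U) <- paste0("x", seq_len(p))
  out <- dplyr::bind_cols(
    tibble::tibble(stratum = sprintf("s%d", stratum_of), case = y),
    tibble::as_tibble(U)
  )
  attr(out, "beta_true") <- beta
  attr(out, "alpha") <- alpha
  attr(out, "design") <- list(n_strata = n_strata, n_controls = sizes - 1L,
                              prevalence = prevalence, predictor = predictor,
                              correlation = correlation, seed = seed)
  out
}

keep_matrix <- function(sizes, size_max) {
  outer(sizes, seq_len(size_max), `>=`)
}

#' Simulate a case-crossover dataset with serially dependent exposures
#'
#' Each subject is one stratum of `n_periods` person-periods. Every
#' predictor's exposure over the periods follows a stationary first-order
#' binary chain with the given marginal prevalence and lag-one correlation
#' `serial_correlation`; the case period is then drawn with probability
#' proportional to `exp(u beta)` across the subject's periods, yielding a
#' 1:(n_periods - 1) matched dataset.
#'
#' `serial_correlation = 1` makes all periods identical (every stratum
#' concordant); `serial_correlation = 0` reduces to independent draws.
#'
#' @param n_subjects Number of subjects (strata).
#' @param n_periods Periods per subject (one case period + the rest), >= 2.
#'   Default 5 (a 1:4 design).
#' @inheritParams simulate_matched
#' @param serial_correlation Lag-one autocorrelation of each exposure chain,
#'   in \[0, 1\].
#' @return A long-format tibble as in [simulate_matched()].
#' @export
simulate_case_crossover <- function(n_subjects, n_periods = 5, beta,
                                    prevalence = 0.2,
                                    serial_correlation = 0, seed = NULL) {
  p <- length(beta)
  if (n_periods < 2) abort("`n_periods` must be >= 2.")
  if (any(prevalence <= 0 | prevalence >= 1)) {
    abort("`prevalence` must be in (0, 1).")
  }
  if (serial_correlation < 0 || serial_correlation > 1) {
    abort("`serial_correlation` must be in [0, 1].")
  }
  prevalence <- rep_len(prevalence, p)
  cleanup <- restore_rng(seed)
  on.exit(if (is.function(cleanup)) cleanup())

  phi <- serial_correlation
  # stationary chain: P(1 | prev 1) = pi + phi (1 - pi), P(1 | prev 0) = pi (1 - phi)
  U <- array(0, dim = c(n_subjects, n_periods, p))
  for (j in seq_len(p)) {
    pi_j <- prevalence[j]
    cur <- runif(n_subjects) < pi_j
    U[, 1, j] <- cur
    if (n_periods > 1) {
      for (t in 2:n_periods) {
        pr <- ifelse(cur, pi_j + phi * (1 - pi_j), pi_j * (1 - phi))
        cur <- runif(n_subjects) < pr
        U[, t, j] <- cur
      }
    }
  }
  lp <- matrix(0, n_subjects, n_periods)
  for (j in seq_len(p)) lp <- lp + U[, , j] * beta[j]
  case_pos <- softmax_draw(lp)

  flat <- matrix(aperm(U, c(2, 1, 3)), n_subjects * n_periods, p)
  colnames(flat) <- paste0("x", seq_len(p))
  stratum_of <- rep(seq_len(n_subjects), each = n_periods)
  pos_of <- rep(seq_len(n_periods), times = n_subjects)
  out <- dplyr::bind_cols(
    tibble::tibble(stratum = sprintf("s%d", stratum_of),
                   case = as.integer(pos_of == case_pos[stratum_of])),
    tibble::as_tibble(flat)
  )
  attr(out, "beta_true") <- beta
  attr(out, "design") <- list(n_subjects = n_subjects, n_periods = n_periods,
                              prevalence = prevalence,
                              serial_correlation = phi, seed = seed)
  out
}
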