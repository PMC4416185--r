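# Random small instances used across the suite. Everything is seeded by the
# caller; draws go through R's RNG directly.

# A random difference matrix with N strata of sizes drawn from `sizes`
# (1 case : M controls), covariates ~ difference of Bernoulli(prev) exposures
# unless gaussian = TRUE.
random_instance <- function(N = 20, M = 1, p = 3, prev = 0.3,
                            gaussian = FALSE, n_forced = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep_len(M, N)
  rows <- sum(sizes)
  X <- if (gaussian) {
    matrix(rnorm(rows * p), rows, p)
  } else {
    matrix(rbinom(rows * p, 1, prev) - rbinom(rows * p, 1, prev), rows, p)
  }
  colnames(X) <- paste0("x", seq_len(p))
  mask <- rep(1L, p)
  if (n_forced > 0) mask[seq_len(n_forced)] <- 0L
  names(mask) <- colnames(X)
  matchedlasso:::new_difference_matrix(
    X = X,
    row_stratum = rep(seq_len(N), times = sizes),
    stratum_sizes = stats::setNames(sizes, paste0("s", seq_len(N))),
    penalty_mask = mask,
    variable_names = colnames(X)
  )
}

# Long-format tibble for a tiny hand-specified dataset.
toy_long <- function() {
  tibble::tibble(
    stratum = c("a", "a", "b", "b"),
    case = c(1, 0, 1, 0),
    x1 = c(1, 0, 0, 1),
    x2 = c(0, 1, 1, 1)
  )
}
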