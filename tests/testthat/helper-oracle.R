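# Independent oracles, deliberately coded without touching the package's
# solver path.
#
# oracle_fit: the penalized conditional likelihood minimized by accelerated
# proximal gradient (FISTA with backtracking and monotone restart) on the
# exact objective. Shares no code with the IRLS-CD implementation: loss and
# gradient are rewritten here from the stratified form, and convergence is
# declared on the unit-step proximal-gradient fixed-point residual.

# negative conditional log-likelihood written directly from the UNDIFFERENCED
# data: -sum_n [u_case beta - log sum_l exp(u_l beta)] over all stratum
# members including the case.
oracle_nll_undifferenced <- function(U, stratum, case, beta) {
  eta <- as.numeric(U %*% beta)
  f <- factor(stratum, levels = unique(stratum))
  terms <- tapply(seq_along(eta), f, function(idx) {
    e <- eta[idx]
    m <- max(e)
    log(sum(exp(e - m))) + m - e[which(case[idx] == 1)]
  })
  sum(terms)
}

.oracle_loss <- function(X, strat, beta) {
  s <- -as.numeric(X %*% beta)
  m <- pmax(as.numeric(tapply(s, strat, max)), 0)
  es <- exp(s - m[strat])
  den <- as.numeric(rowsum(es, strat)) + exp(-m)
  sum(m + log(den))
}

.oracle_grad <- function(X, strat, beta) {
  s <- -as.numeric(X %*% beta)
  m <- pmax(as.numeric(tapply(s, strat, max)), 0)
  es <- exp(s - m[strat])
  den <- as.numeric(rowsum(es, strat)) + exp(-m)
  as.numeric(crossprod(X, -es / den[strat]))
}

oracle_fit <- function(X, strat, penalty, beta0 = NULL, max_iter = 50000,
                       tol = 1e-9) {
  p <- ncol(X)
  beta <- if (is.null(beta0)) numeric(p) else beta0
  y <- beta
  tprev <- 1
  L <- 1
  prox <- function(v, step) sign(v) * pmax(abs(v) - step * penalty, 0)
  obj <- function(b) .oracle_loss(X, strat, b) + sum(penalty * abs(b))
  f_old <- obj(beta)
  k_done <- 0
  for (k in seq_len(max_iter)) {
    g <- .oracle_grad(X, strat, y)
    fy <- .oracle_loss(X, strat, y)
    repeat {
      cand <- prox(y - g / L, 1 / L)
      d <- cand - y
      if (.oracle_loss(X, strat, cand) <=
          fy + sum(g * d) + L / 2 * sum(d^2) + 1e-14) break
      L <- 2 * L
    }
    tcur <- (1 + sqrt(1 + 4 * tprev^2)) / 2
    y <- cand + ((tprev - 1) / tcur) * (cand - beta)
    f_new <- obj(cand)
    if (f_new > f_old) {  # monotone restart
      y <- cand
      tcur <- 1
    }
    beta <- cand
    tprev <- tcur
    f_old <- f_new
    L <- max(L / 1.5, 1e-6)
    k_done <- k
    if (k %% 20 == 0) {
      gb <- .oracle_grad(X, strat, beta)
      if (max(abs(prox(beta - gb, 1) - beta)) < tol) break
    }
  }
  list(beta = beta, objective = obj(beta), iterations = k_done)
}

oracle_fit_dm <- function(dm, lambda, ...) {
  penalty <- lambda * (dm$penalty_mask == 1L)
  oracle_fit(as.matrix(dm$X), dm$row_stratum, penalty, ...)
}
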