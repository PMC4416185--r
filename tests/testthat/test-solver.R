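test_that("soft threshold shrinks toward zero", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(c(-2, 0.3, 4), 0), c(-2, 0.3, 4))
  expect_error(soft_threshold(1, -0.1), ">= 0")
})

test_that("coordinate descent solves orthonormal and linear systems exactly", {
  # A = I: closed form gamma_j = S(b_j, lambda)
  b <- c(2, -0.4, 1.1, -3)
  g <- weighted_lasso_cd(diag(4), b, penalty = 1)
  expect_equal(as.numeric(g), soft_threshold(b, 1))

  # lambda = 0: plain linear solve
  set.seed(41)
  R <- matrix(rnorm(4), 2)
  A <- crossprod(R) + diag(2) * 0.1
  b2 <- rnorm(2)
  g2 <- weighted_lasso_cd(A, b2, penalty = 0, inner_tol = 1e-14,
                          max_sweeps = 10000)
  expect_equal(as.numeric(g2), as.numeric(solve(A, b2)), tolerance = 1e-8)
})

test_that("coordinate descent reaches the penalized weighted LS optimum", {
  # p = 5 SPD system; verify subgradient optimality of the CD solution,
  # then compare objective against a fine grid of perturbations
  set.seed(42)
  R <- matrix(rnorm(25), 5)
  A <- crossprod(R) + diag(5) * 0.5
  b <- rnorm(5)
  lam <- 0.7
  g <- as.numeric(weighted_lasso_cd(A, b, penalty = lam, inner_tol = 1e-13,
                                    max_sweeps = 10000))
  grad_q <- as.numeric(A %*% g) - b   # gradient of the smooth part
  res <- ifelse(g != 0, abs(grad_q + lam * sign(g)), pmax(abs(grad_q) - lam, 0))
  expect_lt(max(res), 1e-10)
  # no coordinate perturbation improves the objective
  qobj <- function(v) 0.5 * sum(v * (A %*% v)) - sum(b * v) + lam * sum(abs(v))
  base <- qobj(g)
  for (j in 1:5) {
    for (h in c(-1e-4, 1e-4)) {
      v <- g; v[j] <- v[j] + h
      expect_gte(qobj(v), base - 1e-12)
    }
  }
})

test_that("zero-curvature coordinates freeze when penalized, error when forced", {
  A <- diag(c(1, 0, 2))
  b <- c(1, 5, -1)
  g <- weighted_lasso_cd(A, b, penalty = c(0.1, 0.1, 0.1))
  expect_equal(as.numeric(g)[2], 0)
  expect_error(weighted_lasso_cd(A, b, penalty = c(0.1, 0, 0.1)),
               "collinear")
})

test_that("line search accepts the full step in easy regions and backtracks otherwise", {
  dm <- random_instance(N = 20, M = 1, p = 2, gaussian = TRUE, seed = 43)
  lam <- 0.1
  beta <- c(0, 0)
  g <- cl_gradient(dm, beta)
  # small step along -g decreases f: full step accepted
  ls <- line_search(dm, beta, -0.01 * as.numeric(g), lam)
  expect_equal(ls$t, 1)
  expect_lt(ls$f_new, cl_objective(dm, beta, lam))

  # a huge step in the ascent direction must backtrack below 1
  delta <- 50 * as.numeric(g)
  ls2 <- line_search(dm, beta, delta, lam)
  expect_lt(ls2$t, 1)
  # Armijo inequality holds at the returned t
  pen <- dm$penalty_mask == 1L
  slope <- sum(g * delta) +
    lam * (sum(abs((beta + delta)[pen])) - sum(abs(beta[pen])))
  expect_lte(ls2$f_new,
             cl_objective(dm, beta, lam) + 0.01 * ls2$t * slope + 1e-12)

  expect_error(line_search(dm, beta, c(0, 0), lam), "nonzero")
})

test_that("fit at lambda >= lambda_max returns the zero solution immediately", {
  set.seed(44)
  for (rep in 1:5) {
    dm <- random_instance(N = sample(10:30, 1), M = sample(1:4, 1), p = 4)
    if (max(colSums(abs(dm$X))) == 0) next
    lmax <- lambda_max(dm)
    f <- clogit_lasso_fit(dm, lmax)
    expect_equal(unname(f$beta), numeric(4))
    expect_equal(f$n_outer, 1L)
    expect_true(f$converged)
    f2 <- clogit_lasso_fit(dm, 1.3 * lmax)
    expect_equal(unname(f2$beta), numeric(4))
  }
})

test_that("solver agrees with the proximal-gradient oracle (1:1 and 1:M)", {
  set.seed(45)
  for (M in c(1, 3)) {
    dm <- random_instance(N = 30, M = M, p = 3, prev = 0.35)
    lmax <- lambda_max(dm)
    for (fr in c(0.05, 0.3)) {
      lam <- fr * lmax
      ours <- clogit_lasso_fit(dm, lam,
                               control = solver_control(kkt_tol = 1e-6))
      orc <- oracle_fit_dm(dm, lam)
      expect_lt(abs(ours$objective - orc$objective) /
                  max(1, abs(orc$objective)), 1e-6)
      expect_lt(max(abs(ours$beta - orc$beta)), 1e-3)
    }
  }
})

test_that("forced covariates are never shrunk to zero by the penalty", {
  set.seed(46)
  d <- simulate_matched(n_strata = 150, n_controls = 1,
                        beta = c(0.8, 0.5, 0), prevalence = 0.3)
  dm <- difference_matrix(matched_data(d, unpenalized = "x1"))
  lmax <- lambda_max(dm)
  f <- clogit_lasso_fit(dm, lmax)
  expect_equal(f$n_nonzero, 0L)          # penalized support empty at lambda_max
  expect_gt(abs(f$beta["x1"]), 0)        # forced coefficient free
  # forced coefficient equals the unpenalized-only MLE at lambda_max
  expect_lt(kkt_residual(dm, unname(f$beta), lmax), 1e-4)
})

test_that("objective sequence is non-increasing across outer iterations", {
  # run fits while recording the objective trace through verbose logging is
  # indirect; instead re-run the outer loop manually and assert descent
  set.seed(47)
  for (rep in 1:5) {
    dm <- random_instance(N = 25, M = sample(1:4, 1), p = 4, prev = 0.35)
    if (max(colSums(abs(dm$X))) == 0) next
    lam <- 0.1 * lambda_max(dm)
    beta <- numeric(4)
    f_prev <- cl_objective(dm, beta, lam)
    for (k in 1:25) {
      wz <- cl_weights(dm, beta)
      A <- crossprod(dm$X, dm$X * wz$w)
      b <- as.numeric(crossprod(dm$X, wz$w * wz$eta + wz$r))
      gam <- weighted_lasso_cd(A, b, lam * (dm$penalty_mask == 1L),
                               beta_init = beta)
      delta <- as.numeric(gam) - beta
      if (max(abs(delta)) == 0) break
      ls <- line_search(dm, beta, delta, lam)
      if (ls$stalled) break
      beta <- ls$beta_new
      expect_lte(ls$f_new, f_prev + 1e-12)
      f_prev <- ls$f_new
    }
  }
})

test_that("KKT residual is zero at lambda_max and lambda_max - lambda below it", {
  set.seed(48)
  dm <- random_instance(N = 20, M = 2, p = 3, prev = 0.4)
  lmax <- lambda_max(dm)
  expect_equal(kkt_residual(dm, numeric(3), lmax), 0)
  expect_equal(kkt_residual(dm, numeric(3), lmax / 2), lmax - lmax / 2)
  # at a converged optimum the residual is tiny
  f <- clogit_lasso_fit(dm, 0.2 * lmax,
                        control = solver_control(kkt_tol = 1e-6))
  expect_lt(kkt_residual(dm, unname(f$beta), 0.2 * lmax), 1e-6)
})

test_that("negating a column negates its coefficient only", {
  set.seed(49)
  dm <- random_instance(N = 40, M = 2, p = 3, prev = 0.35)
  lam <- 0.15 * lambda_max(dm)
  ctrl <- solver_control(kkt_tol = 1e-10, max_outer = 500)
  f1 <- clogit_lasso_fit(dm, lam, control = ctrl)
  dm2 <- dm
  dm2$X[, 2] <- -dm2$X[, 2]
  f2 <- clogit_lasso_fit(dm2, lam, control = ctrl)
  expect_equal(unname(f2$beta[2]), -unname(f1$beta[2]), tolerance = 1e-10)
  expect_equal(unname(f2$beta[c(1, 3)]), unname(f1$beta[c(1, 3)]),
               tolerance = 1e-10)
})

test_that("1:1 Gram matrix equals the exact logistic Hessian", {
  set.seed(50)
  dm <- random_instance(N = 15, M = 1, p = 3, gaussian = TRUE)
  beta <- rnorm(3)
  wz <- cl_weights(dm, beta)
  A <- crossprod(dm$X, dm$X * wz$w)
  h <- 1e-4
  H_fd <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    H_fd[, j] <- (unname(cl_gradient(dm, beta + e)) -
                    unname(cl_gradient(dm, beta - e))) / (2 * h)
  }
  expect_equal(unname(as.matrix(A)), H_fd, tolerance = 1e-6)
})

test_that("1:1 fit equals an independently coded L1 logistic fit on differences", {
  set.seed(51)
  dm <- random_instance(N = 40, M = 1, p = 4, prev = 0.35)
  lmax <- lambda_max(dm)
  lam <- 0.1 * lmax
  ours <- clogit_lasso_fit(dm, lam, control = solver_control(kkt_tol = 1e-8))

  # independent: proximal gradient on log(1 + exp(-x beta)) with response 1
  X <- as.matrix(dm$X)
  nll <- function(b) sum(log1p(exp(-pmin(as.numeric(X %*% b), 700))))
  grad <- function(b) {
    eta <- as.numeric(X %*% b)
    as.numeric(crossprod(X, -1 / (1 + exp(eta))))
  }
  beta <- numeric(4); L <- 1
  for (k in 1:20000) {
    g <- grad(beta)
    repeat {
      cand <- soft_threshold(beta - g / L, lam / L)
      dlt <- cand - beta
      if (nll(cand) <= nll(beta) + sum(g * dlt) + L / 2 * sum(dlt^2) + 1e-14) break
      L <- 2 * L
    }
    if (max(abs(cand - beta)) < 1e-12) { beta <- cand; break }
    beta <- cand
    L <- max(L / 1.5, 1e-4)
  }
  expect_lt(max(abs(ours$beta - beta)), 1e-6)
})
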