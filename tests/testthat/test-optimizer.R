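test_that("Theta coordinate descent: deadzone, scalar stationarity, reference agreement", {
  ## penalty above the gradient bound leaves Theta exactly zero
  s <- random_stats(3, 2, n = 40, seed = 31)
  g0 <- 2 * s$S_cross                       # gradient at Theta = 0
  lay <- scggm_layer(diag(2), matrix(0, 3, 2),
                     lambda_Theta = max(abs(g0)) * 1.01)
  up <- scggm_update_theta(lay, s)
  expect_identical(Matrix::nnzero(up$Theta), 0L)

  ## scalar stationarity: 2 S_xy + 2 Lambda^-1 S_xx Theta = 0 -> Theta = 1
  s1 <- list(S_in = matrix(1), S_cross = matrix(-1), S_out = matrix(2), n = 10)
  lay1 <- scggm_layer(matrix(1), matrix(0), lambda_Theta = 0)
  up1 <- scggm_update_theta(lay1, s1, sweeps = 100)
  expect_equal(as.numeric(up1$Theta), 1, tolerance = 1e-10)

  ## agreement with an independent proximal-gradient subproblem solver
  for (i in 1:3) {
    s <- random_stats(4, 3, n = 60, seed = 40 + i)
    L <- as.matrix(random_layer(0, 3, seed = 50 + i)$Lambda)
    lay <- scggm_layer(L, matrix(0, 4, 3), lambda_Theta = 0.1)
    up <- scggm_update_theta(lay, s, sweeps = 200)
    ref <- ref_theta_subproblem(s$S_in, s$S_cross, solve(L), 0.1)
    expect_equal(as.matrix(up$Theta), ref, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("constant input columns are skipped with a warning", {
  set.seed(32)
  X <- cbind(rnorm(30), 1)
  Y <- matrix(rnorm(60), 30, 2)
  expect_warning(fit_scggm(X, Y, 0.1, 0.05), "constant")
})

test_that("Newton direction vanishes at the unpenalized optimum and matches the scalar update", {
  ## at the MLE with lambda = 0 the direction must be ~0
  s <- random_stats(0, 4, n = 500, seed = 33)
  L_mle <- solve(s$S_out)
  lay <- scggm_layer(L_mle, matrix(0, 0, 4), lambda_Lambda = 0)
  D <- scggm_newton_direction(lay, s, sweeps = 5)
  expect_lt(max(abs(D)), 1e-6)

  ## one-coordinate update equals the closed-form soft-threshold solution
  s2 <- random_stats(2, 3, n = 50, seed = 34)
  lay2 <- random_layer(2, 3, seed = 35)
  lay2$lambda_Lambda <- 0.2
  g <- scggm_gradients(lay2, s2)
  M <- g$Sigma + 2 * g$Psi
  i <- 1; j <- 2
  h <- 2 * M[i, j] * g$Sigma[i, j] + M[j, j] * g$Sigma[i, i] +
    M[i, i] * g$Sigma[j, j]
  c0 <- as.matrix(lay2$Lambda)[i, j]
  ct <- c0 - 2 * g$grad_Lambda[i, j] / h
  thr <- 2 * 0.2 / h
  mu_hand <- (if (ct > thr) ct - thr else if (ct < -thr) ct + thr else 0) - c0
  D1 <- scggm_newton_direction(lay2, s2, active = cbind(i, j), sweeps = 1)
  expect_equal(D1[i, j], mu_hand, tolerance = 1e-12)
  expect_equal(D1[j, i], mu_hand, tolerance = 1e-12)

  ## Hessian action: finite difference of the gradient equals sym(M Delta Sigma)
  set.seed(36)
  Delta <- matrix(rnorm(9, sd = 0.05), 3, 3); Delta <- (Delta + t(Delta)) / 2
  h_fd <- 1e-5
  gp <- scggm_gradients(
    scggm_layer(as.matrix(lay2$Lambda) + h_fd * Delta,
                as.matrix(lay2$Theta)), s2)$grad_Lambda
  gm <- scggm_gradients(
    scggm_layer(as.matrix(lay2$Lambda) - h_fd * Delta,
                as.matrix(lay2$Theta)), s2)$grad_Lambda
  fd <- (gp - gm) / (2 * h_fd)
  pred <- M %*% Delta %*% g$Sigma
  pred <- (pred + t(pred)) / 2
  expect_equal(fd, pred, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("line search preserves positive definiteness and decreases the objective", {
  s <- random_stats(2, 3, n = 80, seed = 37)
  lay <- random_layer(2, 3, seed = 38)
  lay$lambda_Lambda <- 0.05
  ## zero direction: no-op
  ls0 <- scggm_line_search(lay, s, matrix(0, 3, 3))
  expect_equal(as.matrix(ls0$layer$Lambda), as.matrix(lay$Lambda))
  ## real direction: penalized objective strictly decreases
  D <- scggm_newton_direction(lay, s, sweeps = 3)
  expect_gt(max(abs(D)), 0)
  ls <- scggm_line_search(lay, s, D)
  expect_true(ls$alpha > 0)
  f0 <- penalized_objective(lay, s)
  f1 <- penalized_objective(ls$layer, s)
  expect_lt(f1, f0)
  expect_true(perturbnet:::is_pd(ls$layer$Lambda))
})

test_that("active sets follow the gradient/nonzero rule exactly", {
  s <- random_stats(3, 4, n = 40, seed = 39)
  lay <- random_layer(3, 4, seed = 40)
  lay$lambda_Lambda <- 0.15; lay$lambda_Theta <- 0.15
  act <- scggm_active_sets(lay, s)
  g <- scggm_gradients(lay, s)
  L <- as.matrix(lay$Lambda); Th <- as.matrix(lay$Theta)
  ## brute-force rule over all pairs
  expect_brute <- matrix(FALSE, 4, 4)
  for (i in 1:4) for (j in i:4) {
    expect_brute[i, j] <- i == j || abs(g$grad_Lambda[i, j]) > 0.15 ||
      L[i, j] != 0
  }
  got <- matrix(FALSE, 4, 4)
  got[act$set_Lambda] <- TRUE
  expect_identical(got, expect_brute)
  bruteT <- abs(g$grad_Theta) > 0.15 | Th != 0
  gotT <- matrix(FALSE, 3, 4); gotT[act$set_Theta] <- TRUE
  expect_identical(gotT, unname(bruteT))
  ## every nonzero parameter is active
  nzT <- which(Th != 0, arr.ind = TRUE)
  expect_true(all(gotT[nzT]))

  ## all-zero parameters with a huge penalty: only the diagonal remains
  lay0 <- scggm_layer(diag(4), matrix(0, 3, 4),
                      lambda_Lambda = 1e6, lambda_Theta = 1e6)
  act0 <- scggm_active_sets(lay0, s)
  expect_equal(act0$set_Lambda, cbind(1:4, 1:4), ignore_attr = TRUE)
  expect_identical(act0$m_Theta, 0L)
})

test_that("fit_scggm attains its closed-form limits", {
  set.seed(41)
  s <- random_stats(4, 3, n = 200, seed = 42)
  ## infinite penalties: Theta = 0, Lambda = diag(1/diag(S_yy))
  f_inf <- fit_scggm(s, lambda_Lambda = 1e6, lambda_Theta = 1e6)
  expect_identical(Matrix::nnzero(f_inf$Theta), 0L)
  expect_equal(as.matrix(f_inf$Lambda), diag(1 / diag(s$S_out)),
               tolerance = 1e-6, ignore_attr = TRUE)
  ## zero penalties, n >> p + q: conditional-Gaussian MLE
  f0 <- fit_scggm(s, lambda_Lambda = 0, lambda_Theta = 0,
                  control = scggm_control(tol = 1e-10, max_iter = 500))
  L_mle <- solve(s$S_out - t(s$S_cross) %*% solve(s$S_in, s$S_cross))
  T_mle <- -solve(s$S_in, s$S_cross) %*% L_mle
  expect_equal(as.matrix(f0$Lambda), L_mle, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(as.matrix(f0$Theta), T_mle, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("fit_scggm matches the reference solver and satisfies its invariants", {
  for (i in 1:4) {
    s <- random_stats(8, 5, n = 60, seed = 60 + i)
    fit <- fit_scggm(s, lambda_Lambda = 0.1, lambda_Theta = 0.1,
                     control = scggm_control(tol = 1e-9, max_iter = 300))
    ## monotone trajectory and PD iterates
    expect_true(all(diff(fit$fit_info$objective) <= 1e-10))
    expect_true(perturbnet:::is_pd(fit$Lambda))
    ## KKT residual at convergence
    expect_lt(kkt_residual(fit, s), 1e-3)
    ## reference objective agreement
    ref <- ref_scggm_solve(s$S_in, s$S_cross, s$S_out, 0.1, 0.1)
    o_fit <- ref_objective(as.matrix(fit$Lambda), as.matrix(fit$Theta),
                           s$S_in, s$S_cross, s$S_out, 0.1, 0.1)
    expect_lt(abs(o_fit - ref$objective) / abs(ref$objective), 1e-6)
  }
})

test_that("the solution is invariant under sample permutation", {
  set.seed(43)
  X <- matrix(rnorm(200), 50, 4); Y <- matrix(rnorm(150), 50, 3)
  f1 <- fit_scggm(X, Y, 0.1, 0.1)
  perm <- sample(50)
  f2 <- fit_scggm(X[perm, ], Y[perm, ], 0.1, 0.1)
  expect_equal(as.matrix(f1$Lambda), as.matrix(f2$Lambda), tolerance = 1e-6)
  expect_equal(as.matrix(f1$Theta), as.matrix(f2$Theta), tolerance = 1e-6)
})

test_that("with no inputs fit_scggm solves the graphical-lasso problem", {
  set.seed(44)
  Y <- matrix(rnorm(300), 60, 5)
  Y[, 2] <- Y[, 1] + rnorm(60, sd = 0.4)
  fit <- fit_scggm(NULL, Y, lambda_Lambda = 0.1,
                   control = scggm_control(tol = 1e-9, max_iter = 600))
  Yc <- scale(Y, scale = FALSE)
  Syy <- crossprod(Yc) / 60
  ref <- ref_scggm_solve(matrix(0, 0, 0), matrix(0, 0, 5), Syy, 0.1, 0)
  o_fit <- ref_objective(as.matrix(fit$Lambda), matrix(0, 0, 5),
                         matrix(0, 0, 0), matrix(0, 0, 5), Syy, 0.1, 0)
  expect_lt(abs(o_fit - ref$objective) / abs(ref$objective), 1e-6)
  expect_identical(nrow(fit$Theta), 0L)
})
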