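# Independent reference implementations used as oracles.  Everything here
# is written against the mathematical definitions only (base R), on an
# algorithm family (proximal gradient) unrelated to the package's Newton
# coordinate-descent path.

# penalized objective: -log|L| + tr(Syy L + 2 Sxy' T + L^-1 T' Sxx T)
#                      + lamL * sum|offdiag L| + lamT * sum|T|
ref_objective <- function(L, Th, Sxx, Sxy, Syy, lamL, lamT) {
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(Inf)
  iL <- solve(L)
  val <- -sum(log(ev)) + sum(Syy * L)
  if (length(Th)) {
    val <- val + 2 * sum(Sxy * Th) + sum(iL * (t(Th) %*% Sxx %*% Th))
  }
  val + lamL * (sum(abs(L)) - sum(abs(diag(L)))) + lamT * sum(abs(Th))
}

ref_gradients <- function(L, Th, Sxx, Sxy, Syy) {
  iL <- solve(L)
  if (length(Th)) {
    P <- t(Th) %*% Sxx %*% Th
    Psi <- iL %*% P %*% iL
    gT <- 2 * Sxy + 2 * Sxx %*% Th %*% iL
  } else {
    Psi <- matrix(0, nrow(L), ncol(L))
    gT <- Th
  }
  list(gL = Syy - iL - Psi, gT = gT)
}

soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

prox_L <- function(L, t, lamL) {
  out <- soft(L, t * lamL)
  diag(out) <- diag(L)              # diagonal unpenalized
  (out + t(out)) / 2
}

# FISTA with backtracking and a positive-definiteness safeguard; restarts
# on non-monotone steps.  Accurate to ~1e-9 relative on the tiny instances
# used in tests.
ref_scggm_solve <- function(Sxx, Sxy, Syy, lamL, lamT,
                            max_iter = 30000L, tol = 1e-12) {
  q <- ncol(Syy); p <- nrow(Sxx)
  L <- diag(1 / pmax(diag(Syy), 1e-8), q)
  Th <- matrix(0, p, q)
  Ly <- L; Thy <- Th
  tk <- 1; step <- 1
  f_old <- ref_objective(L, Th, Sxx, Sxy, Syy, lamL, lamT)
  for (it in seq_len(max_iter)) {
    g <- ref_gradients(Ly, Thy, Sxx, Sxy, Syy)
    gval <- ref_objective(Ly, Thy, Sxx, Sxy, Syy, 0, 0)
    repeat {
      Ln <- prox_L(Ly - step * g$gL, step, lamL)
      Tn <- if (p > 0) soft(Thy - step * g$gT, step * lamT) else Thy
      ev <- eigen(Ln, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) > 0) {
        gn <- ref_objective(Ln, Tn, Sxx, Sxy, Syy, 0, 0)
        quad <- gval + sum(g$gL * (Ln - Ly)) + sum(g$gT * (Tn - Thy)) +
          (sum((Ln - Ly)^2) + sum((Tn - Thy)^2)) / (2 * step)
        if (gn <= quad + 1e-12) break
      }
      step <- step / 2
      if (step < 1e-14) break
    }
    f_new <- ref_objective(Ln, Tn, Sxx, Sxy, Syy, lamL, lamT)
    if (f_new > f_old) {            # restart acceleration
      Ly <- L; Thy <- Th; tk <- 1
      next
    }
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Ly <- Ln + ((tk - 1) / t_next) * (Ln - L)
    Thy <- Tn + ((tk - 1) / t_next) * (Tn - Th)
    tk <- t_next
    done <- abs(f_old - f_new) < tol * max(1, abs(f_old))
    L <- Ln; Th <- Tn; f_old <- f_new
    step <- step * 2
    if (done) break
  }
  list(Lambda = L, Theta = Th, objective = f_old, iterations = it)
}

# reference Lasso (for the Theta subproblem given fixed Lambda):
# argmin tr(2 Sxy' T + iL T' Sxx T) + lamT |T|_1  by proximal gradient
ref_theta_subproblem <- function(Sxx, Sxy, Sigma, lamT,
                                 max_iter = 20000L, tol = 1e-14) {
  p <- nrow(Sxx); q <- ncol(Sxy)
  Th <- matrix(0, p, q)
  Lip <- 2 * max(eigen(Sxx, symmetric = TRUE, only.values = TRUE)$values) *
    max(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / max(Lip, 1e-12)
  obj <- function(T_) 2 * sum(Sxy * T_) + sum(Sigma * (t(T_) %*% Sxx %*% T_)) +
    lamT * sum(abs(T_))
  f_old <- obj(Th)
  for (it in seq_len(max_iter)) {
    g <- 2 * Sxy + 2 * Sxx %*% Th %*% Sigma
    Th_new <- soft(Th - step * g, step * lamT)
    f_new <- obj(Th_new)
    if (abs(f_old - f_new) < tol * max(1, abs(f_old))) { Th <- Th_new; break }
    Th <- Th_new; f_old <- f_new
  }
  Th
}

# random small stats slice with PD blocks
random_stats <- function(p, q, n = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  Y <- matrix(rnorm(n * q), n, q)
  if (p > 0) {
    B <- matrix(rnorm(p * q, sd = 0.5) * (runif(p * q) < 0.3), p, q)
    Y <- Y + X %*% B
  }
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  list(S_in = crossprod(Xc) / n, S_cross = crossprod(Xc, Yc) / n,
       S_out = crossprod(Yc) / n, n = n)
}

# random PD layer for identity-style tests
random_layer <- function(p, q, seed = NULL, density = 0.4) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(q * q, sd = 0.3) * (runif(q * q) < density), q, q)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  L <- A + diag(q) * (abs(min(eigen(A, symmetric = TRUE,
                                    only.values = TRUE)$values)) + 0.5)
  Th <- matrix(rnorm(p * q) * (runif(p * q) < density), p, q)
  scggm_layer(L, Th, lambda_Lambda = 0.1, lambda_Theta = 0.1)
}
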