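#' Solver options for the alternating Newton coordinate-descent sCGGM fit
#'
#' @param tol relative change of the penalized objective below which the
#'   outer loop stops.
#' @param max_iter maximum number of outer iterations.
#' @param sweeps coordinate-descent passes over the active set per outer
#'   iteration (a single pass, with warm starts, already guarantees descent).
#' @param beta backtracking factor of the line search.
#' @param sigma Armijo sufficient-decrease constant.
#' @param alpha_min below this step size the line search reports stagnation.
#' @param shuffle visit coordinates in a seeded random order instead of the
#'   default fixed lexicographic order.
#' @param seed seed for `shuffle` (ignored otherwise).
#' @param lambda_clip lower clip for the diagonal initialization
#'   `Lambda = diag(1/diag(S_out))`.
#' @param verbose print per-iteration objective lines.
#' @return A list of options for [fit_scggm()].
#' @export
scggm_control <- function(tol = 1e-6, max_iter = 100L, sweeps = 1L,
                          beta = 0.5, sigma = 1e-4, alpha_min = 1e-10,
                          shuffle = FALSE, seed = NULL,
                          lambda_clip = 1e-3, verbose = FALSE) {
  list(tol = tol, max_iter = as.integer(max_iter), sweeps = as.integer(sweeps),
       beta = beta, sigma = sigma, alpha_min = alpha_min,
       shuffle = shuffle, seed = seed, lambda_clip = lambda_clip,
       verbose = verbose)
}

#' Fit one sparse conditional Gaussian graphical model layer
#'
#' Minimizes the penalized objective ([penalized_objective()]) over
#' `(Lambda, Theta)` by alternating Newton coordinate descent: with `Lambda`
#' fixed, the `Theta` subproblem is a Lasso solved by coordinate descent over
#' an active set; with `Theta` fixed, a generalized Newton direction for
#' `Lambda` is found by coordinate descent on the L1-regularized second-order
#' model and applied with an Armijo backtracking line search that preserves
#' positive definiteness.  Active sets, cached matrix products and warm
#' starts across iterations follow the Fast-sCGGM strategy.
#'
#' @param x either a stats slice (list with `S_in`, `S_cross`, `S_out`, `n`;
#'   see [suffstats_slice()]) or an input data matrix (n x p).  Pass `NULL`
#'   (with `y`) for a pure Gaussian graphical model with no inputs.
#' @param y output data matrix (n x q); ignored when `x` is a stats slice.
#' @param lambda_Lambda,lambda_Theta nonnegative penalty weights.
#' @param control solver options from [scggm_control()].
#' @param Lambda0,Theta0 optional warm starts (defaults: diagonal
#'   `1/diag(S_out)` clipped below, and zero).
#' @return An [scggm_layer()] whose `fit_info` records the objective
#'   trajectory, iteration count, convergence flag, and final KKT residual.
#' @examples
#' set.seed(1)
#' Y <- matrix(rnorm(200), 50, 4)
#' fit <- fit_scggm(NULL, Y, lambda_Lambda = 0.2)
#' @export
fit_scggm <- function(x, y = NULL, lambda_Lambda = 0.1, lambda_Theta = 0.1,
                      control = scggm_control(),
                      Lambda0 = NULL, Theta0 = NULL) {
  s <- if (is.list(x) && !is.null(x$S_out)) x else stats_from_xy(x, y)
  fit_scggm_stats(s, lambda_Lambda, lambda_Theta, control, Lambda0, Theta0)
}

fit_scggm_stats <- function(s, lambda_Lambda, lambda_Theta,
                            control = scggm_control(),
                            Lambda0 = NULL, Theta0 = NULL,
                            input_ids = NULL, output_ids = NULL) {
  stopifnot(lambda_Lambda >= 0, lambda_Theta >= 0)
  S_out <- dense(s$S_out); S_in <- dense(s$S_in); S_cross <- dense(s$S_cross)
  q <- ncol(S_out); p <- nrow(S_in)
  Lambda <- if (is.null(Lambda0)) {
    diag(pmax(1 / pmax(diag(S_out), .Machine$double.eps),
              control$lambda_clip), q)
  } else dense(Lambda0)
  Theta <- if (is.null(Theta0)) matrix(0, p, q) else dense(Theta0)
  stopifnot(nrow(Theta) == p, ncol(Theta) == q, ncol(S_cross) == q)

  zero_diag <- p > 0L && any(diag(S_in) == 0)
  if (zero_diag) {
    warning("some input columns are constant (zero variance); ",
            "their Theta coordinates are skipped")
  }
  R <- chol(Lambda)
  Sigma <- chol2inv(R)
  obj <- obj_from_parts(R, Lambda, Theta, Sigma, S_out, S_in, S_cross,
                        lambda_Lambda, lambda_Theta)
  traj <- obj
  converged <- FALSE
  stagnated <- FALSE
  alphas <- numeric(0)
  iter <- 0L

  for (iter in seq_len(control$max_iter)) {
    ## ---- Theta step (Lasso given Lambda) ----
    if (p > 0L) {
      W <- S_in %*% Theta
      gT <- 2 * S_cross + 2 * W %*% Sigma
      actT <- active_indices(gT, Theta, lambda_Theta, pairs = FALSE,
                             control = control)
      if (nrow(actT) > 0L) {
        res <- cd_theta_cpp(Theta, W, S_in, S_cross, Sigma, lambda_Theta,
                            actT, control$sweeps)
        Theta <- res$Theta
        W <- res$W
      }
    } else {
      W <- matrix(0, 0, q)
    }

    ## ---- Lambda step (Newton direction + line search) ----
    P <- if (p > 0L) crossprod(Theta, W) else matrix(0, q, q)
    P <- (P + t(P)) / 2
    Psi <- Sigma %*% P %*% Sigma
    Psi <- (Psi + t(Psi)) / 2
    G <- S_out - Sigma - Psi
    M <- Sigma + 2 * Psi
    actL <- active_indices(G, Lambda, lambda_Lambda, pairs = TRUE,
                           control = control)
    res <- cd_lambda_cpp(matrix(0, q, q), matrix(0, q, q), G, Sigma, M,
                         Lambda, lambda_Lambda, actL, control$sweeps)
    D <- res$Delta
    D <- (D + t(D)) / 2

    ls <- lambda_line_search(Lambda, D, G, P, S_out, lambda_Lambda,
                             beta = control$beta, sigma = control$sigma,
                             alpha_min = control$alpha_min)
    if (ls$stagnated) {
      if (max(abs(D)) > 1e-8) stagnated <- TRUE
      Lambda_new <- Lambda
    } else {
      Lambda_new <- ls$Lambda
      alphas <- c(alphas, ls$alpha)
    }
    Lambda <- Lambda_new
    R <- chol(Lambda)
    Sigma <- chol2inv(R)
    obj_new <- obj_from_parts(R, Lambda, Theta, Sigma, S_out, S_in, S_cross,
                              lambda_Lambda, lambda_Theta)
    traj <- c(traj, obj_new)
    if (control$verbose) {
      message(sprintf("iter %3d  obj %.10g", iter, obj_new))
    }
    rel <- abs(obj - obj_new) / max(abs(obj), 1e-12)
    obj <- obj_new
    if (rel < control$tol) { converged <- TRUE; break }
    if (stagnated) break
  }

  layer <- scggm_layer(
    Lambda = Matrix::drop0(Matrix::forceSymmetric(Matrix::Matrix(Lambda,
                                                                 sparse = TRUE))),
    Theta = Matrix::drop0(Matrix::Matrix(Theta, sparse = TRUE)),
    lambda_Lambda = lambda_Lambda, lambda_Theta = lambda_Theta,
    input_ids = input_ids, output_ids = output_ids,
    fit_info = list(objective = traj, iterations = iter,
                    converged = converged, stagnated = stagnated,
                    step_sizes = alphas),
    check = FALSE
  )
  layer$fit_info$kkt <- kkt_residual(layer, s)
  if (!converged) {
    warning("fit_scggm did not converge in ", control$max_iter,
            " iterations (returning best iterate)")
  }
  layer
}

## objective given precomputed pieces; P = Theta' S_in Theta
obj_from_parts <- function(R, Lambda, Theta, Sigma, S_out, S_in, S_cross,
                           lamL, lamT) {
  -2 * sum(log(diag(R))) + sum(S_out * Lambda) +
    (if (nrow(Theta) > 0L)
      2 * sum(S_cross * Theta) + sum(Sigma * crossprod(Theta, S_in %*% Theta))
     else 0) +
    lamL * sum_abs_offdiag_dense(Lambda) + lamT * sum(abs(Theta))
}

sum_abs_offdiag_dense <- function(A) sum(abs(A)) - sum(abs(diag(A)))

## indices with |grad| > lam or parameter nonzero; pairs = upper triangle
## including all diagonals (Lambda), else all coordinates (Theta).
active_indices <- function(G, P, lam, pairs, control = NULL) {
  sel <- abs(G) > lam | P != 0
  if (pairs) {
    sel[lower.tri(sel)] <- FALSE
    diag(sel) <- TRUE
  }
  idx <- which(sel, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  if (!is.null(control) && isTRUE(control$shuffle)) {
    if (!is.null(control$seed)) set.seed(control$seed)
    idx <- idx[sample.int(nrow(idx)), , drop = FALSE]
  }
  storage.mode(idx) <- "integer"
  idx - 1L
}

## Armijo backtracking on the Lambda part of the objective.
lambda_line_search <- function(Lambda, D, G, P, S_out, lamL,
                               beta = 0.5, sigma = 1e-4, alpha_min = 1e-10) {
  if (max(abs(D)) == 0) {
    return(list(alpha = 0, Lambda = Lambda, stagnated = TRUE))
  }
  fL <- function(L, R) {
    -2 * sum(log(diag(R))) + sum(S_out * L) +
      sum(chol2inv(R) * P) + lamL * sum_abs_offdiag_dense(L)
  }
  R0 <- chol(Lambda)
  f0 <- fL(Lambda, R0)
  delta <- sum(G * D) +
    lamL * (sum_abs_offdiag_dense(Lambda + D) - sum_abs_offdiag_dense(Lambda))
  alpha <- 1
  while (alpha >= alpha_min) {
    Lnew <- Lambda + alpha * D
    R <- tryCatch(chol(Lnew), error = function(e) NULL)
    if (!is.null(R)) {
      if (fL(Lnew, R) <= f0 + sigma * alpha * delta) {
        return(list(alpha = alpha, Lambda = Lnew, stagnated = FALSE))
      }
    }
    alpha <- alpha * beta
  }
  list(alpha = 0, Lambda = Lambda, stagnated = TRUE)
}

## ---- exported single-step operations (solver surface) -----------------

#' Active sets for the coordinate-descent updates
#'
#' A coordinate is active if its smooth-gradient magnitude exceeds the
#' penalty or if the parameter entry is currently nonzero.  For `Lambda`
#' only one of (i, j)/(j, i) is kept and all diagonal entries are included.
#'
#' @inheritParams scggm_neg_loglik
#' @return List with 1-based index matrices `set_Lambda`, `set_Theta` and
#'   sizes `m_Lambda`, `m_Theta`.
#' @export
scggm_active_sets <- function(layer, stats, layer_name = c("xy", "yz")) {
  s <- resolve_slice(stats, layer_name)
  g <- scggm_gradients(layer, s)
  aL <- active_indices(g$grad_Lambda, dense(layer$Lambda),
                       layer$lambda_Lambda, pairs = TRUE) + 1L
  aT <- if (nrow(layer$Theta) > 0L) {
    active_indices(g$grad_Theta, dense(layer$Theta), layer$lambda_Theta,
                   pairs = FALSE) + 1L
  } else matrix(integer(), 0, 2)
  list(set_Lambda = aL, set_Theta = aT,
       m_Lambda = nrow(aL), m_Theta = nrow(aT))
}

#' One block of coordinate-descent passes for Theta given Lambda
#'
#' Solves (partially, `sweeps` passes) the Lasso subproblem for `Theta` with
#' `Lambda` fixed, over the given active set.
#'
#' @inheritParams scggm_neg_loglik
#' @param active optional 1-based index matrix of coordinates to update
#'   (default: the active set rule of [scggm_active_sets()]).
#' @param sweeps number of passes.
#' @return The layer with updated `Theta`.
#' @export
scggm_update_theta <- function(layer, stats, active = NULL, sweeps = 50L,
                               layer_name = c("xy", "yz")) {
  s <- resolve_slice(stats, layer_name)
  Lambda <- dense(layer$Lambda); Theta <- dense(layer$Theta)
  Sigma <- chol2inv(chol(Lambda))
  S_in <- dense(s$S_in); S_cross <- dense(s$S_cross)
  refresh <- is.null(active)   # re-derive the active set between passes
  if (!refresh) act <- matrix(as.integer(active), ncol = 2) - 1L
  W <- S_in %*% Theta
  skipped <- 0L
  for (pass in seq_len(if (refresh) sweeps else 1L)) {
    if (refresh) {
      gT <- 2 * S_cross + 2 * W %*% Sigma
      act <- active_indices(gT, Theta, layer$lambda_Theta, pairs = FALSE)
      if (nrow(act) == 0L) break
    }
    res <- cd_theta_cpp(Theta, W, S_in, S_cross, Sigma,
                        layer$lambda_Theta, act,
                        if (refresh) 1L else as.integer(sweeps))
    skipped <- skipped + res$skipped
    if (refresh && max(abs(res$Theta - Theta)) < 1e-12) {
      Theta <- res$Theta; W <- res$W
      break
    }
    Theta <- res$Theta; W <- res$W
  }
  if (skipped > 0) {
    warning(skipped,
            " Theta coordinates skipped (zero-variance input column)")
  }
  layer$Theta <- Matrix::drop0(Matrix::Matrix(Theta, sparse = TRUE,
                                              dimnames = dimnames(layer$Theta)))
  layer
}

#' Generalized Newton direction for Lambda
#'
#' Coordinate descent over the active set on the L1-regularized second-order
#' model of the smooth objective around the current `Lambda`, with the
#' `U = Delta Sigma` cache maintained after every coordinate update.
#'
#' @inheritParams scggm_update_theta
#' @return A symmetric matrix `D_Lambda`.
#' @export
scggm_newton_direction <- function(layer, stats, active = NULL, sweeps = 20L,
                                   layer_name = c("xy", "yz")) {
  s <- resolve_slice(stats, layer_name)
  g <- scggm_gradients(layer, s)
  q <- ncol(g$Sigma)
  if (is.null(active)) {
    active <- scggm_active_sets(layer, s)$set_Lambda
  }
  act <- matrix(as.integer(active), ncol = 2) - 1L
  M <- g$Sigma + 2 * g$Psi
  res <- cd_lambda_cpp(matrix(0, q, q), matrix(0, q, q), g$grad_Lambda,
                       g$Sigma, M, dense(layer$Lambda), layer$lambda_Lambda,
                       act, as.integer(sweeps))
  (res$Delta + t(res$Delta)) / 2
}

#' Line search along a Lambda direction
#'
#' Backtracks alpha over \{1, beta, beta^2, ...\} until `Lambda + alpha D` is
#' positive definite and satisfies the Armijo sufficient-decrease condition
#' on the penalized objective, then applies the step.
#'
#' @inheritParams scggm_update_theta
#' @param D_Lambda symmetric direction matrix.
#' @param beta,sigma,alpha_min line-search constants (see [scggm_control()]).
#' @return List with `alpha` and the updated `layer`.  Stagnation (no
#'   acceptable step above `alpha_min` for a nonzero direction) is an error.
#' @export
scggm_line_search <- function(layer, stats, D_Lambda, beta = 0.5,
                              sigma = 1e-4, alpha_min = 1e-10,
                              layer_name = c("xy", "yz")) {
  s <- resolve_slice(stats, layer_name)
  g <- scggm_gradients(layer, s)
  Theta <- dense(layer$Theta)
  P <- if (nrow(Theta) > 0L) crossprod(Theta, dense(s$S_in) %*% Theta)
       else matrix(0, ncol(g$Sigma), ncol(g$Sigma))
  ls <- lambda_line_search(dense(layer$Lambda), D_Lambda, g$grad_Lambda, P,
                           dense(s$S_out), layer$lambda_Lambda,
                           beta = beta, sigma = sigma, alpha_min = alpha_min)
  if (ls$stagnated && max(abs(D_Lambda)) > 0) {
    stop("line search stagnated: no acceptable step above ",
         format(alpha_min), " (|D|_max = ", format(max(abs(D_Lambda))),
         "); the direction may not be a descent direction")
  }
  layer$Lambda <- as_symmetric_sparse(Matrix::drop0(
    Matrix::Matrix(ls$Lambda, sparse = TRUE,
                   dimnames = dimnames(layer$Lambda))))
  list(alpha = ls$alpha, layer = layer)
}
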