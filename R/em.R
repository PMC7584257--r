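#' Posterior moments of hidden expression given genotype and traits
#'
#' For samples without expression data the model implies a Gaussian
#' posterior over y with a shared covariance
#' \deqn{\Sigma_{y|x,z} = (\Lambda_y + \Theta_{yz} \Lambda_z^{-1}
#'   \Theta_{yz}^\top)^{-1}}
#' and per-sample mean
#' \eqn{\mu_{y|x,z} = -\Sigma_{y|x,z} (\Theta_{yz} z + \Theta_{xy}^\top x)}.
#' The posterior precision is the gene-network block of the joint
#' representation (see [inf3_posterior_network()]).
#'
#' @param model a [chain_model()].
#' @param X,Z matrices of (centered) genotype and trait rows for the samples
#'   of interest; either may be `NULL` for zero contribution.
#' @return List with `mu` (rows aligned with `X`/`Z`) and `Sigma` (q x q).
#' @export
posterior_moments <- function(model, X = NULL, Z = NULL) {
  Omega <- posterior_precision(model)
  Sigma <- solve(Omega)
  Sigma <- (Sigma + t(Sigma)) / 2
  eta <- posterior_nat_param(model, X, Z)
  mu <- if (is.null(eta)) NULL else -eta %*% Sigma
  list(mu = mu, Sigma = Sigma)
}

posterior_precision <- function(model) {
  Lam_y <- dense(model$layer_xy$Lambda)
  Theta_yz <- dense(model$layer_yz$Theta)
  Lam_z <- dense(model$layer_yz$Lambda)
  Omega <- Lam_y + Theta_yz %*% solve(Lam_z, t(Theta_yz))
  (Omega + t(Omega)) / 2
}

# rows of (z' Theta_yz' + x' Theta_xy); n x q
posterior_nat_param <- function(model, X, Z) {
  if (is.null(X) && is.null(Z)) return(NULL)
  n <- nrow(X %||% Z)
  eta <- matrix(0, n, ncol(model$layer_xy$Lambda))
  if (!is.null(Z)) eta <- eta + Z %*% t(dense(model$layer_yz$Theta))
  if (!is.null(X)) eta <- eta + X %*% dense(model$layer_xy$Theta)
  eta
}

#' Matrix-free posterior-covariance columns by conjugate gradient
#'
#' Solves \eqn{(\Lambda_y + K K^\top) v = e_j} for requested columns j of
#' the posterior covariance \eqn{\Sigma_{y|x,z}}, without forming the dense
#' q x q posterior precision: `Lambda_y` stays sparse and the trait coupling
#' enters through the low-rank factor \eqn{K = \Theta_{yz} L_z^{-\top}}
#' (with \eqn{L_z L_z^\top = \Lambda_z}), so that
#' \eqn{K K^\top = \Theta_{yz} \Lambda_z^{-1} \Theta_{yz}^\top}.
#'
#' @param model a [chain_model()] (uses `layer_xy$Lambda`, `layer_yz`).
#' @param cols integer vector of column indices.
#' @param tol residual norm at which CG stops.
#' @param max_iter maximum CG iterations per column (default `10 * q`).
#' @return A q x length(cols) matrix of covariance columns.
#' @export
implicit_posterior_solve <- function(model, cols, tol = 1e-8,
                                     max_iter = NULL) {
  Lam_y <- methods::as(model$layer_xy$Lambda, "dsCMatrix")
  q <- ncol(Lam_y)
  max_iter <- max_iter %||% (10L * q)
  Rz <- chol(dense(model$layer_yz$Lambda))
  Th <- dense(model$layer_yz$Theta)
  K <- if (nrow(Th) > 0L && ncol(Th) > 0L) {
    t(forwardsolve(t(Rz), t(Th)))
  } else matrix(0, q, 0)
  Amul <- function(v) {
    as.numeric(Lam_y %*% v) + if (ncol(K) > 0L) K %*% crossprod(K, v) else 0
  }
  out <- matrix(0, q, length(cols))
  for (ci in seq_along(cols)) {
    e <- numeric(q); e[cols[ci]] <- 1
    out[, ci] <- cg_solve(Amul, e, tol = tol, max_iter = max_iter)
  }
  out
}

cg_solve <- function(Amul, b, tol = 1e-8, max_iter = 1000L) {
  x <- numeric(length(b))
  r <- b
  p <- r
  rs <- sum(r * r)
  for (it in seq_len(max_iter)) {
    if (sqrt(rs) < tol) return(x)
    Ap <- as.numeric(Amul(p))
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  if (sqrt(rs) >= tol) {
    stop("conjugate gradient did not converge in ", max_iter,
         " iterations (residual ", format(sqrt(rs)), ")")
  }
  x
}

#' Semi-supervised chain-model estimation by EM
#'
#' Handles data bundles where expression rows exist only for a subset of
#' samples.  The E-step imputes hidden expression with the posterior
#' moments of [posterior_moments()]; hidden samples contribute
#' `E[y] = mu` and `E[y y'] = Sigma + mu mu'` to the expected sufficient
#' statistics.  The M-step refits both layers on the expected statistics
#' with [fit_scggm()], warm-started from the previous iterate (so every
#' M-step is a descent step and the penalized observed-data negative
#' log-likelihood is non-increasing).  Column means are computed once
#' (over observed rows for Y, all rows for X and Z) and held fixed across
#' EM iterations.
#'
#' @param data a [data_bundle()]; samples absent from `y_rows` are treated
#'   as hidden.  With no hidden samples this reduces exactly to
#'   [fit_chain()].
#' @inheritParams fit_chain
#' @param em_tol relative change of the observed-data penalized objective
#'   below which EM stops.
#' @param max_em_iter maximum EM iterations.
#' @return A [chain_model()] whose `fit_info` carries the EM trajectory
#'   (`em_objective`, observed-data penalized negative log-likelihood per
#'   iteration) and the number of hidden samples.
#' @export
em_fit <- function(data,
                   lambda_Lambda_y = 0.1, lambda_Theta_xy = 0.1,
                   lambda_Lambda_z = 0.1, lambda_Theta_yz = 0.1,
                   control = scggm_control(), em_tol = 1e-5,
                   max_em_iter = 30L) {
  n <- nrow(data$X)
  obs <- data$y_rows
  hid <- setdiff(seq_len(n), obs)
  if (length(obs) == 0L) stop("at least one fully observed sample is needed")
  if (length(hid) == 0L) {
    return(fit_chain(data, lambda_Lambda_y, lambda_Theta_xy,
                     lambda_Lambda_z, lambda_Theta_yz, control))
  }
  ## fixed centering
  Xc <- center_cols(data$X)
  Zc <- center_cols(data$Z)
  Yc <- sweep(data$Y, 2L, colMeans(data$Y), "-")
  p <- ncol(Xc); q <- ncol(Yc); r <- ncol(Zc)

  ## initialize from the complete cases
  init_data <- data_bundle(data$X[obs, , drop = FALSE], data$Y,
                           data$Z[obs, , drop = FALSE])
  model <- fit_chain(init_data, lambda_Lambda_y, lambda_Theta_xy,
                     lambda_Lambda_z, lambda_Theta_yz, control)

  lam <- c(lambda_Lambda_y, lambda_Theta_xy, lambda_Lambda_z, lambda_Theta_yz)
  obj <- em_observed_objective(model, Xc, Yc, Zc, obs, hid, lam)
  traj <- obj
  q_traj <- numeric(0)
  converged <- FALSE
  Yhat <- matrix(0, n, q,
                 dimnames = list(NULL, data$gene_ids))
  Yhat[obs, ] <- Yc

  for (it in seq_len(max_em_iter)) {
    ## E-step
    post <- posterior_moments(model, X = Xc[hid, , drop = FALSE],
                              Z = Zc[hid, , drop = FALSE])
    Yhat[hid, ] <- post$mu
    stats <- structure(list(
      S_xx = crossprod(Xc) / n,
      S_xy = crossprod(Xc, Yhat) / n,
      S_yy = (crossprod(Yhat) + length(hid) * post$Sigma) / n,
      S_yz = crossprod(Yhat, Zc) / n,
      S_zz = crossprod(Zc) / n,
      n = n, n_y = n,
      snp_ids = data$snp_ids, gene_ids = data$gene_ids,
      trait_ids = data$trait_ids), class = "scggm_suffstats")
    ## M-step (warm-started => descent on the expected objective)
    model <- fit_chain_stats(stats, lambda_Lambda_y, lambda_Theta_xy,
                             lambda_Lambda_z, lambda_Theta_yz, control,
                             warm = model)
    q_traj <- c(q_traj, chain_objective(model, stats))
    obj_new <- em_observed_objective(model, Xc, Yc, Zc, obs, hid, lam)
    traj <- c(traj, obj_new)
    rel <- abs(obj - obj_new) / max(abs(obj), 1e-12)
    obj <- obj_new
    if (rel < em_tol) { converged <- TRUE; break }
  }
  model$fit_info <- c(model$fit_info %||% list(), list(
    em_objective = traj, em_expected_objective = q_traj,
    em_iterations = length(q_traj), em_converged = converged,
    n_hidden = length(hid)))
  model
}

## observed-data penalized negative log-likelihood, scaled by 2/n and with
## 2*pi constants dropped: for observed rows -2 log p(y|x) p(z|y), for
## hidden rows -2 log p(z|x) (Gaussian with the INF-I marginal covariance).
em_observed_objective <- function(model, Xc, Yc, Zc, obs, hid, lam) {
  n <- nrow(Xc)
  Lam_y <- dense(model$layer_xy$Lambda); Th_xy <- dense(model$layer_xy$Theta)
  Lam_z <- dense(model$layer_yz$Lambda); Th_yz <- dense(model$layer_yz$Theta)
  Ry <- chol(Lam_y); Rz <- chol(Lam_z)
  B_xy <- -t(solve(Lam_y, t(Th_xy)))
  B_yz <- -t(solve(Lam_z, t(Th_yz)))
  val <- 0
  ## observed rows
  Ey <- Yc - Xc[obs, , drop = FALSE] %*% B_xy
  val <- val - length(obs) * 2 * sum(log(diag(Ry))) + sum((Ey %*% t(Ry)) ^ 2)
  Ez <- Zc[obs, , drop = FALSE] - Yc %*% B_yz
  val <- val - length(obs) * 2 * sum(log(diag(Rz))) + sum((Ez %*% t(Rz)) ^ 2)
  ## hidden rows: z | x ~ N(B_xz' x, C)
  if (length(hid)) {
    iLz <- chol2inv(Rz)
    Cm <- iLz + iLz %*% t(Th_yz) %*% solve(Lam_y, Th_yz) %*% iLz
    Cm <- (Cm + t(Cm)) / 2
    Rc <- chol(Cm)
    B_xz <- B_xy %*% B_yz
    Ezh <- Zc[hid, , drop = FALSE] - Xc[hid, , drop = FALSE] %*% B_xz
    val <- val + length(hid) * 2 * sum(log(diag(Rc))) +
      sum(forwardsolve(t(Rc), t(Ezh)) ^ 2)
  }
  pen <- lam[1] * sum_abs_offdiag_dense(Lam_y) + lam[2] * sum(abs(Th_xy)) +
    lam[3] * sum_abs_offdiag_dense(Lam_z) + lam[4] * sum(abs(Th_yz))
  val / n + pen
}
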