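#' Smooth negative log-likelihood of an sCGGM layer
#'
#' Evaluates
#' \deqn{g(\Lambda, \Theta) = -\log|\Lambda| + \mathrm{tr}(S_{yy}\Lambda
#'   + 2 S_{xy}^\top \Theta + \Lambda^{-1} \Theta^\top S_{xx} \Theta),}
#' the per-sample-scaled negative conditional log-likelihood (up to an
#' additive constant) of the outputs given the inputs.  Penalties are not
#' included.
#'
#' @param layer an [scggm_layer()].
#' @param stats a stats slice as returned by [suffstats_slice()] (elements
#'   `S_in`, `S_cross`, `S_out`), or a full [compute_suffstats()] object
#'   together with `layer_name`.
#' @param layer_name which slice to take when `stats` is a full suffstats
#'   object.
#' @return A scalar.
#' @export
scggm_neg_loglik <- function(layer, stats, layer_name = c("xy", "yz")) {
  s <- resolve_slice(stats, layer_name)
  Lambda <- dense(layer$Lambda)
  Theta <- dense(layer$Theta)
  R <- tryCatch(chol(Lambda),
                error = function(e) stop("Lambda is not positive definite: ",
                                         "log-determinant undefined"))
  logdet <- 2 * sum(log(diag(R)))
  val <- -logdet + sum(s$S_out * Lambda)
  if (nrow(Theta) > 0L) {
    val <- val + 2 * sum(s$S_cross * Theta) +
      sum(chol2inv(R) * crossprod(Theta, s$S_in %*% Theta))
  }
  val
}

#' Penalized sCGGM objective
#'
#' [scggm_neg_loglik()] plus the elementwise L1 penalties
#' \eqn{\lambda_\Lambda \sum_{i \ne j} |\Lambda_{ij}| + \lambda_\Theta
#' \sum_{ij} |\Theta_{ij}|}.  Diagonal entries of `Lambda` are not
#' penalized, following the usual convention for sparse inverse covariance
#' estimation.
#'
#' @inheritParams scggm_neg_loglik
#' @return A scalar.
#' @export
penalized_objective <- function(layer, stats, layer_name = c("xy", "yz")) {
  scggm_neg_loglik(layer, stats, layer_name) +
    layer$lambda_Lambda * sum_abs_offdiag(layer$Lambda) +
    layer$lambda_Theta * sum(abs(layer$Theta))
}

#' Penalized objective of the whole chain model
#'
#' The estimation problem decouples over the two layers; the chain objective
#' is the sum of the two penalized layer objectives, the x->y layer
#' evaluated on (S_xx, S_xy, S_yy) and the y->z layer on (S_yy, S_yz, S_zz).
#'
#' @param model a [chain_model()].
#' @param stats output of [compute_suffstats()].
#' @return A scalar.
#' @export
chain_objective <- function(model, stats) {
  penalized_objective(model$layer_xy, suffstats_slice(stats, "xy")) +
    penalized_objective(model$layer_yz, suffstats_slice(stats, "yz"))
}

#' Gradients of the smooth sCGGM objective
#'
#' Returns the gradient components used by the solver:
#' `grad_Lambda = S_out - Sigma - Psi` and
#' `grad_Theta = 2 S_cross + 2 S_in Theta Sigma`, where `Sigma = Lambda^-1`
#' and `Psi = Sigma Theta' S_in Theta Sigma`.
#'
#' @inheritParams scggm_neg_loglik
#' @return List with `grad_Lambda`, `grad_Theta`, `Sigma`, `Psi`.
#' @export
scggm_gradients <- function(layer, stats, layer_name = c("xy", "yz")) {
  s <- resolve_slice(stats, layer_name)
  Lambda <- dense(layer$Lambda); Theta <- dense(layer$Theta)
  R <- chol(Lambda)
  Sigma <- chol2inv(R)
  if (nrow(Theta) > 0L) {
    W <- s$S_in %*% Theta
    Psi <- Sigma %*% crossprod(Theta, W) %*% Sigma
    Psi <- (Psi + t(Psi)) / 2
    grad_Theta <- 2 * s$S_cross + 2 * W %*% Sigma
  } else {
    Psi <- matrix(0, ncol(Lambda), ncol(Lambda))
    grad_Theta <- matrix(0, 0, ncol(Lambda))
  }
  list(grad_Lambda = s$S_out - Sigma - Psi, grad_Theta = grad_Theta,
       Sigma = Sigma, Psi = Psi)
}

#' Maximum KKT (subgradient optimality) violation of a fitted layer
#'
#' For coordinates at zero the gradient magnitude must not exceed the
#' penalty; for nonzero coordinates the gradient must equal minus penalty
#' times the sign.  Diagonal entries of `Lambda` are unpenalized, so their
#' gradient must vanish.  Returns the largest violation over all
#' coordinates of `Lambda` and `Theta`.
#'
#' @inheritParams scggm_neg_loglik
#' @return A scalar (0 at an exact optimum).
#' @export
kkt_residual <- function(layer, stats, layer_name = c("xy", "yz")) {
  g <- scggm_gradients(layer, stats, layer_name)
  Lambda <- dense(layer$Lambda); Theta <- dense(layer$Theta)
  viol <- subgrad_violation(g$grad_Lambda, Lambda, layer$lambda_Lambda,
                            skip_diag = TRUE)
  viol_d <- max(abs(diag(g$grad_Lambda)))
  viol_t <- if (nrow(Theta) > 0L) {
    subgrad_violation(g$grad_Theta, Theta, layer$lambda_Theta)
  } else 0
  max(viol, viol_d, viol_t)
}

subgrad_violation <- function(G, P, lam, skip_diag = FALSE) {
  if (skip_diag) diag(P) <- NA  # mark to exclude
  zero <- which(P == 0)
  nz <- which(P != 0 & !is.na(P))
  v <- 0
  if (length(zero)) v <- max(v, max(pmax(abs(G[zero]) - lam, 0)))
  if (length(nz)) v <- max(v, max(abs(G[nz] + lam * sign(P[nz]))))
  v
}

resolve_slice <- function(stats, layer_name = c("xy", "yz")) {
  if (inherits(stats, "scggm_suffstats")) {
    suffstats_slice(stats, match.arg(layer_name))
  } else {
    stopifnot(is.list(stats), !is.null(stats$S_out))
    stats
  }
}
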