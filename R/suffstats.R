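#' Mean-centered sufficient statistics
#'
#' Computes the 1/n-scaled cross-product matrices `S_xx`, `S_xy`, `S_yy`,
#' `S_yz`, `S_zz` from a [data_bundle()].  Each block is
#' \eqn{S = \tilde A^\top \tilde B / n} for mean-centered matrices, centering
#' by the per-column mean of the rows actually used.  With
#' `observed_only = TRUE` (the semi-supervised case) only the samples with
#' expression data contribute to `S_xy`, `S_yy` and `S_yz` (scaled by the
#' number of observed rows), while `S_xx` and `S_zz` use all samples.
#'
#' The solvers never consume raw data matrices directly; all centering and
#' scaling happens here.
#'
#' @param data a [data_bundle()], or any list with elements `X`, `Y`, `Z`
#'   (and optionally `y_rows`).
#' @param observed_only restrict the Y-involving blocks to observed rows.
#' @return An object of class `"scggm_suffstats"`: a list with matrices
#'   `S_xx`, `S_xy`, `S_yy`, `S_yz`, `S_zz`, sample counts `n` (all rows) and
#'   `n_y` (rows used for the Y blocks).
#' @examples
#' d <- data_bundle(X = matrix(c(0, 2), 2, 1), Y = matrix(c(1, 3), 2, 1),
#'                  Z = matrix(0, 2, 1))
#' compute_suffstats(d)$S_xy   # 1
#' @export
compute_suffstats <- function(data, observed_only = FALSE) {
  if (!inherits(data, "data_bundle")) {
    data <- data_bundle(data$X, data$Y, data$Z, y_rows = data$y_rows)
  }
  X <- data$X; Y <- data$Y; Z <- data$Z
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples")
  obs <- data$y_rows
  semi <- length(obs) < n
  if (semi && !observed_only) {
    stop("Y rows are missing for some samples; use observed_only = TRUE ",
         "or em_fit() for semi-supervised estimation")
  }
  if (observed_only) {
    if (length(obs) == 0L) stop("no samples with expression data remain")
    if (length(obs) < 2L) stop("need at least 2 observed samples")
    Xo <- X[obs, , drop = FALSE]
    Zo <- Z[obs, , drop = FALSE]
  } else {
    Xo <- X; Zo <- Z
  }
  n_y <- nrow(Y)
  Xc <- center_cols(X); Zc <- center_cols(Z)
  Xoc <- center_cols(Xo); Yc <- center_cols(Y); Zoc <- center_cols(Zo)
  out <- list(
    S_xx = crossprod(Xc) / n,
    S_xy = crossprod(Xoc, Yc) / n_y,
    S_yy = crossprod(Yc) / n_y,
    S_yz = crossprod(Yc, Zoc) / n_y,
    S_zz = crossprod(Zc) / n,
    n = n, n_y = n_y,
    snp_ids = data$snp_ids, gene_ids = data$gene_ids,
    trait_ids = data$trait_ids
  )
  out$S_yy <- (out$S_yy + t(out$S_yy)) / 2
  out$S_xx <- (out$S_xx + t(out$S_xx)) / 2
  out$S_zz <- (out$S_zz + t(out$S_zz)) / 2
  structure(out, class = "scggm_suffstats")
}

#' Extract the (input, cross, output) slice of sufficient statistics
#'
#' Returns the three matrices an sCGGM layer needs: for the x->y layer the
#' triple (S_xx, S_xy, S_yy); for the y->z layer (S_yy, S_yz, S_zz), the
#' expression covariance playing the input role.
#'
#' @param stats output of [compute_suffstats()].
#' @param layer `"xy"` or `"yz"`.
#' @return A list with elements `S_in`, `S_cross`, `S_out`, `n`.
#' @export
suffstats_slice <- function(stats, layer = c("xy", "yz")) {
  layer <- match.arg(layer)
  if (layer == "xy") {
    list(S_in = stats$S_xx, S_cross = stats$S_xy, S_out = stats$S_yy,
         n = stats$n_y %||% stats$n)
  } else {
    list(S_in = stats$S_yy, S_cross = stats$S_yz, S_out = stats$S_zz,
         n = stats$n_y %||% stats$n)
  }
}

center_cols <- function(A) {
  sweep(A, 2L, colMeans(A), "-")
}

# build a stats slice directly from data matrices (used by fit_scggm when
# given raw X/Y)
stats_from_xy <- function(X, Y) {
  if (!is.null(X)) {
    if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  }
  n <- nrow(Y)
  if (n < 2L) stop("need at least 2 samples")
  Yc <- center_cols(dense(Y))
  if (is.null(X) || ncol(X) == 0L) {
    list(S_in = matrix(0, 0, 0), S_cross = matrix(0, 0, ncol(Y)),
         S_out = crossprod(Yc) / n, n = n)
  } else {
    Xc <- center_cols(dense(X))
    list(S_in = crossprod(Xc) / n, S_cross = crossprod(Xc, Yc) / n,
         S_out = crossprod(Yc) / n, n = n)
  }
}
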