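#' Plan the block structure for a memory-budgeted fit
#'
#' Chooses column blocks of the output dimension (for network/Sigma work)
#' and row blocks of the input dimension (for perturbation/S_xx work) so
#' that the large solver caches stay within `budget` bytes.  The accounting
#' covers the large caches only — Sigma/Psi/U column blocks (6 per active
#' block pair, 8 bytes per double), the maintained `W = S_xx Theta`
#' product, and the recomputed S_xx row blocks; parameter-sized sparse
#' objects and small vectors are exempt.  The plan is deterministic, and a
#' budget at least as large as the dense requirement yields a single block
#' (the block-wise path then degenerates to the in-memory path).
#'
#' @param p,q input/output dimensions.
#' @param budget memory budget in bytes (may be `Inf`); also accepts
#'   strings like `"2G"`, `"500M"`, `"64K"`.
#' @return An object of class `"block_plan"` with the block index lists,
#'   block sizes, the estimated peak working set, and the budget.  An
#'   infeasible budget raises an error naming the minimal feasible budget.
#' @export
plan_blocks <- function(p, q, budget = Inf) {
  budget <- parse_bytes(budget)
  dense_bytes <- 8 * (p^2 + 5 * q^2 + 2 * p * q)
  min_lambda <- 48 * q              # one block pair at bs_q = 1
  min_theta <- if (p > 0) 8 * (p * q + p + q) else 0
  min_budget <- max(min_lambda, min_theta)
  if (budget < min_budget) {
    stop("memory budget ", format(budget), " B infeasible; minimal feasible ",
         "budget for p = ", p, ", q = ", q, " is ", min_budget, " B")
  }
  if (budget >= dense_bytes) {
    return(structure(list(
      q_blocks = list(seq_len(q)), p_blocks = list(seq_len(max(p, 1L))),
      bs_q = q, bs_p = max(p, 1L), single = TRUE,
      est_peak_bytes = dense_bytes, budget = budget), class = "block_plan"))
  }
  bs_q <- max(1L, min(q, floor(budget / (48 * q))))
  bs_p <- if (p > 0) {
    max(1L, min(p, floor((budget / 8 - p * q - q * bs_q) / p)))
  } else 1L
  q_blocks <- split(seq_len(q), ceiling(seq_len(q) / bs_q))
  p_blocks <- if (p > 0) split(seq_len(p), ceiling(seq_len(p) / bs_p))
              else list(integer())
  est <- max(48 * q * bs_q, 8 * (p * q + bs_p * p + q * bs_q))
  structure(list(q_blocks = unname(q_blocks), p_blocks = unname(p_blocks),
                 bs_q = bs_q, bs_p = bs_p, single = FALSE,
                 est_peak_bytes = est, budget = budget),
            class = "block_plan")
}

parse_bytes <- function(x) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^([0-9.]+)\\s*([KMGkmg]?)[Bb]?$", x))[[1]]
  if (length(m) < 2L) stop("cannot parse memory budget: ", x)
  mult <- c("1" = 1, K = 2^10, M = 2^20, G = 2^30)[
    if (m[3] == "") "1" else toupper(m[3])]
  as.numeric(m[2]) * mult
}

#' @export
print.block_plan <- function(x, ...) {
  cat("block plan: ", length(x$q_blocks), " output block(s) (size ",
      x$bs_q, "), ", length(x$p_blocks), " input block(s) (size ", x$bs_p,
      ")\n  estimated peak cache ", format(x$est_peak_bytes),
      " B of budget ", format(x$budget), " B\n", sep = "")
  invisible(x)
}

## simple allocation tracker for the large caches
new_tracker <- function() {
  env <- new.env(parent = emptyenv())
  env$cur <- 0; env$peak <- 0; env$held <- list()
  env
}
trk_alloc <- function(trk, name, bytes) {
  if (!is.null(trk$held[[name]])) trk$cur <- trk$cur - trk$held[[name]]
  trk$held[[name]] <- bytes
  trk$cur <- trk$cur + bytes
  trk$peak <- max(trk$peak, trk$cur)
}
trk_free <- function(trk, name) {
  if (!is.null(trk$held[[name]])) {
    trk$cur <- trk$cur - trk$held[[name]]
    trk$held[[name]] <- NULL
  }
}

#' Memory-budgeted block-wise sCGGM fit
#'
#' Minimizes the same penalized objective as [fit_scggm()] under a memory
#' budget: columns of `Sigma = Lambda^-1` and `Psi` are computed per block
#' by sparse Cholesky solves (never materializing the dense q x q
#' matrices), Newton-direction coordinate descent runs over block pairs,
#' and `Theta` updates are blocked by input rows with the needed rows of
#' `S_xx` recomputed on demand from the centered genotype matrix.  With a
#' budget at or above the dense requirement the call delegates to
#' [fit_scggm()] (identical code path).
#'
#' @param x input data matrix (n x p) or `NULL`.
#' @param y output data matrix (n x q).
#' @param lambda_Lambda,lambda_Theta penalties.
#' @param budget memory budget in bytes or a string like `"256M"`.
#' @param control solver options ([scggm_control()]).
#' @param Lambda0,Theta0 optional warm starts.
#' @return An [scggm_layer()]; `fit_info` additionally records the block
#'   `plan` and the tracked `peak_cache_bytes`.
#' @export
fit_scggm_blockwise <- function(x, y, lambda_Lambda = 0.1,
                                lambda_Theta = 0.1, budget = Inf,
                                control = scggm_control(),
                                Lambda0 = NULL, Theta0 = NULL) {
  Yc <- center_cols(dense(y))
  n <- nrow(Yc); q <- ncol(Yc)
  if (n < 2L) stop("need at least 2 samples")
  Xc <- if (is.null(x) || ncol(as.matrix(x)) == 0L) NULL
        else center_cols(dense(x))
  p <- if (is.null(Xc)) 0L else ncol(Xc)
  plan <- plan_blocks(p, q, budget)
  if (plan$single) {
    fit <- fit_scggm(x, y, lambda_Lambda, lambda_Theta, control,
                     Lambda0 = Lambda0, Theta0 = Theta0)
    fit$fit_info$plan <- plan
    fit$fit_info$peak_cache_bytes <- plan$est_peak_bytes
    return(fit)
  }

  trk <- new_tracker()
  S_yy_diag <- colSums(Yc^2) / n
  Lambda <- if (is.null(Lambda0)) {
    Matrix::Diagonal(q, pmax(1 / pmax(S_yy_diag, .Machine$double.eps),
                             control$lambda_clip))
  } else methods::as(Matrix::forceSymmetric(methods::as(Lambda0,
                                                        "CsparseMatrix")),
                     "dsCMatrix")
  Lambda <- methods::as(Matrix::forceSymmetric(Lambda), "dsCMatrix")
  Theta <- if (is.null(Theta0)) {
    Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                         dims = c(p, q))
  } else methods::as(methods::as(Theta0, "CsparseMatrix"), "generalMatrix")
  S_xy <- if (p > 0) crossprod(Xc, Yc) / n else matrix(0, 0, q)

  obj <- blockwise_objective(Lambda, Theta, Xc, Yc, S_xy, lambda_Lambda,
                             lambda_Theta, plan, trk)
  traj <- obj
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(control$max_iter)) {
    ch <- Matrix::Cholesky(Lambda, LDL = FALSE, perm = TRUE)
    if (p > 0) {
      Theta <- blockwise_theta_step(Theta, ch, Xc, S_xy, lambda_Theta,
                                    plan, control, trk)
    }
    Lambda <- blockwise_lambda_step(Lambda, Theta, ch, Xc, Yc, lambda_Lambda,
                                    plan, control, trk)
    obj_new <- blockwise_objective(Lambda, Theta, Xc, Yc, S_xy,
                                   lambda_Lambda, lambda_Theta, plan, trk)
    traj <- c(traj, obj_new)
    rel <- abs(obj - obj_new) / max(abs(obj), 1e-12)
    obj <- obj_new
    if (rel < control$tol) { converged <- TRUE; break }
  }
  layer <- scggm_layer(
    Lambda = Matrix::drop0(Lambda), Theta = Matrix::drop0(Theta),
    lambda_Lambda = lambda_Lambda, lambda_Theta = lambda_Theta,
    fit_info = list(objective = traj, iterations = iter,
                    converged = converged, plan = plan,
                    peak_cache_bytes = trk$peak),
    check = FALSE)
  if (!converged) {
    warning("fit_scggm_blockwise did not converge in ", control$max_iter,
            " iterations")
  }
  layer
}

## penalized objective computed with block-sized dense intermediates only
blockwise_objective <- function(Lambda, Theta, Xc, Yc, S_xy, lamL, lamT,
                                plan, trk) {
  n <- nrow(Yc)
  ch <- Matrix::Cholesky(Lambda, LDL = FALSE, perm = TRUE)
  logdet <- as.numeric(Matrix::determinant(Lambda, logarithm = TRUE)$modulus)
  tr_SyyL <- sum(as.matrix(Yc %*% Lambda) * Yc) / n
  val <- -logdet + tr_SyyL
  if (!is.null(Xc) && nrow(Theta) > 0L) {
    A <- as.matrix(Xc %*% Theta)           # n x q, data-sized
    Tt <- methods::as(Theta, "TsparseMatrix")
    val <- val + 2 * sum(S_xy[cbind(Tt@i + 1L, Tt@j + 1L)] * Tt@x)
    idx <- split(seq_len(n), ceiling(seq_len(n) / max(plan$bs_q, 1L)))
    acc <- 0
    for (I in idx) {                       # tr(Lambda^-1 A'A)/n blockwise
      Bl <- t(A[I, , drop = FALSE])
      trk_alloc(trk, "obj_solve", 8 * length(Bl))
      acc <- acc + sum(as.matrix(Matrix::solve(ch, Bl, system = "A")) * Bl)
      trk_free(trk, "obj_solve")
    }
    val <- val + acc / n
  }
  val + lamL * sum_abs_offdiag(Lambda) + lamT * sum(abs(Theta))
}

## Theta phase: active sets per (row block, column block); W = S_xx Theta
## maintained; S_xx row blocks recomputed on demand from Xc.
blockwise_theta_step <- function(Theta, ch, Xc, S_xy, lamT, plan, control,
                                 trk) {
  n <- nrow(Xc); p <- ncol(Xc); q <- ncol(S_xy)
  sxx_diag <- colSums(Xc^2) / n
  if (any(sxx_diag == 0)) {
    warning("some input columns are constant; their coordinates are skipped")
  }
  W <- crossprod(Xc, as.matrix(Xc %*% Theta)) / n  # p x q maintained cache
  trk_alloc(trk, "W", 8 * p * q)
  triplets_i <- integer(0); triplets_j <- integer(0); triplets_x <- numeric(0)
  for (J in plan$q_blocks) {
    Sigma_J <- as.matrix(Matrix::solve(ch, diag_cols(q, J), system = "A"))
    trk_alloc(trk, "Sigma_J", 8 * length(Sigma_J))
    gblock <- 2 * S_xy[, J, drop = FALSE] + 2 * W %*% Sigma_J
    Th_J <- as.matrix(Theta[, J, drop = FALSE])
    act <- which(abs(gblock) > lamT | Th_J != 0, arr.ind = TRUE)
    if (nrow(act)) {
      diag_J <- diag(Sigma_J[J, , drop = FALSE])
      for (B in plan$p_blocks) {
        inB <- act[, 1L] %in% B
        if (!any(inB)) next
        actB <- act[inB, , drop = FALSE]
        actB <- actB[order(actB[, 1L], actB[, 2L]), , drop = FALSE]
        S_xxB <- crossprod(Xc[, B, drop = FALSE], Xc) / n
        trk_alloc(trk, "S_xxB", 8 * length(S_xxB))
        for (k in seq_len(nrow(actB))) {
          i <- actB[k, 1L]; jl <- actB[k, 2L]; j <- J[jl]
          il <- match(i, B)
          h <- 2 * S_xxB[il, i] * diag_J[jl]
          if (h <= 0) next
          g <- 2 * S_xy[i, j] + 2 * sum(W[i, ] * Sigma_J[, jl])
          th_old <- Th_J[i, jl]
          c0 <- th_old - g / h
          thr <- lamT / h
          th_new <- if (c0 > thr) c0 - thr else if (c0 < -thr) c0 + thr else 0
          d <- th_new - th_old
          if (d != 0) {
            Th_J[i, jl] <- th_new
            W[, j] <- W[, j] + d * S_xxB[il, ]
          }
        }
        trk_free(trk, "S_xxB")
      }
    }
    nzJ <- which(Th_J != 0, arr.ind = TRUE)
    if (nrow(nzJ)) {
      triplets_i <- c(triplets_i, nzJ[, 1L])
      triplets_j <- c(triplets_j, J[nzJ[, 2L]])
      triplets_x <- c(triplets_x, Th_J[nzJ])
    }
    trk_free(trk, "Sigma_J")
  }
  trk_free(trk, "W")
  Matrix::sparseMatrix(i = triplets_i, j = triplets_j, x = triplets_x,
                       dims = c(p, q))
}

diag_cols <- function(q, J) {
  E <- matrix(0, q, length(J))
  E[cbind(J, seq_along(J))] <- 1
  E
}

## Lambda phase: gradient blocks, active pairs, CD over block pairs,
## line search with sparse Cholesky PD checks.
blockwise_lambda_step <- function(Lambda, Theta, ch, Xc, Yc, lamL, plan,
                                  control, trk) {
  n <- nrow(Yc); q <- ncol(Yc)
  nb <- length(plan$q_blocks)
  A <- if (!is.null(Xc) && nrow(Theta) > 0L) as.matrix(Xc %*% Theta)
       else matrix(0, n, 0)
  has_psi <- ncol(A) > 0L && any(A != 0)

  ## pass 1: gradient blocks -> active pairs with values, diagonals
  diag_S <- numeric(q); diag_P <- numeric(q)
  pair_i <- integer(0); pair_j <- integer(0); pair_g <- numeric(0)
  for (bi in seq_len(nb)) {
    J <- plan$q_blocks[[bi]]
    Sigma_J <- as.matrix(Matrix::solve(ch, diag_cols(q, J), system = "A"))
    trk_alloc(trk, "grad_Sigma_J", 8 * length(Sigma_J))
    Psi_J <- if (has_psi) {
      as.matrix(Matrix::solve(ch, crossprod(A, A %*% Sigma_J) / n,
                              system = "A"))
    } else matrix(0, q, length(J))
    trk_alloc(trk, "grad_Psi_J", 8 * length(Psi_J))
    G_J <- crossprod(Yc, Yc[, J, drop = FALSE]) / n - Sigma_J - Psi_J
    diag_S[J] <- Sigma_J[cbind(J, seq_along(J))]
    diag_P[J] <- Psi_J[cbind(J, seq_along(J))]
    LJ <- as.matrix(Lambda[, J, drop = FALSE])
    sel <- abs(G_J) > lamL | LJ != 0
    idx <- which(sel, arr.ind = TRUE)
    if (nrow(idx)) {
      gi <- idx[, 1L]; gj <- J[idx[, 2L]]
      keep <- gi < gj                       # one of each unordered pair
      pair_i <- c(pair_i, gi[keep]); pair_j <- c(pair_j, gj[keep])
      pair_g <- c(pair_g, G_J[idx][keep])
    }
    ## diagonals always active
    pair_i <- c(pair_i, J); pair_j <- c(pair_j, J)
    pair_g <- c(pair_g, G_J[cbind(J, seq_along(J))])
    trk_free(trk, "grad_Sigma_J"); trk_free(trk, "grad_Psi_J")
  }
  dup <- duplicated(paste(pair_i, pair_j))
  pair_i <- pair_i[!dup]; pair_j <- pair_j[!dup]; pair_g <- pair_g[!dup]
  lam_vals <- lambda_entries(Lambda, pair_i, pair_j)
  pair_val <- numeric(length(pair_i))     # Delta values
  block_of <- integer(q)
  for (bi in seq_len(nb)) block_of[plan$q_blocks[[bi]]] <- bi
  pb_a <- block_of[pair_i]; pb_b <- block_of[pair_j]

  ## pass 2: coordinate descent over block pairs
  for (sw in seq_len(control$sweeps)) {
    for (a in seq_len(nb)) {
      for (b in a:nb) {
        sel <- which(pb_a == a & pb_b == b)
        if (!length(sel)) next
        Ja <- plan$q_blocks[[a]]; Jb <- plan$q_blocks[[b]]
        Sigma_a <- as.matrix(Matrix::solve(ch, diag_cols(q, Ja),
                                           system = "A"))
        Psi_a <- if (has_psi) {
          as.matrix(Matrix::solve(ch, crossprod(A, A %*% Sigma_a) / n,
                                  system = "A"))
        } else matrix(0, q, length(Ja))
        trk_alloc(trk, "cd_Sigma_a", 8 * length(Sigma_a))
        trk_alloc(trk, "cd_Psi_a", 8 * length(Psi_a))
        if (b == a) {
          Sigma_b <- Sigma_a; Psi_b <- Psi_a
        } else {
          Sigma_b <- as.matrix(Matrix::solve(ch, diag_cols(q, Jb),
                                             system = "A"))
          Psi_b <- if (has_psi) {
            as.matrix(Matrix::solve(ch, crossprod(A, A %*% Sigma_b) / n,
                                    system = "A"))
          } else matrix(0, q, length(Jb))
          trk_alloc(trk, "cd_Sigma_b", 8 * length(Sigma_b))
          trk_alloc(trk, "cd_Psi_b", 8 * length(Psi_b))
        }
        M_a <- Sigma_a + 2 * Psi_a; M_b <- Sigma_b + 2 * Psi_b
        Dsp <- if (any(pair_val != 0)) {
          Matrix::sparseMatrix(
            i = c(pair_i, pair_j[pair_i != pair_j]),
            j = c(pair_j, pair_i[pair_i != pair_j]),
            x = c(pair_val, pair_val[pair_i != pair_j]), dims = c(q, q))
        } else Matrix::sparseMatrix(i = integer(), j = integer(),
                                    x = numeric(), dims = c(q, q))
        U_a <- as.matrix(Dsp %*% Sigma_a)
        U_b <- if (b == a) U_a else as.matrix(Dsp %*% Sigma_b)
        trk_alloc(trk, "cd_U_a", 8 * length(U_a))
        trk_alloc(trk, "cd_U_b", if (b == a) 0 else 8 * length(U_b))
        diag_M <- diag_S + 2 * diag_P
        ord <- sel[order(pair_i[sel], pair_j[sel])]
        for (k in ord) {
          i <- pair_i[k]; j <- pair_j[k]
          il <- match(i, Ja); jl <- match(j, Jb)
          if (i == j) {
            h <- diag_M[i] * diag_S[i]
            if (h <= 0) next
            a1 <- pair_g[k] + sum(M_a[, il] * U_a[, il])
            mu <- -a1 / h
          } else {
            Sij <- Sigma_b[i, jl]; Mij <- M_b[i, jl]
            h <- 2 * Mij * Sij + diag_M[j] * diag_S[i] + diag_M[i] * diag_S[j]
            if (h <= 0) next
            ub_j <- if (b == a) U_a[, jl] else U_b[, jl]
            a1 <- 2 * pair_g[k] + sum(M_a[, il] * ub_j) +
              sum(M_b[, jl] * U_a[, il])
            c0 <- lam_vals[k] + pair_val[k]
            thr <- 2 * lamL / h
            ct <- c0 - a1 / h
            mu <- (if (ct > thr) ct - thr else if (ct < -thr) ct + thr
                   else 0) - c0
          }
          if (mu != 0) {
            pair_val[k] <- pair_val[k] + mu
            if (i == j) {
              U_a[i, ] <- U_a[i, ] + mu * Sigma_a[i, ]
              if (b != a) U_b[i, ] <- U_b[i, ] + mu * Sigma_b[i, ]
            } else {
              U_a[i, ] <- U_a[i, ] + mu * Sigma_a[j, ]
              U_a[j, ] <- U_a[j, ] + mu * Sigma_a[i, ]
              if (b != a) {
                U_b[i, ] <- U_b[i, ] + mu * Sigma_b[j, ]
                U_b[j, ] <- U_b[j, ] + mu * Sigma_b[i, ]
              }
            }
          }
        }
        trk_free(trk, "cd_Sigma_a"); trk_free(trk, "cd_Psi_a")
        trk_free(trk, "cd_Sigma_b"); trk_free(trk, "cd_Psi_b")
        trk_free(trk, "cd_U_a"); trk_free(trk, "cd_U_b")
      }
    }
  }
  nzd <- pair_val != 0
  if (!any(nzd)) return(Lambda)
  D <- Matrix::sparseMatrix(
    i = c(pair_i[nzd], pair_j[nzd][pair_i[nzd] != pair_j[nzd]]),
    j = c(pair_j[nzd], pair_i[nzd][pair_i[nzd] != pair_j[nzd]]),
    x = c(pair_val[nzd], pair_val[nzd][pair_i[nzd] != pair_j[nzd]]),
    dims = c(q, q))
  D <- Matrix::forceSymmetric(D)

  ## Armijo line search with sparse PD checks and blockwise objective terms
  off_d <- pair_i != pair_j
  gdot <- sum(pair_g[off_d] * 2 * pair_val[off_d]) +
    sum(pair_g[!off_d] * pair_val[!off_d])
  delta <- gdot + lamL * (sum_abs_offdiag(Lambda + D) -
                            sum_abs_offdiag(Lambda))
  fL <- function(L) {
    chL <- tryCatch(Matrix::Cholesky(methods::as(Matrix::forceSymmetric(L),
                                                 "dsCMatrix"), LDL = FALSE),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(chL)) return(list(ok = FALSE))
    ld <- as.numeric(Matrix::determinant(L, logarithm = TRUE)$modulus)
    v <- -ld + sum(as.matrix(Yc %*% L) * Yc) / n + lamL * sum_abs_offdiag(L)
    if (has_psi) {
      idx <- split(seq_len(n), ceiling(seq_len(n) / max(plan$bs_q, 1L)))
      acc <- 0
      for (I in idx) {
        Bl <- t(A[I, , drop = FALSE])
        acc <- acc + sum(as.matrix(Matrix::solve(chL, Bl, system = "A")) * Bl)
      }
      v <- v + acc / n
    }
    list(ok = TRUE, val = v)
  }
  f0 <- fL(Lambda)$val
  alpha <- 1
  while (alpha >= control$alpha_min) {
    cand <- Lambda + alpha * D
    r <- fL(cand)
    if (r$ok && r$val <= f0 + control$sigma * alpha * delta) {
      return(methods::as(Matrix::forceSymmetric(cand), "dsCMatrix"))
    }
    alpha <- alpha * control$beta
  }
  Lambda   # stagnated: keep current iterate
}

lambda_entries <- function(Lambda, ii, jj) {
  L <- methods::as(methods::as(Lambda, "CsparseMatrix"), "generalMatrix")
  vapply(seq_along(ii), function(k) L[ii[k], jj[k]], numeric(1))
}
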