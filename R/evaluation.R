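#' Sensitivity-FDR recovery curve
#'
#' Ranks candidate discoveries by `|score|` (descending), sweeps the
#' threshold over the distinct score magnitudes (exact ties are grouped at
#' one threshold), and reports sensitivity `TP/P` and false discovery rate
#' `FP/(TP+FP)` at each point.
#'
#' @param scores numeric vector or matrix of scores.
#' @param truth logical (or 0/1) vector/matrix of the same shape marking
#'   true positives.
#' @return A tibble of class `"recovery_curve"` with columns `threshold`,
#'   `tp`, `fp`, `fn`, `sensitivity`, `fdr`.
#' @examples
#' recovery_curve(c(4, 3, 2, 1), c(TRUE, FALSE, TRUE, FALSE))
#' @export
recovery_curve <- function(scores, truth) {
  s <- abs(as.numeric(scores))
  t <- as.logical(truth)
  if (length(s) != length(t)) stop("scores and truth differ in shape")
  if (!any(t)) stop("truth mask has no positives")
  if (all(s == 0)) {
    warning("all scores are zero: flat recovery curve")
  }
  P <- sum(t)
  ord <- order(s, decreasing = TRUE)
  s_ord <- s[ord]; t_ord <- t[ord]
  cum_tp <- cumsum(t_ord)
  cum_fp <- cumsum(!t_ord)
  last <- !duplicated(s_ord, fromLast = TRUE)  # group ties at one threshold
  out <- tibble::tibble(
    threshold = s_ord[last],
    tp = cum_tp[last],
    fp = cum_fp[last],
    fn = P - cum_tp[last],
    sensitivity = cum_tp[last] / P,
    fdr = cum_fp[last] / pmax(cum_tp[last] + cum_fp[last], 1L)
  )
  class(out) <- c("recovery_curve", class(out))
  attr(out, "n_pos") <- P
  out
}

#' Sensitivity at a target FDR
#'
#' The largest sensitivity among curve points whose FDR does not exceed
#' `fdr` (0 if no such point exists).
#'
#' @param curve a [recovery_curve()].
#' @param fdr target false discovery rate (default 0.05, the conventional
#'   operating point).
#' @return A scalar in \[0, 1\].
#' @export
sensitivity_at_fdr <- function(curve, fdr = 0.05) {
  ok <- curve$fdr <= fdr
  if (!any(ok)) 0 else max(curve$sensitivity[ok])
}

#' Average recovery curves over replicates on a common FDR grid
#'
#' Each replicate curve is converted to sensitivity-as-a-function-of-FDR
#' (the best sensitivity attainable at or below each grid FDR) and curves
#' are averaged pointwise.
#'
#' @param curves list of [recovery_curve()] objects.
#' @param fdr_grid grid of FDR values (default 101 points on \[0, 1\]).
#' @return A tibble with columns `fdr`, `sensitivity`, `sens_min`,
#'   `sens_max`, `n_replicates`.
#' @export
average_recovery_curves <- function(curves, fdr_grid = seq(0, 1, 0.01)) {
  mat <- vapply(curves, function(cv) {
    vapply(fdr_grid, function(g) {
      ok <- cv$fdr <= g
      if (!any(ok)) 0 else max(cv$sensitivity[ok])
    }, numeric(1))
  }, numeric(length(fdr_grid)))
  mat <- matrix(mat, nrow = length(fdr_grid))
  tibble::tibble(fdr = fdr_grid,
                 sensitivity = rowMeans(mat),
                 sens_min = apply(mat, 1L, min),
                 sens_max = apply(mat, 1L, max),
                 n_replicates = length(curves))
}

#' Classify mediator genes by how they receive and pass perturbation
#'
#' A gene j mediates the effect of SNP k on trait t when both the overall
#' SNP-gene effect `B_xy[k, j]` and gene-trait effect `B_yz[j, t]` are
#' nonzero.  The mediation is *received* directly if the SNP perturbs the
#' gene directly (`Theta_xy[k, j] != 0`), indirectly otherwise, and
#' *passed* directly if the gene perturbs the trait directly
#' (`Theta_yz[j, t] != 0`), indirectly otherwise — four combinations in
#' total.
#'
#' @param model a [chain_model()] (truth or fit).
#' @param min_abs magnitude below which an overall effect counts as zero.
#' @param snps,genes,traits optional index restrictions (the full triplet
#'   table grows as p x q x r).
#' @return A tibble with columns `snp`, `gene`, `trait`, `receives`,
#'   `passes` (each `"direct"`/`"indirect"`).
#' @export
categorize_mediators <- function(model, min_abs = 1e-10,
                                 snps = NULL, genes = NULL, traits = NULL) {
  B_xy <- indirect_xy(model); B_yz <- indirect_yz(model)
  Th_xy <- as.matrix(model$layer_xy$Theta)
  Th_yz <- as.matrix(model$layer_yz$Theta)
  snps <- snps %||% seq_len(nrow(B_xy))
  genes <- genes %||% seq_len(ncol(B_xy))
  traits <- traits %||% seq_len(ncol(B_yz))
  rows <- list()
  for (j in genes) {
    ks <- snps[abs(B_xy[snps, j]) > min_abs]
    ts <- traits[abs(B_yz[j, traits]) > min_abs]
    if (!length(ks) || !length(ts)) next
    grid <- expand.grid(snp = ks, trait = ts, KEEP.OUT.ATTRS = FALSE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      snp = grid$snp, gene = j, trait = grid$trait,
      receives = ifelse(Th_xy[grid$snp, j] != 0, "direct", "indirect"),
      passes = ifelse(Th_yz[j, grid$trait] != 0, "direct", "indirect"))
  }
  if (!length(rows)) {
    return(tibble::tibble(snp = integer(), gene = integer(),
                          trait = integer(), receives = character(),
                          passes = character()))
  }
  dplyr::bind_rows(rows)
}

#' Two-layer Lasso baseline
#'
#' The mediator-agnostic baseline: each gene is L1-regressed on the SNPs
#' and each trait on the genes, independently (glmnet), and SNP-on-trait
#' effects are the product of the two coefficient matrices.  Per response,
#' the penalty is either fixed or chosen by a Gaussian BIC over the glmnet
#' path.
#'
#' @param data a complete-data [data_bundle()].
#' @param lambda_xy,lambda_yz fixed penalty per layer, or `NULL` to select
#'   per response by BIC over `nlambda` path values.
#' @param nlambda glmnet path length used for BIC selection.
#' @return An object of class `"two_layer_lasso"` with coefficient matrices
#'   `W_xy` (p x q), `W_yz` (q x r), composed effects `B_xz`, and a tibble
#'   `failures` describing per-response solver failures (if any).
#' @export
two_layer_lasso_baseline <- function(data, lambda_xy = NULL,
                                     lambda_yz = NULL, nlambda = 30L) {
  if (length(data$y_rows) != nrow(data$X)) {
    stop("the two-layer Lasso baseline needs complete data")
  }
  fails <- list()
  l1 <- lasso_layer(data$X, data$Y, lambda_xy, nlambda, "xy", fails)
  l2 <- lasso_layer(data$Y, data$Z, lambda_yz, nlambda, "yz", l1$fails)
  W_xy <- l1$W; W_yz <- l2$W
  dimnames(W_xy) <- list(data$snp_ids, data$gene_ids)
  dimnames(W_yz) <- list(data$gene_ids, data$trait_ids)
  structure(list(W_xy = W_xy, W_yz = W_yz, B_xz = W_xy %*% W_yz,
                 failures = dplyr::bind_rows(l2$fails)),
            class = "two_layer_lasso")
}

lasso_layer <- function(X, Y, lambda, nlambda, layer, fails) {
  p <- ncol(X); W <- matrix(0, p, ncol(Y))
  n <- nrow(X)
  for (j in seq_len(ncol(Y))) {
    co <- tryCatch({
      if (!is.null(lambda)) {
        fit <- glmnet::glmnet(X, Y[, j], lambda = lambda,
                              standardize = FALSE)
        as.numeric(coef(fit, s = lambda))[-1L]
      } else {
        fit <- glmnet::glmnet(X, Y[, j], nlambda = nlambda,
                              standardize = FALSE)
        beta <- as.matrix(fit$beta)
        pred <- X %*% beta +
          matrix(fit$a0, n, ncol(beta), byrow = TRUE)
        rss <- colSums((Y[, j] - pred)^2)
        k <- fit$df
        bic <- n * log(rss / n) + k * log(n)
        beta[, which.min(bic)]
      }
    }, error = function(e) e)
    if (inherits(co, "error")) {
      fails[[length(fails) + 1L]] <- tibble::tibble(
        layer = layer, response = j, message = conditionMessage(co))
    } else {
      W[, j] <- co
    }
  }
  list(W = W, fails = fails)
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation with midrank tie handling:
#' `(mean rank of positives - (P+1)/2) / N_negative`.
#'
#' @param scores numeric vector/matrix.
#' @param labels logical (or 0/1) of the same shape.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  s <- as.numeric(scores); l <- as.logical(labels)
  pos <- sum(l); neg <- sum(!l)
  if (pos == 0L || neg == 0L) stop("need both positive and negative labels")
  r <- rank(s)
  (sum(r[l]) - pos * (pos + 1) / 2) / (pos * neg)
}

#' Robustness of the fitted support to subsampling and added noise
#'
#' Refits the chain model on perturbed copies of the data — random sample
#' subsets drawn without replacement (stratified over fully and partially
#' observed samples) and/or independent Gaussian noise added to expression
#' and trait values — and scores, per parameter block, the ROC-AUC of the
#' refit's |estimate| against the reference fit's nonzero pattern.
#'
#' @param data a [data_bundle()].
#' @param fractions sample fractions to keep.
#' @param noise_sds standard deviations of added Gaussian noise.
#' @param lambda_Lambda_y,lambda_Theta_xy,lambda_Lambda_z,lambda_Theta_yz
#'   penalties used for every fit.
#' @param reference optional reference [chain_model()] (default: fit on the
#'   unperturbed data with the same penalties).
#' @param control solver options.
#' @param seed integer seed for the perturbation draws.
#' @return A tibble with columns `fraction`, `noise_sd`, `block`, `auc`,
#'   `n_samples`; cells whose subsample is too small to fit are skipped
#'   with a note column.
#' @export
robustness_suite <- function(data, fractions = c(1, 0.75, 0.5),
                             noise_sds = c(0, 0.25, 0.5),
                             lambda_Lambda_y = 0.1, lambda_Theta_xy = 0.1,
                             lambda_Lambda_z = 0.1, lambda_Theta_yz = 0.1,
                             reference = NULL, control = scggm_control(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference)) {
    reference <- fit_chain(data, lambda_Lambda_y, lambda_Theta_xy,
                           lambda_Lambda_z, lambda_Theta_yz, control)
  }
  ref_masks <- support_masks(reference)
  n <- nrow(data$X)
  obs <- data$y_rows; part <- setdiff(seq_len(n), obs)
  rows <- list()
  for (f in fractions) {
    keep_obs <- sort(sample(obs, round(f * length(obs))))
    keep_part <- if (length(part)) sort(sample(part, round(f * length(part))))
                 else integer()
    keep <- sort(c(keep_obs, keep_part))
    for (sd_n in noise_sds) {
      sub <- tryCatch({
        Y <- data$Y[match(keep_obs, obs), , drop = FALSE]
        Z <- data$Z[keep, , drop = FALSE]
        if (sd_n > 0) {
          Y <- Y + matrix(stats::rnorm(length(Y), sd = sd_n), nrow(Y))
          Z <- Z + matrix(stats::rnorm(length(Z), sd = sd_n), nrow(Z))
        }
        data_bundle(data$X[keep, , drop = FALSE], Y, Z,
                    y_rows = match(keep_obs, keep))
      }, error = function(e) e)
      fit <- if (inherits(sub, "error")) sub else tryCatch({
        if (length(sub$y_rows) == nrow(sub$X)) {
          fit_chain(sub, lambda_Lambda_y, lambda_Theta_xy,
                    lambda_Lambda_z, lambda_Theta_yz, control)
        } else {
          em_fit(sub, lambda_Lambda_y, lambda_Theta_xy,
                 lambda_Lambda_z, lambda_Theta_yz, control)
        }
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          fraction = f, noise_sd = sd_n, block = names(ref_masks),
          auc = NA_real_, n_samples = length(keep),
          note = conditionMessage(fit))
        next
      }
      est <- support_masks(fit, values = TRUE)
      for (b in names(ref_masks)) {
        a <- if (sum(ref_masks[[b]]) == 0L || all(ref_masks[[b]])) {
          NA_real_
        } else auc_score(est[[b]], ref_masks[[b]])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          fraction = f, noise_sd = sd_n, block = b, auc = a,
          n_samples = length(keep), note = NA_character_)
      }
    }
  }
  dplyr::bind_rows(rows)
}

support_masks <- function(model, values = FALSE) {
  f <- function(M, offdiag = FALSE) {
    M <- as.matrix(M)
    if (offdiag) diag(M) <- 0
    keep <- if (offdiag) upper.tri(M) else matrix(TRUE, nrow(M), ncol(M))
    v <- M[keep]
    if (values) abs(v) else v != 0
  }
  list(Lambda_y = f(model$layer_xy$Lambda, offdiag = TRUE),
       Theta_xy = f(model$layer_xy$Theta),
       Lambda_z = f(model$layer_yz$Lambda, offdiag = TRUE),
       Theta_yz = f(model$layer_yz$Theta))
}
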