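#' Fit the full chain model on complete data
#'
#' The penalized chain objective decouples into the two layer problems, so
#' the x->y layer is fitted on (S_xx, S_xy, S_yy) and the y->z layer on
#' (S_yy, S_yz, S_zz), independently, each with [fit_scggm()].
#'
#' @param data a [data_bundle()] with expression observed for all samples.
#' @param lambda_Lambda_y,lambda_Theta_xy penalties of the SNP-to-gene layer.
#' @param lambda_Lambda_z,lambda_Theta_yz penalties of the gene-to-trait
#'   layer.
#' @param control solver options ([scggm_control()]).
#' @param warm optional `chain_model` supplying warm starts for both layers.
#' @return A [chain_model()].
#' @export
fit_chain <- function(data,
                      lambda_Lambda_y = 0.1, lambda_Theta_xy = 0.1,
                      lambda_Lambda_z = 0.1, lambda_Theta_yz = 0.1,
                      control = scggm_control(), warm = NULL) {
  stats <- compute_suffstats(data)
  fit_chain_stats(stats, lambda_Lambda_y, lambda_Theta_xy,
                  lambda_Lambda_z, lambda_Theta_yz, control, warm)
}

fit_chain_stats <- function(stats,
                            lambda_Lambda_y, lambda_Theta_xy,
                            lambda_Lambda_z, lambda_Theta_yz,
                            control = scggm_control(), warm = NULL) {
  layer_xy <- fit_scggm_stats(
    suffstats_slice(stats, "xy"), lambda_Lambda_y, lambda_Theta_xy, control,
    Lambda0 = if (!is.null(warm)) warm$layer_xy$Lambda,
    Theta0 = if (!is.null(warm)) warm$layer_xy$Theta,
    input_ids = stats$snp_ids, output_ids = stats$gene_ids)
  layer_yz <- fit_scggm_stats(
    suffstats_slice(stats, "yz"), lambda_Lambda_z, lambda_Theta_yz, control,
    Lambda0 = if (!is.null(warm)) warm$layer_yz$Lambda,
    Theta0 = if (!is.null(warm)) warm$layer_yz$Theta,
    input_ids = stats$gene_ids, output_ids = stats$trait_ids)
  chain_model(layer_xy, layer_yz,
              fit_info = list(objective = penalized_objective(
                layer_xy, suffstats_slice(stats, "xy")) +
                  penalized_objective(layer_yz, suffstats_slice(stats, "yz"))))
}

#' Bayesian information criterion of a fitted layer
#'
#' Scores a fitted layer as \eqn{\ell - (k/2)\log n}, where
#' \eqn{\ell = -(n/2) g(\Lambda, \Theta)} is the data log-likelihood (up to
#' a parameter-free constant) and the degrees of freedom
#' \eqn{k = \#\{\Theta \ne 0\} + \#\{i<j: \Lambda_{ij} \ne 0\} + q} count
#' the nonzero perturbations, the off-diagonal network pairs and the
#' diagonal.  Higher is better.  With `criterion = "aic"` the penalty is
#' `k` instead of `(k/2) log n`.
#'
#' @inheritParams scggm_neg_loglik
#' @param n sample count (defaults to `stats$n`).
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return A scalar; higher is better.
#' @export
bic_score <- function(layer, stats, n = NULL, layer_name = c("xy", "yz"),
                      criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  s <- resolve_slice(stats, layer_name)
  n <- n %||% s$n
  if (is.null(n)) stop("sample count n is required")
  k <- Matrix::nnzero(layer$Theta) + nnz_offdiag_pairs(layer$Lambda) +
    ncol(layer$Lambda)
  ll <- -(n / 2) * scggm_neg_loglik(layer, s)
  if (criterion == "bic") ll - (k / 2) * log(n) else ll - k
}

#' Select regularization parameters by BIC over a grid
#'
#' Because the chain objective decouples, the two layers are tuned
#' independently.  Within a layer, every combination of the `lambda_Lambda`
#' and `lambda_Theta` candidates is fitted, warm-starting each fit from the
#' previous (sparser) solution along the path, and the BIC-maximizing pair
#' is kept.
#'
#' @param data a complete-data [data_bundle()].
#' @param grid_xy,grid_yz lists with components `lambda_Lambda` and
#'   `lambda_Theta`, each a vector of positive candidates (sorted internally
#'   in decreasing order, sparsest first).
#' @param control solver options.
#' @param criterion `"bic"` or `"aic"`.
#' @return The selected [chain_model()]; the full per-candidate score table
#'   (a tibble) is attached as `fit_info$score_table`.
#' @export
select_lambdas <- function(data,
                           grid_xy = list(lambda_Lambda = c(0.4, 0.2, 0.1),
                                          lambda_Theta = c(0.4, 0.2, 0.1)),
                           grid_yz = grid_xy,
                           control = scggm_control(),
                           criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  stats <- compute_suffstats(data)
  sel_xy <- select_layer(suffstats_slice(stats, "xy"), grid_xy, control,
                         criterion, "xy", stats$snp_ids, stats$gene_ids)
  sel_yz <- select_layer(suffstats_slice(stats, "yz"), grid_yz, control,
                         criterion, "yz", stats$gene_ids, stats$trait_ids)
  model <- chain_model(sel_xy$best, sel_yz$best)
  model$fit_info <- list(
    score_table = dplyr::bind_rows(sel_xy$table, sel_yz$table),
    criterion = criterion)
  model
}

select_layer <- function(s, grid, control, criterion, layer_name,
                         input_ids, output_ids) {
  lamL <- sort(as.numeric(grid$lambda_Lambda), decreasing = TRUE)
  lamT <- sort(as.numeric(grid$lambda_Theta), decreasing = TRUE)
  if (!length(lamL) || !length(lamT)) stop("empty regularization grid")
  if (any(c(lamL, lamT) <= 0)) stop("grid candidates must be positive")
  rows <- list()
  best <- NULL; best_score <- -Inf
  failures <- character()
  warm <- NULL
  for (ll in lamL) {
    warm_path <- warm  # warm start each lambda_Theta path from the column head
    for (lt in lamT) {
      fit <- tryCatch(
        fit_scggm_stats(s, ll, lt, control,
                        Lambda0 = if (!is.null(warm_path)) warm_path$Lambda,
                        Theta0 = if (!is.null(warm_path)) warm_path$Theta,
                        input_ids = input_ids, output_ids = output_ids),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures <- c(failures, conditionMessage(fit))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          layer = layer_name, lambda_Lambda = ll, lambda_Theta = lt,
          score = NA_real_, nnz_Theta = NA_integer_,
          n_edges = NA_integer_, converged = NA)
        next
      }
      warm_path <- fit
      if (lt == lamT[1L]) warm <- fit
      sc <- bic_score(fit, s, criterion = criterion)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        layer = layer_name, lambda_Lambda = ll, lambda_Theta = lt,
        score = sc, nnz_Theta = Matrix::nnzero(fit$Theta),
        n_edges = nnz_offdiag_pairs(fit$Lambda),
        converged = fit$fit_info$converged)
      if (sc > best_score) { best <- fit; best_score <- sc }
    }
  }
  if (is.null(best)) {
    stop("all candidate fits failed for layer ", layer_name, ": ",
         paste(unique(failures), collapse = "; "))
  }
  list(best = best, table = dplyr::bind_rows(rows))
}
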