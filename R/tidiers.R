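#' Tidy an sCGGM layer into an edge table
#'
#' One row per nonzero parameter: network edges (upper-triangle pairs of
#' `Lambda`) and direct perturbations (entries of `Theta`).
#'
#' @param x an [scggm_layer()].
#' @param ... unused.
#' @return A tibble with columns `type` (`"network"`/`"perturbation"`),
#'   `from`, `to`, `value`.
#' @export
tidy.scggm_layer <- function(x, ...) {
  L <- methods::as(methods::as(x$Lambda, "CsparseMatrix"), "TsparseMatrix")
  keep <- L@i < L@j & L@x != 0
  net <- tibble::tibble(type = "network",
                        from = x$output_ids[L@i[keep] + 1L],
                        to = x$output_ids[L@j[keep] + 1L],
                        value = L@x[keep])
  Th <- methods::as(methods::as(x$Theta, "CsparseMatrix"), "TsparseMatrix")
  keep_t <- Th@x != 0
  pert <- tibble::tibble(type = "perturbation",
                         from = x$input_ids[Th@i[keep_t] + 1L],
                         to = x$output_ids[Th@j[keep_t] + 1L],
                         value = Th@x[keep_t])
  dplyr::bind_rows(net, pert)
}

#' @rdname tidy.scggm_layer
#' @export
tidy.chain_model <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$layer_xy), layer = "xy", .before = 1L),
    dplyr::mutate(tidy(x$layer_yz), layer = "yz", .before = 1L))
}

#' One-row summaries of fitted objects
#'
#' @param x an [scggm_layer()] or [chain_model()].
#' @param ... unused.
#' @return A one-row tibble of dimensions, sparsity and convergence
#'   information.
#' @export
glance.scggm_layer <- function(x, ...) {
  fi <- x$fit_info %||% list()
  tibble::tibble(
    q_in = nrow(x$Theta), q_out = ncol(x$Lambda),
    n_edges = nnz_offdiag_pairs(x$Lambda),
    nnz_theta = Matrix::nnzero(x$Theta),
    lambda_Lambda = x$lambda_Lambda, lambda_Theta = x$lambda_Theta,
    iterations = fi$iterations %||% NA_integer_,
    converged = fi$converged %||% NA,
    objective = if (length(fi$objective)) utils::tail(fi$objective, 1L)
                else NA_real_,
    kkt = fi$kkt %||% NA_real_)
}

#' @rdname glance.scggm_layer
#' @export
glance.chain_model <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$layer_xy), layer = "xy", .before = 1L),
    dplyr::mutate(glance(x$layer_yz), layer = "yz", .before = 1L))
}

#' Plot a sensitivity-FDR recovery curve
#'
#' @param object a [recovery_curve()] (or the output of
#'   [average_recovery_curves()]).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fdr,
                                       y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false discovery rate", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Heatmap of SNP-on-trait effects
#'
#' @param object an [effect_set()].
#' @param top_k show only the `top_k` highest-scoring SNPs.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.effect_set <- function(object, top_k = 50L, ...) {
  keep <- rank_snps(object, top_k = top_k)$snp_id
  B <- object$B_xz[keep, , drop = FALSE]
  df <- tibble::tibble(
    snp = factor(rep(rownames(B), ncol(B)), levels = rev(keep)),
    trait = rep(colnames(B) %||% paste0("T", seq_len(ncol(B))),
                each = nrow(B)),
    effect = as.numeric(B))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$snp,
                                   fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "trait", y = "SNP", fill = "effect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot robustness AUCs over noise and subsampling
#'
#' @param results tibble from [robustness_suite()].
#' @return A ggplot object (AUC vs noise sd, faceted by parameter block,
#'   colored by sample fraction).
#' @export
plot_robustness <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$noise_sd, y = .data$auc,
                               colour = factor(.data$fraction))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~block) +
    ggplot2::labs(x = "added noise sd", y = "ROC AUC vs reference fit",
                  colour = "sample\nfraction") +
    ggplot2::theme_minimal()
}
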