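#' Indirect (overall) perturbation effects of one layer
#'
#' The overall effect matrix of an sCGGM layer is \eqn{B = -\Theta
#' \Lambda^{-1}}: direct perturbations propagated through the output
#' network.  Computed by sparse triangular solves; no dense inverse of
#' `Lambda` is formed.
#'
#' @param layer an [scggm_layer()].
#' @return A dense effect matrix (inputs x outputs), with dimnames.
#' @export
indirect_effects <- function(layer) {
  Th <- methods::as(layer$Theta, "CsparseMatrix")
  if (nrow(Th) == 0L) return(matrix(0, 0, ncol(layer$Lambda)))
  L <- methods::as(layer$Lambda, "dsCMatrix")
  B <- -Matrix::t(Matrix::solve(L, Matrix::t(Th)))
  B <- as.matrix(B)
  dimnames(B) <- list(layer$input_ids, layer$output_ids)
  B
}

#' @rdname indirect_effects
#' @param model a [chain_model()].
#' @export
indirect_xy <- function(model) {
  indirect_effects(if (inherits(model, "chain_model")) model$layer_xy else model)
}

#' @rdname indirect_effects
#' @export
indirect_yz <- function(model) {
  indirect_effects(if (inherits(model, "chain_model")) model$layer_yz else model)
}

#' Network-mediated SNP effects on traits (with the z | x marginal)
#'
#' Computes the SNP-on-trait effect matrix
#' \eqn{B_{xz} = B_{xy} B_{yz}} together with the marginal covariance of
#' traits given genotype,
#' \eqn{\Lambda_z^{-1} + \Lambda_z^{-1} \Theta_{yz}^\top \Lambda_y^{-1}
#' \Theta_{yz} \Lambda_z^{-1}}, so that
#' \eqn{p(z|x) = N(B_{xz}^\top x, \cdot)}.
#'
#' @param model a [chain_model()].
#' @return List with `B_xy`, `B_yz`, `B_xz`, and `cov_z_given_x`.
#' @export
inf1_snp_trait_effects <- function(model) {
  B_xy <- indirect_xy(model)
  B_yz <- indirect_yz(model)
  B_xz <- B_xy %*% B_yz
  Lam_z <- dense(model$layer_yz$Lambda)
  Th_yz <- dense(model$layer_yz$Theta)
  Lam_y <- dense(model$layer_xy$Lambda)
  iLz_T <- solve(Lam_z, t(Th_yz))               # Lambda_z^-1 Theta_yz'
  Cov <- solve(Lam_z) + iLz_T %*% solve(Lam_y, t(iLz_T))
  Cov <- (Cov + t(Cov)) / 2
  list(B_xy = B_xy, B_yz = B_yz, B_xz = B_xz, cov_z_given_x = Cov)
}

#' Effect matrices of a chain model as an effect set
#'
#' Materializes `B_xy`, `B_yz` and their product `B_xz` (and, when a module
#' assignment is given, the per-module components) into an `"effect_set"`
#' object used by the summarization and ranking helpers.  Entries smaller
#' than `zero_tol` in absolute value are truncated to exact zero (numerical
#' noise floor).
#'
#' @param model a [chain_model()].
#' @param modules optional module assignment (see
#'   [inf2_module_decomposition()]).
#' @param zero_tol truncation threshold for numerical zeros.
#' @return An object of class `"effect_set"`.
#' @export
effect_set <- function(model, modules = NULL, zero_tol = 1e-12) {
  B_xy <- indirect_xy(model)
  B_yz <- indirect_yz(model)
  B_xz <- B_xy %*% B_yz
  B_xy[abs(B_xy) < zero_tol] <- 0
  B_yz[abs(B_yz) < zero_tol] <- 0
  B_xz[abs(B_xz) < zero_tol] <- 0
  out <- structure(list(B_xy = B_xy, B_yz = B_yz, B_xz = B_xz,
                        by_module = NULL), class = "effect_set")
  if (!is.null(modules)) {
    out$by_module <- inf2_module_decomposition(out, modules)
  }
  out
}

#' @export
print.effect_set <- function(x, ...) {
  cat("effect set: B_xy ", nrow(x$B_xy), "x", ncol(x$B_xy),
      ", B_yz ", nrow(x$B_yz), "x", ncol(x$B_yz), "\n", sep = "")
  if (!is.null(x$by_module)) {
    cat("  decomposed over", length(x$by_module), "gene modules\n")
  }
  invisible(x)
}

#' Decompose SNP-on-trait effects over gene modules
#'
#' For disjoint gene modules \eqn{M_1, \dots, M_s} covering all genes, the
#' overall effects decompose exactly as
#' \eqn{B_{xz} = \sum_m B_{xz}^{(M_m)}} with
#' \eqn{B_{xz}^{(M_m)} = \sum_{j \in M_m} [B_{xy}]_{:,j} [B_{yz}]_{j,:}},
#' the component of every SNP-trait effect that is mediated by the genes of
#' module m.
#'
#' @param effects an [effect_set()] (or any list with `B_xy`, `B_yz`).
#' @param modules either a vector of module labels (one per gene, names
#'   optional) or a data frame with columns `gene_id` and `module`.
#' @return A named list of per-module p x r matrices.
#' @export
inf2_module_decomposition <- function(effects, modules) {
  B_xy <- effects$B_xy; B_yz <- effects$B_yz
  q <- ncol(B_xy)
  lab <- normalize_modules(modules, colnames(B_xy), q)
  out <- lapply(split(seq_len(q), lab), function(idx) {
    B_xy[, idx, drop = FALSE] %*% B_yz[idx, , drop = FALSE]
  })
  out
}

normalize_modules <- function(modules, gene_ids, q) {
  if (is.data.frame(modules)) {
    if (!all(c("gene_id", "module") %in% names(modules))) {
      stop("module data frame needs columns gene_id and module")
    }
    lab <- setNames(as.character(modules$module), modules$gene_id)
    if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(q))
    if (!all(gene_ids %in% names(lab))) {
      stop("module assignment does not cover all genes: missing ",
           paste(head(setdiff(gene_ids, names(lab)), 5), collapse = ", "))
    }
    lab <- lab[gene_ids]
  } else {
    lab <- as.character(modules)
    if (length(lab) != q) {
      stop("module assignment does not cover all genes (length ",
           length(lab), " != ", q, ")")
    }
  }
  factor(lab, levels = unique(lab))
}

#' Posterior gene network given traits (moralization)
#'
#' The posterior precision of expression given genotype and traits is
#' \eqn{\Lambda_{y|x,z} = \Lambda_y + \Theta_{yz} \Lambda_z^{-1}
#' \Theta_{yz}^\top}.  The second term introduces edges between genes that
#' influence the same trait (or traits connected in the trait network) —
#' moralization in graphical-model terms.
#'
#' @param model a [chain_model()].
#' @param zero_tol entries of the moralization term below this magnitude
#'   are treated as zero when listing edges.
#' @return List with the matrix `Lambda_y_given_xz` and a tibble `edges`
#'   (columns `gene_i`, `gene_j`, `weight`, `is_moralized`) of all posterior
#'   network edges; `is_moralized` flags pairs absent from `Lambda_y`.
#' @export
inf3_posterior_network <- function(model, zero_tol = 1e-12) {
  Lam <- posterior_precision(model)
  Lam_y <- dense(model$layer_xy$Lambda)
  ids <- model$layer_xy$output_ids
  ut <- which(upper.tri(Lam) & abs(Lam) > zero_tol, arr.ind = TRUE)
  edges <- tibble::tibble(
    gene_i = ids[ut[, 1L]],
    gene_j = ids[ut[, 2L]],
    weight = Lam[ut],
    is_moralized = Lam_y[ut] == 0
  )
  list(Lambda_y_given_xz = Lam, edges = edges)
}

#' Joint sCGGM representation of the chain model
#'
#' Rewrites p(z, y | x) as a single sCGGM over the stacked vector (z, y)
#' with block precision
#' \deqn{\Lambda_{zy} = \begin{pmatrix} \Lambda_z & \Theta_{yz}^\top \\
#'  \Theta_{yz} & \Lambda_y + \Theta_{yz}\Lambda_z^{-1}\Theta_{yz}^\top
#'  \end{pmatrix}}
#' and perturbation \eqn{\Theta_{zy,x} = (0_{p \times r}, \Theta_{xy})}, so
#' that \eqn{p(z, y|x) = N(-\Lambda_{zy}^{-1}\Theta_{zy,x}^\top x,
#' \Lambda_{zy}^{-1})}.
#'
#' @param model a [chain_model()].
#' @return List with `Lambda_zy`, `Theta_zy_x`, `Lambda_y_given_xz`.
#' @export
build_joint <- function(model) {
  Lam_y <- dense(model$layer_xy$Lambda)
  Th_xy <- dense(model$layer_xy$Theta)
  Lam_z <- dense(model$layer_yz$Lambda)
  Th_yz <- dense(model$layer_yz$Theta)
  r <- ncol(Lam_z); q <- ncol(Lam_y); p <- nrow(Th_xy)
  Lyy <- posterior_precision(model)
  Lambda_zy <- rbind(cbind(Lam_z, t(Th_yz)),
                     cbind(Th_yz, Lyy))
  if (!is_pd(Lambda_zy)) {
    stop("assembled joint precision is not positive definite")
  }
  Theta_zy_x <- cbind(matrix(0, p, r), Th_xy)
  list(Lambda_zy = Lambda_zy, Theta_zy_x = Theta_zy_x,
       Lambda_y_given_xz = Lyy)
}

#' Absolute-effect score of a sub-block
#'
#' The summarization score \eqn{S([A]_{I,J}) = \sum_{i \in I, j \in J}
#' |A_{ij}|} used for all module- and trait-group-level summaries of direct
#' and inferred perturbation effects.
#'
#' @param A an effect (or perturbation) matrix.
#' @param rows,cols index vectors (integer, logical or dimname characters);
#'   default all.
#' @return A scalar; an empty group scores 0 with a warning.
#' @export
score_summary <- function(A, rows = NULL, cols = NULL) {
  A <- as.matrix(A)
  rows <- resolve_group(rows, rownames(A), nrow(A))
  cols <- resolve_group(cols, colnames(A), ncol(A))
  if (length(rows) == 0L || length(cols) == 0L) {
    warning("empty row or column group: score is 0")
    return(0)
  }
  sum(abs(A[rows, cols, drop = FALSE]))
}

resolve_group <- function(g, nms, n) {
  if (is.null(g)) return(seq_len(n))
  if (is.character(g)) {
    idx <- match(g, nms)
    if (anyNA(idx)) stop("unknown identifiers: ",
                         paste(g[is.na(idx)], collapse = ", "))
    return(idx)
  }
  if (is.logical(g)) return(which(g))
  as.integer(g)
}

#' Rank SNPs by overall trait effect
#'
#' Orders SNPs by the row score \eqn{S([B_{xz}]_{i,:})} (sum of absolute
#' effects over all traits), descending, with deterministic ties broken by
#' SNP identifier.
#'
#' @param effects an [effect_set()] or a `B_xz` matrix with SNP rownames.
#' @param top_k keep the top k SNPs (default all).
#' @return A tibble with columns `rank`, `snp_id`, `score`.
#' @export
rank_snps <- function(effects, top_k = Inf) {
  B_xz <- if (inherits(effects, "effect_set")) effects$B_xz else as.matrix(effects)
  ids <- rownames(B_xz) %||% paste0("S", seq_len(nrow(B_xz)))
  sc <- rowSums(abs(B_xz))
  ord <- order(-sc, ids)
  keep <- head(ord, min(top_k, length(ord)))
  tibble::tibble(rank = seq_along(keep), snp_id = ids[keep],
                 score = unname(sc[keep]))
}

#' Label gene modules by connected components of the gene network
#'
#' A convenience labeler: genes in the same connected component of the
#' `Lambda_y` support graph share a module label; singletons get their own.
#' (Any externally produced assignment, e.g. from a graph-clustering tool,
#' can be passed to [inf2_module_decomposition()] instead.)
#'
#' @param layer the x->y [scggm_layer()] (or a [chain_model()]).
#' @return An integer vector of module labels, one per gene.
#' @export
module_components <- function(layer) {
  if (inherits(layer, "chain_model")) layer <- layer$layer_xy
  A <- methods::as(methods::as(layer$Lambda, "CsparseMatrix"), "TsparseMatrix")
  q <- ncol(A)
  parent <- seq_len(q)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ii <- A@i + 1L; jj <- A@j + 1L
  keep <- ii != jj & A@x != 0
  for (k in which(keep)) {
    ri <- find(ii[k]); rj <- find(jj[k])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(q), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}
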