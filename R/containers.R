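#' Construct a single sCGGM layer
#'
#' A sparse conditional Gaussian graphical model (sCGGM) layer holds the
#' output-network precision matrix `Lambda` (q_out x q_out, symmetric positive
#' definite) and the direct perturbation map `Theta` (q_in x q_out) from the
#' inputs of the layer to its outputs, together with the L1 penalty weights
#' under which they were (or are to be) estimated.
#'
#' `Lambda` must be exactly symmetric: asymmetries with a relative magnitude
#' of `1e-8` or more raise an error rather than being silently symmetrized.
#' Positive definiteness is checked by a Cholesky factorization.
#'
#' @param Lambda symmetric positive-definite matrix (dense or `Matrix`
#'   sparse), the output network precision.
#' @param Theta matrix (dense or sparse) of direct perturbation effects,
#'   with one row per input and one column per output.  May be `NULL` for a
#'   pure Gaussian graphical model layer with no inputs (then `q_in = 0`).
#' @param lambda_Lambda,lambda_Theta nonnegative penalty weights.
#' @param input_ids,output_ids optional character identifiers; defaults are
#'   taken from dimnames or generated.
#' @param fit_info optional list of fit metadata (objective trajectory,
#'   iteration count, convergence flag).
#' @param check if `FALSE`, skip the (O(q^3)) positive-definiteness check.
#' @return An object of class `"scggm_layer"`.
#' @examples
#' lay <- scggm_layer(diag(2), matrix(c(1, 0), 1, 2))
#' lay$Lambda
#' @export
scggm_layer <- function(Lambda, Theta = NULL,
                        lambda_Lambda = 0, lambda_Theta = 0,
                        input_ids = NULL, output_ids = NULL,
                        fit_info = NULL, check = TRUE) {
  Lambda <- as_symmetric_sparse(Lambda)
  q <- ncol(Lambda)
  if (is.null(Theta)) {
    Theta <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                  dims = c(0L, q))
  }
  Theta <- methods::as(as_csparse(Theta), "generalMatrix")
  if (ncol(Theta) != q) {
    stop("ncol(Theta) [", ncol(Theta), "] must equal dim(Lambda) [", q, "]")
  }
  if (lambda_Lambda < 0 || lambda_Theta < 0) {
    stop("penalty weights must be nonnegative")
  }
  output_ids <- resolve_ids(output_ids, colnames(Lambda), q, "G")
  input_ids <- resolve_ids(input_ids, rownames(Theta), nrow(Theta), "S")
  if (check) {
    assert_pd(Lambda, "Lambda")
  }
  dimnames(Lambda) <- list(output_ids, output_ids)
  dimnames(Theta) <- list(input_ids, output_ids)
  structure(
    list(Lambda = Lambda, Theta = Theta,
         lambda_Lambda = lambda_Lambda, lambda_Theta = lambda_Theta,
         input_ids = input_ids, output_ids = output_ids,
         fit_info = fit_info),
    class = "scggm_layer"
  )
}

#' Construct a two-layer Gaussian chain graph model
#'
#' Stacks an x->y layer (SNPs to genes) and a y->z layer (genes to traits)
#' into the chain model p(y, z | x) = p(y | x) p(z | y).  The gene
#' identifiers must be shared: the outputs of `layer_xy` are the inputs of
#' `layer_yz`.
#'
#' @param layer_xy,layer_yz objects of class `"scggm_layer"`.
#' @param fit_info optional list of fit metadata.
#' @return An object of class `"chain_model"`.
#' @export
chain_model <- function(layer_xy, layer_yz, fit_info = NULL) {
  stopifnot(inherits(layer_xy, "scggm_layer"), inherits(layer_yz, "scggm_layer"))
  if (!identical(layer_xy$output_ids, layer_yz$input_ids)) {
    stop("gene identifiers of the two layers disagree: ",
         "layer_xy outputs must equal layer_yz inputs")
  }
  structure(list(layer_xy = layer_xy, layer_yz = layer_yz,
                 fit_info = fit_info),
            class = "chain_model")
}

#' Bundle genotype, expression and trait data
#'
#' @param X genotype matrix, n x p, minor-allele counts or real dosages.
#' @param Y expression matrix for the observed samples (n_obs x q).
#' @param Z trait matrix, n x r.
#' @param y_rows integer vector mapping rows of `Y` to rows of `X`/`Z`
#'   (the observed-sample index set).  Defaults to all samples, in which
#'   case `nrow(Y)` must equal `nrow(X)`.
#' @return An object of class `"data_bundle"` with elements `X`, `Y`, `Z`,
#'   `y_rows`, and identifier vectors.
#' @export
data_bundle <- function(X, Y, Z, y_rows = NULL) {
  X <- as_plain_matrix(X, "X"); Y <- as_plain_matrix(Y, "Y")
  Z <- as_plain_matrix(Z, "Z")
  n <- nrow(X)
  if (nrow(Z) != n) stop("X and Z must have the same number of rows")
  if (is.null(y_rows)) {
    if (nrow(Y) != n) {
      stop("nrow(Y) != nrow(X); supply y_rows for semi-supervised data")
    }
    y_rows <- seq_len(n)
  }
  y_rows <- as.integer(y_rows)
  if (length(y_rows) != nrow(Y)) stop("length(y_rows) must equal nrow(Y)")
  if (anyDuplicated(y_rows) || any(y_rows < 1L) || any(y_rows > n)) {
    stop("y_rows must be distinct indices into 1..n")
  }
  for (nm in c("X", "Y", "Z")) {
    if (anyNA(get(nm))) stop("missing values inside ", nm,
                             " are not allowed (Y may only miss whole samples)")
  }
  structure(list(
    X = X, Y = Y, Z = Z, y_rows = y_rows,
    sample_ids = rownames(X) %||% paste0("s", seq_len(n)),
    snp_ids = colnames(X) %||% paste0("S", seq_len(ncol(X))),
    gene_ids = colnames(Y) %||% paste0("G", seq_len(ncol(Y))),
    trait_ids = colnames(Z) %||% paste0("T", seq_len(ncol(Z)))
  ), class = "data_bundle")
}

#' @export
print.scggm_layer <- function(x, ...) {
  q <- ncol(x$Lambda)
  cat("sCGGM layer: ", nrow(x$Theta), " inputs -> ", q, " outputs\n", sep = "")
  cat("  network edges (offdiag pairs): ", nnz_offdiag_pairs(x$Lambda),
      ", direct perturbations: ", Matrix::nnzero(x$Theta), "\n", sep = "")
  cat("  penalties: lambda_Lambda = ", format(x$lambda_Lambda),
      ", lambda_Theta = ", format(x$lambda_Theta), "\n", sep = "")
  if (!is.null(x$fit_info)) {
    cat("  fit: ", x$fit_info$iterations, " iterations, converged = ",
        isTRUE(x$fit_info$converged), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.chain_model <- function(x, ...) {
  cat("Gaussian chain graph model (x -> y -> z)\n")
  cat("p =", nrow(x$layer_xy$Theta), " q =", ncol(x$layer_xy$Lambda),
      " r =", ncol(x$layer_yz$Lambda), "\n")
  invisible(x)
}

#' @export
print.data_bundle <- function(x, ...) {
  cat("data bundle: n =", nrow(x$X), " (", length(x$y_rows),
      "with expression )  p =", ncol(x$X), " q =", ncol(x$Y),
      " r =", ncol(x$Z), "\n")
  invisible(x)
}

## ---- internal helpers -------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

as_plain_matrix <- function(x, nm) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is(x, "Matrix")) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop(nm, " must be a numeric matrix")
  storage.mode(x) <- "double"
  x
}

resolve_ids <- function(ids, dn, n, prefix) {
  ids <- ids %||% dn %||% (if (n > 0) paste0(prefix, seq_len(n)) else character())
  ids <- as.character(ids)
  if (length(ids) != n) stop("identifier vector has wrong length")
  if (anyDuplicated(ids)) stop("duplicate identifiers: ",
                               ids[anyDuplicated(ids)])
  ids
}

as_csparse <- function(x) {
  if (is.matrix(x)) x <- Matrix::Matrix(x, sparse = TRUE)
  methods::as(x, "CsparseMatrix")
}

# Coerce to sparse symmetric, erroring on material asymmetry.
as_symmetric_sparse <- function(Lambda) {
  L <- as_csparse(Lambda)
  if (nrow(L) != ncol(L)) stop("Lambda must be square")
  if (!is(L, "symmetricMatrix")) {
    asym <- max(abs(L - Matrix::t(L)))
    scale <- max(abs(L@x), 1)
    if (asym >= 1e-8 * scale) {
      stop("Lambda is asymmetric (max |L - t(L)| = ", format(asym),
           "); refusing to symmetrize silently")
    }
    L <- Matrix::forceSymmetric(L)
  }
  methods::as(L, "dsCMatrix")
}

assert_pd <- function(Lambda, nm = "Lambda") {
  ok <- tryCatch({
    Matrix::Cholesky(methods::as(Lambda, "dsCMatrix"), LDL = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(nm, " is not positive definite (Cholesky failed)")
  invisible(TRUE)
}

is_pd <- function(Lambda) {
  tryCatch({
    if (is(Lambda, "Matrix")) {
      Matrix::Cholesky(methods::as(Matrix::forceSymmetric(Lambda), "dsCMatrix"),
                       LDL = FALSE)
    } else {
      chol(Lambda)
    }
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
}

nnz_offdiag_pairs <- function(Lambda) {
  L <- methods::as(methods::as(Lambda, "CsparseMatrix"), "TsparseMatrix")
  sum(L@i < L@j & L@x != 0)
}

# dense symmetric-safe conversions used by the solvers
dense <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

sum_abs_offdiag <- function(A) {
  if (is(A, "Matrix")) {
    sum(abs(A)) - sum(abs(Matrix::diag(A)))
  } else {
    sum(abs(A)) - sum(abs(diag(A)))
  }
}
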