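#' Read a TSV matrix with sample and feature identifiers
#'
#' Expects a header row of feature identifiers and a first column of sample
#' identifiers.  Ragged rows, duplicate identifiers and non-numeric cells
#' are errors that name the offending row or column.
#'
#' @param path file path.
#' @param orientation `"samples_by_features"` (default) or
#'   `"features_by_samples"` (the matrix is transposed after reading so the
#'   result is always samples x features).
#' @return A numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path,
                            orientation = c("samples_by_features",
                                            "features_by_samples")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1L]]
  ncol_exp <- length(hdr)
  feat <- hdr[-1L]
  if (anyDuplicated(feat)) {
    stop("duplicate feature id: ", feat[anyDuplicated(feat)])
  }
  body <- fields[-1L]
  n <- length(body)
  if (!n) {
    M <- matrix(numeric(), 0, ncol_exp - 1L,
                dimnames = list(NULL, feat))
    return(if (orientation == "features_by_samples") t(M) else M)
  }
  bad <- which(lengths(body) != ncol_exp)
  if (length(bad)) stop("ragged row ", bad[1L] + 1L, " in ", path,
                        " (expected ", ncol_exp, " fields, found ",
                        lengths(body)[bad[1L]], ")")
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate sample id: ",
                               ids[anyDuplicated(ids)])
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(ncol_exp - 1L)))
  vals <- matrix(vals, nrow = ncol_exp - 1L)
  if (anyNA(vals)) {
    at <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at row '", ids[at[2L]], "', column '",
         feat[at[1L]], "'")
  }
  M <- t(vals)
  dimnames(M) <- list(ids, feat)
  if (orientation == "features_by_samples") M <- t(M)
  M
}

#' Write a matrix as an identifier-headed TSV
#'
#' @param M numeric matrix with dimnames (generated if absent).
#' @param path file path.
#' @param id_header name of the identifier column.
#' @export
write_matrix_tsv <- function(M, path, id_header = "id") {
  M <- as.matrix(M)
  rn <- rownames(M) %||% paste0("s", seq_len(nrow(M)))
  cn <- colnames(M) %||% paste0("f", seq_len(ncol(M)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_header, cn), collapse = "\t"), con)
  body <- apply(M, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rn, body, sep = "\t"), con)
  invisible(path)
}

#' Read a PLINK .raw additive-coded genotype file
#'
#' Parses the standard header (`FID IID PAT MAT SEX PHENOTYPE` followed by
#' SNP columns), returning the n x p dosage matrix with IID rownames and
#' the SNP column names in file order.  `NA` dosages are imputed to the
#' column mean, with the imputed count reported as a message.
#'
#' @param path file path.
#' @return A numeric matrix; attribute `"n_imputed"` carries the NA count.
#' @export
read_plink_raw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           na.strings = c("NA"), stringsAsFactors = FALSE)
  need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (ncol(tab) < 7L || !identical(names(tab)[1:6], need)) {
    stop("malformed .raw header: expected columns ",
         paste(need, collapse = " "), " followed by SNPs")
  }
  G <- as.matrix(tab[, -(1:6), drop = FALSE])
  storage.mode(G) <- "double"
  rownames(G) <- tab$IID
  n_na <- sum(is.na(G))
  if (n_na > 0) {
    message("imputing ", n_na, " missing dosages to column means")
    for (j in which(colSums(is.na(G)) > 0)) {
      G[is.na(G[, j]), j] <- mean(G[, j], na.rm = TRUE)
    }
  }
  attr(G, "n_imputed") <- n_na
  G
}

bundle_version <- "1"

#' Write / read a fitted chain model as a text bundle
#'
#' The bundle directory holds the four sparse parameter matrices in Matrix
#' Market coordinate format (`Lambda_y.mtx`, `Lambda_z.mtx` with symmetric
#' storage; `Theta_xy.mtx`, `Theta_yz.mtx` general) and a `model.json` with
#' identifiers, penalty weights and fit metadata.  Values are written at
#' full double precision, so a round trip reproduces the model exactly.
#'
#' @param model a [chain_model()].
#' @param path bundle directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_model_bundle <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_mm_sym(model$layer_xy$Lambda, file.path(path, "Lambda_y.mtx"))
  write_mm_gen(model$layer_xy$Theta, file.path(path, "Theta_xy.mtx"))
  write_mm_sym(model$layer_yz$Lambda, file.path(path, "Lambda_z.mtx"))
  write_mm_gen(model$layer_yz$Theta, file.path(path, "Theta_yz.mtx"))
  meta <- list(
    format_version = bundle_version,
    package_version = as.character(utils::packageVersion("perturbnet")),
    snp_ids = model$layer_xy$input_ids,
    gene_ids = model$layer_xy$output_ids,
    trait_ids = model$layer_yz$output_ids,
    lambdas = list(
      lambda_Lambda_y = model$layer_xy$lambda_Lambda,
      lambda_Theta_xy = model$layer_xy$lambda_Theta,
      lambda_Lambda_z = model$layer_yz$lambda_Lambda,
      lambda_Theta_yz = model$layer_yz$lambda_Theta),
    fit_info_xy = serializable_fit_info(model$layer_xy$fit_info),
    fit_info_yz = serializable_fit_info(model$layer_yz$fit_info))
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

serializable_fit_info <- function(fi) {
  if (is.null(fi)) return(NULL)
  fi[vapply(fi, function(e) is.numeric(e) || is.logical(e) ||
              is.character(e), logical(1))]
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "model.json"),
                              simplifyVector = TRUE)
  if (!identical(as.character(meta$format_version), bundle_version)) {
    warning("model bundle format version '", meta$format_version,
            "' differs from '", bundle_version, "'; attempting best-effort load")
  }
  Lam_y <- read_mm_sym(file.path(path, "Lambda_y.mtx"))
  Th_xy <- read_mm_gen(file.path(path, "Theta_xy.mtx"))
  Lam_z <- read_mm_sym(file.path(path, "Lambda_z.mtx"))
  Th_yz <- read_mm_gen(file.path(path, "Theta_yz.mtx"))
  ids <- lapply(meta[c("snp_ids", "gene_ids", "trait_ids")], as.character)
  if (ncol(Lam_y) != length(ids$gene_ids) ||
      nrow(Th_xy) != length(ids$snp_ids) ||
      ncol(Lam_z) != length(ids$trait_ids)) {
    stop("bundle dimension mismatch between matrices and model.json")
  }
  lam <- meta$lambdas
  chain_model(
    scggm_layer(Lam_y, Th_xy, lam$lambda_Lambda_y, lam$lambda_Theta_xy,
                input_ids = ids$snp_ids, output_ids = ids$gene_ids,
                fit_info = meta$fit_info_xy),
    scggm_layer(Lam_z, Th_yz, lam$lambda_Lambda_z, lam$lambda_Theta_yz,
                input_ids = ids$gene_ids, output_ids = ids$trait_ids,
                fit_info = meta$fit_info_yz))
}

## Matrix Market writers at full precision (readMM parses the result).
write_mm_sym <- function(L, path) {
  T <- methods::as(methods::as(Matrix::forceSymmetric(L), "CsparseMatrix"),
                   "TsparseMatrix")
  ## a symmetric sparse matrix stores one triangle; MM symmetric format
  ## wants row >= column, so orient every stored entry accordingly
  ii <- pmax(T@i, T@j) + 1L
  jj <- pmin(T@i, T@j) + 1L
  write_mm_body(path, "symmetric", nrow(L), ncol(L), ii, jj, T@x)
}

write_mm_gen <- function(M, path) {
  T <- methods::as(methods::as(M, "CsparseMatrix"), "TsparseMatrix")
  write_mm_body(path, "general", nrow(M), ncol(M),
                T@i + 1L, T@j + 1L, T@x)
}

write_mm_body <- function(path, symmetry, nr, nc, ii, jj, xx) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("%%MatrixMarket matrix coordinate real", symmetry),
               paste(nr, nc, length(ii))), con)
  if (length(ii)) {
    writeLines(sprintf("%d %d %.17g", ii, jj, xx), con)
  }
  invisible(path)
}

read_mm_sym <- function(path) {
  M <- Matrix::readMM(path)
  M <- methods::as(M, "CsparseMatrix")
  if (!is(M, "symmetricMatrix")) {
    asym <- max(abs(M - Matrix::t(M)))
    if (asym >= 1e-8 * max(abs(M@x), 1)) {
      stop("network matrix in ", path, " is asymmetric (max deviation ",
           format(asym), ")")
    }
    M <- Matrix::forceSymmetric(M)
  }
  methods::as(M, "dsCMatrix")
}

read_mm_gen <- function(path) {
  methods::as(methods::as(Matrix::readMM(path), "CsparseMatrix"),
              "generalMatrix")
}

#' Write a reproducibility manifest for a run
#'
#' Records the command, configuration, seed, package version and input-file
#' checksums alongside results so deterministic runs can be reproduced
#' bit for bit.
#'
#' @param dir output directory.
#' @param command command name.
#' @param config named list of options (must be JSON-serializable).
#' @param seed the seed in effect.
#' @param inputs character vector of input file paths (checksummed).
#' @return Path of the manifest, invisibly.
#' @export
write_run_manifest <- function(dir, command, config = list(), seed = NULL,
                               inputs = character()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("perturbnet")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    inputs = if (length(inputs)) {
      lapply(setNames(inputs, inputs), function(f) {
        list(md5 = unname(tools::md5sum(f)))
      })
    } else NULL)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
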