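#' Simulation configuration for ground-truth models
#'
#' Defaults reproduce the study conditions of the simulation design the
#' package targets: scale-free modular networks with 50-node modules,
#' average degree 3, 90% of edges within modules, edge weights drawn from
#' N(0.5, 0.1^2), diagonals set so the minimum eigenvalue is exactly 0.3;
#' sparse module-targeted perturbations with exactly 3 perturbants per
#' target, magnitudes N(0.5, 0.1^2) and random signs; 10% of SNPs
#' trait-perturbing; half of the gene modules perturbed by SNPs and 20%
#' of gene modules silent towards traits; gene modules wired 90%/10% to
#' their primary/secondary trait module; regression-family noise variance
#' 0.5.
#'
#' @param p,q,r numbers of SNPs, genes, and traits.
#' @param module_size nodes per network module (the last module absorbs any
#'   remainder).
#' @param avg_degree target mean node degree of each network.
#' @param within_module_edge_frac fraction of network edges inside modules.
#' @param edge_weight_mean,edge_weight_sd Gaussian edge-weight parameters.
#' @param min_eigenvalue the minimum eigenvalue the precision diagonals are
#'   shifted to.
#' @param perturbants_per_target direct perturbants per output column.
#' @param sign_flip_prob probability a perturbation weight is negative.
#' @param frac_snps_perturbing fraction of SNPs allowed to perturb genes.
#' @param frac_gene_modules_perturbed fraction of gene modules receiving
#'   SNP perturbation.
#' @param frac_gene_modules_trait_silent fraction of gene modules with no
#'   influence on traits.
#' @param trait_wiring primary/secondary wiring fractions of a gene module
#'   across trait modules.
#' @param noise_variance residual variance of the regression family.
#' @param network_sign_flip also apply random signs to network edge weights
#'   (off by default; signs are documented for the perturbation parameters
#'   only).
#' @param family `"chain"` (two stacked sCGGMs), `"regression"` (two-layer
#'   linear model with independent outputs), or `"ggm"` (networks without
#'   perturbation).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(p = 10000L, q = 5000L, r = 100L,
                       module_size = 50L, avg_degree = 3,
                       within_module_edge_frac = 0.9,
                       edge_weight_mean = 0.5, edge_weight_sd = 0.1,
                       min_eigenvalue = 0.3,
                       perturbants_per_target = 3L,
                       sign_flip_prob = 0.5,
                       frac_snps_perturbing = 0.1,
                       frac_gene_modules_perturbed = 0.5,
                       frac_gene_modules_trait_silent = 0.2,
                       trait_wiring = c(0.9, 0.1),
                       noise_variance = 0.5,
                       network_sign_flip = FALSE,
                       family = c("chain", "regression", "ggm")) {
  family <- match.arg(family)
  stopifnot(p >= 1, q >= 2, r >= 1, module_size >= 2,
            avg_degree > 0, edge_weight_sd > 0,
            within_module_edge_frac >= 0, within_module_edge_frac <= 1,
            sign_flip_prob >= 0, sign_flip_prob <= 1,
            frac_snps_perturbing > 0, frac_snps_perturbing <= 1,
            min_eigenvalue > 0, noise_variance > 0)
  structure(as.list(environment()), class = "sim_config")
}

module_labels <- function(dim, module_size) {
  n_mod <- max(1L, dim %/% module_size)
  lab <- rep(seq_len(n_mod), each = module_size, length.out = dim)
  lab[lab > n_mod] <- n_mod
  lab
}

#' Scale-free modular precision matrix
#'
#' Generates a sparse positive-definite precision matrix whose support is a
#' scale-free-style network: edges are added one at a time with endpoint
#' probabilities proportional to (degree + 1), an exact
#' `round(within_module_edge_frac * E)` of them constrained within modules
#' and the rest between modules, for `E = round(avg_degree * dim / 2)`
#' total edges.  Edge weights are N(edge_weight_mean, edge_weight_sd^2) and
#' the diagonal is shifted so the minimum eigenvalue equals
#' `min_eigenvalue` (to within eigen-solver precision).
#'
#' @param dim matrix dimension.
#' @param config a [sim_config()].
#' @return A `dsCMatrix` with a `"modules"` attribute (integer labels).
#' @export
make_scalefree_precision <- function(dim, config = sim_config()) {
  mod <- module_labels(dim, config$module_size)
  n_mod <- max(mod)
  E <- round(config$avg_degree * dim / 2)
  if (E > dim * (dim - 1) / 2) stop("avg_degree infeasible for dim ", dim)
  E_w <- if (n_mod > 1L) round(config$within_module_edge_frac * E) else E
  max_within <- sum(vapply(split(mod, mod), function(m) {
    k <- length(m); k * (k - 1) / 2
  }, numeric(1)))
  if (E_w > max_within) stop("within-module edge count infeasible: ",
                             "modules too small for avg_degree")
  E_b <- E - E_w
  deg <- numeric(dim)
  seen <- new.env(hash = TRUE, size = 4L * E)
  edges_i <- integer(E); edges_j <- integer(E)
  n_acc <- 0L
  draw_pair <- function(within) {
    for (try in 1:200) {
      i <- sample.int(dim, 1L, prob = deg + 1)
      cand <- if (within) which(mod == mod[i]) else which(mod != mod[i])
      cand <- cand[cand != i]
      if (!length(cand)) next
      j <- if (length(cand) == 1L) cand else
        sample(cand, 1L, prob = deg[cand] + 1)
      a <- min(i, j); b <- max(i, j)
      key <- paste0(a, "_", b)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        return(c(a, b))
      }
    }
    NULL
  }
  for (w in c(rep(TRUE, E_w), rep(FALSE, E_b))) {
    pr <- draw_pair(w)
    if (is.null(pr)) next  # saturated; drop the edge
    n_acc <- n_acc + 1L
    edges_i[n_acc] <- pr[1L]; edges_j[n_acc] <- pr[2L]
    deg[pr] <- deg[pr] + 1
  }
  edges_i <- edges_i[seq_len(n_acc)]; edges_j <- edges_j[seq_len(n_acc)]
  w <- stats::rnorm(n_acc, config$edge_weight_mean, config$edge_weight_sd)
  if (config$network_sign_flip) {
    w <- w * sample(c(-1, 1), n_acc, replace = TRUE,
                    prob = c(config$sign_flip_prob, 1 - config$sign_flip_prob))
  }
  A <- Matrix::sparseMatrix(i = c(edges_i, edges_j), j = c(edges_j, edges_i),
                            x = c(w, w), dims = c(dim, dim))
  ev_min <- min(eigen(as.matrix(A), symmetric = TRUE,
                      only.values = TRUE)$values)
  P <- A + Matrix::Diagonal(dim, config$min_eigenvalue - ev_min)
  P <- methods::as(Matrix::forceSymmetric(P), "dsCMatrix")
  attr(P, "modules") <- mod
  P
}

#' Sparse module-targeted perturbation matrix
#'
#' Builds a perturbation map in which every perturbed output column has
#' exactly `perturbants_per_target` nonzero inputs, with magnitudes
#' N(edge_weight_mean, edge_weight_sd^2) and signs negative with
#' probability `sign_flip_prob`.  For the SNP-to-gene layer
#' (`layer = "xy"`) inputs are drawn only from the designated perturbing
#' SNP set and columns in unperturbed gene modules stay zero.  For the
#' gene-to-trait layer (`layer = "yz"`) each non-silent gene module is
#' assigned a primary trait module and each trait draws its perturbant
#' genes from gene modules wired to its trait module with the
#' `trait_wiring` (90/10) split.
#'
#' @param n_in,n_out input/output dimensions.
#' @param modules_out integer module labels of the outputs.
#' @param config a [sim_config()].
#' @param layer `"xy"` or `"yz"`.
#' @param perturbing_in for `"xy"`: indices of SNPs allowed to perturb
#'   (default: a random `frac_snps_perturbing` fraction).
#' @param modules_in for `"yz"`: module labels of the input genes.
#' @return A `dgCMatrix`; attributes record the perturbing inputs and the
#'   perturbed output modules.
#' @export
make_perturbation <- function(n_in, n_out, modules_out,
                              config = sim_config(),
                              layer = c("xy", "yz"),
                              perturbing_in = NULL, modules_in = NULL) {
  layer <- match.arg(layer)
  k <- config$perturbants_per_target
  if (layer == "xy") {
    if (is.null(perturbing_in)) {
      n_pert <- min(n_in, max(k, round(config$frac_snps_perturbing * n_in)))
      perturbing_in <- sort(sample.int(n_in, n_pert))
    }
    if (length(perturbing_in) < k) {
      stop("designated perturbing set (", length(perturbing_in),
           ") smaller than perturbants_per_target (", k, ")")
    }
    n_mod <- max(modules_out)
    n_pert_mod <- round(config$frac_gene_modules_perturbed * n_mod)
    pert_mod <- sort(sample.int(n_mod, n_pert_mod))
    target_cols <- which(modules_out %in% pert_mod)
    pick <- function(col) sample(perturbing_in, k)
  } else {
    if (is.null(modules_in)) stop("modules_in required for the yz layer")
    n_gmod <- max(modules_in)
    n_silent <- round(config$frac_gene_modules_trait_silent * n_gmod)
    silent <- if (n_silent > 0) sort(sample.int(n_gmod, n_silent)) else integer()
    active_mod <- setdiff(seq_len(n_gmod), silent)
    if (!length(active_mod)) stop("all gene modules are trait-silent")
    n_tmod <- max(modules_out)
    primary <- setNames(rep(seq_len(n_tmod), length.out = length(active_mod)),
                        active_mod)
    target_cols <- seq_len(n_out)
    pert_mod <- active_mod
    perturbing_in <- which(modules_in %in% active_mod)
    pick <- function(col) {
      tm <- modules_out[col]
      own <- as.integer(names(primary))[primary == tm]
      other <- setdiff(active_mod, own)
      vapply(seq_len(k), function(.) {
        use_own <- length(other) == 0L || length(own) == 0L ||
          stats::runif(1) < config$trait_wiring[1L]
        mods <- if (length(own) && (use_own || !length(other))) own else other
        cand <- which(modules_in %in% mods)
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
    }
  }
  ii <- integer(0); jj <- integer(0)
  for (col in target_cols) {
    rows <- unique(pick(col))
    while (length(rows) < k) {  # resample duplicates for yz picks
      rows <- unique(c(rows, pick(col)))
    }
    rows <- rows[seq_len(k)]
    ii <- c(ii, rows); jj <- c(jj, rep(col, k))
  }
  mag <- stats::rnorm(length(ii), config$edge_weight_mean,
                      config$edge_weight_sd)
  sgn <- ifelse(stats::runif(length(ii)) < config$sign_flip_prob, -1, 1)
  Th <- Matrix::sparseMatrix(i = ii, j = jj, x = abs(mag) * sgn,
                             dims = c(n_in, n_out))
  attr(Th, "perturbing_in") <- perturbing_in
  attr(Th, "perturbed_modules") <- pert_mod
  Th
}

#' Ground-truth model for simulation
#'
#' Draws a full ground-truth model of the requested family together with
#' the indicator masks used for recovery scoring: true network edges, true
#' direct perturbations, and true SNP-to-trait paths (nonzero entries of
#' the composed effect matrix).
#'
#' @param config a [sim_config()].
#' @param seed integer seed (the generator is fully reproducible).
#' @return An object of class `"ground_truth"`: list with `family`,
#'   `model` (a [chain_model()] for the chain/ggm families) or `W1`, `W2`,
#'   `sigma2` (regression family), module labels, and `masks`.
#' @export
make_ground_truth <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- config$p; q <- config$q; r <- config$r
  Lam_y <- make_scalefree_precision(q, config)
  Lam_z <- make_scalefree_precision(r, config)
  mod_y <- attr(Lam_y, "modules"); mod_z <- attr(Lam_z, "modules")
  perturb <- config$family != "ggm"
  Th_xy <- if (perturb) {
    make_perturbation(p, q, mod_y, config, layer = "xy")
  } else Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(p, q))
  Th_yz <- if (perturb) {
    make_perturbation(q, r, mod_z, config, layer = "yz", modules_in = mod_y)
  } else Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(q, r))
  out <- list(family = config$family, config = config,
              modules_y = mod_y, modules_z = mod_z,
              perturbing_snps = attr(Th_xy, "perturbing_in"))
  if (config$family == "regression") {
    out$W1 <- as.matrix(Th_xy); out$W2 <- as.matrix(Th_yz)
    out$sigma2 <- config$noise_variance
    B_xz <- out$W1 %*% out$W2
    out$masks <- list(
      theta_xy = as.matrix(Th_xy != 0), theta_yz = as.matrix(Th_yz != 0),
      snp_trait = B_xz != 0)
  } else {
    snp_ids <- paste0("S", seq_len(p)); gene_ids <- paste0("G", seq_len(q))
    trait_ids <- paste0("T", seq_len(r))
    model <- chain_model(
      scggm_layer(Lam_y, Th_xy, check = FALSE,
                  input_ids = snp_ids, output_ids = gene_ids),
      scggm_layer(Lam_z, Th_yz, check = FALSE,
                  input_ids = gene_ids, output_ids = trait_ids))
    out$model <- model
    B_xz <- indirect_xy(model) %*% indirect_yz(model)
    out$masks <- list(
      net_y = offdiag_mask(Lam_y), net_z = offdiag_mask(Lam_z),
      theta_xy = as.matrix(Th_xy != 0), theta_yz = as.matrix(Th_yz != 0),
      snp_trait = abs(B_xz) > 1e-10)
  }
  structure(out, class = "ground_truth")
}

offdiag_mask <- function(L) {
  M <- as.matrix(L) != 0
  diag(M) <- FALSE
  M
}

#' Independent-SNP genotype simulator
#'
#' Minor-allele counts drawn as Binomial(2, MAF) per SNP with MAFs uniform
#' on `maf_range`.  No linkage-disequilibrium structure is simulated.
#'
#' @param p,n numbers of SNPs and samples.
#' @param maf_range minor-allele-frequency range, inside (0, 0.5].
#' @param seed optional integer seed.
#' @return An n x p matrix with values in \{0, 1, 2\} and a `"maf"`
#'   attribute.
#' @export
genotype_simulator <- function(p, n, maf_range = c(0.1, 0.5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5)
  maf <- stats::runif(p, maf_range[1], maf_range[2])
  X <- matrix(stats::rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  colnames(X) <- paste0("S", seq_len(p))
  attr(X, "maf") <- maf
  X
}

#' Sample a dataset from a ground-truth model
#'
#' Ancestral sampling: for the chain family
#' \eqn{y \sim N(B_{xy}^\top x, \Lambda_y^{-1})} then
#' \eqn{z \sim N(B_{yz}^\top y, \Lambda_z^{-1})}; for the regression family
#' linear responses with noise variance `sigma2`; for the ggm family draws
#' from the two networks without perturbation.
#'
#' @param truth a [make_ground_truth()] object.
#' @param n number of samples.
#' @param X optional genotype matrix (n x p); simulated with
#'   [genotype_simulator()] when absent.
#' @param seed optional integer seed (identical seeds give bit-identical
#'   datasets).
#' @return A [data_bundle()].
#' @export
sample_dataset <- function(truth, n, X = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$config
  if (is.null(X)) X <- genotype_simulator(cfg$p, n)
  stopifnot(nrow(X) == n, ncol(X) == cfg$p)
  if (truth$family == "regression") {
    Y <- X %*% truth$W1 +
      matrix(stats::rnorm(n * cfg$q, sd = sqrt(truth$sigma2)), n, cfg$q)
    Z <- Y %*% truth$W2 +
      matrix(stats::rnorm(n * cfg$r, sd = sqrt(truth$sigma2)), n, cfg$r)
  } else {
    model <- truth$model
    B_xy <- indirect_xy(model); B_yz <- indirect_yz(model)
    Y <- X %*% B_xy + sample_gaussian_prec(n, model$layer_xy$Lambda)
    Z <- Y %*% B_yz + sample_gaussian_prec(n, model$layer_yz$Lambda)
  }
  colnames(Y) <- paste0("G", seq_len(cfg$q))
  colnames(Z) <- paste0("T", seq_len(cfg$r))
  data_bundle(as.matrix(X), as.matrix(Y), as.matrix(Z))
}

# n draws from N(0, Lambda^-1): solve R e = z for upper Cholesky R.
sample_gaussian_prec <- function(n, Lambda) {
  R <- chol(dense(Lambda))
  q <- ncol(R)
  Zm <- matrix(stats::rnorm(n * q), q, n)
  t(backsolve(R, Zm))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground truth (", x$family, " family): p=", x$config$p,
      " q=", x$config$q, " r=", x$config$r, "\n", sep = "")
  invisible(x)
}
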