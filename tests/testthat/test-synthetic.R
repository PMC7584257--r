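test_that("scale-free precision hits the target minimum eigenvalue exactly", {
  cfg <- sim_config(p = 10, q = 100, r = 10, module_size = 20)
  set.seed(101)
  P <- make_scalefree_precision(100, cfg)
  ev <- eigen(as.matrix(P), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(abs(min(ev) - 0.3), 1e-8)
  expect_true(perturbnet:::is_pd(P))
})

test_that("network degree, module fraction and edge weights match the design", {
  cfg <- sim_config(p = 10, q = 500, r = 10)
  set.seed(102)
  P <- make_scalefree_precision(500, cfg)
  mod <- attr(P, "modules")
  T <- methods::as(methods::as(P, "CsparseMatrix"), "TsparseMatrix")
  edges <- which(T@i < T@j & T@x != 0)
  n_edges <- length(edges)
  mean_deg <- 2 * n_edges / 500
  expect_lt(abs(mean_deg - 3) / 3, 0.1)
  within <- mean(mod[T@i[edges] + 1L] == mod[T@j[edges] + 1L])
  expect_lt(abs(within - 0.9), 0.03)
  w <- T@x[edges]
  expect_lt(abs(mean(w) - 0.5), 0.02)     # N(0.5, 0.1^2) weights
  expect_lt(abs(sd(w) - 0.1), 0.02)
  ## degree distribution is heavy-tailed: hubs well above the mean exist
  deg <- tabulate(c(T@i[edges], T@j[edges]) + 1L, nbins = 500)
  expect_gt(max(deg), 9)
})

test_that("perturbation matrices have exactly 3 perturbants per target and balanced signs", {
  cfg <- sim_config(p = 300, q = 200, r = 10, module_size = 50)
  set.seed(103)
  mod_y <- perturbnet:::module_labels(200, 50)
  Th <- make_perturbation(300, 200, mod_y, cfg, layer = "xy")
  nnz_col <- Matrix::colSums(Th != 0)
  pert_mod <- attr(Th, "perturbed_modules")
  expect_true(all(nnz_col[mod_y %in% pert_mod] == 3))
  expect_true(all(nnz_col[!mod_y %in% pert_mod] == 0))
  expect_length(pert_mod, 2L)             # half of the 4 gene modules
  ## all perturbants come from the designated SNP set
  T <- methods::as(Th, "TsparseMatrix")
  expect_true(all((T@i + 1L) %in% attr(Th, "perturbing_in")))
  expect_length(attr(Th, "perturbing_in"), 30L)   # 10% of 300 SNPs
  ## sign balance ~ 0.5
  expect_lt(abs(mean(T@x < 0) - 0.5), 0.08)
  ## magnitudes N(0.5, 0.1^2)
  expect_lt(abs(mean(abs(T@x)) - 0.5), 0.03)
})

test_that("trait-layer wiring respects silent modules and the 90/10 split", {
  cfg <- sim_config(p = 10, q = 200, r = 100, module_size = 50,
                    frac_gene_modules_trait_silent = 0.25)
  set.seed(104)
  mod_y <- perturbnet:::module_labels(200, 50)
  mod_z <- perturbnet:::module_labels(100, 50)
  Th <- make_perturbation(200, 100, mod_z, cfg, layer = "yz",
                          modules_in = mod_y)
  expect_true(all(Matrix::colSums(Th != 0) == 3))
  ## silent gene modules never perturb traits
  active <- attr(Th, "perturbed_modules")
  silent <- setdiff(seq_len(4), active)
  expect_length(silent, 1L)
  T <- methods::as(Th, "TsparseMatrix")
  expect_false(any(mod_y[T@i + 1L] %in% silent))
  ## most perturbants of a trait come from modules primary to its module
  primary <- setNames(rep(1:2, length.out = length(active)), active)
  frac_own <- mean(vapply(seq_len(100), function(tr) {
    genes <- T@i[T@j + 1L == tr] + 1L
    own_mods <- as.integer(names(primary))[primary == mod_z[tr]]
    mean(mod_y[genes] %in% own_mods)
  }, numeric(1)))
  expect_gt(frac_own, 0.8)
  expect_lt(frac_own, 0.98)
})

test_that("genotype simulation is reproducible with valid allele counts", {
  X1 <- genotype_simulator(20, 100, seed = 105)
  X2 <- genotype_simulator(20, 100, seed = 105)
  expect_identical(X1, X2)
  expect_true(all(X1 %in% 0:2))
  X3 <- genotype_simulator(5, 4000, maf_range = c(0.4999, 0.5), seed = 106)
  expect_lt(max(abs(colMeans(X3) - 1)), 0.06)
})

test_that("sampled datasets have the model-implied residual structure", {
  cfg <- sim_config(p = 6, q = 5, r = 4, module_size = 5,
                    frac_snps_perturbing = 1)
  truth <- make_ground_truth(cfg, seed = 107)
  ## residual covariance matches Lambda_y^-1 at large n
  n <- 1e5
  d <- sample_dataset(truth, n = n, seed = 108)
  B_xy <- indirect_xy(truth$model)
  E <- d$Y - d$X %*% B_xy
  S_emp <- crossprod(scale(E, scale = FALSE)) / n
  S_true <- solve(as.matrix(truth$model$layer_xy$Lambda))
  se <- sqrt((outer(diag(S_true), diag(S_true)) + S_true^2) / n)
  expect_true(all(abs(S_emp - S_true) < 4 * se))
  ## identical seeds give bit-identical datasets
  d1 <- sample_dataset(truth, n = 50, seed = 109)
  d2 <- sample_dataset(truth, n = 50, seed = 109)
  expect_identical(d1$Y, d2$Y); expect_identical(d1$X, d2$X)
})

test_that("all three families are sampled with their stated structure", {
  ## ggm family: no perturbation, Y independent of X
  cfg_g <- sim_config(p = 8, q = 6, r = 4, module_size = 6, family = "ggm")
  tg <- make_ground_truth(cfg_g, seed = 110)
  expect_identical(Matrix::nnzero(tg$model$layer_xy$Theta), 0L)
  dg <- sample_dataset(tg, n = 4000, seed = 111)
  expect_lt(max(abs(cor(dg$X, dg$Y))), 0.08)

  ## regression family: linear responses with noise variance 0.5
  cfg_r <- sim_config(p = 10, q = 6, r = 4, module_size = 6,
                      family = "regression", frac_snps_perturbing = 1)
  tr <- make_ground_truth(cfg_r, seed = 112)
  expect_equal(tr$sigma2, 0.5)
  dr <- sample_dataset(tr, n = 2e4, seed = 113)
  Er <- dr$Y - dr$X %*% tr$W1
  v <- apply(Er, 2, var)
  expect_true(all(abs(v - 0.5) < 0.03))
  expect_true(all(colSums(tr$W1 != 0) %in% c(0L, 3L)))
})

test_that("round-trip recovery: conditioning on genotype helps network recovery when n > p", {
  ## chain fits vs GGM-style fits ignoring X, matched network penalty,
  ## averaged over seeded replicates at q = 100, p = 300, n = 500
  a_chain <- a_ggm <- numeric(4)
  for (i in 1:4) {
    cfg <- sim_config(p = 300, q = 100, r = 20, module_size = 50)
    truth <- make_ground_truth(cfg, seed = 2600 + i)
    d <- sample_dataset(truth, n = 500, seed = 2700 + i)
    ut <- upper.tri(truth$masks$net_y)
    pn <- fit_scggm(d$X, d$Y, 0.1, 0.1)
    gg <- fit_scggm(NULL, d$Y, lambda_Lambda = 0.1)
    a_chain[i] <- auc_score(abs(as.matrix(pn$Lambda))[ut],
                            truth$masks$net_y[ut])
    a_ggm[i] <- auc_score(abs(as.matrix(gg$Lambda))[ut],
                          truth$masks$net_y[ut])
  }
  expect_gt(mean(a_chain), mean(a_ggm))
  expect_gt(mean(a_chain), 0.85)
})
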