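test_that("indirect effects match closed forms and sparse-solve identities", {
  ## Lambda = I: B = -Theta
  lay <- scggm_layer(diag(3), matrix(c(1, 0, 2, 0, 0, -1), 2, 3))
  expect_equal(indirect_effects(lay), -as.matrix(lay$Theta),
               ignore_attr = TRUE)
  ## 2x2 hand inverse
  lay2 <- scggm_layer(matrix(c(1, 0.5, 0.5, 1), 2), matrix(c(1, 0), 1, 2))
  expect_equal(indirect_effects(lay2), matrix(c(-4 / 3, 2 / 3), 1, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## scalar: Theta = 1, Lambda = 2 -> B = -0.5
  lay3 <- scggm_layer(matrix(2), matrix(1))
  expect_equal(as.numeric(indirect_effects(lay3)), -0.5)
  ## a SNP with no direct targets has no indirect effects either
  Th <- matrix(0, 3, 2); Th[1, 1] <- 1
  lay4 <- scggm_layer(matrix(c(1, 0.4, 0.4, 1), 2), Th)
  B <- indirect_effects(lay4)
  expect_true(all(B[2:3, ] == 0))
  expect_true(all(B[1, ] != 0))
  ## columns solve Lambda v = -theta_row
  lay5 <- random_layer(4, 5, seed = 91)
  B5 <- indirect_effects(lay5)
  resid <- as.matrix(lay5$Lambda) %*% t(B5) + t(as.matrix(lay5$Theta))
  expect_lt(max(abs(resid)), 1e-10)
})

scalar_chain <- function() {
  chain_model(
    scggm_layer(matrix(1), matrix(2), output_ids = "G1"),
    scggm_layer(matrix(2), matrix(1), input_ids = "G1"))
}

test_that("INF-I composes effects and produces the correct z|x marginal", {
  m <- scalar_chain()
  out <- inf1_snp_trait_effects(m)
  expect_equal(as.numeric(out$B_xz), 1)      # (-2) * (-0.5)
  expect_equal(as.numeric(out$cov_z_given_x), 0.75)

  ## Theta_xy = 0: no SNP effects, covariance unchanged
  m0 <- m
  m0$layer_xy$Theta <- Matrix::Matrix(matrix(0, 1, 1), sparse = TRUE)
  out0 <- inf1_snp_trait_effects(m0)
  expect_equal(as.numeric(out0$B_xz), 0)
  expect_equal(out0$cov_z_given_x, out$cov_z_given_x)

  ## Monte-Carlo ancestral sampling agrees with the closed form
  cfg <- sim_config(p = 4, q = 5, r = 4, module_size = 5,
                    frac_snps_perturbing = 1)
  truth <- make_ground_truth(cfg, seed = 92)
  m2 <- truth$model
  n <- 1e5
  set.seed(93)
  X <- matrix(rnorm(n * 4), n, 4)
  B_xy <- indirect_xy(m2); B_yz <- indirect_yz(m2)
  Y <- X %*% B_xy + perturbnet:::sample_gaussian_prec(n, m2$layer_xy$Lambda)
  Z <- Y %*% B_yz + perturbnet:::sample_gaussian_prec(n, m2$layer_yz$Lambda)
  out2 <- inf1_snp_trait_effects(m2)
  resid <- Z - X %*% out2$B_xz
  emp_cov <- crossprod(resid) / n
  se <- sqrt((outer(diag(out2$cov_z_given_x), diag(out2$cov_z_given_x)) +
                out2$cov_z_given_x^2) / n)
  expect_true(all(abs(emp_cov - out2$cov_z_given_x) < 3.5 * se))
})

test_that("module decomposition is exact and telescopes to B_xz", {
  truth <- make_ground_truth(sim_config(p = 20, q = 12, r = 4,
                                        module_size = 6), seed = 94)
  eff <- effect_set(truth$model)
  ## one module holding all genes reproduces B_xz
  dec1 <- inf2_module_decomposition(eff, rep("all", 12))
  expect_equal(dec1$all, eff$B_xz, tolerance = 1e-12)
  ## components over the true modules telescope to B_xz
  dec <- inf2_module_decomposition(eff, truth$modules_y)
  expect_equal(Reduce(`+`, dec), eff$B_xz, tolerance = 1e-12)
  ## two singleton modules: per-gene scalar path products
  m <- chain_model(
    scggm_layer(diag(2), matrix(c(1, 2), 1, 2), output_ids = c("a", "b")),
    scggm_layer(matrix(1), matrix(c(3, 4), 2, 1), input_ids = c("a", "b")))
  e2 <- effect_set(m)
  d2 <- inf2_module_decomposition(e2, c("m1", "m2"))
  expect_equal(as.numeric(d2$m1), (-1) * (-3))
  expect_equal(as.numeric(d2$m2), (-2) * (-4))
  ## incomplete assignment is a structural error
  expect_error(inf2_module_decomposition(eff, rep(1, 5)), "cover")
})

test_that("the posterior network adds exactly the moralized edges", {
  ## Lambda_y = I2, Theta_yz = (1, 0)', Lambda_z = 2
  m <- chain_model(
    scggm_layer(diag(2), matrix(0, 1, 2), output_ids = c("G1", "G2")),
    scggm_layer(matrix(2), matrix(c(1, 0), 2, 1),
                input_ids = c("G1", "G2")))
  post <- inf3_posterior_network(m)
  expect_equal(post$Lambda_y_given_xz, diag(c(1.5, 1)), ignore_attr = TRUE)

  ## Theta_yz = 0 leaves the network untouched
  m0 <- m
  m0$layer_yz$Theta <- Matrix::Matrix(matrix(0, 2, 1), sparse = TRUE)
  expect_equal(inf3_posterior_network(m0)$Lambda_y_given_xz,
               diag(2), ignore_attr = TRUE)

  ## moralized edges appear exactly where Theta_yz Lambda_z^-1 Theta_yz' != 0
  truth <- make_ground_truth(sim_config(p = 10, q = 10, r = 4,
                                        module_size = 5), seed = 95)
  mt <- truth$model
  post_t <- inf3_posterior_network(mt)
  Lam_y <- as.matrix(mt$layer_xy$Lambda)
  moral <- as.matrix(mt$layer_yz$Theta) %*%
    solve(as.matrix(mt$layer_yz$Lambda), t(as.matrix(mt$layer_yz$Theta)))
  expected <- which(upper.tri(Lam_y) & Lam_y == 0 & abs(moral) > 1e-12,
                    arr.ind = TRUE)
  got <- post_t$edges[post_t$edges$is_moralized, ]
  ids <- mt$layer_xy$output_ids
  expect_setequal(paste(got$gene_i, got$gene_j),
                  paste(ids[expected[, 1]], ids[expected[, 2]]))
  ## INF-III equals the (y, y) block of the joint representation
  jt <- build_joint(mt)
  expect_equal(post_t$Lambda_y_given_xz, jt$Lambda_y_given_xz,
               tolerance = 1e-12)
})

test_that("the joint representation factorizes and is block-diagonal when decoupled", {
  truth <- make_ground_truth(sim_config(p = 8, q = 6, r = 4,
                                        module_size = 6), seed = 96)
  m <- truth$model
  jt <- build_joint(m)
  q <- 6; r <- 4
  ## joint log-density equals the sum of the two factor log-densities
  set.seed(97)
  for (k in 1:3) {
    x <- rnorm(8); y <- rnorm(q); z <- rnorm(r)
    Ly <- as.matrix(m$layer_xy$Lambda); Txy <- as.matrix(m$layer_xy$Theta)
    Lz <- as.matrix(m$layer_yz$Lambda); Tyz <- as.matrix(m$layer_yz$Theta)
    ldet <- function(M) as.numeric(determinant(M)$modulus)
    B1 <- -Txy %*% solve(Ly); B2 <- -Tyz ## note B2 unused; density via quad forms
    lp_y <- 0.5 * ldet(Ly) - 0.5 * (q * log(2 * pi)) -
      0.5 * t(y - t(B1) %*% x) %*% Ly %*% (y - t(B1) %*% x)
    Bz <- -Tyz %*% solve(Lz)
    lp_z <- 0.5 * ldet(Lz) - 0.5 * (r * log(2 * pi)) -
      0.5 * t(z - t(Bz) %*% y) %*% Lz %*% (z - t(Bz) %*% y)
    v <- c(z, y)
    mu <- -solve(jt$Lambda_zy, t(jt$Theta_zy_x) %*% x)
    lp_joint <- 0.5 * ldet(jt$Lambda_zy) - 0.5 * ((q + r) * log(2 * pi)) -
      0.5 * t(v - mu) %*% jt$Lambda_zy %*% (v - mu)
    expect_equal(as.numeric(lp_joint), as.numeric(lp_y + lp_z),
                 tolerance = 1e-8)
  }
  ## decoupled layers give a block-diagonal joint precision
  m0 <- m
  m0$layer_yz$Theta <- Matrix::Matrix(matrix(0, q, r), sparse = TRUE)
  jt0 <- build_joint(m0)
  expect_equal(jt0$Lambda_zy[1:r, r + (1:q)], matrix(0, r, q),
               ignore_attr = TRUE)
  ## B_xz is association-order invariant
  eff <- effect_set(m)
  B_alt <- (-as.matrix(m$layer_xy$Theta) %*%
              solve(as.matrix(m$layer_xy$Lambda))) %*%
    (-as.matrix(m$layer_yz$Theta) %*% solve(as.matrix(m$layer_yz$Lambda)))
  expect_equal(eff$B_xz, B_alt, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("score summaries and SNP ranking follow their definitions", {
  A <- matrix(c(1, 3, -2, 0), 2, 2)
  expect_equal(score_summary(A, rows = 1:2, cols = 1), 4)
  expect_equal(score_summary(matrix(0, 3, 3)), 0)
  expect_warning(s0 <- score_summary(A, rows = integer()), "empty")
  expect_equal(s0, 0)
  ## additivity over a column partition
  expect_equal(score_summary(A, cols = 1) + score_summary(A, cols = 2),
               score_summary(A))

  B <- matrix(0, 3, 2, dimnames = list(c("s1", "s2", "s3"), NULL))
  B[2, ] <- c(1, -1)
  rk <- rank_snps(B)
  expect_identical(rk$snp_id[1], "s2")
  ## equal scores break ties by identifier
  B2 <- matrix(1, 3, 1, dimnames = list(c("c", "a", "b"), NULL))
  expect_identical(rank_snps(B2)$snp_id, c("a", "b", "c"))
  ## agrees with a brute-force sort on a random model
  set.seed(98)
  Bbig <- matrix(rnorm(100 * 4), 100, 4,
                 dimnames = list(sprintf("s%03d", 1:100), NULL))
  rk2 <- rank_snps(Bbig, top_k = 10)
  brute <- names(sort(rowSums(abs(Bbig)), decreasing = TRUE))[1:10]
  expect_identical(rk2$snp_id, brute)
})

test_that("connected-component module labels partition the network", {
  L <- diag(4)
  L[1, 2] <- L[2, 1] <- 0.3
  lay <- scggm_layer(L, matrix(0, 2, 4))
  lab <- module_components(lay)
  expect_identical(lab[1], lab[2])
  expect_identical(length(unique(lab)), 3L)
})
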