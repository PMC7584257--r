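toy_model <- function() {
  ## q = 2 genes, 1 trait, Lambda_y = I, Theta_yz = (1, 0)', Lambda_z = 2
  chain_model(
    scggm_layer(diag(2), matrix(0, 1, 2), output_ids = c("G1", "G2")),
    scggm_layer(matrix(2), matrix(c(1, 0), 2, 1),
                input_ids = c("G1", "G2")))
}

test_that("posterior moments match the hand-worked toy example", {
  m <- toy_model()
  post <- posterior_moments(m, X = matrix(0, 1, 1), Z = matrix(1, 1, 1))
  ## Sigma = (I + Theta_yz Lambda_z^-1 Theta_yz')^-1 = diag(2/3, 1)
  expect_equal(post$Sigma, diag(c(2 / 3, 1)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.numeric(post$mu), c(-2 / 3, 0), tolerance = 1e-12)

  ## numerical cross-check by conditioning the joint Gaussian
  jt <- build_joint(m)
  S_full <- solve(jt$Lambda_zy)            # covariance over (z, y)
  S_zz <- S_full[1, 1]; S_yz <- S_full[2:3, 1, drop = FALSE]
  S_yy <- S_full[2:3, 2:3]
  cond_cov <- S_yy - S_yz %*% t(S_yz) / S_zz
  expect_equal(post$Sigma, cond_cov, tolerance = 1e-12, ignore_attr = TRUE)
  mu_full <- -solve(jt$Lambda_zy, t(jt$Theta_zy_x) %*% c(0))
  cond_mu <- mu_full[2:3] + S_yz %*% ((1 - mu_full[1]) / S_zz)
  expect_equal(as.numeric(post$mu), as.numeric(cond_mu), tolerance = 1e-12)
})

test_that("vanishing trait coupling reduces the posterior to the x-only form", {
  m <- toy_model()
  m$layer_yz$Theta <- Matrix::Matrix(matrix(0, 2, 1), sparse = TRUE)
  m$layer_xy$Theta <- Matrix::Matrix(matrix(c(0.5, -1), 1, 2), sparse = TRUE)
  post <- posterior_moments(m, X = matrix(2, 1, 1), Z = matrix(5, 1, 1))
  expect_equal(post$Sigma, solve(as.matrix(m$layer_xy$Lambda)),
               ignore_attr = TRUE)
  ## mu depends only on x: -Sigma Theta_xy' x
  expect_equal(as.numeric(post$mu), as.numeric(-c(0.5, -1) * 2))
})

test_that("conjugate-gradient posterior columns match dense inversion", {
  ## K = 0: columns of Lambda_y^-1
  m0 <- toy_model()
  m0$layer_yz$Theta <- Matrix::Matrix(matrix(0, 2, 1), sparse = TRUE)
  v <- implicit_posterior_solve(m0, cols = 1:2)
  expect_equal(v, diag(2), tolerance = 1e-8, ignore_attr = TRUE)

  ## random q = 30 instance
  set.seed(71)
  lay_y <- random_layer(0, 30, seed = 72)
  lay_z <- random_layer(0, 4, seed = 73)
  Th_yz <- matrix(rnorm(120) * (runif(120) < 0.2), 30, 4)
  m <- chain_model(
    scggm_layer(as.matrix(lay_y$Lambda), matrix(0, 5, 30),
                output_ids = paste0("G", 1:30)),
    scggm_layer(as.matrix(lay_z$Lambda), Th_yz,
                input_ids = paste0("G", 1:30)))
  dense_Sigma <- posterior_moments(m)$Sigma
  cols <- c(1, 7, 30)
  v <- implicit_posterior_solve(m, cols = cols)
  expect_lt(max(abs(v - dense_Sigma[, cols])), 1e-6)
  ## residual of the linear system
  Om <- perturbnet:::posterior_precision(m)
  for (k in seq_along(cols)) {
    e <- numeric(30); e[cols[k]] <- 1
    expect_lt(sqrt(sum((Om %*% v[, k] - e)^2)), 1e-7)
  }
})

test_that("EM with no hidden samples reduces exactly to the complete-data fit", {
  cfg <- sim_config(p = 20, q = 10, r = 4, module_size = 5)
  truth <- make_ground_truth(cfg, seed = 74)
  d <- sample_dataset(truth, n = 120, seed = 75)
  em <- em_fit(d, 0.1, 0.1, 0.1, 0.1)
  fc <- fit_chain(d, 0.1, 0.1, 0.1, 0.1)
  expect_identical(as.matrix(em$layer_xy$Lambda), as.matrix(fc$layer_xy$Lambda))
  expect_identical(as.matrix(em$layer_yz$Theta), as.matrix(fc$layer_yz$Theta))
})

test_that("EM decreases the observed-data penalized objective monotonically", {
  cfg <- sim_config(p = 24, q = 12, r = 4, module_size = 6)
  truth <- make_ground_truth(cfg, seed = 76)
  d <- sample_dataset(truth, n = 200, seed = 77)
  set.seed(78)
  obs <- sort(sample(200, 130))
  dsemi <- data_bundle(d$X, d$Y[obs, , drop = FALSE], d$Z, y_rows = obs)
  em <- em_fit(dsemi, 0.1, 0.1, 0.1, 0.1, max_em_iter = 12,
               control = scggm_control(max_iter = 300))
  tr <- em$fit_info$em_objective
  expect_gte(length(tr), 3)
  expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  expect_identical(em$fit_info$n_hidden, 70L)
})

test_that("traits inform imputation: posterior means beat genotype-only predictions", {
  cfg <- sim_config(p = 24, q = 12, r = 6, module_size = 6,
                    edge_weight_mean = 0.9)   # strong trait coupling
  truth <- make_ground_truth(cfg, seed = 79)
  d <- sample_dataset(truth, n = 250, seed = 80)
  set.seed(81)
  obs <- sort(sample(250, 150))
  hid <- setdiff(1:250, obs)
  dsemi <- data_bundle(d$X, d$Y[obs, , drop = FALSE], d$Z, y_rows = obs)
  em <- em_fit(dsemi, 0.08, 0.08, 0.08, 0.08, max_em_iter = 10,
               control = scggm_control(max_iter = 600))
  Xc <- scale(d$X, scale = FALSE); Zc <- scale(d$Z, scale = FALSE)
  post <- posterior_moments(em, X = Xc[hid, ], Z = Zc[hid, ])
  mu_x_only <- Xc[hid, ] %*% indirect_xy(em)
  truth_y <- scale(d$Y, scale = FALSE)[hid, ]
  cor_full <- cor(as.numeric(post$mu), as.numeric(truth_y))
  cor_x <- cor(as.numeric(mu_x_only), as.numeric(truth_y))
  expect_gt(cor_full, cor_x + 0.05)
})

test_that("support overlap with the complete-data fit degrades gracefully with hiddenness", {
  cfg <- sim_config(p = 24, q = 12, r = 4, module_size = 6)
  truth <- make_ground_truth(cfg, seed = 82)
  d <- sample_dataset(truth, n = 240, seed = 83)
  full <- fit_chain(d, 0.1, 0.1, 0.1, 0.1)
  ref_support <- as.matrix(full$layer_xy$Theta) != 0
  overlap <- function(frac_hidden) {
    if (frac_hidden == 0) return(1)
    set.seed(84)
    obs <- sort(sample(240, round(240 * (1 - frac_hidden))))
    dsemi <- data_bundle(d$X, d$Y[obs, , drop = FALSE], d$Z, y_rows = obs)
    em <- em_fit(dsemi, 0.1, 0.1, 0.1, 0.1, max_em_iter = 8,
                 control = scggm_control(max_iter = 300))
    est <- as.matrix(em$layer_xy$Theta) != 0
    (sum(est & ref_support) + sum(!est & !ref_support)) / length(est)
  }
  o0 <- overlap(0); o10 <- overlap(0.1); o50 <- overlap(0.5)
  expect_identical(o0, 1)
  expect_gte(o10, o50 - 0.02)
  expect_gt(o50, 0.8)
})
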