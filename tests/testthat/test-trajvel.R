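test_that("marker imputation averages latent-space neighbours", {
  expect_equal(formals(impute_missing_marker)$k, 10)
  # all neighbours sharing one value impute exactly that value
  facs <- data.frame(cell = paste0("c", 1:12),
                     Sca1 = c(NA, rep(7, 11)),
                     cKit = rep(2, 12), Lin = rep(1, 12))
  latent <- matrix(rnorm(24), 12, 2, dimnames = list(facs$cell, NULL))
  out <- impute_missing_marker(facs, latent, k = 10)
  expect_equal(out$facs$Sca1[1], 7)
  expect_true(out$imputed[1, "Sca1"])
  expect_equal(sum(out$imputed), 1)
  # fewer complete cells than k: use all, warn
  facs2 <- facs[1:4, ]
  expect_warning(out2 <- impute_missing_marker(facs2, latent[1:4, ], k = 10),
                 "using all")
  expect_equal(out2$facs$Sca1[1], 7)
  facs$cKit[1] <- NA
  expect_error(impute_missing_marker(facs, latent), "more than one")
})

test_that("imputation error tracks the local noise for smooth markers", {
  # marker linear in the latent coordinates, dense sampling
  withr::with_seed(60, {
    n <- 400
    latent <- cbind(runif(n), runif(n))
    truth <- 3 * latent[, 1] - 2 * latent[, 2]
    noise_sd <- 0.05
    sca1 <- truth + rnorm(n, sd = noise_sd)
    facs <- data.frame(cell = paste0("c", 1:n), Sca1 = sca1,
                       cKit = 1, Lin = 1)
    masked <- sample.int(n, 60)
    facs$Sca1[masked] <- NA
  })
  rownames(latent) <- facs$cell
  out <- impute_missing_marker(facs, latent, k = 10)
  rmse <- sqrt(mean((out$facs$Sca1[masked] - truth[masked])^2))
  expect_lt(rmse, 2 * noise_sd)
})

test_that("ternary coordinates live on the simplex", {
  expect_equal(unname(ternary_coords(1, 1, 1)), matrix(1 / 3, 1, 3),
               ignore_attr = TRUE)
  expect_equal(unname(ternary_coords(5, 0, 0)[1, ]), c(1, 0, 0))
  withr::with_seed(61, m <- matrix(runif(30), 10, 3))
  tc <- ternary_coords(m[, 1], m[, 2], m[, 3])
  expect_equal(rowSums(tc), rep(1, 10))
  expect_true(all(tc >= 0))
  expect_error(ternary_coords(0, 0, 0), "all-zero")
  expect_error(ternary_coords(-1, 1, 1), "nonnegative")
})

test_that("pseudotime ranks cells along the trajectory axis", {
  # equally spaced cells on a line give equally spaced pseudotimes
  n <- 20
  sc <- cbind(PC1 = seq_len(n), PC2 = 0.5 * seq_len(n), PC3 = rnorm(n))
  rownames(sc) <- paste0("c", 1:n)
  lab <- setNames(rep(c("start", "end"), each = n / 2), rownames(sc))
  t <- pseudotime_from_pcs(sc, c(1, 2), rownames(sc), lab, "start")
  expect_equal(unname(t), seq(0, 1, length.out = n))
  # flipping the orientation label reflects pseudotime
  t_rev <- pseudotime_from_pcs(sc, c(1, 2), rownames(sc), lab, "end")
  expect_equal(unname(t_rev), 1 - unname(t))
  expect_error(pseudotime_from_pcs(sc, c(1, 2), rownames(sc), lab, "absent"),
               "absent")
  expect_error(pseudotime_from_pcs(sc, c(1, 9), rownames(sc), lab, "start"),
               "two columns")
})

test_that("planted trajectory order is recovered from noisy PCs", {
  withr::with_seed(62, {
    n <- 150
    t_true <- runif(n)
    sc <- cbind(PC1 = 4 * t_true + rnorm(n, sd = 0.15),
                PC2 = -2 * t_true + rnorm(n, sd = 0.15))
    rownames(sc) <- paste0("c", 1:n)
    lab <- setNames(ifelse(t_true < 0.3, "HSPC", "mature"), rownames(sc))
  })
  t_hat <- pseudotime_from_pcs(sc, c(1, 2), rownames(sc), lab, "HSPC")
  expect_gte(cor(t_hat, t_true, method = "spearman"), 0.95)
})

test_that("spline fits are exact on linear signal and track noisy curves", {
  t <- seq(0, 1, length.out = 200)
  lin <- 2 + 3 * t
  sp <- fit_trajectory_spline(lin, t, df = 6)
  expect_lt(max(abs(predict(sp, t) - lin)), 1e-8)  # cubic contains linear
  expect_error(fit_trajectory_spline(lin, t, df = 3), "df >= 4")
  expect_error(fit_trajectory_spline(lin, rep(0.5, 200)), "degenerate")
  withr::with_seed(63, {
    noise_sd <- 0.1
    y <- sin(2 * pi * t) + rnorm(200, sd = noise_sd)
  })
  spn <- fit_trajectory_spline(y, t, df = 6)
  rmse <- sqrt(mean((predict(spn, t) - sin(2 * pi * t))^2))
  expect_lt(rmse, 1.5 * noise_sd)
})

test_that("velocity is the spline derivative with boundary clipping", {
  expect_equal(formals(chromatin_velocity)$delta, 0.01)
  t <- seq(0, 1, length.out = 120)
  sp_lin <- fit_trajectory_spline(1 + 4.5 * t, t, df = 6)
  v <- chromatin_velocity(sp_lin, t)
  interior <- t > 0.05 & t < 0.95
  expect_lt(max(abs(v[interior] - 4.5)), 1e-6)
  # constant signal: zero velocity everywhere
  sp_const <- fit_trajectory_spline(rep(2, 120) + 1e-12 * t, t, df = 6)
  expect_lt(max(abs(chromatin_velocity(sp_const, t))), 1e-6)
  # at the right edge the difference is one-sided but still defined
  expect_true(is.finite(chromatin_velocity(sp_lin, 1)))
  expect_error(chromatin_velocity(sp_lin, t, delta = 0), "delta")
})

test_that("velocity projection is linear and registry-checked", {
  withr::with_seed(64, {
    sig <- matrix(rnorm(30 * 10), 30, 10,
                  dimnames = list(paste0("r", 1:30), paste0("c", 1:10)))
    vel <- matrix(rnorm(30 * 10), 30, 10, dimnames = dimnames(sig))
  })
  pc <- project_pca(sig)
  arrows <- project_velocity(vel, pc$loadings)
  expect_equal(dim(arrows), c(10L, 2L))
  # zero velocity maps to zero arrows
  expect_equal(unname(project_velocity(vel * 0, pc$loadings)),
               matrix(0, 10, 2))
  # project-then-differentiate equals differentiate-then-project:
  # projecting signal differences equals differencing projected signal
  sig2 <- sig + 0.01 * vel
  proj1 <- t(sig2 - sig) %*% pc$loadings[, 1:2] / 0.01
  expect_equal(unname(arrows), unname(proj1), tolerance = 1e-8)
  # orthonormal loadings preserve the norm of in-subspace velocities
  coefs <- matrix(rnorm(ncol(pc$loadings) * 10), ncol(pc$loadings), 10)
  vel_span <- pc$loadings %*% coefs
  full <- project_velocity(vel_span, pc$loadings,
                           pcs = seq_len(ncol(pc$loadings)))
  expect_equal(unname(rowSums(full^2)), unname(colSums(vel_span^2)),
               tolerance = 1e-8)
  bad <- vel[1:20, ]
  expect_error(project_velocity(bad, pc$loadings), "registries")
})
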