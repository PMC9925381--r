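# Closed-form oracle for the one-factor Poisson model with offset: group
# rate MLEs and deviances have explicit forms, independent of glm().
poisson_oracle <- function(y, celltype, offset) {
  mu_of <- function(rate_per_cell) 2 * sum(ifelse(y > 0, y * log(y / rate_per_cell), 0) -
                                             (y - rate_per_cell))
  e <- exp(offset)
  null_mu <- sum(y) / sum(e) * e
  rates <- tapply(y, celltype, sum) / tapply(e, celltype, sum)
  full_mu <- rates[celltype] * e
  list(null_dev = mu_of(null_mu), full_dev = mu_of(unname(full_mu)),
       rates = rates)
}

test_that("region GLM matches the closed-form Poisson oracle", {
  withr::with_seed(20, {
    ct <- rep(c("A", "B", "C"), each = 40)
    off <- log(runif(120, 800, 1200))
    y <- rpois(120, exp(off) * 0.01 * ifelse(ct == "B", 3, 1))
  })
  fit <- fit_region_glm(y, ct, off, reference = "A")
  oracle <- poisson_oracle(y, ct, off)
  expect_equal(fit$null_dev, oracle$null_dev, tolerance = 1e-6)
  expect_equal(fit$full_dev, oracle$full_dev, tolerance = 1e-6)
  expect_gte(fit$null_dev, fit$full_dev)  # nesting
  expect_equal(fit$df, 2)
  # coefficient equals the log rate ratio
  expect_equal(unname(fit$log2fc["B"]),
               log2(oracle$rates[["B"]] / oracle$rates[["A"]]),
               tolerance = 1e-6)
  # single type: full = null, p = 1
  single <- fit_region_glm(y, rep("A", 120), off)
  expect_equal(single$p, 1)
  expect_equal(single$dev_diff, 0)
  # all-zero region: defined p = 1 and zero folds
  zero <- fit_region_glm(rep(0, 120), ct, off)
  expect_equal(zero$p, 1)
  expect_true(all(zero$log2fc == 0))
})

test_that("deviance test is calibrated under the null and detects folds", {
  withr::with_seed(22, {
    n_cell <- 150; n_region <- 300
    ct <- rep(c("A", "B", "C"), each = n_cell / 3)
    depth <- rep(1000, n_cell)
    null_counts <- matrix(rpois(n_region * n_cell, 5), n_region, n_cell)
    dimnames(null_counts) <- list(paste0("r", 1:n_region),
                                  paste0("c", 1:n_cell))
    res <- diff_mark_test(null_counts, setNames(ct, colnames(null_counts)),
                          offset = log(depth))
    expect_true(all(res$null_dev >= res$full_dev - 1e-8))
    rej <- mean(res$p < 0.05)
    # binomial CI around nominal 0.05 at 300 regions
    expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / n_region))
    # planted 4-fold effect in type B
    eff_counts <- matrix(rpois(50 * n_cell, 5 * ifelse(ct == "B", 4, 1)),
                         50, n_cell, byrow = TRUE)
    dimnames(eff_counts) <- list(paste0("e", 1:50), colnames(null_counts))
    res_eff <- diff_mark_test(eff_counts, setNames(ct, colnames(null_counts)),
                              offset = log(depth))
    expect_gt(mean(res_eff$q < 0.05), 0.9)
  })
})

test_that("BH adjustment matches an explicit step-up enumeration", {
  withr::with_seed(23, p <- round(runif(10), 3))
  bh_brute <- function(p) {
    n <- length(p); o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  expect_equal(adjust_q(p), bh_brute(p))
  expect_true(all(adjust_q(p) >= p))
  expect_equal(adjust_q(rep(1, 5)), rep(1, 5))
  expect_error(adjust_q(c(0.5, 2)), "\\[0,1\\]")
})

test_that("dynamic calling uses the mark-specific thresholds", {
  thr <- default_q_thresholds()
  expect_equal(unname(thr[c("H3K4me1", "H3K4me3", "H3K27me3")]), rep(1e-50, 3))
  expect_equal(unname(thr["H3K9me3"]), 1e-9)
  res <- data.frame(region = c("a", "b"), q = c(1e-60, 1e-20))
  expect_equal(call_dynamic(res, "H3K4me1")$dynamic, c(TRUE, FALSE))
  expect_equal(call_dynamic(res, "H3K9me3")$dynamic, c(TRUE, TRUE))
  expect_true(all(call_dynamic(res, "H3K9me3",
                               q_thresholds = c(H3K9me3 = 1))$dynamic))
  expect_error(call_dynamic(res, "H3K99me9"), "unknown mark")
})

test_that("GLM fold changes agree with normalised pseudobulk ratios", {
  withr::with_seed(24, {
    ct <- rep(c("HSPC", "Bcell"), each = 100)
    base_rate <- runif(40, 20, 60)
    counts <- rbind(
      t(sapply(base_rate[1:20], function(r) rpois(200, r))),            # flat
      t(sapply(base_rate[21:40], function(r)
        rpois(200, r * ifelse(ct == "Bcell", 2, 1)))))                  # doubled
    dimnames(counts) <- list(paste0("r", 1:40), paste0("c", 1:200))
  })
  labels <- setNames(ct, colnames(counts))
  res <- diff_mark_test(counts, labels, reference = "HSPC")
  fc <- fold_change_vs_reference(res, "HSPC")
  expect_true(all(fc["HSPC", ] == 0))
  # depth normalisation shifts all folds by a common constant, so the
  # doubled-vs-flat contrast is the invariant quantity: exactly 1
  expect_equal(mean(fc["Bcell", 21:40]) - mean(fc["Bcell", 1:20]), 1,
               tolerance = 0.05)
  # pseudobulk ratio estimator agrees at high counts
  pb <- pseudobulk(counts, labels)
  fc_pb <- fold_change_vs_reference(pb, "HSPC")
  expect_lt(max(abs(fc["Bcell", ] - fc_pb["Bcell", colnames(fc)])), 0.05)
})

test_that("fate-independence matches brute-force set enumeration", {
  # 20-region fixture, 3 non-reference types, mixed signs
  withr::with_seed(25, {
    fc <- matrix(round(runif(60, -2, 2), 2), 20, 3,
                 dimnames = list(paste0("r", 1:20), c("T1", "T2", "T3")))
    dyn <- runif(20) < 0.7
  })
  res <- make_diff_result(fc, dyn)
  out <- classify_fate_independent(res, min_effect = 0.1)
  # brute force: loop over regions, types, directions
  for (t in colnames(fc)) {
    for (d in c(1, -1)) {
      dname <- if (d == 1) "gain" else "loss"
      changing <- which(dyn & sign(fc[, t]) == d & abs(fc[, t]) > 0.1)
      indep <- Filter(function(r) {
        all(dyn[r] & sign(fc[r, ]) == d & abs(fc[r, ]) > 0.1)
      }, changing)
      expected <- if (length(changing)) length(indep) / length(changing) else NA_real_
      expect_equal(out$fraction[t, dname], expected)
    }
  }
  # all types sharing one planted direction give fraction 1
  shared <- make_diff_result(matrix(1.5, 5, 3,
                                    dimnames = list(paste0("r", 1:5),
                                                    c("T1", "T2", "T3"))),
                             rep(TRUE, 5))
  frac <- classify_fate_independent(shared)$fraction
  expect_equal(unname(frac[, "gain"]), rep(1, 3))
  expect_true(all(is.na(frac[, "loss"])))
  # min_effect above every fold leaves fractions undefined
  expect_warning(none <- classify_fate_independent(shared, min_effect = 10),
                 "undefined")
  expect_true(all(is.na(none$fraction)))
})

test_that("top-depleted selection is a monotone, tie-stable scan", {
  folds <- c(r3 = -2, r1 = 0.5, r2 = -2, r4 = -5, r5 = 1)
  expect_equal(select_top_depleted(folds, k = 1), "r4")  # argmin oracle
  expect_equal(select_top_depleted(folds, k = 3), c("r4", "r2", "r3"))
  expect_true(all(select_top_depleted(folds, 2) %in% select_top_depleted(folds, 4)))
  expect_warning(allr <- select_top_depleted(folds, 150), "returning all")
  expect_equal(length(allr), 5)
  expect_equal(formals(select_top_depleted)$k, 150)
})
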