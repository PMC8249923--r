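test_that("log transform floors at the detection limit", {
  vals <- matrix(c(1, 0, exp(1), 50), 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  sm <- secretome_matrix(vals, detection_floor = 0.1)
  ln <- log_transform(sm)
  expect_equal(ln["a", "s1"], 0)
  expect_equal(ln["b", "s1"], log(0.1), tolerance = 1e-6)  # -2.302585
  expect_equal(ln["a", "s2"], 1)
  # missing stays missing
  vals[2, 2] <- NA
  ln2 <- log_transform(secretome_matrix(vals, detection_floor = 0.1))
  expect_true(is.na(ln2["b", "s2"]))
})

test_that("iterative SVD imputation recovers low-rank structure", {
  # no missing entries: fixed point
  X <- matrix(rnorm(12), 3)
  expect_equal(unname(impute_missing_svd(X)), X, ignore_attr = TRUE)

  # rank-1 closed form: r2 * c2 = 2 * 3 = 6
  M <- outer(c(1, 2), c(1, 3))
  M[2, 2] <- NA
  imp <- impute_missing_svd(M, rank = 1, tol = 1e-10, max_iter = 5000)
  expect_equal(imp[2, 2], 6, tolerance = 1e-6)
  expect_equal(imp[1:2, 1], c(1, 2))  # observed entries untouched
  expect_true(attr(imp, "converged"))

  # exact rank-2 completion at 5% masking
  set.seed(17)
  X2 <- tcrossprod(matrix(rnorm(40), 20, 2), matrix(rnorm(40), 20, 2))
  mask <- sample(length(X2), 20)
  Xm <- X2; Xm[mask] <- NA
  imp2 <- impute_missing_svd(Xm, rank = 2, tol = 1e-12, max_iter = 5000)
  expect_lt(max(abs(imp2[mask] - X2[mask])), 1e-6)

  # all-missing row is an error, non-convergence only a flag
  bad <- M; bad[1, ] <- NA
  expect_error(impute_missing_svd(bad, rank = 1), "all-missing")
  slow <- impute_missing_svd(M, rank = 1, tol = 1e-14, max_iter = 3)
  expect_false(attr(slow, "converged"))
})

test_that("decomposition matches the Gram-matrix oracle on small matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:10, 1); m <- sample(2:10, 1)
    X <- matrix(rnorm(n * m, 2), n)
    dec <- surprisal_decompose(X)
    ora <- gram_svd(X)
    expect_equal(dec$singular_values, ora$d[seq_along(dec$singular_values)],
                 tolerance = 1e-8)
    for (a in seq_len(ncol(dec$G))) {
      if (dec$singular_values[a] < 1e-6 * dec$singular_values[1]) next
      diff <- min(max(abs(dec$G[, a] - ora$u[, a])),
                  max(abs(dec$G[, a] + ora$u[, a])))
      expect_lt(diff, 1e-6)
    }
  }
})

test_that("decomposition invariants hold", {
  set.seed(4)
  X <- matrix(rlnorm(30 * 12, 3, 1), 30)
  dec <- surprisal_decompose(log(X))
  # exact reconstruction with all components
  expect_lt(max(abs(dec$G %*% dec$lambda - log(X))), 1e-8)
  # orthonormal weights, non-increasing spectrum
  expect_equal(crossprod(dec$G), diag(ncol(dec$G)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(dec$singular_values) <= 1e-10))
  # steady state is the rank-1 leading term
  expect_equal(dec$steady_state_log, outer(dec$G[, 1], dec$lambda[1, ]),
               ignore_attr = TRUE)
  # sign convention: largest-|G| cytokine positive in every component
  for (a in seq_len(ncol(dec$G))) {
    expect_gt(dec$G[which.max(abs(dec$G[, a])), a], 0)
  }
  expect_error(surprisal_decompose(matrix(1:3, 3, 1)), "2 samples")
  expect_error(surprisal_decompose(matrix(c(1, NA), 1)), "missing")
})

test_that("identical columns leave no deviation from steady state", {
  X <- matrix(rep(c(5, 2, 8), 6), 3)
  dec <- surprisal_decompose(X)
  expect_lt(max(abs(dec$lambda[-1, ])), 1e-8)
})

test_that("scaling concentrations moves only the steady state", {
  # exact when the planted deviations are orthogonal to the baseline and
  # constant directions (as generated): ln(cX) = ln c + ln X shifts the
  # matrix along the rank-1 constant direction only
  tr <- synthetic_truth(k_true = 3, noise_sd = 0, seed = 12)
  sm <- gen_secretome(tr)$secretome
  d1 <- surprisal_decompose(log_transform(sm))
  sm10 <- secretome_matrix(unclass(sm) * 10,
                           detection_floor = attr(sm, "detection_floor"))
  d2 <- surprisal_decompose(log_transform(sm10))
  expect_lt(max(abs(d1$lambda[2:4, ] - d2$lambda[2:4, ])), 1e-8)
  # on generic noisy data the deviation amplitudes are preserved up to the
  # (tiny) coupling through the shifted steady state
  smn <- make_secretome(n = 8, m = 6, seed = 12)
  n1 <- surprisal_decompose(log_transform(smn))
  n2 <- surprisal_decompose(log_transform(
    secretome_matrix(unclass(smn) * 10,
                     detection_floor = attr(smn, "detection_floor"))))
  for (a in 2:4) {
    expect_gt(abs(cor(n1$lambda[a, ], n2$lambda[a, ])), 0.99)
  }
})

test_that("significance counting is exact in the noiseless limit", {
  tr <- synthetic_truth(k_true = 2, noise_sd = 0, seed = 6)
  dec <- surprisal_decompose(log_transform(gen_secretome(tr)$secretome))
  dec <- count_significant_processes(dec, noise_sd = 0)
  expect_identical(dec$K_significant, 2L)
  expect_error(count_significant_processes(dec, noise_sd = 0.1, n_boot = 5),
               "n_boot")
})

test_that("noise SD is estimable from replicate fragments", {
  set.seed(33)
  base <- rnorm(20, 5)
  groups <- rep(paste0("A", 1:8), each = 6)
  lnX <- outer(base, rep(1, 48)) + matrix(rnorm(20 * 48, 0, 0.3), 20)
  est <- estimate_noise_sd(lnX, groups)
  expect_equal(est, 0.3, tolerance = 0.05)
  dec <- surprisal_decompose(lnX)
  dec <- count_significant_processes(dec, noise_sd = "estimate",
                                     groups = groups, n_boot = 50)
  expect_equal(dec$noise_sd_est, est)
  expect_error(count_significant_processes(dec, noise_sd = "estimate"),
               "groups")
})

test_that("membership follows the fold-over-lowest-quantile rule", {
  gv <- c(0.50, 0.24, 0.30, 0.013, 0.02, 0.015, 0.012, 0.011, 0.009, 0.010)
  lnX <- matrix(rnorm(40, 5), 10,
                dimnames = list(paste0("CK", 1:10), paste0("S", 1:4)))
  dec <- surprisal_decompose(lnX)
  dec$G[, 2] <- gv
  pm <- process_membership(dec, 1, fold = 20, quantile = 0.20)
  expect_equal(pm$baseline, mean(c(0.009, 0.010)))      # = 0.0095
  expect_equal(pm$member_ids, c("CK1", "CK2", "CK3"))   # |G| >= 0.19
  expect_equal(unname(pm$member_weights), c(0.50, 0.24, 0.30))

  # signed membership: opposite-direction members keep their signs
  # (fold chosen so the threshold separates the 0.02 bystanders from both
  # participating cytokines: 5 x 0.02 = 0.1)
  dec$G[, 2] <- c(-0.50, 0.24, rep(0.02, 8))
  pm2 <- process_membership(dec, 1, fold = 5)
  expect_true(all(c("CK1", "CK2") %in% pm2$member_ids))
  expect_false("CK3" %in% pm2$member_ids)
  expect_lt(pm2$member_weights[["CK1"]], 0)
  expect_gt(pm2$member_weights[["CK2"]], 0)

  # all-equal weights: everything is a member iff fold <= 1
  dec$G[, 2] <- rep(0.3, 10)
  expect_length(process_membership(dec, 1, fold = 1)$member_ids, 10L)
  expect_length(process_membership(dec, 1, fold = 1.01)$member_ids, 0L)

  expect_error(process_membership(dec, 0), "steady state")
})

test_that("membership is monotone non-increasing in fold", {
  for (seed in 1:25) {
    set.seed(seed)
    lnX <- matrix(rnorm(15 * 6, 4), 15)
    dec <- surprisal_decompose(lnX)
    alpha <- sample(seq_len(ncol(dec$G) - 1L), 1)
    sizes <- vapply(c(1, 2, 5, 10, 20, 50),
                    function(f) length(process_membership(dec, alpha,
                                                          fold = f)$member_ids),
                    integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("activity calls follow sign and threshold semantics", {
  lnX <- matrix(rnorm(12, 5), 4,
                dimnames = list(paste0("CK", 1:4), paste0("S", 1:3)))
  dec <- surprisal_decompose(lnX)
  dec$lambda[2, ] <- c(3.1, 0.02, 2.5)
  act <- process_activity(dec, 1, threshold = 1.0)
  expect_equal(unname(act$activity_calls),
               c("active_positive", "inactive", "active_positive"))
  # samples 1 and 3 are influenced in the same direction; sample 2 inactive
  expect_equal(act$activity_calls[["S1"]], act$activity_calls[["S3"]])

  dec$lambda[2, ] <- c(0, 0, 0)
  expect_true(all(process_activity(dec, 1, 1)$activity_calls == "inactive"))

  dec$lambda[2, ] <- c(-2, 2, 0)
  calls <- process_activity(dec, 1, 1)$activity_calls
  expect_equal(unname(calls[1:2]), c("active_negative", "active_positive"))

  expect_error(process_activity(dec, 1, threshold = -1), "positive")
  expect_error(process_activity(dec, 1, threshold = "auto"),
               "count_significant_processes")
})

test_that("reconstruction truncates and completes as expected", {
  tr <- synthetic_truth(seed = 14)
  g <- gen_secretome(tr)
  ln <- log_transform(g$secretome)
  dec <- surprisal_decompose(ln)
  # steady-state-only matrix has rank 1
  r0 <- reconstruct(dec, 0)
  expect_equal(qr(r0)$rank, 1L)
  # all components reproduce the input
  expect_lt(max(abs(reconstruct(dec, ncol(dec$G) - 1L) - ln)), 1e-8)
  # truncating at k_true leaves only the noise floor
  resid <- ln - reconstruct(dec, tr$k_true)
  expect_lte(sd(resid), 1.1 * tr$noise_sd)
})

test_that("recovered subspaces match planted ones across conditions", {
  ok <- 0L; total <- 0L
  for (k in 1:5) {
    for (seed in 1:8) {
      tr <- synthetic_truth(k_true = k, snr = 5, seed = 40 + 10 * k + seed)
      dec <- surprisal_decompose(log_transform(gen_secretome(tr)$secretome))
      ang <- principal_angles(dec$G[, 1 + seq_len(k), drop = FALSE],
                              tr$planted_G)
      total <- total + 1L
      if (max(ang) < 5) ok <- ok + 1L
    }
  }
  expect_gte(ok / total, 0.95)
})
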