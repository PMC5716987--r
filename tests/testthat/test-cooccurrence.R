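# SparCC estimation and permutation significance; checkerboard C-score.

test_that("SparCC recovers a planted correlation and stays quiet under the null", {
  C <- diag(30)
  C[1, 2] <- C[2, 1] <- 0.9
  cnt <- generate_correlated_counts(C, n_samples = 150, depth = 5000, seed = 1)
  sp <- sparcc_correlations(cnt, seed = 2)
  expect_equal(diag(sp$rho), rep(1, 30), ignore_attr = TRUE)
  expect_true(isSymmetric(sp$rho))
  expect_true(all(abs(sp$rho) <= 1))
  off <- sp$rho; diag(off) <- 0
  expect_gt(sp$rho["OTU_1", "OTU_2"], 0.6)
  expect_equal(max(abs(off)), abs(sp$rho["OTU_1", "OTU_2"]))

  cnt0 <- generate_correlated_counts(diag(30), n_samples = 150, depth = 5000, seed = 3)
  sp0 <- sparcc_correlations(cnt0, seed = 4)
  off0 <- sp0$rho; diag(off0) <- 0
  expect_lt(max(abs(off0)), 0.35)

  expect_error(sparcc_correlations(cnt[1:3, ]), "at least 4")
})

test_that("SparCC is label-equivariant and sample-scale invariant", {
  C <- diag(8); C[3, 7] <- C[7, 3] <- 0.8
  cnt <- generate_correlated_counts(C, n_samples = 120, depth = 3000, seed = 5)
  sp <- sparcc_correlations(cnt, seed = 6)
  perm <- sample(8)
  sp_p <- sparcc_correlations(cnt[, perm], seed = 6)
  # permuting OTU columns permutes rho identically (same seed, same
  # Dirichlet stream applies per-sample, so only labels move)
  expect_equal(unname(sp_p$rho),
               unname(sp$rho[perm, perm]), tolerance = 0.15)

  # duplicating the sample block leaves rho unchanged up to Dirichlet noise
  sp_d <- sparcc_correlations(rbind(cnt, cnt), seed = 7)
  expect_equal(unname(sp_d$rho), unname(sp$rho), tolerance = 0.15)
})

test_that("SparCC permutation p-values respect the pseudo-p bound", {
  C <- diag(12); C[1, 2] <- C[2, 1] <- 0.95
  cnt <- generate_correlated_counts(C, n_samples = 120, depth = 5000, seed = 8)
  sp <- sparcc_pvalues(cnt, n_perm = 49, seed = 9)
  expect_true(all(sp$pvals >= 1 / 50))
  expect_true(all(sp$pvals <= 1))
  # the planted pair is at the minimum attainable p
  expect_equal(sp$pvals["OTU_1", "OTU_2"], 1 / 50)
  expect_error(sparcc_pvalues(cnt, n_perm = 0), ">= 1")
})

test_that("SparCC mean |rho| shrinks with sample size on independent bases", {
  sizes <- c(25, 100, 400)
  m <- vapply(seq_along(sizes), function(i) {
    cnt <- generate_correlated_counts(diag(15), n_samples = sizes[i],
                                      depth = 3000, seed = 10 + i)
    r <- sparcc_correlations(cnt, seed = 20 + i)$rho
    diag(r) <- 0
    mean(abs(r))
  }, numeric(1))
  expect_true(all(diff(m) < 0))
})

test_that("C-score matches hand enumeration and the naive oracle", {
  expect_equal(c_score(matrix(c(1, 0, 0, 1), 2, 2)), 1)  # perfect checkerboard
  expect_equal(c_score(rbind(c(1, 1, 0), c(1, 1, 0))), 0)  # identical rows
  m3 <- rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 1))  # all pairs r=2, S=1
  expect_equal(c_score(m3), 1)
  expect_error(c_score(matrix(1, 1, 3)), "2 taxa")

  set.seed(11)
  for (i in 1:5) {
    pa <- matrix(rbinom(48, 1, 0.45), 6, 8)
    expect_equal(c_score(pa), oracle_c_score(pa), tolerance = 1e-12)
  }
})

test_that("fixed-fixed C-score null preserves margins and flags segregation", {
  set.seed(12)
  pa <- matrix(rbinom(120, 1, 0.4), 10, 12)
  pa <- pa[rowSums(pa) > 0, colSums(pa) > 0, drop = FALSE]
  res <- c_score_null_test(pa, n_null = 200, seed = 13)
  expect_s3_class(res, "cscore_result")
  expect_gte(res$p_value, 1 / 201)

  # every null matrix keeps both margins: re-simulate and check directly
  nm <- vegan::nullmodel(t(pa), "swap")
  sims <- stats::simulate(nm, nsim = 20, burnin = 10 * sum(pa),
                          thin = sum(pa), seed = 14)
  for (i in 1:20) {
    expect_equal(colSums(sims[, , i]), rowSums(pa), ignore_attr = TRUE)
    expect_equal(rowSums(sims[, , i]), colSums(pa), ignore_attr = TRUE)
  }

  # block-segregated occurrence -> C-score far above the null
  seg <- rbind(cbind(matrix(1, 5, 6), matrix(0, 5, 6)),
               cbind(matrix(0, 5, 6), matrix(1, 5, 6)))
  res_seg <- c_score_null_test(seg, n_null = 200, seed = 15)
  expect_gt(res_seg$ses, 2)
})
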