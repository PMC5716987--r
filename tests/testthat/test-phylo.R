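# Core phylogenetic structure metrics against brute-force oracles and
# exhaustive enumeration; null-model conservation laws; scale invariance.

test_that("cophenetic distances equal path sums on hand and random trees", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(cophenetic_distances(two)["A", "B"], 2)

  tr <- balanced4()
  D <- cophenetic_distances(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_true(all(diag(D) == 0))

  for (s in 1:3) {
    rt <- simulate_yule_tree(6, seed = s)
    expect_equal(cophenetic_distances(rt), oracle_cophenetic(rt), tolerance = 1e-12)
  }
})

test_that("environmental optima are abundance-weighted means over samples", {
  f <- matrix(c(1, 1, 0,
                1, 0, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("Oa", "Ob", "Oc")))
  env <- c(S1 = 4, S2 = 8)
  opt <- environmental_optimum(f, env)
  expect_equal(opt[["Oa"]], 6)   # counts (1,1) at env (4,8)
  expect_equal(opt[["Ob"]], 4)   # single-sample OTU gets that sample's env
  expect_equal(opt[["Oc"]], 8)
  expect_equal(unname(environmental_optimum(f, c(S1 = 5, S2 = 5))), rep(5, 3))
  f2 <- cbind(f, Od = c(0, 0))
  expect_message(opt2 <- environmental_optimum(f2, env), "absent")
  expect_false("Od" %in% names(opt2))
})

test_that("alpha MPD matches the printed formula and the naive oracle", {
  tr <- balanced4()
  D <- cophenetic_distances(tr)
  f2 <- stats::setNames(c(0.7, 0.3, 0, 0), tr$tip.label)
  expect_equal(alpha_mpd(f2, D), 2)  # any two-taxon split at distance 2

  Dm <- matrix(c(0, 2, 4, 2, 0, 2, 4, 2, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  f3 <- stats::setNames(c(0.5, 0.25, 0.25), c("A", "B", "C"))
  expect_equal(alpha_mpd(f3, Dm), 2.75)  # 0.5*3 + 0.25*2 + 0.25*3

  # permuting OTU order leaves the value unchanged
  perm <- c("C", "A", "B")
  expect_equal(alpha_mpd(f3[perm], Dm[perm, perm]), 2.75)

  expect_warning(v <- alpha_mpd(stats::setNames(c(1, 0, 0, 0), tr$tip.label), D),
                 "undefined")
  expect_true(is.na(v))

  # oracle sweep: random communities on random trees up to 6 tips
  for (s in 1:5) {
    rt <- simulate_yule_tree(sample(4:6, 1), seed = s)
    Dr <- cophenetic_distances(rt)
    f <- stats::setNames(runif(ape::Ntip(rt)), rt$tip.label)
    f[sample(length(f), 1)] <- 0
    f <- f / sum(f)
    expect_equal(alpha_mpd(f, Dr), unname(oracle_alpha_mpd(f, Dr)), tolerance = 1e-12)
  }
})

test_that("phylogeny-pool null preserves richness and the abundance multiset", {
  pool <- paste0("O", 1:8)
  f <- stats::setNames(c(0.5, 0.3, 0.2, rep(0, 5)), pool)
  r <- phylogeny_pool_null(f, pool, seed = 1)
  expect_equal(sum(r > 0), 3)
  expect_equal(sum(r), 1)
  expect_setequal(r[r > 0], c(0.5, 0.3, 0.2))

  # pool size equal to richness: a permutation of the same taxa
  r2 <- phylogeny_pool_null(f[1:3], pool[1:3], seed = 2)
  expect_setequal(names(r2)[r2 > 0], pool[1:3])
  expect_error(phylogeny_pool_null(f, pool[1:2]), "exceeds")

  # uniform pair frequencies: richness 2 from a 4-taxon pool -> each of the
  # 6 unordered pairs at 1/6 within 3 SE over many draws
  pool4 <- paste0("P", 1:4)
  f4 <- stats::setNames(c(0.6, 0.4, 0, 0), pool4)
  draws <- withr::with_seed(42, replicate(6000, {
    rr <- phylogeny_pool_null(f4, pool4)
    paste(sort(names(rr)[rr > 0]), collapse = "+")
  }))
  freq <- table(draws) / 6000
  expect_equal(length(freq), 6)
  se <- sqrt((1 / 6) * (5 / 6) / 6000)
  expect_true(all(abs(freq - 1 / 6) <= 3 * se))
})

test_that("alpha NRI signs follow clade membership on the balanced 4-tip tree", {
  tr <- balanced4()
  D <- cophenetic_distances(tr)
  within <- alpha_nri(stats::setNames(c(0.5, 0.5, 0, 0), tr$tip.label), D,
                      n_rand = 2000, seed = 3)
  expect_gt(within$nri, 0)  # observed 2 < null mean 10/3 -> clustered
  expect_equal(within$nri, -within$ses)
  cross <- alpha_nri(stats::setNames(c(0.5, 0, 0.5, 0), tr$tip.label), D,
                     n_rand = 2000, seed = 4)
  expect_lt(cross$nri, 0)   # observed 4 > null mean -> overdispersed

  # observed equal to the null mean -> nri ~ 0 by construction
  nulls <- attr(within, "null")
  expect_equal(within$null_mean, mean(nulls))
  expect_equal(within$ses, (within$observed - mean(nulls)) / sd(nulls))
})

test_that("beta MPD matches hand values and the naive oracle", {
  tr <- balanced4()
  D <- cophenetic_distances(tr)
  one <- stats::setNames(c(1, 0, 0, 0), tr$tip.label)
  expect_equal(beta_mpd(one, one, D), 0)            # identical singletons
  oneB <- stats::setNames(c(0, 1, 0, 0), tr$tip.label)
  expect_equal(beta_mpd(one, oneB, D), 2)
  half <- stats::setNames(c(0.5, 0.5, 0, 0), tr$tip.label)
  expect_equal(beta_mpd(half, one, D), 1)           # 0.5*0 + 0.5*2

  for (s in 1:5) {
    rt <- simulate_yule_tree(6, seed = 10 + s)
    Dr <- cophenetic_distances(rt)
    fk <- stats::setNames(runif(6), rt$tip.label); fk[sample(6, 2)] <- 0
    fl <- stats::setNames(runif(6), rt$tip.label); fl[sample(6, 3)] <- 0
    fk <- fk / sum(fk); fl <- fl / sum(fl)
    expect_equal(beta_mpd(fk, fl, Dr), oracle_beta_mpd(fk, fl, Dr),
                 tolerance = 1e-12)
  }
  empty <- stats::setNames(rep(0, 4), tr$tip.label)
  expect_error(beta_mpd(empty, one, D), "non-empty")
})

test_that("beta NRI is the stored-null formula to machine precision", {
  tr <- simulate_yule_tree(12, seed = 20)
  D <- cophenetic_distances(tr)
  fk <- stats::setNames(rep(0, 12), tr$tip.label); fk[1:4] <- 0.25
  fl <- stats::setNames(rep(0, 12), tr$tip.label); fl[5:9] <- 0.2
  b <- beta_nri(fk, fl, D, n_rand = 200, seed = 21)
  nulls <- attr(b, "null")
  expect_equal(b$beta_nri, (b$beta_mpd_observed - mean(nulls)) / sd(nulls),
               tolerance = 1e-12)
  expect_equal(b$n_randomizations, 200)
})

test_that("group means of beta metrics average the C(n,2) within-group pairs", {
  res <- data.frame(sample_1 = c("a1", "a1", "a2", "b1", "a1"),
                    sample_2 = c("a2", "a3", "a3", "b2", "b1"),
                    beta_mpd = c(1, 2, 3, 5, 9))
  md <- data.frame(sample_id = c("a1", "a2", "a3", "b1", "b2", "c1"),
                   group = c("A", "A", "A", "B", "B", "C"))
  expect_warning(g <- group_mean_beta(res, md, "beta_mpd"), "c1|C")
  A <- g[g$group == "A", ]
  expect_equal(A$n_pairs, 3)  # C(3,2)
  expect_equal(A$mean, 2)
  B <- g[g$group == "B", ]
  expect_equal(B$mean, 5)
  expect_equal(B$sd, 0)       # single pair
  expect_match(A$display, "^2\\.000 ± 1\\.000$")
})

test_that("MPD scales with branch lengths while NRI is scale-free", {
  tr <- simulate_yule_tree(30, seed = 30)
  D <- cophenetic_distances(tr)
  f <- stats::setNames(rep(0, 30), tr$tip.label)
  f[sample(30, 10)] <- 0.1
  a1 <- alpha_nri(f, D, n_rand = 300, seed = 31)
  a2 <- alpha_nri(f, D * 3.5, n_rand = 300, seed = 31)
  expect_equal(a2$observed, 3.5 * a1$observed, tolerance = 1e-12)
  expect_equal(a2$nri, a1$nri, tolerance = 1e-9)  # same seed, same draws
})

test_that("weighted alpha MPD agrees with picante on equal-abundance communities", {
  skip_if_not_installed("picante")
  tr <- simulate_yule_tree(15, seed = 40)
  D <- cophenetic_distances(tr)
  comm <- matrix(0, 1, 15, dimnames = list("s", tr$tip.label))
  comm[1, sample(15, 6)] <- 1
  f <- comm[1, ] / sum(comm[1, ])
  # with equal weights the focal-taxon form reduces to unweighted MPD
  expect_equal(alpha_mpd(f, D),
               picante::mpd(comm, D, abundance.weighted = FALSE),
               tolerance = 1e-12)
})

test_that("Mantel correlogram finds conservatism and honors its structure", {
  tr <- simulate_yule_tree(60, seed = 50)
  D <- cophenetic_distances(tr)
  opt <- evolve_trait_bm(tr, sigma2 = 1, seed = 51)
  cg <- mantel_correlogram(D, as.matrix(dist(opt)), n_classes = 12,
                           n_perm = 199, seed = 52)
  expect_s3_class(cg, "mantel_correlogram")
  expect_equal(nrow(cg), 12)
  expect_true(all(diff(cg$midpoint) > 0))
  # strong Brownian signal: smallest class positive and significant
  expect_gt(cg$mantel_r[1], 0)
  expect_lt(cg$p_permutation[1], 0.05)
  # empty classes are flagged, not errors
  expect_true(all(cg$flag[cg$n_pairs == 0] == "no pairs in class"))
  expect_error(mantel_correlogram(D, as.matrix(dist(opt)), n_classes = 1), ">= 2")
})
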