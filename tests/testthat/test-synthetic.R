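# Synthetic-data generator: determinism, distributional ground truth, and
# the limit/enumeration identities of the assembly rules.

test_that("Yule trees have the right shape and are seed-deterministic", {
  t2 <- simulate_yule_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(t2$Nnode, 1)

  t64 <- simulate_yule_tree(64, seed = 2)
  expect_equal(t64$Nnode, 63)  # rooted binary: n - 1 internal nodes
  expect_true(all(t64$edge.length > 0))
  depths <- ape::node.depth.edgelength(t64)[seq_len(64)]
  expect_gt(mean(depths), 0)
  expect_identical(ape::write.tree(simulate_yule_tree(64, seed = 2)),
                   ape::write.tree(t64))
  expect_error(simulate_yule_tree(1), ">= 2")
})

test_that("Brownian trait variance matches the closed form on a two-tip tree", {
  tree <- ape::read.tree(text = "(A:1.5,B:2.5);")
  diffs <- vapply(1:1500, function(i)
    diff(evolve_trait_bm(tree, sigma2 = 0.8, seed = i)), numeric(1))
  # Var(tipA - tipB) = sigma2 * (pathA + pathB) = 0.8 * 4 = 3.2
  expect_lt(abs(var(diffs) - 3.2) / 3.2, 0.10)

  expect_equal(unname(evolve_trait_bm(tree, sigma2 = 0, root_value = 7)), c(7, 7))
  expect_identical(evolve_trait_bm(tree, 1, seed = 9), evolve_trait_bm(tree, 1, seed = 9))
  expect_error(evolve_trait_bm(tree, sigma2 = -1), ">= 0")
})

test_that("neutral assembly with full pool keeps every taxon", {
  tree <- simulate_yule_tree(10, seed = 3)
  opt <- evolve_trait_bm(tree, seed = 4)
  prof <- assemble_community(tree, opt, assembly_scenario("neutral", 10), seed = 5)
  expect_true(all(prof > 0))
  expect_equal(sum(prof), 1)
})

test_that("infinite filter breadth is distributionally neutral (KS on chosen optima)", {
  tree <- simulate_yule_tree(20, seed = 6)
  opt <- evolve_trait_bm(tree, seed = 7)
  wide <- assembly_scenario("filtering", 10, filter_breadth = 1e9)
  neut <- assembly_scenario("neutral", 10)
  opt_f <- unlist(lapply(1:500, function(i) {
    p <- assemble_community(tree, opt, wide, seed = 10000 + i)
    opt[names(p)[p > 0]]
  }))
  opt_n <- unlist(lapply(1:500, function(i) {
    p <- assemble_community(tree, opt, neut, seed = 20000 + i)
    opt[names(p)[p > 0]]
  }))
  ks <- suppressWarnings(stats::ks.test(opt_f, opt_n))
  expect_gt(ks$p.value, 0.01)
})

test_that("greedy overdispersion on the balanced 4-tip tree always picks a cross-clade pair", {
  tree <- balanced4()
  opt <- stats::setNames(rep(0, 4), tree$tip.label)
  sc <- assembly_scenario("overdispersion", 2)
  for (i in 1:25) {
    chosen <- names(which(assemble_community(tree, opt, sc, seed = i) > 0))
    # the greedy max-min rule must cross the basal split
    expect_equal(sum(chosen %in% c("A", "B")), 1, info = paste(chosen, collapse = ","))
  }
})

test_that("multinomial counts respect the profile", {
  prof <- stats::setNames(c(1, 0, 0), paste0("O", 1:3))
  cnt <- counts_from_profile(prof, 100, seed = 1)
  expect_equal(unname(cnt), c(100L, 0L, 0L))
  expect_error(counts_from_profile(prof, 0), ">= 1")

  prof2 <- stats::setNames(c(0.6, 0.3, 0.1), paste0("O", 1:3))
  cnt2 <- counts_from_profile(prof2, 10000, seed = 2)
  expect_equal(sum(cnt2), 10000)
  se <- sqrt(prof2 * (1 - prof2) * 10000)
  expect_true(all(abs(cnt2 - 10000 * prof2) <= 3 * se))
})

test_that("correlated count generator recovers its basis correlation", {
  C <- diag(10)
  C[1, 2] <- C[2, 1] <- 0.9
  cnt <- generate_correlated_counts(C, n_samples = 500, depth = 5000, seed = 8)
  expect_identical(attr(cnt, "basis_corr"), C)
  Z <- attr(cnt, "log_basis")
  expect_lt(abs(cor(Z[, 1], Z[, 2]) - 0.9), 0.05)
  # the planted pair is also the strongest count-level association
  L <- log(cnt + 1)
  expect_lt(abs(cor(L[, 1], L[, 2]) - 0.9), 0.1)

  cnt0 <- generate_correlated_counts(diag(10), n_samples = 200, depth = 5000, seed = 9)
  Z0 <- attr(cnt0, "log_basis")
  R <- cor(Z0)
  diag(R) <- 0
  # null sampling bound: SE(r) = 1/sqrt(n-1); Bonferroni z for the max over
  # the 45 pairs at alpha = 0.01 is ~3.5. (Count-level log correlations
  # additionally carry the closure bias of about -1/(p-1), which is what
  # SparCC corrects for.)
  expect_lt(max(abs(R)), 3.5 / sqrt(199))
  expect_lt(mean(abs(R[upper.tri(R)])), 0.06)

  expect_identical(generate_correlated_counts(C, 20, depth = 100, seed = 4),
                   generate_correlated_counts(C, 20, depth = 100, seed = 4))
  bad <- matrix(c(1, 2, 2, 1), 2, 2)  # not PSD
  expect_error(generate_correlated_counts(bad, 10), "positive semi-definite")
})

test_that("make_study yields the 7x4 design with recorded ground truth", {
  st <- make_study(n_tips = 60, design = default_study_design(20), seed = 11,
                   depth = 2000)
  expect_equal(nrow(st$counts), 28)  # 7 treatments x 4 replicates
  expect_equal(sort(unique(st$metadata$group)),
               sort(c("Control", "NK", "NP", "NPK", "OM", "OMN", "PK")))
  expect_equal(st$truth$sample_id, st$metadata$sample_id)
  expect_true(all(st$truth$process == "filtering"))
  expect_true(all(colnames(st$counts) %in% st$tree$tip.label))

  neutral <- lapply(stats::setNames(nm = c("A", "B")), function(x)
    assembly_scenario("neutral", 10))
  st2 <- make_study(n_tips = 40, design = neutral, seed = 12, depth = 500)
  expect_true(all(st2$truth$process == "neutral"))
  expect_error(make_study(n_tips = 40, design = list(), seed = 1), "at least one")
})

test_that("a study serializes byte-identically under the same seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(make_study(n_tips = 40, design = default_study_design(12),
                         seed = 13, depth = 500), d1)
  write_study(make_study(n_tips = 40, design = default_study_design(12),
                         seed = 13, depth = 500), d2)
  for (f in c("otu_table.tsv", "tree.nwk", "metadata.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})
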