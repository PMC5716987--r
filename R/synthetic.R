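## synthetic_data: trees, conserved traits, community assembly under known
## processes, and compositional count tables with known basis correlation.
## Everything is seed-deterministic; the generator is the ground truth that
## the inference modules are validated against.

#' Simulate a Yule (pure-birth) tree
#'
#' Rooted binary tree with exponential waiting times between speciation
#' events, conditioned on the number of extant tips. Tips are labelled
#' `OTU_1 ... OTU_n`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed optional integer seed.
#' @param birth speciation rate (time units are arbitrary; default 1).
#' @return an `ape::phylo` tree with positive branch lengths.
#' @export
simulate_yule_tree <- function(n_tips, seed = NULL, birth = 1) {
  if (n_tips < 2L) stopf("n_tips must be >= 2")
  tree <- with_seed_or_not(seed, ape::rphylo(n_tips, birth = birth, death = 0))
  tree$tip.label <- paste0("OTU_", seq_len(n_tips))
  tree
}

#' Evolve a continuous trait on a tree by Brownian motion
#'
#' Models phylogenetically conserved environmental optima: tip values are
#' the sum of independent Gaussian increments along branches, so variance
#' around the root value grows as `sigma2` times root-to-tip path length and
#' close relatives end up with similar optima.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length). `0` is
#'   accepted and returns all tips equal to `root_value`.
#' @param root_value trait value at the root.
#' @param seed optional integer seed.
#' @return named numeric vector of per-tip optima.
#' @export
evolve_trait_bm <- function(tree, sigma2 = 1, root_value = 0, seed = NULL) {
  if (sigma2 < 0) stopf("sigma2 must be >= 0")
  if (is.null(tree$edge.length)) stopf("tree must have branch lengths")
  if (sigma2 == 0) {
    out <- rep(root_value, length(tree$tip.label))
    names(out) <- tree$tip.label
    return(out)
  }
  with_seed_or_not(seed,
    ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2),
                    root.value = root_value))
}

#' An assembly scenario description
#'
#' @param process one of `"filtering"`, `"overdispersion"`, `"neutral"`.
#' @param n_taxa_community community richness to assemble.
#' @param filter_breadth niche breadth in trait units (filtering only;
#'   smaller = stronger filtering).
#' @param env_value local environmental value in trait units (filtering).
#' @param dirichlet_alpha symmetric Dirichlet concentration for relative
#'   abundances of the chosen taxa.
#' @return a list of class `assembly_scenario`.
#' @export
assembly_scenario <- function(process = c("filtering", "overdispersion", "neutral"),
                              n_taxa_community,
                              filter_breadth = 1,
                              env_value = 0,
                              dirichlet_alpha = 1) {
  process <- match.arg(process)
  if (filter_breadth <= 0) stopf("filter_breadth must be > 0")
  if (n_taxa_community < 1L) stopf("n_taxa_community must be >= 1")
  structure(list(process = process,
                 n_taxa_community = as.integer(n_taxa_community),
                 filter_breadth = filter_breadth,
                 env_value = env_value,
                 dirichlet_alpha = dirichlet_alpha),
            class = "assembly_scenario")
}

#' Assemble one community under a known ecological process
#'
#' * `filtering`: taxa are drawn without replacement with probability
#'   proportional to `exp(-(optimum - env_value)^2 / (2 * filter_breadth^2))`
#'   (Gaussian environmental filter around the local environment).
#' * `overdispersion`: greedy competitive-exclusion caricature; starting
#'   from a random tip, iteratively add the taxon maximizing the minimum
#'   patristic distance to the taxa already chosen (ties broken at random).
#' * `neutral`: uniform sampling without replacement.
#'
#' Relative abundances of the chosen taxa are a symmetric Dirichlet draw.
#'
#' @param tree `ape::phylo`; its tips are the species pool.
#' @param optima named per-tip trait optima (used by `filtering`).
#' @param scenario an [assembly_scenario()].
#' @param seed optional integer seed.
#' @param D optional precomputed patristic distance matrix (speeds up
#'   repeated `overdispersion` calls).
#' @return named numeric relative-abundance profile over all pool taxa
#'   (zeros for absent taxa), summing to 1.
#' @export
assemble_community <- function(tree, optima, scenario, seed = NULL, D = NULL) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  pool <- tree$tip.label
  S <- scenario$n_taxa_community
  if (S > length(pool)) stopf("n_taxa_community (%d) exceeds pool size (%d)", S, length(pool))
  with_seed_or_not(seed, {
    chosen <- switch(scenario$process,
      neutral = sample(pool, S),
      filtering = {
        if (is.na(scenario$env_value))
          stopf("filtering scenario needs env_value (see place_environment)")
        opt <- optima[pool]
        w <- exp(-(opt - scenario$env_value)^2 / (2 * scenario$filter_breadth^2))
        eligible <- sum(w > 0)
        if (eligible < S)
          stopf("only %d taxa have positive filter weight; %d needed", eligible, S)
        sample(pool, S, prob = w)
      },
      overdispersion = {
        if (is.null(D)) D <- cophenetic_distances(tree)
        D <- D[pool, pool]
        sel <- sample(pool, 1L)
        while (length(sel) < S) {
          rest <- setdiff(pool, sel)
          mind <- apply(D[rest, sel, drop = FALSE], 1L, min)
          best <- rest[mind == max(mind)]
          sel <- c(sel, if (length(best) > 1L) sample(best, 1L) else best)
        }
        sel
      })
    ab <- stats::rgamma(S, shape = scenario$dirichlet_alpha, rate = 1)
    ab <- ab / sum(ab)
    profile <- stats::setNames(numeric(length(pool)), pool)
    profile[chosen] <- ab
    profile
  })
}

#' Multinomially sample integer counts from a relative-abundance profile
#'
#' @param profile non-negative vector summing to 1.
#' @param depth total number of reads to draw (>= 1).
#' @param seed optional integer seed.
#' @return named integer vector summing to `depth`.
#' @export
counts_from_profile <- function(profile, depth, seed = NULL) {
  if (depth < 1L) stopf("depth must be >= 1")
  if (any(profile < 0) || abs(sum(profile) - 1) > 1e-8)
    stopf("profile must be non-negative and sum to 1")
  cnt <- with_seed_or_not(seed, stats::rmultinom(1L, size = depth, prob = profile))
  stats::setNames(as.integer(cnt), names(profile))
}

#' Generate compositional counts with a known basis correlation
#'
#' Basis abundances are log-normal: log-abundances are multivariate normal
#' with correlation `basis_corr` (and unit log-variance by default), closed
#' to compositions per sample and multinomially sampled at `depth`. The
#' ground-truth matrix is attached as attribute `basis_corr`.
#'
#' @param basis_corr positive semi-definite correlation matrix (unit
#'   diagonal), one row per OTU.
#' @param n_samples number of samples.
#' @param n_otus number of OTUs; must match `nrow(basis_corr)`.
#' @param depth sequencing depth per sample.
#' @param seed optional integer seed.
#' @param log_mean,log_sd mean and sd of log basis abundances.
#' @return samples x OTUs integer matrix with attributes `basis_corr`
#'   (the target) and `log_basis` (the latent log-abundance draws, so the
#'   ground truth can be checked directly, free of the negative
#'   correlation bias that compositional closure adds to count-level
#'   log correlations).
#' @export
generate_correlated_counts <- function(basis_corr, n_samples, n_otus = nrow(basis_corr),
                                       depth = 5000, seed = NULL,
                                       log_mean = 0, log_sd = 1) {
  if (!isSymmetric(unname(basis_corr)) || any(abs(diag(basis_corr) - 1) > 1e-8))
    stopf("basis_corr must be symmetric with unit diagonal")
  if (n_otus != nrow(basis_corr)) stopf("n_otus must match nrow(basis_corr)")
  ev <- eigen(basis_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stopf("basis_corr is not positive semi-definite")
  Sigma <- basis_corr * log_sd^2
  with_seed_or_not(seed, {
    Z <- MASS::mvrnorm(n_samples, mu = rep(log_mean, n_otus), Sigma = Sigma)
    basis <- exp(Z)
    fracs <- basis / rowSums(basis)
    counts <- t(apply(fracs, 1L, function(p) stats::rmultinom(1L, depth, p)))
    dimnames(counts) <- list(paste0("S", seq_len(n_samples)),
                             paste0("OTU_", seq_len(n_otus)))
    storage.mode(counts) <- "integer"
    attr(counts, "basis_corr") <- basis_corr
    attr(counts, "log_basis") <- Z
    counts
  })
}

#' Place the environmental value where filtering selects a coherent guild
#'
#' Community-phylogenetics inference of environmental filtering presumes
#' niche conservatism: the taxa favoured by the local environment must be
#' a phylogenetically coherent guild, not a trait-convergent scatter.
#' Under Brownian motion that premise holds at some trait values and not
#' others (taxa near the ancestral value occur in every clade). This
#' helper scans candidate environment values over the quantiles of the
#' tip optima and returns the one whose Gaussian filter weights
#' `w_i = exp(-(opt_i - env)^2 / (2 fb^2))` minimize the weighted expected
#' pairwise patristic distance `sum(w_i w_j D_ij) / sum(w_i w_j)` —
#' i.e. the environment that selects the most phylogenetically clustered
#' set — subject to the filter retaining enough taxa.
#'
#' @param optima named per-tip trait optima.
#' @param D patristic distance matrix over the same tips.
#' @param filter_breadth niche breadth the filter will use.
#' @param min_effective_pool minimum effective number of taxa
#'   (`sum(w)`) the chosen environment must retain (default 30).
#' @param probs quantile grid of candidate environment values.
#' @return the chosen environment value (numeric scalar).
#' @export
place_environment <- function(optima, D, filter_breadth = 0.25,
                              min_effective_pool = 30,
                              probs = seq(0.02, 0.98, by = 0.02)) {
  optima <- optima[rownames(D)]
  cand <- stats::quantile(optima, probs, names = FALSE)
  stats_ <- vapply(cand, function(ev) {
    w <- exp(-(optima - ev)^2 / (2 * filter_breadth^2))
    W <- tcrossprod(w)
    diag(W) <- 0
    c(sum(W * D) / sum(W), sum(w))
  }, numeric(2))
  ok <- stats_[2L, ] >= min_effective_pool
  if (!any(ok)) ok <- stats_[2L, ] == max(stats_[2L, ])
  cand[ok][which.min(stats_[1L, ok])]
}

#' Default 7-treatment x 4-replicate study design
#'
#' Emulates a long-term fertilization trial: seven regimes (Control, NK,
#' NP, NPK, OM, OMN, PK) with four replicates each, all assembled by
#' environmental filtering around a common optimum but with graded niche
#' breadth — strongest filtering in the P-deficient regimes (NK, Control),
#' weakest in PK. Available phosphorus (AP) rises monotonically with niche
#' breadth; yield peaks at intermediate filtering. The shared environment
#' value is `NA` here and is placed per realization by [make_study()] via
#' [place_environment()], so the filter targets a phylogenetically
#' coherent guild (all treatments share one optimum, mirroring a single
#' field site).
#'
#' @param n_taxa_community per-sample richness.
#' @return named list mapping treatment to [assembly_scenario()], with a
#'   `filter_breadth` gradient attribute used for covariate generation.
#' @export
default_study_design <- function(n_taxa_community = 75L) {
  breadth <- c(NK = 0.15, Control = 0.20, NPK = 0.30, OM = 0.35,
               OMN = 0.40, NP = 0.45, PK = 0.70)
  design <- lapply(breadth, function(b)
    assembly_scenario("filtering", n_taxa_community = n_taxa_community,
                      filter_breadth = b, env_value = NA_real_))
  attr(design, "filter_breadth") <- breadth
  design
}

#' Generate a full synthetic study with known assembly ground truth
#'
#' Simulates a Yule phylogeny, Brownian environmental optima (standardized
#' to unit variance so `filter_breadth` is in trait-sd units), per-sample
#' communities under the design's scenarios, multinomial counts, and
#' covariates with stated monotone links to filtering strength plus
#' Gaussian noise.
#'
#' @param n_tips species-pool size.
#' @param design named list of treatment -> [assembly_scenario()];
#'   default [default_study_design()].
#' @param seed integer master seed (all randomness derives from it).
#' @param n_replicates replicates per treatment.
#' @param depth sequencing depth per sample (multinomial total).
#' @return list of class `synthetic_study` with elements `tree`, `optima`
#'   (standardized), `counts` (samples x OTUs), `metadata` (sample_id,
#'   group, covariates), `truth` (per-sample scenario record), `seed`.
#' @export
make_study <- function(n_tips = 500L, design = default_study_design(),
                       seed = 1L, n_replicates = 4L, depth = 10000L) {
  if (length(design) == 0L) stopf("design must map at least one treatment to a scenario")
  if (is.null(names(design)) || any(names(design) == ""))
    stopf("design must be a named list of treatments")
  tree <- simulate_yule_tree(n_tips, seed = derive_seed(seed, 1L))
  optima <- evolve_trait_bm(tree, sigma2 = 1, seed = derive_seed(seed, 2L))
  optima <- (optima - mean(optima)) / stats::sd(optima)
  D <- cophenetic_distances(tree)

  # scenarios with env_value = NA share an optimum placed where filtering
  # selects a phylogenetically coherent guild (see place_environment)
  needs_env <- vapply(design, function(s)
    s$process == "filtering" && is.na(s$env_value), logical(1))
  if (any(needs_env)) {
    fb_ref <- min(vapply(design[needs_env], function(s) s$filter_breadth,
                         numeric(1)))
    env_shared <- place_environment(optima, D, filter_breadth = max(fb_ref, 0.25))
    for (tr in names(design)[needs_env]) design[[tr]]$env_value <- env_shared
  }

  treatments <- names(design)
  breadth <- attr(design, "filter_breadth") %||%
    vapply(design, function(s) s$filter_breadth, numeric(1))
  sample_ids <- character(0)
  rows <- list()
  truth <- list()
  k <- 0L
  for (tr in treatments) {
    for (rep_i in seq_len(n_replicates)) {
      k <- k + 1L
      sid <- sprintf("%s_%d", tr, rep_i)
      prof <- assemble_community(tree, optima, design[[tr]],
                                 seed = derive_seed(seed, 100L + k), D = D)
      cnt <- counts_from_profile(prof, depth, seed = derive_seed(seed, 5000L + k))
      rows[[sid]] <- cnt
      truth[[sid]] <- data.frame(sample_id = sid, group = tr,
                                 process = design[[tr]]$process,
                                 n_taxa_community = design[[tr]]$n_taxa_community,
                                 filter_breadth = design[[tr]]$filter_breadth,
                                 env_value = design[[tr]]$env_value,
                                 stringsAsFactors = FALSE)
      sample_ids <- c(sample_ids, sid)
    }
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- sample_ids
  counts <- validate_otu_table(counts)
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  metadata <- with_seed_or_not(derive_seed(seed, 9L), {
    b <- breadth[truth$group]
    noise <- function(sd) stats::rnorm(nrow(truth), 0, sd)
    data.frame(
      sample_id = truth$sample_id,
      group = truth$group,
      # AP rises with niche breadth (P availability relaxes the filter)
      AP = 5 + 20 * b + noise(0.8),
      # pH mildly alkaline, weakly linked to breadth
      pH = 8.3 - 0.3 * b + noise(0.08),
      # carbon / nitrogen pools richer under weaker filtering
      SOC = 6 + 4 * b + noise(0.4),
      TN = 0.6 + 0.45 * b + noise(0.05),
      AK = 80 + noise(8),
      Ivt = 8 + 5 * b + noise(0.7),
      MC = 150 + 120 * b + noise(15),
      # yield peaks at intermediate filtering strength
      yield = 6500 - 9000 * (b - 0.35)^2 + noise(150),
      P_max = 20 + 30 * b + noise(2),
      t_max = 50 - 25 * b + noise(2.5),
      Q_T = 18 + noise(1.5),
      K_growth = 0.02 + 0.05 * b + noise(0.003),
      stringsAsFactors = FALSE)
  })

  structure(list(tree = tree, optima = optima, counts = counts,
                 metadata = metadata, truth = truth, seed = as.integer(seed)),
            class = "synthetic_study")
}

#' Write a synthetic study to a directory
#'
#' Emits `otu_table.tsv`, `tree.nwk`, `metadata.tsv` and the ground truth
#' `truth.json` so a pipeline run can be scored against the generator.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(study$counts, file.path(dir, "otu_table.tsv"))
  write_tree_newick(study$tree, file.path(dir, "tree.nwk"))
  write_sample_metadata(study$metadata, file.path(dir, "metadata.tsv"))
  truth <- list(seed = study$seed,
                optima = as.list(round(study$optima, 10)),
                samples = study$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
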