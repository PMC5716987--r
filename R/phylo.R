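## phylo_structure: the core computation. Phylogenetic signal (Mantel
## correlogram on environmental optima), abundance-weighted alpha/beta mean
## pairwise phylogenetic distance, phylogeny-pool null models, and the
## standardized effect sizes NRI / betaNRI with the +/-2 process rules.

#' Patristic (cophenetic) distances between all tips
#'
#' @param tree `ape::phylo` with branch lengths and >= 2 tips.
#' @return symmetric matrix of tip-to-tip path-length distances, ordered
#'   as `tree$tip.label`.
#' @export
cophenetic_distances <- function(tree) {
  if (length(tree$tip.label) < 2L) stopf("need a tree with >= 2 tips")
  if (is.null(tree$edge.length)) {
    warnf("tree has no branch lengths; treating them as 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Abundance-weighted environmental optimum of each OTU
#'
#' The optimum of OTU i is the mean of the environmental variable over the
#' samples it occurs in, weighted by its relative abundance there:
#' `optimum_i = sum_k f'_ik * env_k`, with `f'_ik` the OTU's abundances
#' normalized over samples. OTUs absent everywhere are excluded with a
#' message.
#'
#' @param f samples x OTUs relative-abundance (or count) matrix.
#' @param env named (or table-ordered) numeric vector, one value per sample.
#' @return named numeric vector of optima for the OTUs present somewhere.
#' @export
environmental_optimum <- function(f, env) {
  if (length(env) != nrow(f)) stopf("need one environmental value per sample")
  if (!is.null(names(env))) env <- env[rownames(f)]
  totals <- colSums(f)
  absent <- totals == 0
  if (any(absent)) {
    message(sum(absent), " OTU(s) absent from every sample excluded from optima")
    f <- f[, !absent, drop = FALSE]
    totals <- totals[!absent]
  }
  w <- sweep(f, 2L, totals, "/")
  stats::setNames(as.vector(crossprod(w, env)), colnames(f))
}

#' Abundance-weighted alpha mean pairwise phylogenetic distance
#'
#' \deqn{\alpha MPD = \sum_i f_i \, \mathrm{mean}_{j \ne i}(\Delta_{ij})}
#' over the OTUs present in the sample: each focal taxon contributes its
#' relative abundance times the unweighted mean patristic distance to its
#' co-occurring partners. A fully pairwise-weighted variant is available
#' for sensitivity checks.
#'
#' @param f_row relative abundances for one sample (named over the OTUs of
#'   `D`, zeros for absent taxa). Weights are renormalized over present
#'   taxa.
#' @param D patristic distance matrix covering the present OTUs.
#' @param pairwise_weighted if `TRUE`, use
#'   `sum_ij f_i f_j Delta_ij / sum_ij f_i f_j` (i != j) instead.
#' @return numeric scalar; `NA` with a warning when fewer than 2 OTUs are
#'   present (undefined).
#' @export
alpha_mpd <- function(f_row, D, pairwise_weighted = FALSE) {
  ids <- names(f_row)[f_row > 0]
  if (length(ids) < 2L) {
    warnf("alpha MPD undefined for a community with < 2 taxa")
    return(NA_real_)
  }
  w <- f_row[ids] / sum(f_row[ids])
  sub <- D[ids, ids, drop = FALSE]
  if (pairwise_weighted) {
    W <- tcrossprod(w)
    diag(W) <- 0
    return(sum(W * sub) / sum(W))
  }
  partner_mean <- rowSums(sub) / (length(ids) - 1L)
  sum(w * partner_mean)
}

#' Phylogeny-pool randomization of one community
#'
#' Preserves the sample's richness and abundance multiset; the abundances
#' are reassigned (in shuffled order) to taxa drawn uniformly without
#' replacement from the full species pool — all tips of the phylogeny.
#'
#' @param f_row named abundances over the pool.
#' @param pool_ids character vector of pool taxa.
#' @param seed optional integer seed.
#' @return randomized named vector over `pool_ids`.
#' @export
phylogeny_pool_null <- function(f_row, pool_ids, seed = NULL) {
  ab <- f_row[f_row > 0]
  S <- length(ab)
  if (S > length(pool_ids)) stopf("richness %d exceeds pool size %d", S, length(pool_ids))
  with_seed_or_not(seed, {
    chosen <- sample(pool_ids, S)
    out <- stats::setNames(numeric(length(pool_ids)), pool_ids)
    out[chosen] <- if (S > 1L) sample(unname(ab)) else unname(ab)
    out
  })
}

## Fast inner null draw: returns the alpha MPD of one phylogeny-pool
## randomization without materializing the full pool-length vector.
.null_alpha_mpd <- function(ab_sorted, S, pool_ids, D, pairwise_weighted) {
  ids <- sample(pool_ids, S)
  w <- sample(ab_sorted)
  w <- w / sum(w)
  sub <- D[ids, ids, drop = FALSE]
  if (pairwise_weighted) {
    W <- tcrossprod(w)
    diag(W) <- 0
    sum(W * sub) / sum(W)
  } else {
    sum(w * (rowSums(sub) / (S - 1L)))
  }
}

#' Alpha NRI: standardized effect size of alpha MPD under the phylogeny pool
#'
#' The observed alpha MPD is compared with its null distribution under
#' [phylogeny_pool_null()]; `ses = (obs - mean(null)) / sd(null)` with the
#' sample standard deviation over the null draws, and `NRI = -ses`.
#' `NRI > +2` is read as phylogenetic clustering (environmental
#' filtering), `NRI < -2` as overdispersion (competitive exclusion), and
#' values between as stochastic assembly.
#'
#' @param f_row named abundances for one sample over the pool.
#' @param D patristic distance matrix over the pool.
#' @param pool_ids species pool (default: all taxa of `D`).
#' @param n_rand number of null randomizations.
#' @param seed optional integer seed.
#' @param pairwise_weighted passed to [alpha_mpd()].
#' @return a one-row data.frame of class `ses_result`: `observed`,
#'   `null_mean`, `null_sd`, `ses`, `nri`, `n_randomizations`, `p_rank`
#'   (two-sided rank p), `classification`, `flag`; the null draws are
#'   attached as attribute `null`.
#' @export
alpha_nri <- function(f_row, D, pool_ids = rownames(D), n_rand = 1000L,
                      seed = NULL, pairwise_weighted = FALSE) {
  obs <- alpha_mpd(f_row, D, pairwise_weighted)
  if (is.na(obs)) stopf("alpha MPD undefined for the observed community")
  ab <- unname(f_row[f_row > 0])
  S <- length(ab)
  nulls <- with_seed_or_not(seed,
    vapply(seq_len(n_rand), function(i)
      .null_alpha_mpd(ab, S, pool_ids, D, pairwise_weighted), numeric(1)))
  .ses_result(obs, nulls)
}

## Shared SES bookkeeping for alpha and beta variants.
.ses_result <- function(obs, nulls) {
  mu <- mean(nulls)
  sdev <- stats::sd(nulls)
  n <- length(nulls)
  flag <- ""
  if (sdev == 0) {
    ses <- NA_real_
    flag <- "degenerate null (sd = 0)"
  } else {
    ses <- (obs - mu) / sdev
  }
  n_ge <- sum(nulls >= obs)
  n_le <- sum(nulls <= obs)
  p <- min(1, 2 * (min(n_ge, n_le) + 1) / (n + 1))
  nri <- -ses
  classification <- if (is.na(nri)) "undefined"
    else if (nri > 2) "clustered (environmental filtering)"
    else if (nri < -2) "overdispersed (competitive exclusion)"
    else "stochastic"
  out <- data.frame(observed = obs, null_mean = mu, null_sd = sdev,
                    ses = ses, nri = nri, n_randomizations = n,
                    p_rank = p, classification = classification,
                    flag = flag, stringsAsFactors = FALSE)
  attr(out, "null") <- nulls
  class(out) <- c("ses_result", class(out))
  out
}

#' Beta mean pairwise phylogenetic distance between two samples
#'
#' Fully abundance-weighted cross-community mean:
#' \deqn{\beta MPD = \sum_i \sum_j f_{ik} f_{jl} \Delta_{ij}} over all
#' taxon pairs with one member in each community; shared taxa contribute
#' distance 0.
#'
#' @param f_row_k,f_row_l named abundances of the two samples (renormalized
#'   over present taxa).
#' @param D patristic distance matrix.
#' @return numeric scalar.
#' @export
beta_mpd <- function(f_row_k, f_row_l, D) {
  ik <- names(f_row_k)[f_row_k > 0]
  il <- names(f_row_l)[f_row_l > 0]
  if (length(ik) == 0L || length(il) == 0L) stopf("both samples must be non-empty")
  wk <- f_row_k[ik] / sum(f_row_k[ik])
  wl <- f_row_l[il] / sum(f_row_l[il])
  as.numeric(crossprod(wk, D[ik, il, drop = FALSE] %*% wl))
}

#' Beta NRI: standardized effect size of beta MPD
#'
#' The null distribution applies the phylogeny-pool randomization to both
#' communities independently in each draw;
#' `betaNRI = (betaMPD_obs - mean(betaMPD_null)) / sd(betaMPD_null)`.
#' `betaNRI < -2` indicates less-than-expected phylogenetic turnover
#' (homogeneous selection), `> +2` greater than expected (variable
#' selection).
#'
#' @inheritParams beta_mpd
#' @param pool_ids species pool (default all taxa of `D`).
#' @param n_rand number of null randomizations.
#' @param seed optional integer seed.
#' @return one-row data.frame of class `beta_ses_result` with
#'   `beta_mpd_observed`, `null_mean`, `null_sd`, `beta_nri`, `p_rank`,
#'   `classification`, `flag`; null draws attached as attribute `null`.
#' @export
beta_nri <- function(f_row_k, f_row_l, D, pool_ids = rownames(D),
                     n_rand = 1000L, seed = NULL) {
  obs <- beta_mpd(f_row_k, f_row_l, D)
  abk <- unname(f_row_k[f_row_k > 0]); Sk <- length(abk)
  abl <- unname(f_row_l[f_row_l > 0]); Sl <- length(abl)
  if (max(Sk, Sl) > length(pool_ids)) stopf("richness exceeds pool size")
  nulls <- with_seed_or_not(seed, vapply(seq_len(n_rand), function(i) {
    ik <- sample(pool_ids, Sk)
    il <- sample(pool_ids, Sl)
    wk <- if (Sk > 1L) sample(abk) else abk
    wl <- if (Sl > 1L) sample(abl) else abl
    wk <- wk / sum(wk); wl <- wl / sum(wl)
    as.numeric(crossprod(wk, D[ik, il, drop = FALSE] %*% wl))
  }, numeric(1)))
  res <- .ses_result(obs, nulls)
  ses <- res$ses
  out <- data.frame(beta_mpd_observed = res$observed,
                    null_mean = res$null_mean, null_sd = res$null_sd,
                    beta_nri = ses, n_randomizations = res$n_randomizations,
                    p_rank = res$p_rank,
                    classification = if (is.na(ses)) "undefined"
                      else if (ses < -2) "homogeneous selection"
                      else if (ses > 2) "variable selection"
                      else "stochastic turnover",
                    flag = res$flag, stringsAsFactors = FALSE)
  attr(out, "null") <- attr(res, "null")
  class(out) <- c("beta_ses_result", class(out))
  out
}

#' Within-group means of pairwise beta metrics
#'
#' Averages a beta metric over the `choose(n, 2)` within-group sample
#' pairs of each group, reporting mean, sd, and a `mean ± sd` display
#' string. Groups of size 1 are skipped with a warning.
#'
#' @param results data.frame with columns `sample_1`, `sample_2` and the
#'   metric column (e.g. the output of [beta_diversity_table()]).
#' @param metadata data.frame with `sample_id` and `group`.
#' @param metric name of the metric column (`"beta_mpd"` or `"beta_nri"`).
#' @return data.frame: `group`, `n_samples`, `n_pairs`, `mean`, `sd`,
#'   `display`.
#' @export
group_mean_beta <- function(results, metadata, metric = "beta_mpd") {
  if (!metric %in% names(results)) stopf("metric '%s' not in results", metric)
  grp <- stats::setNames(metadata$group, metadata$sample_id)
  g1 <- grp[results$sample_1]
  g2 <- grp[results$sample_2]
  within <- results[!is.na(g1) & !is.na(g2) & g1 == g2, , drop = FALSE]
  within$group <- grp[within$sample_1]
  sizes <- table(metadata$group)
  singletons <- names(sizes)[sizes < 2]
  if (length(singletons))
    warnf("group(s) with a single sample skipped: %s", paste(singletons, collapse = ", "))
  out <- do.call(rbind, lapply(split(within, within$group), function(d) {
    data.frame(group = d$group[1L],
               n_samples = as.integer(sizes[d$group[1L]]),
               n_pairs = nrow(d),
               mean = mean(d[[metric]]),
               sd = if (nrow(d) > 1L) stats::sd(d[[metric]]) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$display <- sprintf("%.3f ± %.3f", out$mean, out$sd)
  out
}

#' Alpha diversity table for all samples
#'
#' Convenience wrapper running [alpha_mpd()] and [alpha_nri()] on every
#' sample of a table.
#'
#' @param f samples x OTUs relative-abundance matrix.
#' @param D patristic distances over the pool.
#' @param pool_ids species pool.
#' @param n_rand,seed,pairwise_weighted passed to [alpha_nri()].
#' @return data.frame with one row per sample (`sample_id`, richness and
#'   the `ses_result` columns).
#' @export
alpha_diversity_table <- function(f, D, pool_ids = rownames(D),
                                  n_rand = 1000L, seed = NULL,
                                  pairwise_weighted = FALSE) {
  rows <- lapply(seq_len(nrow(f)), function(i) {
    res <- alpha_nri(f[i, ], D, pool_ids, n_rand = n_rand,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, i),
                     pairwise_weighted = pairwise_weighted)
    cbind(data.frame(sample_id = rownames(f)[i],
                     richness = sum(f[i, ] > 0), stringsAsFactors = FALSE),
          as.data.frame(res))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise beta diversity table
#'
#' Runs [beta_nri()] for the requested sample pairs (default: all pairs).
#'
#' @param f samples x OTUs relative-abundance matrix.
#' @param D patristic distances.
#' @param pairs optional 2-column matrix/data.frame of sample-id pairs.
#' @param pool_ids,n_rand,seed passed to [beta_nri()].
#' @return data.frame with `sample_1`, `sample_2` and the
#'   `beta_ses_result` columns.
#' @export
beta_diversity_table <- function(f, D, pairs = NULL, pool_ids = rownames(D),
                                 n_rand = 1000L, seed = NULL) {
  if (is.null(pairs)) {
    cmb <- utils::combn(rownames(f), 2L)
    pairs <- data.frame(sample_1 = cmb[1L, ], sample_2 = cmb[2L, ],
                        stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    res <- beta_nri(f[pairs[[1L]][i], ], f[pairs[[2L]][i], ], D, pool_ids,
                    n_rand = n_rand,
                    seed = if (is.null(seed)) NULL else derive_seed(seed, i))
    cbind(data.frame(sample_1 = pairs[[1L]][i], sample_2 = pairs[[2L]][i],
                     stringsAsFactors = FALSE),
          as.data.frame(res))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mantel correlogram of phylogenetic signal in environmental optima
#'
#' Partitions the patristic distances into equal-width classes and, within
#' each class, computes the Mantel correlation between class membership
#' and the distances of the taxa's environmental optima, with permutation
#' p-values and progressive Holm correction in increasing distance order.
#' A significant positive correlation in a class means taxa that far apart
#' phylogenetically have more similar optima than expected — phylogenetic
#' niche conservatism at that depth.
#'
#' @param Dphy patristic distance matrix (taxa x taxa).
#' @param Dopt environmental-optimum distance matrix over the same taxa
#'   (e.g. `as.matrix(dist(optima))`).
#' @param n_classes number of distance classes (default 100).
#' @param n_perm permutations per class (default 999).
#' @param seed optional integer seed.
#' @param cutoff if `TRUE`, drop classes beyond the one containing the
#'   largest distance at which all points are connected (vegan's default);
#'   `FALSE` keeps all classes and flags empty ones.
#' @return data.frame of class `mantel_correlogram`: `class_index`,
#'   `midpoint`, `n_pairs`, `mantel_r`, `p_permutation`, `p_corrected`,
#'   `significant`, `flag`.
#' @export
mantel_correlogram <- function(Dphy, Dopt, n_classes = 100L, n_perm = 999L,
                               seed = NULL, cutoff = FALSE) {
  if (n_classes < 2L) stopf("n_classes must be >= 2")
  ids <- rownames(Dphy)
  if (!is.null(ids) && !is.null(rownames(Dopt))) {
    if (!setequal(ids, rownames(Dopt))) stopf("Dphy and Dopt must share taxon ids")
    Dopt <- Dopt[ids, ids]
  }
  mc <- with_seed_or_not(seed,
    vegan::mantel.correlog(D.eco = stats::as.dist(Dopt),
                           D.geo = stats::as.dist(Dphy),
                           n.class = n_classes, cutoff = cutoff,
                           nperm = n_perm, mult = "holm", progressive = TRUE))
  res <- as.data.frame(mc$mantel.res)
  names(res) <- c("midpoint", "n_pairs", "mantel_r", "p_permutation", "p_corrected")
  out <- data.frame(class_index = seq_len(nrow(res)), res,
                    stringsAsFactors = FALSE)
  out$n_pairs <- as.integer(out$n_pairs)
  out$significant <- !is.na(out$p_corrected) & out$p_corrected < 0.05
  out$flag <- ifelse(out$n_pairs == 0 | is.na(out$mantel_r), "no pairs in class", "")
  class(out) <- c("mantel_correlogram", class(out))
  out
}
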