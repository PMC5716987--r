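## cooccurrence: SparCC compositional correlation inference with
## permutation significance. SparCC estimates the correlations of the
## (unobserved) basis abundances from log-ratio variances of compositional
## counts, under a sparsity assumption on the true correlation network.

## One basis-correlation estimate from a single Dirichlet-smoothed
## fraction draw. `counts` is samples x OTUs.
.sparcc_one <- function(counts, excl_thresh, excl_iters) {
  n <- nrow(counts); p <- ncol(counts)
  # Dirichlet posterior draw of fractions per sample (counts + 1 prior)
  g <- matrix(stats::rgamma(n * p, shape = counts + 1, rate = 1), n, p)
  fr <- g / rowSums(g)
  L <- log(fr)
  V <- stats::cov(L)
  vars <- diag(V)
  # variation matrix: t_ij = Var(log(x_i / x_j))
  Tm <- outer(vars, vars, "+") - 2 * V

  # adjacency of pairs still included in the linear system
  A <- matrix(1, p, p); diag(A) <- 0

  solve_rho <- function(A) {
    M <- A + diag(rowSums(A))
    t_i <- rowSums(Tm * A)
    w <- tryCatch(solve(M, t_i), error = function(e) NULL)
    if (is.null(w)) return(NULL)
    w <- pmax(w, 1e-12)  # basis variances; clip tiny negatives
    om <- sqrt(w)
    rho <- (outer(w, w, "+") - Tm) / (2 * outer(om, om))
    rho[rho > 1] <- 1; rho[rho < -1] <- -1
    diag(rho) <- 1
    rho
  }

  rho <- solve_rho(A)
  if (is.null(rho)) stopf("SparCC linear system is singular")
  for (it in seq_len(excl_iters)) {
    masked <- abs(rho)
    masked[A == 0] <- 0
    diag(masked) <- 0
    m <- max(masked)
    if (m <= excl_thresh) break
    idx <- which(masked == m, arr.ind = TRUE)[1L, ]
    A[idx[1L], idx[2L]] <- A[idx[2L], idx[1L]] <- 0
    if (any(rowSums(A) < 2)) {
      warnf("SparCC exclusion stopped: too few pairs left for the linear system")
      break
    }
    nxt <- solve_rho(A)
    if (is.null(nxt)) {
      warnf("SparCC exclusion stopped: singular system")
      break
    }
    rho <- nxt
  }
  rho
}

#' SparCC basis correlations of compositional count data
#'
#' Per inner iteration: draw Dirichlet-smoothed fractions (counts + 1),
#' form the log-ratio variation matrix `t_ij = Var(log(x_i/x_j))`, solve
#' the sparsity-approximated linear system for the basis variances
#' `omega_i^2`, and derive
#' `rho_ij = (omega_i^2 + omega_j^2 - t_ij) / (2 omega_i omega_j)`
#' clipped to `[-1, 1]`. The most strongly correlated pair is iteratively
#' excluded from the system (up to `excl_iters` rounds, while any |rho|
#' exceeds `excl_thresh`) and the element-wise median over inner
#' iterations is reported.
#'
#' @param counts samples x OTUs integer matrix (>= 4 samples and OTUs).
#' @param excl_thresh exclusion threshold on |rho| (original-tool default
#'   0.1).
#' @param excl_iters maximum exclusion rounds (default 10).
#' @param inner_iters number of Dirichlet resampling iterations whose
#'   median is reported (default 20).
#' @param seed optional integer seed.
#' @return list of class `sparcc_result`: `otu_ids`, `rho` (symmetric,
#'   unit diagonal), `pvals` (`NULL` until [sparcc_pvalues()] is run),
#'   `n_permutations`, `settings`.
#' @export
sparcc_correlations <- function(counts, excl_thresh = 0.1, excl_iters = 10L,
                                inner_iters = 20L, seed = NULL) {
  if (nrow(counts) < 4L || ncol(counts) < 4L)
    stopf("SparCC needs at least 4 samples and 4 OTUs")
  rhos <- with_seed_or_not(seed,
    lapply(seq_len(inner_iters), function(i)
      .sparcc_one(counts, excl_thresh, excl_iters)))
  arr <- simplify2array(rhos)
  rho <- apply(arr, c(1L, 2L), stats::median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  structure(list(otu_ids = colnames(counts), rho = rho, pvals = NULL,
                 n_permutations = 0L,
                 settings = list(excl_thresh = excl_thresh,
                                 excl_iters = as.integer(excl_iters),
                                 inner_iters = as.integer(inner_iters),
                                 seed = seed)),
            class = "sparcc_result")
}

#' Permutation pseudo p-values for SparCC correlations
#'
#' Each permutation independently shuffles every OTU's counts across
#' samples (destroying all between-OTU association while keeping each
#' OTU's count distribution) and recomputes the SparCC correlation matrix.
#' Two-sided pseudo-p per pair:
#' `p = (1 + #\{|rho_perm| >= |rho_obs|\}) / (n_perm + 1)`, so the minimum
#' attainable p is `1/(n_perm + 1)`.
#'
#' @param counts samples x OTUs matrix the observed `rho` was computed on.
#' @param n_perm number of permutations (>= 1). The field convention is
#'   9,999; smaller values are typical for desk-scale runs.
#' @param seed optional integer seed.
#' @param sparcc optional precomputed [sparcc_correlations()] result; if
#'   absent it is computed first with the same settings.
#' @param whole_sample if `TRUE`, permute whole samples (rows) instead of
#'   within-OTU shuffles (alternative reading of "random selections").
#' @param ... settings passed to [sparcc_correlations()].
#' @return the `sparcc_result` with `pvals` and `n_permutations` filled in.
#' @export
sparcc_pvalues <- function(counts, n_perm = 999L, seed = NULL, sparcc = NULL,
                           whole_sample = FALSE, ...) {
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  if (is.null(sparcc))
    sparcc <- sparcc_correlations(counts, seed = if (is.null(seed)) NULL else derive_seed(seed, 0L), ...)
  obs <- abs(sparcc$rho)
  exceed <- matrix(0, nrow(obs), ncol(obs))
  st <- sparcc$settings
  with_seed_or_not(seed, {
    for (b in seq_len(n_perm)) {
      perm <- if (whole_sample) counts[sample(nrow(counts)), , drop = FALSE]
              else apply(counts, 2L, sample)
      r <- sparcc_correlations(perm, excl_thresh = st$excl_thresh,
                               excl_iters = st$excl_iters,
                               inner_iters = st$inner_iters)$rho
      exceed <- exceed + (abs(r) >= obs)
    }
  })
  p <- (1 + exceed) / (n_perm + 1)
  diag(p) <- 1
  dimnames(p) <- dimnames(sparcc$rho)
  sparcc$pvals <- p
  sparcc$n_permutations <- as.integer(n_perm)
  sparcc
}
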