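## cooccurrence: checkerboard C-score and its fixed-fixed null test.

#' Checkerboard C-score of a binary occurrence matrix
#'
#' For each pair of taxa (i, j): `CU_ij = (r_i - S_ij) (r_j - S_ij)` where
#' `r` are the taxa's occupied-site counts and `S_ij` the number of shared
#' sites; the C-score is the mean of `CU` over all taxon pairs. Higher
#' values than expected under a null indicate segregated (non-random)
#' co-occurrence.
#'
#' @param pa binary taxa x samples matrix (taxa as rows).
#' @return numeric scalar (mean checkerboard units).
#' @export
c_score <- function(pa) {
  if (nrow(pa) < 2L) stopf("need at least 2 taxa")
  pa <- (pa > 0) + 0
  S <- tcrossprod(pa)
  r <- rowSums(pa)
  CU <- outer(r, r, function(a, b) a) - S
  CU <- CU * (outer(r, r, function(a, b) b) - S)
  mean(CU[upper.tri(CU)])
}

#' Fixed-fixed null-model test of the C-score
#'
#' Null matrices preserve both row and column sums, generated by the
#' sequential checkerboard-swap algorithm (burn-in of `10 * fill` swaps,
#' thinning of `fill` swaps between saved matrices, `fill` = number of
#' occurrences). The standardized effect size is
#' `ses = (observed - mean(null)) / sd(null)` with a two-sided rank
#' p-value. When no 2x2 submatrix is swappable the null is degenerate and
#' `p = 1` is reported with a flag.
#'
#' @param pa binary taxa x samples matrix.
#' @param n_null number of null matrices (default 1000).
#' @param seed optional integer seed.
#' @param burnin,thin override the default burn-in / thinning (in swaps).
#' @return one-row data.frame of class `cscore_result`: `observed_c`,
#'   `null_mean`, `null_sd`, `ses`, `p_value`, `n_null`, `flag`; null
#'   values attached as attribute `null`.
#' @export
c_score_null_test <- function(pa, n_null = 1000L, seed = NULL,
                              burnin = NULL, thin = NULL) {
  pa <- (pa > 0) + 0
  if (any(rowSums(pa) == 0) || any(colSums(pa) == 0))
    stopf("every row and column must have at least one occurrence")
  obs <- c_score(pa)
  fill <- sum(pa)
  burnin <- burnin %||% (10L * fill)
  thin <- thin %||% fill
  # vegan's community matrices are sites x species; swaps preserve both
  # margins so the transpose is immaterial to the null distribution.
  nm <- vegan::nullmodel(t(pa), "swap")
  sims <- stats::simulate(nm, nsim = n_null, burnin = burnin, thin = thin,
                          seed = if (is.null(seed)) NULL else as.integer(seed))
  nulls <- vapply(seq_len(n_null), function(i) c_score(t(sims[, , i])), numeric(1))
  mu <- mean(nulls); sdev <- stats::sd(nulls)
  flag <- ""
  if (sdev == 0) {
    ses <- NA_real_
    p <- 1
    flag <- "degenerate null (no swappable submatrix)"
  } else {
    ses <- (obs - mu) / sdev
    n_ge <- sum(nulls >= obs); n_le <- sum(nulls <= obs)
    p <- min(1, 2 * (min(n_ge, n_le) + 1) / (n_null + 1))
  }
  out <- data.frame(observed_c = obs, null_mean = mu, null_sd = sdev,
                    ses = ses, p_value = p, n_null = as.integer(n_null),
                    flag = flag, stringsAsFactors = FALSE)
  attr(out, "null") <- nulls
  class(out) <- c("cscore_result", class(out))
  out
}
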