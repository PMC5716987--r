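## preprocess: count-table normalization applied before diversity and
## network analyses — rarefaction to even depth, dominant-OTU selection,
## presence/absence and relative abundance transforms.

#' Rarefy an OTU table to even depth
#'
#' Random subsampling of each sample's reads to a common depth, without
#' replacement (hypergeometric), the convention of the amplicon
#' literature. Samples whose total is below `depth` are an error that
#' names them — never a silent drop.
#'
#' @param counts samples x OTUs integer matrix.
#' @param depth target depth (every sample's total must be >= depth).
#' @param seed optional integer seed; output is bit-reproducible under it.
#' @param with_replacement draw with replacement instead (multinomial).
#' @param drop_empty_otus drop OTUs that end up zero in all samples.
#' @return integer matrix with every row summing to `depth`; attributes
#'   `depth` and `seed` record the rarefaction.
#' @export
rarefy <- function(counts, depth = 7000L, seed = NULL,
                   with_replacement = FALSE, drop_empty_otus = FALSE) {
  counts <- validate_otu_table(counts)
  totals <- rowSums(counts)
  low <- totals < depth
  if (any(low))
    stopf("samples below rarefaction depth %d: %s", depth,
          paste(sprintf("%s (%d)", rownames(counts)[low], totals[low]), collapse = ", "))
  out <- with_seed_or_not(seed, {
    t(apply(counts, 1L, function(x) {
      reads <- rep.int(seq_along(x), x)
      take <- if (with_replacement) {
        sample(reads, depth, replace = TRUE)
      } else if (length(reads) == depth) {
        reads
      } else {
        sample(reads, depth)
      }
      tabulate(take, nbins = length(x))
    }))
  })
  dimnames(out) <- dimnames(counts)
  if (drop_empty_otus) out <- out[, colSums(out) > 0, drop = FALSE]
  storage.mode(out) <- "integer"
  attr(out, "depth") <- as.integer(depth)
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  out
}

#' Keep the k most dominant OTUs
#'
#' Dominance is total raw count summed over the samples of the supplied
#' table (subset to one treatment's samples first to get per-regime
#' dominants). Ties are broken lexicographically by OTU id so the result
#' is deterministic.
#'
#' @param counts samples x OTUs matrix.
#' @param k number of OTUs to keep (default 500, the usual network-stage
#'   choice).
#' @return matrix restricted to the top `k` OTUs (original column order
#'   preserved).
#' @export
top_k_otus <- function(counts, k = 500L) {
  if (k < 1L) stopf("k must be >= 1")
  if (k >= ncol(counts)) {
    if (k > ncol(counts)) warnf("k = %d exceeds the %d OTUs present; keeping all", k, ncol(counts))
    return(counts)
  }
  totals <- colSums(counts)
  ord <- order(-totals, colnames(counts))
  keep <- sort(ord[seq_len(k)])
  counts[, keep, drop = FALSE]
}

#' Convert counts to presence/absence
#' @param counts samples x OTUs matrix.
#' @return binary integer matrix of the same shape (1 = count > 0).
#' @export
to_presence_absence <- function(counts) {
  out <- (counts > 0) + 0L
  dimnames(out) <- dimnames(counts)
  out
}

#' Convert counts to relative abundances
#'
#' @param counts samples x OTUs matrix.
#' @return numeric matrix whose rows sum to 1.
#' @export
relative_abundance <- function(counts) {
  totals <- rowSums(counts)
  empty <- totals == 0
  if (any(empty))
    stopf("all-zero sample(s): %s", paste(rownames(counts)[empty], collapse = ", "))
  sweep(counts, 1L, totals, "/")
}
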