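# Independent brute-force oracles and small fixtures, deliberately written
# with naive loops so they share no code path with the implementation.

balanced4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# tip-to-tip path-length distances via weighted shortest paths on the
# tree's edge graph (independent of ape's cophenetic algorithm)
oracle_cophenetic <- function(tree) {
  n_node <- max(tree$edge)
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2]),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n_node))))
  igraph::E(g)$weight <- tree$edge.length
  tips <- as.character(seq_along(tree$tip.label))
  d <- igraph::distances(g, v = tips, to = tips)
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# naive double-loop alpha MPD: sum_i f_i * mean_{j != i} D_ij
oracle_alpha_mpd <- function(f_row, D) {
  ids <- names(f_row)[f_row > 0]
  if (length(ids) < 2) return(NA_real_)
  w <- f_row[ids] / sum(f_row[ids])
  tot <- 0
  for (i in ids) {
    acc <- 0
    for (j in setdiff(ids, i)) acc <- acc + D[i, j]
    tot <- tot + w[[i]] * acc / (length(ids) - 1)
  }
  tot
}

# naive double-loop beta MPD: sum_i sum_j f_ik f_jl D_ij
oracle_beta_mpd <- function(f_k, f_l, D) {
  ik <- names(f_k)[f_k > 0]
  il <- names(f_l)[f_l > 0]
  wk <- f_k[ik] / sum(f_k[ik])
  wl <- f_l[il] / sum(f_l[il])
  tot <- 0
  for (i in ik) for (j in il) tot <- tot + wk[[i]] * wl[[j]] * D[i, j]
  tot
}

# naive pairwise C-score
oracle_c_score <- function(pa) {
  pa <- (pa > 0) + 0
  n <- nrow(pa)
  vals <- c()
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    ri <- sum(pa[i, ]); rj <- sum(pa[j, ])
    s <- sum(pa[i, ] == 1 & pa[j, ] == 1)
    vals <- c(vals, (ri - s) * (rj - s))
  }
  mean(vals)
}

# exhaustive phylogeny-pool null for a community of richness S with equal
# abundances: alpha MPD of every S-subset of the pool
oracle_exhaustive_null <- function(S, D) {
  pool <- rownames(D)
  sets <- utils::combn(pool, S, simplify = FALSE)
  vapply(sets, function(ids) {
    f <- stats::setNames(rep(0, length(pool)), pool)
    f[ids] <- 1 / S
    oracle_alpha_mpd(f, D)
  }, numeric(1))
}

# audit a compact letter display against its Tukey p-matrix:
# two groups must share a letter iff adjusted p >= alpha
audit_letters <- function(ld) {
  P <- attr(ld, "p_matrix")
  alpha <- attr(ld, "alpha")
  letts <- strsplit(stats::setNames(ld$letters, ld$group), "")
  for (a in ld$group) for (b in ld$group) {
    if (a == b) next
    share <- length(intersect(letts[[a]], letts[[b]])) > 0
    if (share != (P[a, b] >= alpha)) return(FALSE)
  }
  TRUE
}

# tiny deterministic OTU matrix fixture
toy_counts <- function() {
  m <- matrix(c(10L, 5L, 0L, 3L,
                2L,  8L, 4L, 0L,
                6L,  1L, 9L, 2L),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("S1", "S2", "S3"),
                              c("OTU_1", "OTU_2", "OTU_3", "OTU_4")))
  m
}
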