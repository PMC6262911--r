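# Independent oracles: naive, from-scratch implementations used to check
# the fast engine. Deliberately simple and unoptimised.

# All permutations of 1:n, one per row (n small).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  do.call(rbind, lapply(seq_len(n), function(first) {
    sub <- all_perms(n - 1L)
    rest <- setdiff(seq_len(n), first)
    cbind(first, matrix(rest[sub], nrow(sub), n - 1L), deparse.level = 0)
  }))
}

# Naive Secondary-Only survivor curve for an explicit plant order: after
# each plant removal, recompute every pollinator's cumulative lost fraction
# from the full original matrix. Losses are monotone in the removed set, so
# recomputation is equivalent to incremental accounting.
oracle_so_curve <- function(M, ord, threshold, weighted = FALSE) {
  W <- if (weighted) M else (M > 0) * 1
  A <- nrow(W); P <- ncol(W)
  tot <- rowSums(W)
  a <- integer(P + 1L)
  a[1L] <- A
  gone <- rep(FALSE, P)
  for (s in seq_len(P)) {
    gone[ord[s]] <- TRUE
    lost <- rowSums(W[, gone, drop = FALSE])
    a[s + 1L] <- sum(lost / tot < threshold - 1e-12)
  }
  a
}

oracle_so_R <- function(M, ord, threshold, weighted = FALSE) {
  a <- oracle_so_curve(M, ord, threshold, weighted)
  sum(a) / (nrow(M) * ncol(M))
}

# Exact distribution of R under uniformly random SO sequences: one value
# per permutation, all equally likely.
oracle_so_exact <- function(M, threshold, weighted = FALSE) {
  P <- ncol(M)
  perms <- all_perms(P)
  apply(perms, 1L, function(ord) oracle_so_R(M, ord, threshold, weighted))
}

# Brute-force shared-pollinator matrix: double loop over plant pairs.
oracle_shared_matrix <- function(C) {
  P <- ncol(C)
  F_ <- matrix(0, P, P, dimnames = dimnames(crossprod(C)))
  for (e in seq_len(P)) for (g in seq_len(P)) {
    if (e == g) next
    F_[e, g] <- sum(C[, e] > 0 & C[, g] > 0)
  }
  F_
}

# Spearman rho by rank-then-Pearson.
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# Moment-formula skewness.
oracle_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  (sum((x - m)^3) / n) / (sum((x - m)^2) / n)^1.5
}

# A small pool of random generated fixtures for property-style loops.
property_fixtures <- function() {
  lapply(1:5, function(i)
    generate_network(P = 4 + i, A = 6 + 2 * i, E = 14 + 4 * i,
                     skew = if (i %% 2) "uniform" else "skewed",
                     weight_model = if (i > 3) "geometric" else "unit",
                     seed = 100 + i))
}
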