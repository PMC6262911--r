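# Degree-distribution manipulation null models. All schemes operate on the
# binary pattern and conserve the number of interactions E exactly, so
# connectance is invariant. Zero-degree species can arise inside an ensemble
# draw; they are fine for ensemble statistics but such draws are ineligible
# as exemplars (extinction runs require every species to start alive).

#' Fully randomize a binary network
#'
#' Places all `E` interactions between `E` distinct animal-plant pairs
#' chosen uniformly without replacement from the `A x P` grid. Both guilds'
#' degree distributions are randomized; labels and `E` are preserved.
#'
#' @param net a `bipartite_network` (used for its binary pattern).
#' @param seed optional integer seed.
#' @return a binary `bipartite_network`; may contain zero-degree species,
#'   in which case validation is deferred (see [select_exemplar()]).
#' @export
randomize_full <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- n_animals(net); P <- n_plants(net); E <- n_edges(net)
  M <- matrix(0, A, P, dimnames = list(net$animal_labels, net$plant_labels))
  M[sample.int(A * P, E)] <- 1
  .as_unchecked_network(M)
}

#' Randomize one guild's degree distribution, conserving the other
#'
#' `preserve = "animals"` keeps every pollinator's degree exactly and places
#' its edges in a uniformly random set of plants (row sums exact, column
#' sums randomized) -- this randomizes the plant degree distribution.
#' `preserve = "plants"` is the symmetric operation on columns.
#'
#' @param net a `bipartite_network` (binary pattern used).
#' @param preserve which guild's degrees to conserve.
#' @param seed optional integer seed.
#' @return a binary `bipartite_network` (possibly with zero-degree species
#'   in the randomized guild).
#' @export
randomize_guild <- function(net, preserve = c("animals", "plants"),
                            seed = NULL) {
  preserve <- match.arg(preserve)
  if (!is.null(seed)) set.seed(seed)
  B <- (net$M > 0) * 1
  A <- nrow(B); P <- ncol(B)
  M <- matrix(0, A, P, dimnames = dimnames(net$M))
  if (preserve == "animals") {
    k <- rowSums(B)
    for (i in seq_len(A)) M[i, sample.int(P, k[i])] <- 1
  } else {
    k <- colSums(B)
    for (j in seq_len(P)) M[sample.int(A, k[j]), j] <- 1
  }
  .as_unchecked_network(M)
}

# Ensemble draws may legitimately contain zero-degree species, so bypass
# the zero-row/column validation while keeping the class structure.
.as_unchecked_network <- function(M) {
  structure(list(M = M, weighted = FALSE,
                 animal_labels = rownames(M), plant_labels = colnames(M)),
            class = "bipartite_network")
}

# Draw i of a scheme, reproducible in isolation.
.draw_randomized <- function(net, scheme, master_seed, i) {
  seed <- .derive_seed(master_seed, i)
  switch(scheme,
         full = randomize_full(net, seed = seed),
         randomize_plants = randomize_guild(net, "animals", seed = seed),
         randomize_animals = randomize_guild(net, "plants", seed = seed),
         stop("unknown scheme: ", scheme))
}

# Degree counts as a vector indexed by k = 0..kmax.
.degree_counts <- function(deg, kmax) {
  tabulate(deg + 1L, nbins = kmax + 1L)
}

#' Expected degree distributions of a randomization ensemble
#'
#' Generates `ensemble_size` randomized networks under the given scheme and
#' returns the per-degree mean species counts `G_A(k)` and `G_P(k)` for
#' both guilds (including `k = 0`, which random placement can produce).
#'
#' @param net a binary `bipartite_network`.
#' @param scheme `"full"` (both guilds randomized), `"randomize_plants"`
#'   (pollinator degrees conserved), or `"randomize_animals"` (plant
#'   degrees conserved).
#' @param ensemble_size number of draws (reference analyses use 10,000).
#' @param master_seed integer master seed.
#' @return a list with numeric vectors `G_A` and `G_P`, named by degree
#'   `0..kmax`, each summing to `A` (resp. `P`).
#' @export
expected_degree_distribution <- function(net, scheme = c("full",
                                                         "randomize_plants",
                                                         "randomize_animals"),
                                         ensemble_size = 10000L,
                                         master_seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(ensemble_size >= 1L)
  A <- n_animals(net); P <- n_plants(net)
  kmaxA <- P; kmaxP <- A
  GA <- numeric(kmaxA + 1L); GP <- numeric(kmaxP + 1L)
  for (i in seq_len(ensemble_size)) {
    r <- .draw_randomized(net, scheme, master_seed, i)
    GA <- GA + .degree_counts(rowSums(r$M > 0), kmaxA)
    GP <- GP + .degree_counts(colSums(r$M > 0), kmaxP)
  }
  list(G_A = stats::setNames(GA / ensemble_size, 0:kmaxA),
       G_P = stats::setNames(GP / ensemble_size, 0:kmaxP))
}

# L1 distance between a network's degree distributions and the ensemble
# expectation, summed over both guilds and all degrees.
.degree_distance <- function(net, G) {
  kmaxA <- length(G$G_A) - 1L; kmaxP <- length(G$G_P) - 1L
  sum(abs(.degree_counts(rowSums(net$M > 0), kmaxA) - G$G_A)) +
    sum(abs(.degree_counts(colSums(net$M > 0), kmaxP) - G$G_P))
}

#' Select the exemplar network of an ensemble
#'
#' Returns the ensemble member whose guild degree distributions are closest
#' (L1 distance over all degrees, both guilds) to the expected distributions
#' `G_A`, `G_P`. Members containing zero-degree species are excluded (they
#' cannot host an extinction run); ties are broken by generation index.
#'
#' @param ensemble a list of binary `bipartite_network`s.
#' @param G a list with `G_A` and `G_P` as returned by
#'   [expected_degree_distribution()].
#' @return the winning `bipartite_network`, validated, with attribute
#'   `"distance"` holding its L1 distance.
#' @export
select_exemplar <- function(ensemble, G) {
  stopifnot(length(ensemble) >= 1L)
  best <- NULL; best_d <- Inf; best_i <- NA_integer_
  for (i in seq_along(ensemble)) {
    nt <- ensemble[[i]]
    if (any(rowSums(nt$M) == 0) || any(colSums(nt$M) == 0)) next
    d <- .degree_distance(nt, G)
    if (d < best_d) { best <- nt; best_d <- d; best_i <- i }
  }
  if (is.null(best))
    stop("no eligible exemplar: every ensemble member has a zero-degree species")
  validate_network(best)
  attr(best, "distance") <- best_d
  attr(best, "index") <- best_i
  best
}

#' Build a degree-manipulated exemplar network
#'
#' One-call pipeline: draws an ensemble of randomized networks, computes the
#' expected degree distributions, and returns the zero-degree-free member
#' closest to them. Memory-light: only degree distributions are kept during
#' the pass; the winner is regenerated from its per-draw seed.
#'
#' @inheritParams expected_degree_distribution
#' @return the exemplar `bipartite_network`, with attributes `"distance"`,
#'   `"index"`, and `"G"` (the expected distributions).
#' @export
randomized_exemplar <- function(net, scheme = c("full", "randomize_plants",
                                                "randomize_animals"),
                                ensemble_size = 10000L, master_seed = 1L) {
  scheme <- match.arg(scheme)
  A <- n_animals(net); P <- n_plants(net)
  kmaxA <- P; kmaxP <- A
  degsA <- vector("list", ensemble_size)
  degsP <- vector("list", ensemble_size)
  eligible <- logical(ensemble_size)
  GA <- numeric(kmaxA + 1L); GP <- numeric(kmaxP + 1L)
  for (i in seq_len(ensemble_size)) {
    r <- .draw_randomized(net, scheme, master_seed, i)
    da <- .degree_counts(rowSums(r$M > 0), kmaxA)
    dp <- .degree_counts(colSums(r$M > 0), kmaxP)
    degsA[[i]] <- da; degsP[[i]] <- dp
    eligible[i] <- da[1L] == 0 && dp[1L] == 0   # no degree-0 species
    GA <- GA + da; GP <- GP + dp
  }
  GA <- GA / ensemble_size; GP <- GP / ensemble_size
  if (!any(eligible))
    stop("no eligible exemplar: every ensemble member has a zero-degree species")
  dist <- vapply(seq_len(ensemble_size), function(i) {
    if (!eligible[i]) return(Inf)
    sum(abs(degsA[[i]] - GA)) + sum(abs(degsP[[i]] - GP))
  }, 0)
  best_i <- which.min(dist)
  best <- .draw_randomized(net, scheme, master_seed, best_i)
  validate_network(best)
  attr(best, "distance") <- dist[best_i]
  attr(best, "index") <- best_i
  attr(best, "G") <- list(G_A = stats::setNames(GA, 0:kmaxA),
                          G_P = stats::setNames(GP, 0:kmaxP))
  best
}
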