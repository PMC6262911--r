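#' Connectance
#'
#' The proportion of realized interactions, `c = E / (A * P)`.
#'
#' @param net a `bipartite_network`.
#' @return a fraction in (0, 1].
#' @export
connectance <- function(net) n_edges(net) / (n_animals(net) * n_plants(net))

#' Degree distribution of one guild
#'
#' Degrees are always counted on the binary pattern, regardless of mode:
#' "degree" counts interaction partners, not interaction strength.
#'
#' @param net a `bipartite_network`.
#' @param guild `"plants"` or `"animals"`.
#' @return an object of class `degree_distribution`: a list with `guild`,
#'   `degrees` (per-species degree vector, named) and `counts` (table of
#'   species count per degree k).
#' @export
degree_distribution <- function(net, guild = c("plants", "animals")) {
  guild <- match.arg(guild)
  B <- net$M > 0
  deg <- if (guild == "plants") colSums(B) else rowSums(B)
  counts <- table(factor(deg, levels = sort(unique(deg))))
  structure(list(guild = guild,
                 degrees = deg,
                 counts = counts),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("degree_distribution (%s): %d species, E = %d\n",
              x$guild, length(x$degrees), sum(x$degrees)))
  print(x$counts)
  invisible(x)
}

#' NODF nestedness
#'
#' Nestedness metric based on overlap and decreasing fill, computed on the
#' binary pattern. For every ordered pair of rows (and of columns) with
#' strictly decreasing marginal totals, the paired overlap is the percentage
#' of the smaller species' partners shared with the larger one; pairs with
#' equal or increasing totals contribute zero. NODF is the mean over all
#' row pairs and column pairs, on a 0--100 scale.
#'
#' @param net a `bipartite_network`.
#' @return NODF percentage in \[0, 100\].
#' @export
nodf <- function(net) {
  B <- (net$M > 0) * 1
  paired_sum <- function(X) {
    # rows of X; ordered pairs i < j scored with the larger-fill row first
    n <- nrow(X)
    if (n < 2L) return(c(0, 0))
    fill <- rowSums(X)
    S <- X %*% t(X)                     # shared partners
    total <- 0
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (fill[i] == fill[j]) next      # decreasing fill is strict
      lo <- if (fill[i] > fill[j]) j else i
      hi <- if (fill[i] > fill[j]) i else j
      if (fill[lo] == 0) next
      total <- total + 100 * S[hi, lo] / fill[lo]
    }
    c(total, n * (n - 1L) / 2)
  }
  rows <- paired_sum(B)
  cols <- paired_sum(t(B))
  as.numeric((rows[1L] + cols[1L]) / (rows[2L] + cols[2L]))
}

#' Largest plant degree
#'
#' Maximum column sum of the binary pattern: the number of pollinator
#' species visiting the best-connected plant.
#'
#' @param net a `bipartite_network`.
#' @return an integer, at most `A`.
#' @export
largest_plant_degree <- function(net) max(colSums(net$M > 0))

#' Skewness of a degree distribution
#'
#' Third standardized moment of the per-species degree list. The default is
#' the bias-uncorrected moment estimator `m3 / m2^(3/2)`; `adjusted = TRUE`
#' applies the usual small-sample correction
#' `sqrt(n(n-1))/(n-2) * g1`.
#'
#' @param dist a `degree_distribution` (or a bare numeric vector of degrees).
#' @param adjusted logical; apply the bias correction.
#' @return a real number; error if the degrees have zero variance (skewness
#'   undefined).
#' @export
degree_skewness <- function(dist, adjusted = FALSE) {
  x <- if (inherits(dist, "degree_distribution")) dist$degrees else as.numeric(dist)
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) stop("skewness undefined: degree distribution has zero variance")
  g1 <- mean((x - mean(x))^3) / m2^1.5
  if (adjusted) {
    if (n < 3L) stop("adjusted skewness needs at least 3 species")
    g1 <- sqrt(n * (n - 1)) / (n - 2) * g1
  }
  g1
}

#' One-line structural summary of a network
#'
#' The Table-1-style descriptor set: guild sizes, edge count, connectance,
#' NODF, and largest plant degree.
#'
#' @param net a `bipartite_network`.
#' @return a one-row `data.frame` with columns `P`, `A`, `E`, `connectance`,
#'   `NODF`, `largest_plant_degree`.
#' @export
network_summary <- function(net) {
  out <- data.frame(P = n_plants(net), A = n_animals(net), E = n_edges(net),
                    connectance = connectance(net),
                    NODF = nodf(net),
                    largest_plant_degree = largest_plant_degree(net))
  rownames(out) <- NULL
  out
}
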