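#' Model configuration for a knockout extinction run
#'
#' Bundles the choices that define one extinction model variant: the model
#' family, whether losses are counted on edges (binary) or edge weights,
#' the fractional extinction threshold `T`, and an optional seed.
#'
#' The three model families are:
#' \describe{
#'   \item{SO}{Secondary Only -- every plant extinction is an independent,
#'     uniformly random primary extinction; pollinators die by the threshold
#'     rule; plants are never removed by the threshold rule.}
#'   \item{DA}{Deterministic Avalanche -- after a random trigger, the
#'     threshold rule is applied to both guilds, so pollinator losses can
#'     leave plants below threshold and extinctions ripple out as an
#'     avalanche; a new random trigger is drawn when the avalanche stops.}
#'   \item{RW}{Random Walk -- extinction jumps from the current plant to a
#'     neighbour chosen with probability proportional to the number of
#'     surviving shared pollinators; pollinators die by the threshold rule;
#'     when the current plant shares no pollinators with any survivor, a
#'     fresh random trigger is drawn.}
#' }
#'
#' @param model `"SO"`, `"DA"`, or `"RW"` (case-insensitive).
#' @param weighted logical; count losses in summed edge weight rather than
#'   edge number.
#' @param threshold extinction threshold `T`: a node dies once it has lost a
#'   fraction `>= T` of its original edges (binary) or total weight
#'   (weighted). Must satisfy `0 < T <= 1`; `T = 0` is rejected as the
#'   uninformative case in which the first extinction kills everything.
#' @param seed optional integer seed for the run's random stream.
#' @return an object of class `model_config`.
#' @export
model_config <- function(model = c("SO", "DA", "RW"), weighted = FALSE,
                         threshold = 0.5, seed = NULL) {
  model <- toupper(model)
  model <- match.arg(model, c("SO", "DA", "RW"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !(threshold > 0 && threshold <= 1))
    stop("threshold must satisfy 0 < T <= 1")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(model = model, weighted = isTRUE(weighted),
                 threshold = threshold, seed = seed),
            class = "model_config")
}

# Smallest integer m with m/k >= T, guarded against floating-point in T*k.
.min_loss <- function(k, threshold) {
  m <- ceiling(threshold * k)
  if (m >= 1 && (m - 1) / k >= threshold) m <- m - 1
  if (m / k < threshold) m <- m + 1
  m
}

#' Effective extinction threshold
#'
#' In a binary network a node of degree `k` dies after losing `m` whole
#' edges, where `m` is the smallest integer with `m/k >= T`. The effective
#' threshold is that smallest realizable lost fraction, `m/k = ceil(T*k)/k`.
#' A node of degree 5 at `T = 0.5` dies after losing 3 edges, so its
#' effective threshold is 3/5 = 0.6.
#'
#' @param k node degree (positive integer, vectorised).
#' @param threshold specified threshold `T`, `0 < T <= 1`.
#' @return the effective threshold(s), in `[T, 1]`.
#' @export
effective_threshold <- function(k, threshold) {
  if (any(k < 1)) stop("degree k must be >= 1")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must satisfy 0 < T <= 1")
  vapply(k, function(ki) .min_loss(ki, threshold) / ki, 0)
}

#' Node-averaged effective threshold
#'
#' Mean of [effective_threshold()] over node degrees, computed on the
#' binary pattern. By default the average runs over all `A + P` nodes of
#' both guilds; `guild` restricts it to one side.
#'
#' @param net a `bipartite_network`.
#' @param threshold threshold `T`.
#' @param guild `"both"` (default), `"animals"`, or `"plants"`.
#' @return a fraction in `[T, 1]`.
#' @export
node_average_effective_threshold <- function(net, threshold,
                                             guild = c("both", "animals",
                                                       "plants")) {
  guild <- match.arg(guild)
  B <- net$M > 0
  deg <- switch(guild,
                both = c(rowSums(B), colSums(B)),
                animals = rowSums(B),
                plants = colSums(B))
  mean(effective_threshold(deg, threshold))
}

#' Robustness of an extinction run
#'
#' The normalized area under the pollinator survival curve:
#' `R = (1/(A*P)) * sum_{p=0}^{P} a(p)`, where `a(p)` is the number of
#' pollinator species remaining after `p` plant extinctions.
#'
#' @param a_curve survivor counts for `p = 0..P` (length `P + 1`), starting
#'   at `A`, ending at 0, non-increasing.
#' @param A,P guild sizes.
#' @return robustness fraction, `1/P <= R < 1`.
#' @export
robustness <- function(a_curve, A, P) {
  if (length(a_curve) != P + 1L)
    stop("a_curve must have P + 1 entries")
  if (a_curve[1L] != A || a_curve[P + 1L] != 0)
    stop("a_curve must start at A and end at 0")
  if (any(diff(a_curve) > 0)) stop("a_curve must be non-increasing")
  sum(a_curve) / (A * P)
}

# ---------------------------------------------------------------------------
# Functional extinction state (reference semantics are in the fast engine
# below; this object exists for inspection, stepping, and oracle tests).

#' Initialise an extinction state
#'
#' The state tracks the reduced matrix `C` (the original matrix restricted
#' to surviving species), the per-node original totals, and the cumulative
#' losses used by the threshold rule.
#'
#' @param net a `bipartite_network`.
#' @param config a [model_config()]; only `weighted` and `threshold` are
#'   used here.
#' @return an object of class `extinction_state`.
#' @export
extinction_state <- function(net, config) {
  W <- if (config$weighted) net$M else (net$M > 0) * 1
  A <- nrow(W); P <- ncol(W)
  structure(list(
    C = W,
    alive_animals = rep(TRUE, A),
    alive_plants = rep(TRUE, P),
    original_totals = list(animals = rowSums(W), plants = colSums(W)),
    loss = list(animals = numeric(A), plants = numeric(P)),
    weighted = config$weighted,
    threshold = config$threshold,
    cut = .loss_cutoffs(net, config)
  ), class = "extinction_state")
}

# Absolute loss at which a node dies: exact integer count in binary mode,
# tolerance-guarded fraction of total weight in weighted mode.
.loss_cutoffs <- function(net, config) {
  B <- net$M > 0
  if (config$weighted) {
    at <- rowSums(net$M); pt <- colSums(net$M)
    tol <- 1e-9
    list(animals = config$threshold * at - tol * pmax(at, 1),
         plants = config$threshold * pt - tol * pmax(pt, 1))
  } else {
    list(animals = vapply(rowSums(B), .min_loss, 0, threshold = config$threshold),
         plants = vapply(colSums(B), .min_loss, 0, threshold = config$threshold))
  }
}

#' Remove one plant and apply the pollinator threshold rule
#'
#' Removes `plant` from the state, zeroes its column in the reduced matrix,
#' credits the lost edges/weights to every surviving pollinator, and removes
#' every pollinator whose cumulative loss has reached its threshold cutoff
#' (those losses are in turn credited to the surviving plants, for use by
#' the avalanche rule). Pollinator extinctions within one plant removal are
#' simultaneous.
#'
#' @param state an `extinction_state`.
#' @param plant plant index (must be alive).
#' @return a list with `state` (updated) and `extinct_animals` (indices of
#'   pollinators removed by this plant extinction).
#' @export
remove_plant <- function(state, plant) {
  if (!state$alive_plants[plant]) stop("plant ", plant, " is already extinct")
  w <- state$C[, plant]
  state$alive_plants[plant] <- FALSE
  state$C[, plant] <- 0
  hit <- which(state$alive_animals & w > 0)
  dead <- integer(0)
  if (length(hit)) {
    state$loss$animals[hit] <- state$loss$animals[hit] + w[hit]
    dead <- hit[state$loss$animals[hit] >= state$cut$animals[hit]]
    if (length(dead)) {
      dw <- if (length(dead) == 1L) state$C[dead, ] else colSums(state$C[dead, , drop = FALSE])
      state$alive_animals[dead] <- FALSE
      state$C[dead, ] <- 0
      up <- which(state$alive_plants & dw > 0)
      if (length(up)) state$loss$plants[up] <- state$loss$plants[up] + dw[up]
    }
  }
  list(state = state, extinct_animals = dead)
}

#' Shared-pollinator matrix
#'
#' The `P x P` one-mode projection of the current reduced matrix: entry
#' `(e, g)` is the number of surviving pollinator species visiting both
#' plants `e` and `g`. Symmetric, zero diagonal; rows and columns of
#' extinct plants are zero.
#'
#' @param state an `extinction_state`.
#' @return a `P x P` nonnegative integer matrix.
#' @export
shared_pollinator_matrix <- function(state) {
  Bc <- (state$C > 0) * 1
  F_ <- crossprod(Bc)
  diag(F_) <- 0
  F_
}

# ---------------------------------------------------------------------------
# Fast in-place engine used by the run_* front ends.

.ko_engine <- function(net, config, order = NULL) {
  M <- net$M
  A <- nrow(M); P <- ncol(M)
  weighted <- config$weighted
  W <- if (weighted) M else (M > 0) * 1
  B <- M > 0
  cut <- .loss_cutoffs(net, config)
  animCut <- cut$animals; plantCut <- cut$plants

  alivePlant <- rep(TRUE, P); aliveAnim <- rep(TRUE, A)
  lossA <- numeric(A); lossP <- numeric(P)
  a_curve <- integer(P + 1L); a_curve[1L] <- A
  seqv <- integer(P); trig <- logical(P)
  nAlive <- A
  step <- 0L

  kill <- function(e, is_trigger) {
    step <<- step + 1L
    seqv[step] <<- e
    trig[step] <<- is_trigger
    alivePlant[e] <<- FALSE
    w <- W[, e]
    hit <- which(aliveAnim & w > 0)
    if (length(hit)) {
      lossA[hit] <<- lossA[hit] + w[hit]
      dead <- hit[lossA[hit] >= animCut[hit]]
      if (length(dead)) {
        aliveAnim[dead] <<- FALSE
        nAlive <<- nAlive - length(dead)
        # a dead animal's surviving edges (those to still-alive plants)
        # become losses for those plants; edges to already-dead plants were
        # accounted when the plants died
        dw <- if (length(dead) == 1L) W[dead, ] else colSums(W[dead, , drop = FALSE])
        dw[!alivePlant] <- 0
        lp <- which(dw > 0)
        if (length(lp)) lossP[lp] <<- lossP[lp] + dw[lp]
      }
    }
    a_curve[step + 1L] <<- nAlive
  }

  if (!is.null(order)) {
    for (e in order) kill(e, TRUE)
  } else if (config$model == "SO") {
    while (step < P) {
      alive <- which(alivePlant)
      kill(alive[sample.int(length(alive), 1L)], TRUE)
    }
  } else if (config$model == "DA") {
    while (step < P) {
      alive <- which(alivePlant)
      kill(alive[sample.int(length(alive), 1L)], TRUE)
      repeat {
        marked <- which(alivePlant & lossP >= plantCut)
        if (!length(marked)) break
        f <- if (length(marked) == 1L) marked
             else marked[sample.int(length(marked), 1L)]
        kill(f, FALSE)
      }
    }
  } else { # RW
    e <- NA_integer_; is_trig <- TRUE
    while (step < P) {
      if (is.na(e)) {
        alive <- which(alivePlant)
        e <- alive[sample.int(length(alive), 1L)]
        is_trig <- TRUE
      }
      # choose the next victim from the shared-pollinator row of e,
      # computed on the current reduced network before e is removed
      va <- aliveAnim & B[, e]
      f_next <- NA_integer_
      if (any(va)) {
        shared <- colSums(B[va, , drop = FALSE])
        shared[!alivePlant] <- 0
        shared[e] <- 0
        cand <- which(shared > 0)
        if (length(cand))
          f_next <- cand[sample.int(length(cand), 1L, prob = shared[cand])]
      }
      kill(e, is_trig)
      e <- f_next
      is_trig <- FALSE
    }
  }

  R <- sum(a_curve) / (A * P)
  ranks <- integer(P)
  ranks[seqv] <- seq_len(P)
  names(ranks) <- net$plant_labels
  structure(list(plant_sequence = seqv, a_curve = a_curve, R = R,
                 ranks = ranks, trigger_flags = trig,
                 model = if (is.null(order)) config$model else "ordered",
                 weighted = weighted, threshold = config$threshold),
            class = "extinction_run")
}

#' @export
print.extinction_run <- function(x, ...) {
  cat(sprintf("extinction_run (%s, %s, T = %g): P = %d, R = %.4f, %d triggers\n",
              x$model, if (x$weighted) "weighted" else "binary", x$threshold,
              length(x$plant_sequence), x$R, sum(x$trigger_flags)))
  invisible(x)
}

#' Run one knockout extinction simulation
#'
#' `run_model()` dispatches on `config$model`; `run_so()`, `run_da()`, and
#' `run_rw()` are explicit front ends. Each run removes plants one at a time
#' until every species is extinct, recording the pollinator survival curve
#' `a(p)` after every individual plant removal, and returns the full run
#' record.
#'
#' If `config$seed` is set, the run's random stream is seeded with it, so
#' identical `(network, config, seed)` triples give bit-identical runs.
#'
#' @param net a validated `bipartite_network`.
#' @param config a [model_config()].
#' @return an object of class `extinction_run` with fields
#'   `plant_sequence` (the order in which the `P` plants went extinct),
#'   `a_curve` (`a(p)` for `p = 0..P`), `R` (robustness), `ranks`
#'   (per-plant extinction rank, named), and `trigger_flags` (`TRUE` where
#'   the step was a randomly chosen trigger rather than an avalanche or
#'   walk step).
#' @export
run_model <- function(net, config) {
  validate_network(net)
  if (!is.null(config$seed)) set.seed(config$seed)
  .ko_engine(net, config)
}

#' @rdname run_model
#' @export
run_so <- function(net, config) {
  stopifnot(config$model == "SO")
  run_model(net, config)
}

#' @rdname run_model
#' @export
run_da <- function(net, config) {
  stopifnot(config$model == "DA")
  run_model(net, config)
}

#' @rdname run_model
#' @export
run_rw <- function(net, config) {
  stopifnot(config$model == "RW")
  run_model(net, config)
}

#' Run a deterministic ordered extinction sequence
#'
#' Secondary-Only mechanics with a predetermined primary sequence: plants
#' are removed in order of increasing or decreasing degree (ties broken by
#' original column index, for replay determinism) or in an explicitly given
#' permutation. Used to bracket the robustness distribution between its
#' practical extremes.
#'
#' @param net a `bipartite_network`.
#' @param order `"increasing_degree"`, `"decreasing_degree"`, or an integer
#'   permutation of `1:P`.
#' @param config a [model_config()]; only `weighted` and `threshold` apply.
#' @return an `extinction_run`.
#' @export
run_ordered <- function(net, order, config) {
  validate_network(net)
  P <- n_plants(net)
  if (is.character(order)) {
    order <- match.arg(order, c("increasing_degree", "decreasing_degree"))
    deg <- colSums(net$M > 0)
    idx <- if (order == "increasing_degree")
      order(deg, seq_len(P)) else order(-deg, seq_len(P))
  } else {
    idx <- as.integer(order)
    if (length(idx) != P || !setequal(idx, seq_len(P)))
      stop("explicit order must be a permutation of 1:P")
  }
  .ko_engine(net, config, order = idx)
}
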