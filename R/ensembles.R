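# Per-run / per-draw seeds are derived from a master seed via a counter, so
# each run is reproducible in isolation. Kept below 2^31 - 1.
.derive_seed <- function(master, i) {
  as.integer((as.double(master %% 2147483647L) * 69069 +
                as.double(i) * 1234567) %% 2147483587)
}

#' Simulate an ensemble of extinction runs
#'
#' Runs the configured model `n` times with independent per-run seeds
#' derived from `master_seed`, and aggregates the robustness values into a
#' distribution `f(R)` plus per-plant extinction-rank histograms `h(r)`.
#'
#' @param net a `bipartite_network`.
#' @param config a [model_config()] (its own `seed` field is ignored here).
#' @param n number of runs (the reference analyses use 25,000; tests use
#'   smaller ensembles with widened tolerances).
#' @param master_seed integer master seed.
#' @return a list with
#'   \describe{
#'     \item{distribution}{a `robustness_distribution`: `values`, `n`,
#'       `median`, `iqr`, `q025`, `q975`.}
#'     \item{rank_profiles}{a `rank_profiles` object: matrix `h` of rank
#'       counts (plants in rows, ranks `1..P` in columns), per-plant median
#'       rank `r_m`, and per-plant degree `k`.}
#'   }
#' @export
simulate_ensemble <- function(net, config, n, master_seed = 1L) {
  validate_network(net)
  stopifnot(n >= 1L)
  P <- n_plants(net)
  values <- numeric(n)
  h <- matrix(0L, P, P, dimnames = list(net$plant_labels, seq_len(P)))
  cfg <- config
  for (i in seq_len(n)) {
    cfg$seed <- .derive_seed(master_seed, i)
    run <- run_model(net, cfg)
    values[i] <- run$R
    h[cbind(seq_len(P), run$ranks)] <- h[cbind(seq_len(P), run$ranks)] + 1L
  }
  list(distribution = robustness_distribution(values),
       rank_profiles = rank_profiles(h, net))
}

#' Robustness distribution f(R)
#'
#' Container for the robustness values of an ensemble of runs, with the
#' summaries used for box plots: median `R_m`, interquartile range, and the
#' central 95% (2.5--97.5%) interval.
#'
#' @param values numeric vector of robustness values in (0, 1).
#' @return an object of class `robustness_distribution`.
#' @export
robustness_distribution <- function(values) {
  stopifnot(length(values) >= 1L, all(values > 0), all(values < 1))
  q <- stats::quantile(values, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE)
  structure(list(values = values, n = length(values),
                 median = q[3L], iqr = q[4L] - q[2L],
                 q025 = q[1L], q975 = q[5L]),
            class = "robustness_distribution")
}

#' @export
print.robustness_distribution <- function(x, ...) {
  cat(sprintf(
    "f(R) over %d runs: R_m = %.4f, IQR = %.4f, 95%% interval [%.4f, %.4f]\n",
    x$n, x$median, x$iqr, x$q025, x$q975))
  invisible(x)
}

#' Summarize a robustness distribution
#'
#' Median, IQR, central 95% interval, mean, and standard deviation.
#' Percentiles use linear interpolation between order statistics (the usual
#' box-plot convention); the median of an even-length sample is the
#' midpoint of the two central order statistics.
#'
#' @param dist a `robustness_distribution`.
#' @return a one-row `data.frame`.
#' @export
summarize_distribution <- function(dist) {
  data.frame(n = dist$n, median = dist$median, iqr = dist$iqr,
             q025 = dist$q025, q975 = dist$q975,
             mean = mean(dist$values), sd = stats::sd(dist$values))
}

# Rank histograms -> per-plant median rank via the cumulative counts.
rank_profiles <- function(h, net) {
  n <- sum(h[1L, ])
  r_m <- apply(h, 1L, function(counts) {
    cum <- cumsum(counts)
    if (n %% 2 == 0) {
      # midpoint of the two central order statistics
      (which(cum >= n / 2)[1L] + which(cum >= n / 2 + 1)[1L]) / 2
    } else {
      which(cum >= (n + 1) / 2)[1L]
    }
  })
  structure(list(h = h, r_m = r_m, k = colSums(net$M > 0), n = n),
            class = "rank_profiles")
}

#' @export
print.rank_profiles <- function(x, ...) {
  cat(sprintf("rank_profiles: %d plants, %d runs; r_m in [%g, %g]\n",
              nrow(x$h), x$n, min(x$r_m), max(x$r_m)))
  invisible(x)
}

#' Correlation between median extinction rank and degree
#'
#' Spearman rank correlation between each plant's median extinction rank
#' `r_m` and its degree `k`, with average-rank tie handling. A positive
#' coefficient means high-degree plants tend to die late (as under the
#' avalanche model); negative means they die early (as under the random
#' walk). The p-value is two-sided: an exact permutation test when `P <= 8`,
#' otherwise the large-sample t approximation.
#'
#' @param profiles a `rank_profiles` object (or a list with `r_m` and `k`).
#' @return a list with `rho` and `p`; error if either variable has zero
#'   variance (the Secondary-Only limit, where `r_m` is constant).
#' @export
rank_degree_correlation <- function(profiles) {
  r_m <- profiles$r_m; k <- profiles$k
  if (length(r_m) < 3L) stop("need at least 3 plants")
  if (stats::var(r_m) == 0 || stats::var(k) == 0)
    stop("rank-degree correlation undefined: zero variance (constant r_m or k)")
  rr <- rank(r_m); rk <- rank(k)
  rho <- stats::cor(rr, rk)
  n <- length(r_m)
  if (n <= 8L) {
    perms <- .permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rr[p], rk))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

# All permutations of 1:n as rows (n small).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[row + seq_len(nrow(sub)), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Threshold sweep
#'
#' For each threshold value, runs an ensemble and reports the node-averaged
#' effective threshold and the median robustness. Reproduces the
#' characteristic pattern that `R_m` increases monotonically (but
#' nonlinearly) with `T`, and roughly linearly with `T_eff`.
#'
#' @param net a `bipartite_network`.
#' @param config a [model_config()]; its threshold is replaced per sweep
#'   point.
#' @param T_values thresholds to sweep (default 0.1 to 1 by 0.1).
#' @param n runs per threshold.
#' @param master_seed integer; each threshold gets a derived sub-seed.
#' @return a `data.frame` with columns `T`, `T_eff`, `R_m`, `iqr`, `n`.
#' @export
threshold_sweep <- function(net, config, T_values = seq(0.1, 1, by = 0.1),
                            n = 1000L, master_seed = 1L) {
  stopifnot(all(T_values > 0 & T_values <= 1))
  rows <- lapply(seq_along(T_values), function(i) {
    cfg <- model_config(config$model, config$weighted, T_values[i])
    sim <- simulate_ensemble(net, cfg, n,
                             master_seed = .derive_seed(master_seed, 7919L * i))
    data.frame(T = T_values[i],
               T_eff = node_average_effective_threshold(net, T_values[i]),
               R_m = sim$distribution$median,
               iqr = sim$distribution$iqr,
               n = n)
  })
  do.call(rbind, rows)
}
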