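#' Construct a bipartite interaction network
#'
#' A bipartite network holds the `A x P` incidence matrix `M` of observed
#' interactions between `A` animal (pollinator) species -- the rows -- and
#' `P` plant species -- the columns. Entries are nonnegative interaction
#' weights (typically visit counts); in binary mode every positive entry is
#' treated as presence/absence.
#'
#' @param M numeric matrix, animals in rows, plants in columns; all entries
#'   nonnegative, at least one positive, and no all-zero row or column
#'   (every species must have at least one interaction).
#' @param weighted logical; if `FALSE` the network is interpreted on its
#'   binary pattern and positive weights are collapsed to 1.
#' @param animal_labels,plant_labels optional character vectors of species
#'   names; default to the dimnames of `M` or generated labels.
#'
#' @return an object of class `bipartite_network`: a list with elements
#'   `M` (labelled numeric matrix), `weighted` (flag), and the label vectors.
#' @examples
#' M <- matrix(c(1, 0, 0, 2), 2, 2,
#'             dimnames = list(c("bee", "fly"), c("aster", "clover")))
#' net <- bipartite_network(M)
#' n_animals(net); n_plants(net); n_edges(net)
#' @export
bipartite_network <- function(M, weighted = TRUE,
                              animal_labels = NULL, plant_labels = NULL) {
  if (!is.matrix(M) || !is.numeric(M))
    stop("M must be a numeric matrix (animals x plants)")
  if (is.null(animal_labels))
    animal_labels <- rownames(M) %||% paste0("A", seq_len(nrow(M)))
  if (is.null(plant_labels))
    plant_labels <- colnames(M) %||% paste0("P", seq_len(ncol(M)))
  if (!weighted) M[M > 0] <- 1
  dimnames(M) <- list(animal_labels, plant_labels)
  net <- structure(
    list(M = M, weighted = isTRUE(weighted),
         animal_labels = as.character(animal_labels),
         plant_labels = as.character(plant_labels)),
    class = "bipartite_network")
  validate_network(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a bipartite network
#'
#' Checks the invariants required by the extinction models: nonnegative
#' entries, at least one interaction, unique labels, and no species with
#' zero interactions (a zero row/column would make the initial survivor
#' count wrong and distort robustness). Non-integer weights are tolerated
#' with a warning, since the models only require nonnegativity.
#'
#' @param net a `bipartite_network`.
#' @return `net`, invisibly, if valid; otherwise an error naming the problem
#'   (and offending species, where relevant).
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  M <- net$M
  if (nrow(M) < 1L || ncol(M) < 1L)
    stop("network must have at least one animal and one plant")
  if (anyNA(M)) stop("network matrix contains missing values")
  if (any(M < 0)) stop("network matrix contains negative entries")
  if (!any(M > 0)) stop("network has no interactions")
  if (anyDuplicated(net$animal_labels))
    stop("duplicate animal labels: ",
         paste(unique(net$animal_labels[duplicated(net$animal_labels)]),
               collapse = ", "))
  if (anyDuplicated(net$plant_labels))
    stop("duplicate plant labels: ",
         paste(unique(net$plant_labels[duplicated(net$plant_labels)]),
               collapse = ", "))
  zr <- rowSums(M) == 0
  if (any(zr))
    stop("animal species with no interactions: ",
         paste(net$animal_labels[zr], collapse = ", "))
  zc <- colSums(M) == 0
  if (any(zc))
    stop("plant species with no interactions: ",
         paste(net$plant_labels[zc], collapse = ", "))
  if (net$weighted && any(M != round(M)))
    warning("non-integer weights present; treated as valid nonnegative weights")
  invisible(net)
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "bipartite_network: %d animals x %d plants, E = %d, %s\n",
    n_animals(x), n_plants(x), n_edges(x),
    if (x$weighted) "weighted" else "binary"))
  invisible(x)
}

#' Network dimensions and edge count
#'
#' `n_animals()` and `n_plants()` return the guild sizes `A` and `P`;
#' `n_edges()` returns `E`, the number of strictly positive entries of `M`
#' (identical in binary and weighted mode).
#'
#' @param net a `bipartite_network`.
#' @return an integer scalar.
#' @export
n_animals <- function(net) nrow(net$M)

#' @rdname n_animals
#' @export
n_plants <- function(net) ncol(net$M)

#' @rdname n_animals
#' @export
n_edges <- function(net) sum(net$M > 0)

#' Collapse a network to its binary pattern
#'
#' Replaces every positive weight by 1, preserving labels and the zero
#' pattern (and hence `E`). Idempotent.
#'
#' @param net a `bipartite_network`.
#' @return a binary-mode `bipartite_network`.
#' @export
to_binary <- function(net) {
  bipartite_network((net$M > 0) * 1, weighted = FALSE,
                    animal_labels = net$animal_labels,
                    plant_labels = net$plant_labels)
}

#' Read a bipartite interaction matrix from a delimited text file
#'
#' Parses the labelled-matrix dialect used by interaction-web repositories:
#' the first row holds the plant labels, the first column the animal labels,
#' and the body is a rectangular block of nonnegative numbers. The top-left
#' cell is ignored.
#'
#' @param path file to read.
#' @param delimiter field separator; `NULL` (default) auto-detects tab
#'   versus comma from the header line.
#' @param weighted logical; `FALSE` collapses entries to the binary pattern.
#' @param transpose logical; set `TRUE` for files stored plants-in-rows.
#' @return a validated [bipartite_network()].
#' @export
read_network <- function(path, delimiter = NULL, weighted = TRUE,
                         transpose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("file too short to be a labelled matrix: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\t", lines[[1]])) "\t" else ","
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  width <- length(cells[[1L]])
  ragged <- which(lengths(cells) != width)
  if (length(ragged))
    stop(sprintf("ragged row %d in %s: expected %d fields, found %d",
                 ragged[1L], path, width, lengths(cells)[ragged[1L]]))
  header <- trimws(cells[[1L]])
  plant_labels <- header[-1L]
  body <- cells[-1L]
  animal_labels <- trimws(vapply(body, `[[`, "", 1L))
  M <- matrix(NA_real_, length(body), width - 1L)
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[i]][-1L]))
    bad <- which(is.na(vals))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column %d of %s: '%s'",
                   i + 1L, bad[1L] + 1L, path, body[[i]][bad[1L] + 1L]))
    M[i, ] <- vals
  }
  if (transpose) {
    M <- t(M)
    tmp <- animal_labels; animal_labels <- plant_labels; plant_labels <- tmp
  }
  bipartite_network(M, weighted = weighted,
                    animal_labels = animal_labels,
                    plant_labels = plant_labels)
}

#' Write a bipartite network as a delimited labelled matrix
#'
#' Emits the same dialect [read_network()] accepts, so write/read round-trips
#' are exact. Binary-mode networks are written as 0/1.
#'
#' @param net a `bipartite_network`.
#' @param path output file.
#' @param delimiter field separator (default tab).
#' @export
write_network <- function(net, path, delimiter = "\t") {
  M <- net$M
  fmt <- function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           format(x, trim = TRUE))
  }
  header <- paste(c("", net$plant_labels), collapse = delimiter)
  rows <- vapply(seq_len(nrow(M)), function(i)
    paste(c(net$animal_labels[i], fmt(M[i, ])), collapse = delimiter), "")
  ok <- tryCatch(writeLines(c(header, rows), path),
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}

#' Export a network as JSON
#'
#' Serialises labels, matrix, and mode flag for downstream tooling.
#'
#' @param net a `bipartite_network`.
#' @param path optional file; if `NULL`, the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
network_to_json <- function(net, path = NULL) {
  obj <- list(animal_labels = net$animal_labels,
              plant_labels = net$plant_labels,
              weighted = net$weighted,
              M = unname(net$M))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
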