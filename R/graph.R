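#' Build an areal adjacency graph from an edge list
#'
#' Constructs the symmetric neighbourhood structure used by the intrinsic CAR
#' priors. Edges are deduplicated (an unordered pair appears once), every area
#' in the registry is represented even if it has no edges (isolated areas form
#' singleton components), and connected components are reported so that
#' sum-to-zero constraints can be applied per component.
#'
#' @param edge_records a two-column matrix or data frame of area-id pairs, or a
#'   list of length-2 vectors. Ids must appear in `area_ids`.
#' @param area_ids ordered character vector of area identifiers; defines the
#'   internal 1..n indexing of areas.
#' @return an object of class `spatial_graph` with elements `n_areas`,
#'   `edges` (m x 2 integer matrix, first index < second), `n_neighbors`,
#'   `component` (integer membership), `n_components`, `singletons`
#'   (indices of isolated areas), `area_ids`.
#' @examples
#' g <- build_adjacency(rbind(c("a", "b"), c("b", "c")), c("a", "b", "c", "d"))
#' g$n_neighbors  # 1 2 1 0
#' @export
build_adjacency <- function(edge_records, area_ids) {
  area_ids <- as.character(area_ids)
  if (length(area_ids) < 1L) stop("area_ids must be non-empty")
  if (anyDuplicated(area_ids)) stop("duplicate ids in area registry")
  em <- as_edge_matrix(edge_records)
  if (nrow(em) > 0L) {
    ia <- match(em[, 1L], area_ids)
    ib <- match(em[, 2L], area_ids)
    bad <- unique(c(em[, 1L][is.na(ia)], em[, 2L][is.na(ib)]))
    if (length(bad)) {
      stop("edge list refers to unknown area id(s): ", paste(bad, collapse = ", "))
    }
    if (any(ia == ib)) {
      stop("self-loop edge for area id(s): ",
           paste(unique(em[ia == ib, 1L]), collapse = ", "))
    }
    lo <- pmin(ia, ib)
    hi <- pmax(ia, ib)
    keep <- !duplicated(lo + hi * (length(area_ids) + 1))
    edges <- cbind(lo, hi, deparse.level = 0)[keep, , drop = FALSE]
  } else {
    edges <- matrix(integer(0), ncol = 2L)
  }
  new_spatial_graph(length(area_ids), edges, area_ids)
}

as_edge_matrix <- function(edge_records) {
  if (is.list(edge_records) && !is.data.frame(edge_records)) {
    if (length(edge_records) == 0L) return(matrix(character(0), ncol = 2L))
    edge_records <- do.call(rbind, lapply(edge_records, function(p) {
      if (length(p) != 2L) stop("each edge record must have exactly two ids")
      as.character(p)
    }))
  }
  em <- as.matrix(edge_records)
  if (ncol(em) != 2L) stop("edge records must have two columns")
  storage.mode(em) <- "character"
  em
}

new_spatial_graph <- function(n_areas, edges, area_ids) {
  storage.mode(edges) <- "integer"
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n_areas)
  g <- igraph::make_graph(edges = as.vector(t(edges)), n = n_areas,
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  singles <- which(deg == 0L)
  structure(
    list(n_areas = n_areas,
         edges = edges,
         n_neighbors = deg,
         component = as.integer(comp),
         n_components = max(comp),
         singletons = singles,
         area_ids = area_ids),
    class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf("spatial_graph: %d areas, %d edges, %d component(s), %d isolated\n",
              x$n_areas, nrow(x$edges), x$n_components, length(x$singletons)))
  invisible(x)
}

# Degrees of freedom of the (per-component sum-to-zero) intrinsic CAR prior
# plus one proper dimension per isolated area (exchangeable normal prior).
icar_rank <- function(graph) {
  graph$n_areas - graph$n_components + length(graph$singletons)
}

#' Intrinsic CAR quadratic form
#'
#' The pairwise-difference penalty of the intrinsic conditional autoregressive
#' prior: the sum over adjacency edges (a, b) of `(field[a] - field[b])^2`.
#' It is invariant to adding a constant (per connected component) to the field
#' and equals `t(field) %*% L %*% field` for the graph Laplacian `L`.
#'
#' @param field numeric vector, one value per area.
#' @param graph a `spatial_graph`.
#' @return non-negative scalar.
#' @export
icar_quadform <- function(field, graph) {
  if (length(field) != graph$n_areas) {
    stop("field length ", length(field), " does not match n_areas ",
         graph$n_areas)
  }
  if (nrow(graph$edges) == 0L) return(0)
  sum((field[graph$edges[, 1L]] - field[graph$edges[, 2L]])^2)
}

#' Random-walk-1 quadratic form
#'
#' First-difference penalty of the RW1 temporal prior:
#' `sum((series[j + 1] - series[j])^2)`.
#'
#' @param series numeric vector of length >= 2 (one value per period).
#' @return non-negative scalar.
#' @export
rw1_quadform <- function(series) {
  if (length(series) < 2L) stop("rw1_quadform needs at least 2 periods")
  sum(diff(series)^2)
}

# internal: RW1 penalty that tolerates a single period (contributes 0)
rw1_quad0 <- function(series) {
  if (length(series) < 2L) return(0)
  sum(diff(series)^2)
}

#' Read an adjacency file
#'
#' Two dialects are supported: a two-column edge list (whitespace- or
#' comma-separated area ids, optionally with a header line `from,to`) and the
#' GAL dialect (header line `0 N`, then for each area a line `id k` followed
#' by a line of its k neighbour ids).
#'
#' @param path file path.
#' @param area_ids optional ordered registry of area ids; defaults to the ids
#'   appearing in the file (GAL: header order; edge list: order of appearance).
#' @param format `"auto"`, `"edgelist"` or `"gal"`.
#' @return a `spatial_graph`.
#' @export
read_adjacency <- function(path, area_ids = NULL,
                           format = c("auto", "edgelist", "gal")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty adjacency file: ", path)
  if (format == "auto") {
    first <- strsplit(trimws(lines[[1L]]), "[,[:space:]]+")[[1L]]
    format <- if (length(first) == 2L && identical(first[[1L]], "0") &&
                  !is.na(suppressWarnings(as.integer(first[[2L]])))) {
      "gal"
    } else {
      "edgelist"
    }
  }
  if (format == "gal") read_gal_lines(lines, area_ids)
  else read_edgelist_lines(lines, area_ids)
}

read_edgelist_lines <- function(lines, area_ids) {
  toks <- lapply(lines, function(l) strsplit(trimws(l), "[,[:space:]]+")[[1L]])
  if (all(tolower(toks[[1L]]) %in% c("from", "to", "a", "b", "area1", "area2"))) {
    toks <- toks[-1L]
  }
  bad <- which(vapply(toks, length, 1L) != 2L)
  if (length(bad)) stop("edge list line ", bad[[1L]], " does not have 2 fields")
  em <- do.call(rbind, toks)
  if (is.null(area_ids)) area_ids <- unique(as.vector(t(em)))
  build_adjacency(em, area_ids)
}

read_gal_lines <- function(lines, area_ids) {
  header <- strsplit(trimws(lines[[1L]]), "[[:space:]]+")[[1L]]
  n <- as.integer(header[[length(header)]])
  ids <- character(n)
  edges <- vector("list", n)
  row <- 2L
  for (a in seq_len(n)) {
    if (row > length(lines)) stop("GAL file truncated at area ", a)
    hd <- strsplit(trimws(lines[[row]]), "[[:space:]]+")[[1L]]
    if (length(hd) != 2L) stop("malformed GAL area header: ", lines[[row]])
    ids[[a]] <- hd[[1L]]
    k <- as.integer(hd[[2L]])
    row <- row + 1L
    if (k > 0L) {
      nb <- strsplit(trimws(lines[[row]]), "[[:space:]]+")[[1L]]
      if (length(nb) != k) {
        stop("GAL area ", ids[[a]], " declares ", k, " neighbours, found ",
             length(nb))
      }
      edges[[a]] <- cbind(rep(ids[[a]], k), nb)
      row <- row + 1L
    }
  }
  em <- do.call(rbind, edges[!vapply(edges, is.null, TRUE)])
  if (is.null(area_ids)) area_ids <- ids
  if (is.null(em)) em <- matrix(character(0), ncol = 2L)
  build_adjacency(em, area_ids)
}

#' Write a graph as a two-column edge-list file
#'
#' @param graph a `spatial_graph`.
#' @param path output file path.
#' @export
write_edge_list <- function(graph, path) {
  df <- data.frame(from = graph$area_ids[graph$edges[, 1L]],
                   to = graph$area_ids[graph$edges[, 2L]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# dense graph Laplacian (used by the generator and in tests)
graph_laplacian <- function(graph) {
  n <- graph$n_areas
  L <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    for (e in seq_len(nrow(graph$edges))) {
      a <- graph$edges[e, 1L]; b <- graph$edges[e, 2L]
      L[a, b] <- L[a, b] - 1
      L[b, a] <- L[b, a] - 1
      L[a, a] <- L[a, a] + 1
      L[b, b] <- L[b, b] + 1
    }
  }
  L
}
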