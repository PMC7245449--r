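#' Build a district adjacency graph from an edge list
#'
#' Constructs the symmetric common-boundary neighbourhood structure used
#' by both the Moran's I screen and the intrinsic CAR prior. Edges are
#' deduplicated and symmetrised; self-loops and out-of-range indices are
#' rejected. Isolated districts (no neighbours) are allowed but
#' reported, since they need special handling in the CAR prior.
#'
#' @param edges Two-column data frame or matrix of 1-based node index
#'   pairs.
#' @param n_nodes Total number of districts.
#' @return An object of class `district_graph`: a list with `n_nodes`,
#'   `nb` (list of sorted neighbour index vectors), `n_edges`,
#'   `isolated` (indices), and `n_components` (connected components
#'   among all nodes, isolated nodes counting as their own component).
#' @export
build_adjacency <- function(edges, n_nodes) {
  e <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(e) <- "integer"
  if (nrow(e) > 0) {
    if (any(is.na(e)) || any(e < 1L) || any(e > n_nodes)) {
      abort("build_adjacency(): node index out of range.",
            class = "nutrimap_format_error")
    }
    if (any(e[, 1] == e[, 2])) {
      abort("build_adjacency(): self-loops are not allowed.",
            class = "nutrimap_format_error")
    }
  }
  nb <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) nb[[i]] <- integer(0)
  if (nrow(e) > 0) {
    a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
    uq <- unique(cbind(a, b))
    for (k in seq_len(nrow(uq))) {
      i <- uq[k, 1]; j <- uq[k, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
    nb <- lapply(nb, function(v) sort(unique(v)))
  }
  iso <- which(lengths(nb) == 0L)
  if (length(iso)) {
    warn(sprintf("build_adjacency(): %d isolated node(s): %s",
                 length(iso), paste(iso, collapse = ", ")))
  }
  g <- structure(
    list(n_nodes = n_nodes, nb = nb,
         n_edges = sum(lengths(nb)) / 2L, isolated = iso,
         n_components = NA_integer_),
    class = "district_graph")
  g$n_components <- graph_components(g)
  g
}

# number of connected components (BFS over all nodes)
graph_components <- function(graph) {
  n <- graph$n_nodes
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (u in graph$nb[[v]]) {
        if (comp[u] == 0L) { comp[u] <- cur; queue <- c(queue, u) }
      }
    }
  }
  cur
}

# BFS spanning forest: tibble of (parent, child) edges, roots excluded
spanning_forest <- function(graph) {
  n <- graph$n_nodes
  seen <- logical(n)
  parent <- integer(0); child <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    seen[s] <- TRUE
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (u in graph$nb[[v]]) {
        if (!seen[u]) {
          seen[u] <- TRUE
          parent <- c(parent, v); child <- c(child, u)
          queue <- c(queue, u)
        }
      }
    }
  }
  cbind(parent = parent, child = child)
}

# unique undirected edge list as a 2-column matrix (i < j)
graph_edges <- function(graph) {
  out <- NULL
  for (i in seq_len(graph$n_nodes)) {
    js <- graph$nb[[i]]
    js <- js[js > i]
    if (length(js)) out <- rbind(out, cbind(i, js))
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  colnames(out) <- c("node_a", "node_b")
  out
}

#' @export
print.district_graph <- function(x, ...) {
  cat(sprintf(
    "district_graph: %d nodes, %d edges, %d component(s), %d isolated\n",
    x$n_nodes, x$n_edges, x$n_components, length(x$isolated)))
  invisible(x)
}

#' Read / write a district adjacency edge list CSV
#'
#' Two-column CSV (`node_a`, `node_b`) of 1-based district indices,
#' shared between the spatial screen and the space-time model.
#'
#' @param path File path.
#' @param n_nodes Number of districts (defaults to the largest index in
#'   the file).
#' @param graph A `district_graph`.
#' @return `read_edges_csv()` returns a `district_graph`;
#'   `write_edges_csv()` returns `path` invisibly.
#' @export
read_edges_csv <- function(path, n_nodes = NULL) {
  e <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(node_a = "i", node_b = "i"))
  if (is.null(n_nodes)) n_nodes <- max(e$node_a, e$node_b)
  build_adjacency(e, n_nodes)
}

#' @rdname read_edges_csv
#' @export
write_edges_csv <- function(graph, path) {
  readr::write_csv(tibble::as_tibble(graph_edges(graph)), path)
  invisible(path)
}
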