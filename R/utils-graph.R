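# Internal graph primitives over a 2-column character edge matrix
# (column 1 = parent/from, column 2 = child/to). Kept dependency-free:
# every operation here has an enumeration oracle in the test suite.

empty_edges <- function() {
  matrix(character(0), ncol = 2L, dimnames = list(NULL, c("from", "to")))
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || length(edges) == 0L) return(empty_edges())
  m <- matrix(as.character(edges), ncol = 2L)
  colnames(m) <- c("from", "to")
  m
}

edge_keys <- function(edges) paste(edges[, 1L], edges[, 2L], sep = "\r")

#' @keywords internal
adjacency_list <- function(nodes, edges, reverse = FALSE) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (n in nodes) adj[[n]] <- character(0)
  if (nrow(edges)) {
    a <- if (reverse) edges[, 2L] else edges[, 1L]
    b <- if (reverse) edges[, 1L] else edges[, 2L]
    sp <- split(b, factor(a, levels = nodes))
    for (n in names(sp)) if (length(sp[[n]])) adj[[n]] <- unname(sp[[n]])
  }
  adj
}

# Kahn topological sort; returns NULL if a cycle exists.
topo_sort <- function(nodes, edges) {
  edges <- as_edge_matrix(edges)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    t <- table(factor(edges[, 2L], levels = nodes))
    indeg[names(t)] <- as.integer(t)
  }
  adj <- adjacency_list(nodes, edges)
  # deterministic: among in-degree-0 nodes pick lexicographically smallest
  avail <- sort(names(indeg)[indeg == 0L])
  out <- character(0)
  while (length(avail)) {
    n <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, n)
    for (m in adj[[n]]) {
      indeg[[m]] <- indeg[[m]] - 1L
      if (indeg[[m]] == 0L) avail <- sort(c(avail, m))
    }
  }
  if (length(out) != length(nodes)) NULL else out
}

is_acyclic <- function(nodes, edges) !is.null(topo_sort(nodes, edges))

# One directed cycle (node sequence), for error messages.
find_cycle <- function(nodes, edges) {
  edges <- as_edge_matrix(edges)
  adj <- adjacency_list(nodes, edges)
  state <- stats::setNames(integer(length(nodes)), nodes) # 0 new, 1 open, 2 done
  path <- character(0)
  res <- NULL
  visit <- function(n) {
    if (!is.null(res)) return()
    state[[n]] <<- 1L
    path <<- c(path, n)
    for (m in adj[[n]]) {
      if (!is.null(res)) return()
      if (state[[m]] == 1L) {
        i <- match(m, path)
        res <<- c(path[i:length(path)], m)
        return()
      }
      if (state[[m]] == 0L) visit(m)
    }
    state[[n]] <<- 2L
    path <<- path[-length(path)]
  }
  for (n in nodes) if (state[[n]] == 0L) visit(n)
  res
}

# Nodes reachable from `from` (excluded set removed first).
reachable_from <- function(nodes, edges, from, undirected = FALSE,
                           excluded = character(0)) {
  keep <- setdiff(nodes, excluded)
  edges <- as_edge_matrix(edges)
  if (nrow(edges)) {
    ok <- edges[, 1L] %in% keep & edges[, 2L] %in% keep
    edges <- edges[ok, , drop = FALSE]
  }
  if (undirected && nrow(edges)) edges <- rbind(edges, edges[, 2:1, drop = FALSE])
  adj <- adjacency_list(keep, edges)
  from <- intersect(from, keep)
  seen <- stats::setNames(logical(length(keep)), keep)
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    n <- queue[[1L]]
    queue <- queue[-1L]
    nb <- adj[[n]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  names(seen)[seen]
}

# Undirected simple graph as sorted unordered pairs.
upair <- function(a, b) {
  swap <- a > b
  cbind(from = ifelse(swap, b, a), to = ifelse(swap, a, b))
}

ugraph <- function(nodes, edges = NULL) {
  edges <- as_edge_matrix(edges)
  if (nrow(edges)) {
    edges <- upair(edges[, 1L], edges[, 2L])
    edges <- edges[!duplicated(edge_keys(edges)), , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = edges), class = "cbn_ugraph")
}

ugraph_neighbors <- function(g, x) {
  e <- g$edges
  if (!nrow(e)) return(character(0))
  sort(unique(c(e[e[, 1L] == x, 2L], e[e[, 2L] == x, 1L])))
}

ugraph_add <- function(g, a, b) {
  g$edges <- rbind(g$edges, upair(a, b))
  g$edges <- g$edges[!duplicated(edge_keys(g$edges)), , drop = FALSE]
  g
}

ugraph_remove <- function(g, a, b) {
  k <- edge_keys(upair(a, b))
  g$edges <- g$edges[edge_keys(g$edges) != k, , drop = FALSE]
  g
}

ugraph_has_edge <- function(g, a, b) {
  nrow(g$edges) > 0L && edge_keys(upair(a, b)) %in% edge_keys(g$edges)
}

# Connected: is `to` reachable from `from` ignoring direction?
ugraph_connected <- function(g, from, to, excluded = character(0)) {
  to %in% reachable_from(g$nodes, g$edges, from, undirected = TRUE,
                         excluded = excluded)
}
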