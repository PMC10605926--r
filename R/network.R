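# Agent communication graphs and Metropolis mixing weights.
#
# Agents are 1-based vertices of a connected undirected graph; self-loops are
# never stored in the edge set -- the diagonal of the Metropolis matrix plays
# that role.

new_comm_graph <- function(m, edges, topology_kind, weights = NULL) {
  structure(list(m = as.integer(m), edges = edges,
                 topology_kind = topology_kind, weights = weights),
            class = "comm_graph")
}

#' @export
print.comm_graph <- function(x, ...) {
  cat(sprintf("<comm_graph> %s, m = %d, %d edges, weights %s\n",
              x$topology_kind, x$m, nrow(x$edges),
              if (is.null(x$weights)) "unset" else "set"))
  invisible(x)
}

graph_degrees <- function(graph) {
  deg <- integer(graph$m)
  if (nrow(graph$edges)) {
    t <- table(factor(c(graph$edges[, 1], graph$edges[, 2]), levels = seq_len(graph$m)))
    deg <- as.integer(t)
  }
  deg
}

adjacency_of <- function(graph) {
  A <- matrix(FALSE, graph$m, graph$m)
  if (nrow(graph$edges)) {
    A[graph$edges] <- TRUE
    A[graph$edges[, 2:1, drop = FALSE]] <- TRUE
  }
  A
}

graph_is_connected <- function(m, edges) {
  if (m == 1L) return(TRUE)
  if (nrow(edges) == 0L) return(FALSE)
  adj <- vector("list", m)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(m); seen[1] <- TRUE; stack <- 1L
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  all(seen)
}

canonical_edges <- function(edges) {
  if (is.null(edges) || length(edges) == 0L) {
    return(matrix(integer(0), 0, 2))
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

#' Build an agent communication topology
#'
#' Constructs a connected undirected graph over `m` agents. Supported kinds:
#' `complete`, `ring`, `path`, `star` (agent 1 is the hub -- the
#' semi-centralised, server-plus-clients layout) and `erdos_renyi` (edge
#' probability `p`, resampled with fresh sub-seeds until connected, at most
#' 1000 attempts). Weights are left unset; see [metropolis_weights()].
#'
#' @param kind topology name.
#' @param m number of agents (`>= 1`).
#' @param p edge probability, required for `erdos_renyi`.
#' @param seed RNG seed, required for `erdos_renyi`.
#' @return a `comm_graph` with unset weights.
#' @export
build_topology <- function(kind = c("complete", "ring", "path", "star", "erdos_renyi"),
                           m, p = NULL, seed = NULL) {
  kind <- match.arg(kind)
  m <- check_count(m, "m")
  edges <- switch(kind,
    complete = if (m > 1) t(utils::combn(m, 2)) else matrix(integer(0), 0, 2),
    path = if (m > 1) cbind(1:(m - 1), 2:m) else matrix(integer(0), 0, 2),
    ring = if (m > 2) rbind(cbind(1:(m - 1), 2:m), c(1L, m))
           else if (m == 2) cbind(1L, 2L) else matrix(integer(0), 0, 2),
    star = if (m > 1) cbind(1L, 2:m) else matrix(integer(0), 0, 2),
    erdos_renyi = {
      p <- check_scalar(p, "p", lower = 0, upper = 1, open_lower = TRUE)
      if (is.null(seed)) stop_("erdos_renyi requires a seed")
      found <- NULL
      for (attempt in seq_len(1000L)) {
        cand <- with_seed(derive_seed(seed, attempt), {
          all_pairs <- if (m > 1) t(utils::combn(m, 2)) else matrix(integer(0), 0, 2)
          keep <- stats::runif(nrow(all_pairs)) < p
          all_pairs[keep, , drop = FALSE]
        })
        if (graph_is_connected(m, cand)) { found <- cand; break }
      }
      if (is.null(found)) {
        stop_("no connected Erdos-Renyi graph found in 1000 attempts (m = %d, p = %g)", m, p)
      }
      found
    })
  edges <- canonical_edges(edges)
  if (!graph_is_connected(m, edges)) stop_("constructed graph is not connected")
  new_comm_graph(m, edges, kind)
}

#' Metropolis mixing weights
#'
#' Fills in the doubly stochastic Metropolis weight matrix of a connected
#' graph: `w_ij = 1 / (max(deg_i, deg_j) + 1)` on edges, `0` on non-edges,
#' and `w_ii = 1 - sum_h w_ih` on the diagonal. The result is symmetric,
#' nonnegative, has unit row and column sums, and (having a strictly positive
#' diagonal on a connected graph) a second-largest eigenvalue modulus
#' strictly below 1, which is what makes repeated mixing contract to the
#' network average.
#'
#' @param graph a `comm_graph` from [build_topology()].
#' @return the same graph with `weights` set.
#' @export
metropolis_weights <- function(graph) {
  stopifnot(inherits(graph, "comm_graph"))
  if (!graph_is_connected(graph$m, graph$edges)) stop_("graph must be connected")
  m <- graph$m
  deg <- graph_degrees(graph)
  W <- matrix(0, m, m)
  if (nrow(graph$edges)) {
    for (k in seq_len(nrow(graph$edges))) {
      i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
      w <- 1 / (max(deg[i], deg[j]) + 1)
      W[i, j] <- w; W[j, i] <- w
    }
  }
  diag(W) <- 1 - rowSums(W)
  graph$weights <- W
  graph
}

#' Serialise a communication graph
#'
#' Writes the edge list as plain text (one `"i j"` pair per line) plus a JSON
#' sidecar `<path>.json` holding `m` and `topology_kind`. `read_comm_graph`
#' restores the graph (weights are recomputed, not stored).
#'
#' @param graph a `comm_graph`.
#' @param path path of the edge-list file.
#' @return `write_comm_graph` returns `path` invisibly; `read_comm_graph`
#'   returns a `comm_graph` with weights unset.
#' @export
write_comm_graph <- function(graph, path) {
  stopifnot(inherits(graph, "comm_graph"))
  lines <- apply(graph$edges, 1, paste, collapse = " ")
  writeLines(as.character(lines), path)
  jsonlite::write_json(list(m = graph$m, topology_kind = graph$topology_kind),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_comm_graph
#' @export
read_comm_graph <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  edges <- if (length(lines)) {
    do.call(rbind, lapply(strsplit(lines, "\\s+"), function(x) as.integer(x[1:2])))
  } else matrix(integer(0), 0, 2)
  new_comm_graph(meta$m, canonical_edges(edges), meta$topology_kind)
}
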