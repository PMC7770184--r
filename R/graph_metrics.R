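#' Node degree of a binary network
#'
#' Degree k_i = sum_j a_ij, the number of links incident to node i.
#'
#' @param net `binary_connectome` adjacency matrix (0/1, symmetric,
#'   zero diagonal).
#' @return Named integer vector of degrees.
#' @export
node_degree <- function(net) {
  a <- check_adjacency(net)
  k <- as.integer(rowSums(a))
  names(k) <- rownames(a)
  k
}

#' Clustering coefficient per node
#'
#' C_i = E_i / choose(k_i, 2), where E_i is the number of edges among
#' the neighbors of node i. Computed via the triangle identity
#' E_i = diag(A^3)_i / 2. Nodes with fewer than two neighbors have no
#' neighbor pairs; their coefficient is defined as 0.
#'
#' @inheritParams node_degree
#' @return Named numeric vector of C_i in `[0, 1]`.
#' @export
clustering_coefficient <- function(net) {
  a <- check_adjacency(net)
  k <- rowSums(a)
  tri2 <- diag(a %*% a %*% a)      # 2 * E_i
  denom <- k * (k - 1)             # 2 * choose(k, 2)
  ci <- ifelse(denom > 0, tri2 / denom, 0)
  names(ci) <- rownames(a)
  ci
}

#' All-pairs shortest path lengths (hop counts)
#'
#' Breadth-first hop distances on the binary graph; unreachable pairs
#' are `Inf`, the diagonal is 0.
#'
#' @inheritParams node_degree
#' @return R x R numeric matrix of hop counts.
#' @export
shortest_path_lengths <- function(net) {
  a <- check_adjacency(net)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  d <- igraph::distances(g)
  dimnames(d) <- dimnames(a)
  d
}

#' Local efficiency per node
#'
#' Two variants of the nodal segregation measure are offered:
#'
#' * `mode = "literal"` (default): E_node(i) = (1/N) * sum_{j != i}
#'   1 / L_ij over the whole graph, with N the number of nodes and
#'   unreachable pairs contributing 0. This is the nodal-efficiency
#'   reading of the formula.
#' * `mode = "neighborhood"`: the conventional local efficiency — the
#'   efficiency of the subgraph induced by the neighbors of i,
#'   normalized by k_i (k_i - 1), and 0 when k_i < 2.
#'
#' @inheritParams node_degree
#' @param mode `"literal"` or `"neighborhood"`.
#' @return Named numeric vector of E_node(i); carries the mode as the
#'   `"mode"` attribute.
#' @export
local_efficiency <- function(net, mode = c("literal", "neighborhood")) {
  mode <- match.arg(mode)
  a <- check_adjacency(net)
  n <- nrow(a)
  if (mode == "literal") {
    d <- shortest_path_lengths(a)
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    e <- rowSums(inv) / n
  } else {
    e <- numeric(n)
    for (i in seq_len(n)) {
      nbrs <- which(a[i, ] > 0)
      k <- length(nbrs)
      if (k < 2L) next
      sub <- a[nbrs, nbrs, drop = FALSE]
      g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
      dsub <- igraph::distances(g)
      inv <- 1 / dsub
      diag(inv) <- 0
      inv[!is.finite(inv)] <- 0
      e[i] <- sum(inv) / (k * (k - 1))
    }
  }
  names(e) <- rownames(a)
  attr(e, "mode") <- mode
  e
}

#' Node metric table for a set of sessions
#'
#' Runs degree, clustering coefficient and local efficiency on every
#' session's binary network and stacks the results in tidy long format,
#' one row per (session, ROI).
#'
#' @param nets Named list of `binary_connectome` matrices; names are
#'   session ids (`<subject>_<session>`).
#' @param design Optional design data frame (columns `subject_id`,
#'   `group`, `session`, with session ids `subject_id` + `"_"` +
#'   `session`) used to annotate rows.
#' @param efficiency_mode Passed to [local_efficiency()].
#' @return Data frame with columns subject_id, session, group, roi,
#'   degree, clustering, local_efficiency, mode.
#' @export
node_metric_table <- function(nets, design = NULL,
                              efficiency_mode = c("literal", "neighborhood")) {
  efficiency_mode <- match.arg(efficiency_mode)
  if (is.null(names(nets))) stop("nets must be a named list (session ids)")
  rows <- lapply(names(nets), function(id) {
    a <- nets[[id]]
    labs <- rownames(a)
    if (is.null(labs)) labs <- paste0("ROI", seq_len(nrow(a)))
    data.frame(session_id = id,
               roi = labs,
               degree = node_degree(a),
               clustering = clustering_coefficient(a),
               local_efficiency = as.numeric(local_efficiency(a, efficiency_mode)),
               mode = efficiency_mode,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(design)) {
    key <- paste0(design$subject_id, "_", design$session)
    idx <- match(out$session_id, key)
    out$subject_id <- design$subject_id[idx]
    out$session <- design$session[idx]
    out$group <- design$group[idx]
    out <- out[, c("subject_id", "session", "group", "roi",
                   "degree", "clustering", "local_efficiency", "mode")]
  }
  out
}

# validate and coerce an adjacency matrix: square, symmetric, 0/1,
# zero diagonal
check_adjacency <- function(net) {
  a <- unclass(as.matrix(net))
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (!all(a %in% c(0, 1))) stop("adjacency must be 0/1")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  if (!isTRUE(all.equal(a, t(a)))) stop("adjacency must be symmetric")
  storage.mode(a) <- "numeric"
  a
}
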