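#' Weighted shortest path lengths
#'
#' Converts edge weights to lengths and computes all-pairs shortest path
#' lengths with Dijkstra's algorithm (nonnegative lengths). The conversion is
#' the single most consequential convention in weighted-efficiency analysis
#' and is therefore explicit and recorded in the result: the default
#' `"inverse"` rule sets `L_edge = 1/W` (stronger connections are shorter),
#' the alternative `"neglog"` sets `L_edge = -log(W)` (requires weights
#' `<= 1`). Disconnected pairs have infinite length.
#'
#' @param net a [hemispheric_network()] or plain symmetric nonnegative weight
#'   matrix; zero entries mean "no edge".
#' @param rule weight-to-length conversion.
#' @return a `path_lengths` object: list with `lengths` (N x N matrix,
#'   zero diagonal, `Inf` for disconnected pairs) and `rule`.
#' @export
shortest_paths <- function(net, rule = c("inverse", "neglog")) {
  rule <- match.arg(rule)
  W <- if (inherits(net, "hemispheric_network")) net$weights else as.matrix(net)
  n <- nrow(W)
  stopifnot(ncol(W) == n, all(W >= 0))
  if (any(abs(W - t(W)) > 1e-12)) stop("weight matrix must be symmetric")
  if (rule == "neglog" && any(W > 1 + 1e-12))
    stop("neglog rule requires weights <= 1")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- if (rule == "inverse") 1 / igraph::E(g)$weight
         else -log(igraph::E(g)$weight)
  L <- igraph::distances(g, weights = len, algorithm = "dijkstra")
  dimnames(L) <- NULL
  structure(list(lengths = L, rule = rule), class = "path_lengths")
}

as_length_matrix <- function(x) {
  if (inherits(x, "path_lengths")) x$lengths else as.matrix(x)
}

#' Global network efficiency
#'
#' The average inverse shortest path length over ordered node pairs:
#' `E_glob = 1/(N(N-1)) * sum_{i != j} 1/L_ij`. Disconnected pairs contribute
#' zero. Larger values indicate more efficient whole-network integration.
#'
#' @param L a `path_lengths` object (or plain length matrix).
#' @return scalar efficiency.
#' @export
global_efficiency <- function(L) {
  M <- as_length_matrix(L)
  n <- nrow(M)
  if (n < 2) stop("global efficiency requires at least 2 nodes")
  inv <- 1 / M
  inv[!is.finite(inv)] <- 0   # disconnected pairs and the diagonal
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Nodal efficiency
#'
#' The mean inverse shortest path length from node `i` to all other nodes:
#' `E_nodal(i) = 1/(N-1) * sum_{j != i} 1/L_ij` — the capacity of the node to
#' communicate with the rest of the network. The mean of `E_nodal` over all
#' nodes equals `E_glob` identically.
#'
#' @param L a `path_lengths` object (or length matrix).
#' @param i node index, or `NULL` for the full N-vector.
#' @return scalar or vector of nodal efficiencies.
#' @export
nodal_efficiency <- function(L, i = NULL) {
  M <- as_length_matrix(L)
  n <- nrow(M)
  if (n < 2) stop("nodal efficiency requires at least 2 nodes")
  inv <- 1 / M
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  en <- rowSums(inv) / (n - 1)
  if (is.null(i)) en else en[i]
}

#' Local network efficiency
#'
#' The average over nodes of the global efficiency of each node's neighbor
#' subgraph: `E_loc = 1/N * sum_i E_glob(G_i)`, where `G_i` contains the
#' neighbors of `i` (excluding `i` itself) and the original weights among
#' them. Nodes with fewer than two neighbors contribute zero (the
#' `N(N-1)` normalization of `E_glob` needs at least two nodes). Reflects
#' fault tolerance of the local circuitry.
#'
#' @param net a `hemispheric_network` or weight matrix.
#' @param rule weight-to-length conversion passed to [shortest_paths()].
#' @return scalar efficiency.
#' @export
local_efficiency <- function(net, rule = "inverse") {
  W <- if (inherits(net, "hemispheric_network")) net$weights else as.matrix(net)
  n <- nrow(W)
  if (n < 1) stop("local efficiency requires at least 1 node")
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(shortest_paths(W[nb, nb, drop = FALSE], rule))
  }, numeric(1))
  mean(vals)
}

#' All efficiency measures of one network
#'
#' @inheritParams local_efficiency
#' @return list with `e_glob`, `e_loc`, and the N-vector `e_nodal`.
#' @export
network_metrics <- function(net, rule = "inverse") {
  L <- shortest_paths(net, rule)
  list(e_glob = global_efficiency(L),
       e_loc = local_efficiency(net, rule),
       e_nodal = nodal_efficiency(L))
}

#' Hemispheric asymmetry index
#'
#' `AI = (M_R - M_L) / (M_R + M_L)` for a nonnegative measure evaluated on
#' the right and left hemispheric networks. AI lies in `[-1, 1]`; a positive
#' value is a rightward asymmetry, a negative value leftward. Undefined when
#' both measures are zero (returned as `NA` with a warning).
#'
#' @param m_right,m_left nonnegative measure values (vectorized).
#' @return AI values.
#' @export
asymmetry_index <- function(m_right, m_left) {
  if (length(m_right) != length(m_left))
    stop("m_right and m_left must have equal length")
  if (any(m_right < 0) || any(m_left < 0))
    stop("asymmetry index is defined for nonnegative measures")
  denom <- m_right + m_left
  ai <- ifelse(denom > 0, (m_right - m_left) / denom, NA_real_)
  if (anyNA(ai))
    warning(sprintf("AI undefined (M_R + M_L = 0) for %d value(s); returned NA",
                    sum(is.na(ai))))
  ai
}

#' Mean nodal AI over a node subset
#'
#' Arithmetic mean of the nodal asymmetry indices over a chosen set of nodes
#' (typically the nodes surviving a significance screen).
#'
#' @param ai numeric AI vector (one value per node).
#' @param nodes integer node indices; must be nonempty.
#' @export
mean_nodal_ai <- function(ai, nodes) {
  if (length(nodes) == 0) stop("node subset must be nonempty")
  if (any(nodes < 1 | nodes > length(ai))) stop("node index out of range")
  mean(ai[nodes])
}

#' Long-format efficiency table for a cohort
#'
#' Computes `e_glob`, `e_loc`, and `e_nodal` for every subject and
#' hemisphere of a simulated or loaded cohort.
#'
#' @param networks named list, one element per subject, each a list with
#'   `left` and `right` [hemispheric_network()]s (or weight matrices).
#' @param rule weight-to-length conversion.
#' @return data.frame with columns `subject`, `hemisphere`, `measure`,
#'   `node` (NA for global/local), `value`.
#' @export
cohort_metrics <- function(networks, rule = "inverse") {
  stopifnot(length(networks) > 0)
  ids <- names(networks)
  if (is.null(ids)) ids <- as.character(seq_along(networks))
  rows <- vector("list", 2 * length(networks))
  k <- 0
  for (s in seq_along(networks)) {
    for (h in c("left", "right")) {
      m <- network_metrics(networks[[s]][[h]], rule)
      k <- k + 1
      rows[[k]] <- data.frame(
        subject = ids[s], hemisphere = h,
        measure = c("e_glob", "e_loc", rep("e_nodal", length(m$e_nodal))),
        node = c(NA_integer_, NA_integer_, seq_along(m$e_nodal)),
        value = c(m$e_glob, m$e_loc, m$e_nodal))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' AI table from a long-format metrics table
#'
#' Pairs each subject's right and left values per measure (and node) and
#' computes the asymmetry index.
#'
#' @param metrics output of [cohort_metrics()].
#' @return data.frame with columns `subject`, `measure`, `node`, `m_right`,
#'   `m_left`, `ai`.
#' @export
ai_table <- function(metrics) {
  r <- metrics[metrics$hemisphere == "right", ]
  l <- metrics[metrics$hemisphere == "left", ]
  m <- merge(r[, c("subject", "measure", "node", "value")],
             l[, c("subject", "measure", "node", "value")],
             by = c("subject", "measure", "node"),
             suffixes = c("_right", "_left"), sort = FALSE)
  names(m)[names(m) == "value_right"] <- "m_right"
  names(m)[names(m) == "value_left"] <- "m_left"
  m$ai <- suppressWarnings(asymmetry_index(m$m_right, m$m_left))
  m
}
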