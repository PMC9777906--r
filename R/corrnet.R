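#' Pearson correlation matrix of node time-series
#'
#' Computes the full sample Pearson correlation matrix between the columns of
#' a series matrix (rows = time points, columns = nodes: lattice sites, or
#' individual energy series). Zero-variance (constant) series — frozen Ising
#' sites in the ordered phase, motionless individuals — have an undefined
#' Pearson coefficient; such nodes get correlation 0 with everything and are
#' listed in `zero_variance_nodes`, consistent with treating a quiescent
#' series as uncorrelated.
#'
#' A long tibble with columns `t`, an id column and a value column (e.g. the
#' output of [kinetic_energy()]) is accepted and pivoted automatically.
#'
#' @param series Numeric matrix (m x n, m time points, n nodes) or a long
#'   tibble with columns `individual_id`, `t` and one value column.
#' @return A `correlation_matrix` object: list with `r` (n x n symmetric
#'   matrix, unit diagonal), `node_ids` and `zero_variance_nodes` (integer
#'   indices).
#' @export
#' @examples
#' x <- cbind(a = sin(1:50), b = sin(1:50) + rnorm(50, sd = 0.1), c = rnorm(50))
#' pearson_matrix(x)
pearson_matrix <- function(series) {
  if (is.data.frame(series)) {
    value_col <- setdiff(names(series), c("individual_id", "t", "window"))
    if (length(value_col) != 1)
      abort("long input must have exactly one value column besides individual_id/t")
    wide <- tidyr::pivot_wider(series[, c("individual_id", "t", value_col)],
                               names_from = "individual_id",
                               values_from = dplyr::all_of(value_col))
    wide <- wide[order(wide$t), , drop = FALSE]
    series <- as.matrix(wide[, -1, drop = FALSE])
  }
  m <- nrow(series); n <- ncol(series)
  if (is.null(m) || m < 3) abort("need at least 3 time points per series")
  if (n < 2) abort("need at least 2 node series")
  if (anyNA(series)) abort("series contain missing values (equal-length, complete grids required)")
  ids <- colnames(series)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  mu <- colMeans(series)
  xc <- sweep(series, 2, mu)
  ss <- sqrt(colSums(xc^2))
  zero_var <- which(ss == 0)
  ss[ss == 0] <- 1
  xs <- sweep(xc, 2, ss, "/")
  r <- crossprod(xs)
  if (length(zero_var)) {
    r[zero_var, ] <- 0
    r[, zero_var] <- 0
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- NULL
  structure(list(r = r, node_ids = ids, zero_variance_nodes = zero_var),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  n <- length(x$node_ids)
  cat(sprintf("<correlation_matrix> %d nodes, %d zero-variance\n",
              n, length(x$zero_variance_nodes)))
  invisible(x)
}

upper_values <- function(corr) {
  corr$r[upper.tri(corr$r)]
}

mean_degree_at <- function(ut, n, p) {
  2 * sum(ut > p) / n
}

#' Scan binarisation thresholds against mean degree
#'
#' For each threshold `p`, reports the mean degree of the graph whose edges
#' are the node pairs with correlation strictly greater than `p`. Used to
#' place networks from different systems on a common footing by matching
#' their mean degree rather than their (incomparable) correlation scales.
#'
#' @param corr A `correlation_matrix`.
#' @param thresholds Strictly increasing numeric vector.
#' @return A tibble of class `threshold_scan` with columns `threshold`,
#'   `mean_degree`.
#' @export
scan_thresholds <- function(corr, thresholds = seq(-0.2, 0.9, by = 0.02)) {
  stopifnot(inherits(corr, "correlation_matrix"))
  if (is.unsorted(thresholds, strictly = TRUE))
    abort("thresholds must be strictly increasing")
  ut <- upper_values(corr)
  n <- length(corr$node_ids)
  k <- vapply(thresholds, function(p) mean_degree_at(ut, n, p), numeric(1))
  out <- tibble::tibble(threshold = thresholds, mean_degree = k)
  class(out) <- c("threshold_scan", class(out))
  out
}

#' Choose a threshold matching a target mean degree
#'
#' Bisection on the threshold `p` until the mean degree of the resulting
#' graph is within `tol` of `target_k`, or until the discrete edge structure
#' cannot get closer, in which case the closest achievable threshold is
#' returned. The achieved mean degree is always reported alongside `p`.
#'
#' @param corr A `correlation_matrix`.
#' @param target_k Target mean degree in `[0, n-1]`.
#' @param tol Tolerance on the achieved mean degree (default 1% of
#'   `target_k`).
#' @return A list with `p` (threshold), `achieved_k`, `target_k`.
#' @export
choose_threshold <- function(corr, target_k, tol = 0.01 * target_k) {
  stopifnot(inherits(corr, "correlation_matrix"))
  n <- length(corr$node_ids)
  if (target_k > n - 1 || target_k < 0)
    abort("target_k must lie in [0, n-1]")
  ut <- upper_values(corr)
  lo <- min(ut) - 1e-9  # everything connected
  hi <- 1               # edgeless
  k_lo <- mean_degree_at(ut, n, lo)
  if (k_lo <= target_k)
    return(list(p = lo, achieved_k = k_lo, target_k = target_k))
  best_p <- hi; best_k <- 0
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    k_mid <- mean_degree_at(ut, n, mid)
    if (abs(k_mid - target_k) < abs(best_k - target_k)) {
      best_p <- mid; best_k <- k_mid
    }
    if (abs(k_mid - target_k) <= tol) break
    if (k_mid > target_k) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  list(p = best_p, achieved_k = best_k, target_k = target_k)
}

#' Threshold a correlation matrix into a binary network
#'
#' Builds the undirected simple graph whose edges join node pairs with
#' correlation strictly greater than `p` (positive tail only by default;
#' with `absolute = TRUE`, `|r| > p`). Isolated nodes are retained in the
#' node set — correlation networks of sparse activity can have many of them
#' and they carry information (they count toward `n` when reporting degree
#' distributions).
#'
#' @param corr A `correlation_matrix`.
#' @param p Threshold.
#' @param absolute Threshold on `|r|` instead of `r` (default `FALSE`).
#' @return An [igraph::igraph] graph with vertex attribute `name` (node ids)
#'   and graph attributes `threshold` and `absolute`.
#' @export
build_network <- function(corr, p, absolute = FALSE) {
  stopifnot(inherits(corr, "correlation_matrix"))
  r <- corr$r
  v <- if (absolute) abs(r) else r
  adj <- v > p
  if (length(corr$zero_variance_nodes)) {
    # constant series carry no signal: their nodes stay isolated at any
    # threshold (their conventional r = 0 must not create edges)
    adj[corr$zero_variance_nodes, ] <- FALSE
    adj[, corr$zero_variance_nodes] <- FALSE
  }
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(corr$node_ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = corr$node_ids)
  if (nrow(idx) > 0)
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]))
  g <- igraph::set_graph_attr(g, "threshold", p)
  igraph::set_graph_attr(g, "absolute", absolute)
}

#' Write a binary network as an edge list plus node manifest
#'
#' Writes `source<TAB>target` rows (node ids as given) and a sidecar node
#' list (one id per line) so that isolated nodes survive the round trip.
#' A GraphML copy can be written too.
#'
#' @param g An igraph graph with vertex names.
#' @param path Output edge-list path.
#' @param nodes_path Node-manifest path (default `path` + `.nodes`).
#' @param graphml_path Optional GraphML output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, nodes_path = paste0(path, ".nodes"),
                          graphml_path = NULL) {
  el <- igraph::as_edgelist(g, names = TRUE)
  utils::write.table(el, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(igraph::V(g)$name, nodes_path)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  invisible(path)
}

#' Read a binary network written by [write_network()]
#'
#' @param path Edge-list path.
#' @param nodes_path Node-manifest path (default `path` + `.nodes`).
#' @return An igraph graph including any isolated nodes from the manifest.
#' @export
read_network <- function(path, nodes_path = paste0(path, ".nodes")) {
  nodes <- readLines(nodes_path)
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    el <- utils::read.table(path, sep = "\t", colClasses = "character")
    g <- igraph::graph_from_edgelist(as.matrix(el), directed = FALSE)
    missing <- setdiff(nodes, igraph::V(g)$name)
    if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
  } else {
    g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = nodes)
  }
  g
}
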