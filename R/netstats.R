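#' Degree sequence of a network
#'
#' @param g An igraph graph.
#' @return Integer vector, one degree per node in vertex order; sums to
#'   twice the edge count.
#' @export
degree_sequence <- function(g) {
  as.integer(igraph::degree(g))
}

#' Giant (largest connected) component
#'
#' Induced subgraph on the largest connected node set; ties are broken by
#' the smallest contained vertex index, so the result is deterministic.
#'
#' @param g An igraph graph.
#' @return An igraph graph.
#' @export
giant_component <- function(g) {
  comp <- igraph::components(g)
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1) {
    # smallest vertex index contained in each tied component
    first_vertex <- vapply(big, function(cc) min(which(comp$membership == cc)),
                           integer(1))
    big <- big[which.min(first_vertex)]
  }
  igraph::induced_subgraph(g, which(comp$membership == big))
}

#' Average local clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient (closed triples /
#' possible triples at the node); nodes of degree < 2 contribute 0.
#'
#' @param g An igraph graph.
#' @return A number in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  if (igraph::vcount(g) == 0) return(0)
  igraph::transitivity(g, type = "localaverageundirected", isolates = "zero")
}

#' Average shortest-path length and diameter
#'
#' On a connected graph, computes the average shortest-path length `L` over
#' distinct node pairs and the exact diameter `D`. For graphs up to
#' `exact_limit` nodes, `L` comes from exact all-pairs BFS; above it, `L` is
#' estimated from `n_sources` uniformly sampled BFS sources (seeded,
#' standard error reported). The diameter is always exact.
#'
#' @param g A connected igraph graph (pass the output of
#'   [giant_component()]).
#' @param exact_limit Node count up to which all-pairs BFS is used
#'   (default 2000).
#' @param n_sources Number of sampled BFS sources above the limit
#'   (default 1000).
#' @param seed Seed for source sampling (default 1).
#' @return A list with `L`, `D`, `L_se` (NA when exact), `exact` (logical).
#' @export
path_metrics <- function(g, exact_limit = 2000, n_sources = 1000, seed = 1) {
  n <- igraph::vcount(g)
  if (n == 0) abort("empty graph")
  if (igraph::components(g)$no > 1)
    abort("graph is disconnected; compute metrics on giant_component(g)")
  if (n == 1) return(list(L = NaN, D = 0L, L_se = NA_real_, exact = TRUE))
  D <- as.integer(igraph::diameter(g, unconnected = FALSE))
  if (n <= exact_limit) {
    L <- igraph::mean_distance(g, unconnected = FALSE)
    return(list(L = L, D = D, L_se = NA_real_, exact = TRUE))
  }
  set.seed(seed)
  src <- sample.int(n, min(n_sources, n))
  dmat <- igraph::distances(g, v = src)
  # drop the zero self-distances: each sampled row contains exactly one
  per_source <- (rowSums(dmat)) / (n - 1)
  L <- mean(per_source)
  list(L = L, D = D, L_se = sd(per_source) / sqrt(length(src)), exact = FALSE)
}

#' Erdős–Rényi reference ensemble
#'
#' Generates `n_graphs` independent `G(n, p)` graphs with
#' `p = k_mean / (n - 1)` (expected-degree matching), computes clustering,
#' average path length and diameter on each giant component, and averages.
#' Used as the random-graph baseline when deciding whether an empirical
#' network is small-world (clustering far above the baseline at comparable
#' path length).
#'
#' @param n Node count of the reference graphs.
#' @param k_mean Target mean degree (0 < k_mean < n).
#' @param n_graphs Ensemble size (default 10).
#' @param seed Seed (default 1).
#' @param exact_limit,n_sources Passed to [path_metrics()].
#' @return A list with `C_rand`, `L_rand`, `D_rand` (ensemble means) and
#'   `per_graph` (tibble of per-graph values).
#' @export
er_reference <- function(n, k_mean, n_graphs = 10, seed = 1,
                         exact_limit = 2000, n_sources = 1000) {
  stopifnot(n >= 2, k_mean > 0, k_mean < n)
  p <- k_mean / (n - 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_graphs)
  rows <- purrr::map(seq_len(n_graphs), function(i) {
    set.seed(seeds[i])
    g <- igraph::sample_gnp(n, p)
    gc0 <- giant_component(g)
    pm <- path_metrics(gc0, exact_limit = exact_limit, n_sources = n_sources,
                       seed = seeds[i])
    tibble::tibble(graph = i, n_giant = igraph::vcount(gc0),
                   C = clustering_coefficient(gc0), L = pm$L, D = pm$D)
  })
  per_graph <- dplyr::bind_rows(rows)
  list(C_rand = mean(per_graph$C), L_rand = mean(per_graph$L),
       D_rand = mean(per_graph$D), per_graph = per_graph)
}

#' Small-world metrics report for a network
#'
#' Computes, on the giant component: node count, mean degree, average local
#' clustering `C`, average shortest-path length `L` and diameter `D`, plus
#' the same metrics averaged over a matched Erdős–Rényi ensemble
#' (`C_rand`, `L_rand`, `D_rand`). A network whose `C` greatly exceeds
#' `C_rand` while `L` stays within a small factor of `L_rand` has the
#' small-world property.
#'
#' @param g An igraph graph (the full network; the giant component is
#'   extracted internally).
#' @param n_er Ensemble size for the random reference (default 10).
#' @param seed Seed for path sampling and the ensemble (default 1).
#' @param exact_limit,n_sources Passed to [path_metrics()].
#' @return A one-row tibble of class `metrics_report` with columns
#'   `n_giant`, `k_mean`, `C`, `L`, `D`, `C_rand`, `L_rand`, `D_rand`;
#'   attribute `er_per_graph` holds the per-graph ensemble values.
#' @export
metrics_report <- function(g, n_er = 10, seed = 1,
                           exact_limit = 2000, n_sources = 1000) {
  gc0 <- giant_component(g)
  n <- igraph::vcount(gc0)
  k_mean <- mean(igraph::degree(gc0))
  C <- clustering_coefficient(gc0)
  pm <- path_metrics(gc0, exact_limit = exact_limit, n_sources = n_sources,
                     seed = seed)
  er <- er_reference(n, k_mean, n_graphs = n_er, seed = seed + 1,
                     exact_limit = exact_limit, n_sources = n_sources)
  out <- tibble::tibble(n_giant = n, k_mean = k_mean, C = C,
                        L = pm$L, D = pm$D,
                        C_rand = er$C_rand, L_rand = er$L_rand,
                        D_rand = er$D_rand)
  attr(out, "er_per_graph") <- er$per_graph
  attr(out, "L_se") <- pm$L_se
  class(out) <- c("metrics_report", class(out))
  out
}
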