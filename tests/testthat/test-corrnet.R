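make_corr <- function(n = 6, seed = 101, m = 40) {
  set.seed(seed)
  pearson_matrix(matrix(rnorm(m * n), m, n))
}

test_that("pearson matrix matches the definition and handles edge cases", {
  set.seed(100)
  x <- rnorm(30)
  mat <- cbind(a = x, b = -x, c = rnorm(30))
  cm <- pearson_matrix(mat)
  expect_equal(cm$r[1, 1], 1)
  expect_equal(cm$r[1, 2], -1)
  expect_equal(cm$r[1, 3], oracle_pearson(x, mat[, 3]), tolerance = 1e-12)
  expect_equal(cm$r, t(cm$r))
  # three 5-point series against the from-the-definition oracle
  set.seed(7)
  s5 <- matrix(rnorm(15), 5, 3)
  cm5 <- pearson_matrix(s5)
  for (i in 1:3) for (j in 1:3) if (i != j)
    expect_equal(cm5$r[i, j], oracle_pearson(s5[, i], s5[, j]),
                 tolerance = 1e-12)
  expect_error(pearson_matrix(matrix(rnorm(4), 2, 2)), "3 time points")
})

test_that("zero-variance series get correlation 0 and are flagged", {
  set.seed(102)
  mat <- cbind(rnorm(20), rep(3, 20), rnorm(20))
  cm <- pearson_matrix(mat)
  expect_equal(cm$zero_variance_nodes, 2)
  expect_equal(cm$r[2, c(1, 3)], c(0, 0))
  expect_equal(cm$r[2, 2], 1)
  # all-constant input yields an edgeless network at any threshold
  allc <- pearson_matrix(cbind(rep(1, 10), rep(2, 10), rep(5, 10)))
  g <- build_network(allc, p = -0.5)
  expect_equal(igraph::ecount(g), 0)
  expect_equal(igraph::vcount(g), 3)
})

test_that("pearson matrix is invariant under positive affine transforms", {
  set.seed(103)
  mat <- matrix(rnorm(200), 50, 4)
  cm <- pearson_matrix(mat)
  mat2 <- sweep(sweep(mat, 2, c(2, 0.5, 7, 1.3), "*"), 2, c(-5, 3, 0, 100), "+")
  cm2 <- pearson_matrix(mat2)
  expect_equal(cm$r, cm2$r, tolerance = 1e-10)
})

test_that("long tibbles pivot to the same matrix as wide input", {
  set.seed(104)
  wide <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  long <- purrr::map_dfr(colnames(wide), function(id)
    tibble::tibble(individual_id = id, t = 1:10, k = wide[, id]))
  expect_equal(pearson_matrix(long)$r, pearson_matrix(wide)$r)
})

test_that("threshold scan counts edges exactly and is monotone", {
  cm <- make_corr()
  ths <- seq(-1, 1, by = 0.05)
  sc <- scan_thresholds(cm, ths)
  for (i in seq_along(ths)) {
    brute <- 0
    for (a in 1:5) for (b in (a + 1):6)
      if (cm$r[a, b] > ths[i]) brute <- brute + 1
    expect_equal(sc$mean_degree[i], 2 * brute / 6)
  }
  expect_true(all(diff(sc$mean_degree) <= 0))
  expect_equal(sc$mean_degree[ths >= 1], rep(0, sum(ths >= 1)))
  expect_equal(sc$mean_degree[1], 5)  # p = -1 below every off-diagonal entry
})

test_that("threshold choice reproduces the scan-based closest threshold", {
  cm <- make_corr(n = 8, seed = 105)
  for (target in c(1, 3, 5.5, 7)) {
    ch <- choose_threshold(cm, target, tol = 0)
    ut <- cm$r[upper.tri(cm$r)]
    # best achievable mean degree over all distinct edge counts
    achievable <- unique(2 * (0:length(ut)) / 8)
    expect_equal(ch$achieved_k,
                 achievable[which.min(abs(achievable - target))])
    expect_equal(2 * sum(ut > ch$p) / 8, ch$achieved_k)
  }
  expect_equal(choose_threshold(cm, 7)$achieved_k, 7)  # full graph reachable
  expect_error(choose_threshold(cm, 8), "target_k")
})

test_that("network construction is strict-threshold, simple and keeps isolates", {
  cm <- make_corr(n = 6, seed = 106)
  g1 <- build_network(cm, p = 1)
  expect_equal(igraph::ecount(g1), 0)
  expect_equal(igraph::vcount(g1), 6)
  gfull <- build_network(cm, p = -1.01)
  expect_equal(igraph::ecount(gfull), 15)
  p <- 0.1
  g <- build_network(cm, p)
  adj <- adj_from_graph(g)
  for (a in 1:6) for (b in 1:6) {
    if (a == b) expect_equal(adj[a, b], 0)
    else expect_equal(adj[a, b] > 0, cm$r[a, b] > p)
  }
  expect_true(igraph::is_simple(g))
  # absolute mode picks up strong negative correlations too
  set.seed(9); x <- rnorm(30)
  cmneg <- pearson_matrix(cbind(x, -x + rnorm(30, sd = 1e-4), rnorm(30)))
  expect_equal(igraph::ecount(build_network(cmneg, 0.9)), 0)
  expect_equal(igraph::ecount(build_network(cmneg, 0.9, absolute = TRUE)), 1)
})

test_that("scan mean degree equals built-network mean degree at each threshold", {
  cm <- make_corr(n = 10, seed = 107)
  for (p in c(-0.3, 0, 0.2, 0.6)) {
    g <- build_network(cm, p)
    expect_equal(2 * igraph::ecount(g) / 10,
                 scan_thresholds(cm, c(p, 1))$mean_degree[1])
  }
})

test_that("edge-list round trip preserves isolated nodes", {
  cm <- make_corr(n = 7, seed = 108)
  g <- build_network(cm, 0.5)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "net.tsv")
  write_network(g, path, graphml_path = file.path(dir, "net.graphml"))
  back <- read_network(path)
  expect_equal(igraph::vcount(back), 7)
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  gm <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::vcount(gm), 7)
})
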