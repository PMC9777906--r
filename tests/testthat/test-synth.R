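test_that("fgn generator reproduces the closed-form autocovariance", {
  # H = 0.5 is white noise: lag-1..10 autocovariance indistinguishable from 0
  x5 <- generate_fgn(16384, 0.5, seed = 501)
  ac <- acf(x5, lag.max = 10, plot = FALSE, demean = TRUE)$acf[-1]
  se <- 1 / sqrt(length(x5))
  expect_true(all(abs(ac) < 3 * se))
  # H = 0.8: sample autocovariance at small lags matches theory (averaged
  # over replicates; single-series acf of long-memory data fluctuates)
  gamma_th <- function(k, H) 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) +
                                      abs(k - 1)^(2 * H))
  ac8 <- rowMeans(sapply(1:5, function(s)
    acf(generate_fgn(65536, 0.8, seed = 500 + s), lag.max = 8,
        plot = FALSE)$acf[, 1, 1]))
  for (k in c(1, 2, 4, 8))
    expect_equal(ac8[k + 1], gamma_th(k, 0.8), tolerance = 0.1)
  # determinism and marginal scale
  expect_identical(generate_fgn(1024, 0.7, seed = 9),
                   generate_fgn(1024, 0.7, seed = 9))
  expect_equal(sd(generate_fgn(65536, 0.6, sigma = 2, seed = 5)), 2,
               tolerance = 0.1)
  expect_error(generate_fgn(1000, 0.5), "power of two")
})

test_that("a shared group driver forces near-perfect energy correlations", {
  # noiseless bees in one group alternating burst/quiescence: kinetic energy
  # is a pure function of the common telegraph signal, so r = 1 pairwise
  det <- generate_hive(n_bees = 6, n_groups = 1, duration = 400, dt = 1,
                       burst_on_rate = 1 / 40, burst_off_rate = 1 / 40,
                       noise_sd = 0, inactive_fraction = 0,
                       dropout_fraction = 0, seed = 503)
  tracks <- resample_tracks(det, dt = 1)
  en <- kinetic_energy(tracks)
  cm <- pearson_matrix(en)
  off <- cm$r[upper.tri(cm$r)]
  expect_true(all(off > 0.95))
})

test_that("independent groups separate in correlation and in the network", {
  det <- generate_hive(n_bees = 40, n_groups = 2, duration = 900, dt = 1,
                       burst_on_rate = 1 / 120, burst_off_rate = 1 / 120,
                       inactive_fraction = 0, dropout_fraction = 0,
                       seed = 504)
  groups <- attr(det, "groups")
  en <- kinetic_energy(resample_tracks(det, dt = 1))
  cm <- pearson_matrix(en)
  grp <- groups$group[match(cm$node_ids, groups$individual_id)]
  same <- outer(grp, grp, "==") & upper.tri(cm$r)
  cross <- !outer(grp, grp, "==") & upper.tri(cm$r)
  expect_gt(mean(cm$r[same]) - mean(cm$r[cross]), 0.3)
  # a threshold between the two levels splits the network along groups
  p_mid <- (mean(cm$r[same]) + mean(cm$r[cross])) / 2
  g <- build_network(cm, p_mid)
  comp <- igraph::components(g)
  expect_gte(comp$no, 2)
  big2 <- order(comp$csize, decreasing = TRUE)[1:2]
  for (cc in big2) {
    members <- grp[comp$membership == cc]
    expect_equal(length(unique(members)), 1)
  }
})

test_that("hive generator honours fractions, arena bounds and determinism", {
  d0 <- generate_hive(n_bees = 0, seed = 1)
  expect_equal(nrow(d0), 0)
  det <- generate_hive(n_bees = 10, n_groups = 3, duration = 200, dt = 1,
                       dropout_fraction = 0.3, arena = c(100, 50), seed = 505)
  expect_true(all(det$x >= 0 & det$x <= 100))
  expect_true(all(det$y >= 0 & det$y <= 50))
  expect_equal(nrow(det), 10 * 201 * 0.7, tolerance = 0.05)
  expect_identical(det,
    generate_hive(n_bees = 10, n_groups = 3, duration = 200, dt = 1,
                  dropout_fraction = 0.3, arena = c(100, 50), seed = 505),
    ignore_attr = TRUE)
  # inactive bees never enter the burst state: lower total displacement
  det2 <- generate_hive(n_bees = 30, n_groups = 1, duration = 300, dt = 1,
                        burst_on_rate = 1 / 50, burst_off_rate = 1 / 200,
                        inactive_fraction = 0.4, dropout_fraction = 0,
                        seed = 506)
  gr <- attr(det2, "groups")
  disp <- det2 |>
    dplyr::group_by(individual_id) |>
    dplyr::summarise(d = sum(sqrt(diff(x)^2 + diff(y)^2)))
  disp$inactive <- gr$inactive[match(disp$individual_id, gr$individual_id)]
  expect_gt(mean(disp$d[!disp$inactive]), 2 * mean(disp$d[disp$inactive]))
})

test_that("dropouts reduce coverage and are repaired by interpolation", {
  det <- generate_hive(n_bees = 8, n_groups = 2, duration = 300, dt = 1,
                       dropout_fraction = 0.2, seed = 507)
  tracks <- resample_tracks(det, dt = 1)
  st <- dplyr::group_by(tracks, individual_id) |>
    dplyr::summarise(cov = mean(covered))
  expect_true(all(st$cov > 0.5))
  nodrop <- generate_hive(n_bees = 8, n_groups = 2, duration = 300, dt = 1,
                          dropout_fraction = 0, seed = 507)
  tr2 <- resample_tracks(nodrop, dt = 1)
  expect_true(all(tr2$covered))
})

test_that("fixture suite is byte-stable and hand-checkable", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- fixture_suite(d1, seed = 1)
  p2 <- fixture_suite(d2, seed = 1)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  obj <- attr(p1, "objects")
  padded <- c(obj$series3, rep(2, 5))
  expect_equal(obj$series3 - mean(padded), c(-1, 1, 0))  # deviations
  expect_equal(cumulative_deviations(padded)[1:3], c(-1, 0, 0))
  # disjoint 5-clique + 3-clique: giant component is the 5-clique
  cl <- igraph::graph_from_edgelist(as.matrix(utils::read.table(p1[["cliques"]])),
                                    directed = FALSE)
  expect_equal(igraph::vcount(giant_component(cl)), 5)
})
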