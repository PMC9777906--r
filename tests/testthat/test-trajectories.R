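test_that("resampling interpolates linearly onto the grid", {
  det <- tibble::tibble(individual_id = "a", timestamp = c(0, 2),
                        x = c(0, 4), y = c(1, 1))
  tr <- resample_tracks(det, dt = 1)
  expect_equal(tr$x, c(0, 2, 4))
  expect_equal(tr$y, c(1, 1, 1))
  expect_true(all(tr$covered))

  # detections already on the grid come back unchanged
  det2 <- tibble::tibble(individual_id = "b", timestamp = 0:5,
                         x = cumsum(runif(6)), y = cumsum(runif(6)))
  tr2 <- resample_tracks(det2, dt = 1)
  expect_equal(tr2$x, det2$x)
  expect_equal(tr2$y, det2$y)
})

test_that("irregular detections match an independent interpolation oracle", {
  set.seed(42)
  ts <- sort(runif(50, 0, 100))
  xs <- cumsum(rnorm(50)); ys <- cumsum(rnorm(50))
  det <- tibble::tibble(individual_id = "z", timestamp = ts, x = xs, y = ys)
  tr <- resample_tracks(det, dt = 2, t_start = 0, t_end = 100)
  grid <- seq(0, 100, by = 2)
  expect_equal(tr$t, grid)
  expect_equal(tr$x, oracle_interp(ts, xs, grid), tolerance = 1e-12)
  expect_equal(tr$y, oracle_interp(ts, ys, grid), tolerance = 1e-12)
  expect_equal(tr$covered, grid >= ts[1] & grid <= ts[50])
})

test_that("duplicate timestamps keep the first detection; sparse tracks drop", {
  det <- tibble::tibble(individual_id = c("a", "a", "a", "lone"),
                        timestamp = c(0, 0, 2, 1),
                        x = c(5, 99, 7, 0), y = c(0, 99, 0, 0))
  tr <- resample_tracks(det, dt = 1, t_start = 0, t_end = 2)
  expect_equal(attr(tr, "dropped"), "lone")
  expect_equal(tr$x[tr$t == 0], 5)  # first duplicate wins
})

test_that("inactivity filter applies both predicates exactly", {
  set.seed(1)
  # 20 constructed two-point tracks with known coverage and displacement
  dets <- purrr::map_dfr(1:20, function(i) {
    span <- runif(1, 1, 10)  # observed span inside a 10 s grid window
    disp <- runif(1, 0, 5)
    tibble::tibble(individual_id = sprintf("t%02d", i),
                   timestamp = c(0, span), x = c(0, disp), y = 0)
  })
  tr <- resample_tracks(dets, dt = 1, t_start = 0, t_end = 10)
  st <- dplyr::group_by(tr, individual_id) |>
    dplyr::summarise(cov = mean(covered),
                     disp = sum(sqrt(diff(x)^2 + diff(y)^2)))
  for (mc in c(0, 0.5, 0.9)) for (md in c(0, 1, 3)) {
    kept <- unique(filter_inactive(tr, mc, md)$individual_id)
    expect_setequal(kept, st$individual_id[st$cov >= mc & st$disp >= md])
  }
  # monotone: raising either threshold never adds a track
  k1 <- unique(filter_inactive(tr, 0.3, 1)$individual_id)
  k2 <- unique(filter_inactive(tr, 0.6, 1)$individual_id)
  k3 <- unique(filter_inactive(tr, 0.3, 2)$individual_id)
  expect_true(all(k2 %in% k1))
  expect_true(all(k3 %in% k1))
})

test_that("kinetic energy is squared displacement per interval", {
  tr <- tibble::tibble(individual_id = "a", t = 0:1,
                       x = c(0, 3), y = c(0, 4), covered = TRUE)
  expect_equal(kinetic_energy(tr)$k, 25)

  still <- tibble::tibble(individual_id = "s", t = 0:9, x = 2, y = 7,
                          covered = TRUE)
  expect_equal(kinetic_energy(still)$k, rep(0, 9))

  set.seed(3)
  rnd <- tibble::tibble(individual_id = "r", t = 0:9,
                        x = rnorm(10), y = rnorm(10), covered = TRUE)
  ke <- kinetic_energy(rnd)
  expect_equal(ke$k, diff(rnd$x)^2 + diff(rnd$y)^2)
  expect_equal(nrow(ke), 9)
  expect_error(kinetic_energy(tr[1, ]), "at least 2")
})

test_that("kinetic energy is invariant under rigid motions", {
  set.seed(4)
  tr <- tibble::tibble(individual_id = "a", t = 0:19,
                       x = cumsum(rnorm(20)), y = cumsum(rnorm(20)),
                       covered = TRUE)
  theta <- 0.83
  rot <- tr
  rot$x <- cos(theta) * tr$x - sin(theta) * tr$y + 12.5
  rot$y <- sin(theta) * tr$x + cos(theta) * tr$y - 3.1
  expect_equal(kinetic_energy(rot)$k, kinetic_energy(tr)$k, tolerance = 1e-10)
})

test_that("hive activity averages elementwise and respects the grid", {
  set.seed(5)
  e3 <- purrr::map_dfr(1:3, function(i)
    tibble::tibble(individual_id = paste0("b", i), t = 0:9, k = runif(10)))
  act <- hive_activity(e3)
  man <- tapply(e3$k, e3$t, mean)
  expect_equal(act$value, as.numeric(man))
  expect_equal(attr(act, "n_individuals"), 3)
  # n copies of one series give back that series (mean mode)
  one <- e3[e3$individual_id == "b1", ]
  copies <- dplyr::bind_rows(one,
    dplyr::mutate(one, individual_id = "b1copy"))
  expect_equal(hive_activity(copies)$value, one$k)
  # sum mode is n times the mean
  expect_equal(hive_activity(e3, "sum")$value, 3 * act$value)
  # mismatched grids refuse
  bad <- dplyr::bind_rows(one, tibble::tibble(individual_id = "x",
                                              t = 5:14, k = 1))
  expect_error(hive_activity(bad), "grid")
})

test_that("window partition is half-open and boundary samples go once to the later window", {
  s <- tibble::tibble(t = 0:9, value = 1:10)
  full <- partition_windows(s, tibble::tibble(label = "all", start = 0, end = 10))
  expect_equal(full$value, s$value)
  none <- partition_windows(s, tibble::tibble(label = "off", start = 100, end = 200))
  expect_equal(nrow(none), 0)
  two <- partition_windows(s, tibble::tibble(label = c("w1", "w2"),
                                             start = c(0, 5), end = c(5, 10)))
  expect_equal(nrow(two), nrow(s))
  expect_equal(sum(two$t == 5), 1)
  expect_equal(two$window[two$t == 5], "w2")
  expect_error(partition_windows(s, tibble::tibble(label = c("a", "b"),
                                                   start = c(0, 3), end = c(5, 8))),
               "overlap")
})

test_that("detection files round-trip through read/write", {
  det <- generate_hive(n_bees = 5, n_groups = 2, duration = 30, dt = 1,
                       dropout_fraction = 0, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(det, path)
  back <- read_detections(path)
  expect_equal(back$individual_id, det$individual_id)
  expect_equal(back$x, det$x, tolerance = 1e-12)
  # tab dialect is auto-detected
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual_id\ttimestamp\tx\ty", "a\t0\t1\t2", "a\t1\t2\t3"), tsv)
  expect_equal(read_detections(tsv)$x, c(1, 2))
})
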