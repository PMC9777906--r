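#' Fractional Gaussian noise via circulant embedding
#'
#' Generates a stationary Gaussian series whose autocovariance is the exact
#' fractional-Gaussian-noise form
#' \eqn{\gamma(k) = (\sigma^2/2)(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H})}
#' using the Davies-Harte circulant-embedding construction (FFT of the
#' embedded covariance; exact for any length at which the embedding is
#' non-negative definite, which holds for all `0 < H < 1` at power-of-two
#' lengths). At `H = 0.5` this is white noise. Used as the ground-truth
#' input for validating [estimate_hurst()].
#'
#' @param n Series length; a power of two, at least 256.
#' @param H Target Hurst exponent in (0, 1).
#' @param sigma Marginal standard deviation (default 1).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' x <- generate_fgn(1024, H = 0.8, seed = 1)
#' estimate_hurst(x)
generate_fgn <- function(n, H, sigma = 1, seed = 1) {
  stopifnot(H > 0, H < 1, sigma > 0)
  if (n < 256 || bitwAnd(n, n - 1L) != 0)
    abort("n must be a power of two >= 256")
  k <- 0:n
  gamma_k <- (sigma^2 / 2) *
    (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  m <- 2L * n
  c_row <- c(gamma_k[1:(n + 1)], gamma_k[n:2])  # circulant first row, length 2n
  lambda <- Re(fft(c_row))
  if (any(lambda < -1e-8 * max(lambda)))
    abort("circulant embedding not non-negative definite for these parameters")
  lambda[lambda < 0] <- 0
  set.seed(seed)
  z1 <- rnorm(m); z2 <- rnorm(m)
  w <- complex(length.out = m)
  w[1] <- sqrt(lambda[1] / m) * z1[1]
  w[n + 1] <- sqrt(lambda[n + 1] / m) * z1[n + 1]
  j <- 2:n
  w[j] <- sqrt(lambda[j] / (2 * m)) * complex(real = z1[j], imaginary = z2[j])
  w[m + 2 - j] <- Conj(w[j])
  Re(fft(w))[1:n]
}

#' Synthetic hive-like trajectory data
#'
#' Generates raw detections emulating the shape of barcode-tracked colony
#' data: `n_bees` individuals moving in a bounded rectangular arena, sampled
#' at interval `dt` over `duration` seconds. Each of `n_groups` groups
#' carries a latent two-state (burst/quiescent) continuous-time Markov
#' activity signal; a bee's per-step speed is
#' `rest_speed + (active_speed - rest_speed) * state + N(0, noise_sd)`,
#' its heading follows a bounded random walk, and motion reflects off the
#' arena walls. A seeded fraction of bees is inactive (rest speed only,
#' ignoring the group signal) and a seeded fraction of detection rows is
#' deleted to exercise interpolation and coverage filtering downstream.
#'
#' This generator deliberately implements a *non-critical* system with
#' controllable correlation structure: within-group energy series share a
#' common driver (high pairwise correlation), across groups they are
#' independent. It provides known ground truth for the pipeline; the Ising
#' simulator supplies the genuinely critical test signal.
#'
#' @param n_bees Number of individuals (default 1200, the typical colony
#'   size of barcode-tracking studies).
#' @param n_groups Number of independent activity groups (default 6).
#' @param duration Recording length in seconds (default 7200).
#' @param dt Sampling interval in seconds (default 1).
#' @param burst_on_rate,burst_off_rate Per-second switching rates of the
#'   latent activity signal (defaults 1/300 and 1/300: bursts and quiescent
#'   spells of ~5 min on average).
#' @param active_speed,rest_speed Mean step speed (position units per
#'   interval) in the active/quiescent state (defaults 4 and 0.2).
#' @param noise_sd Per-bee speed noise, position units (default 0.5).
#' @param inactive_fraction Fraction of bees that never activate
#'   (default 0.05).
#' @param dropout_fraction Fraction of detection rows deleted (default 0.1).
#' @param arena Arena width and height, position units
#'   (default `c(500, 300)`).
#' @param seed Integer seed; the output is a pure function of the
#'   configuration and seed.
#' @return A detections tibble (`individual_id`, `timestamp`, `x`, `y`),
#'   time-ordered within each individual, with attributes `groups`
#'   (tibble id, group, inactive) and `config`.
#' @export
generate_hive <- function(n_bees = 1200, n_groups = 6, duration = 7200,
                          dt = 1, burst_on_rate = 1 / 300,
                          burst_off_rate = 1 / 300, active_speed = 4,
                          rest_speed = 0.2, noise_sd = 0.5,
                          inactive_fraction = 0.05, dropout_fraction = 0.1,
                          arena = c(500, 300), seed = 1) {
  stopifnot(n_bees == 0 || n_groups <= n_bees,
            burst_on_rate > 0, burst_off_rate > 0,
            inactive_fraction >= 0, inactive_fraction <= 1,
            dropout_fraction >= 0, dropout_fraction <= 1)
  config <- as.list(environment())
  if (n_bees == 0) {
    out <- tibble::tibble(individual_id = character(), timestamp = numeric(),
                          x = numeric(), y = numeric())
    attr(out, "config") <- config
    return(out)
  }
  set.seed(seed)
  n_steps <- floor(duration / dt)
  times <- (0:n_steps) * dt

  # latent two-state telegraph signal per group, sampled on the grid
  p_on <- 1 - exp(-burst_on_rate * dt)   # quiescent -> burst
  p_off <- 1 - exp(-burst_off_rate * dt) # burst -> quiescent
  group_state <- matrix(0L, n_steps + 1, n_groups)
  group_state[1, ] <- stats::rbinom(n_groups, 1,
                                    burst_on_rate / (burst_on_rate + burst_off_rate))
  for (t in 2:(n_steps + 1)) {
    u <- runif(n_groups)
    prev <- group_state[t - 1, ]
    group_state[t, ] <- ifelse(prev == 1L,
                               ifelse(u < p_off, 0L, 1L),
                               ifelse(u < p_on, 1L, 0L))
  }

  ids <- sprintf("bee%04d", seq_len(n_bees))
  group_of <- sample(rep_len(seq_len(n_groups), n_bees))
  inactive <- runif(n_bees) < inactive_fraction

  per_bee <- purrr::map(seq_len(n_bees), function(b) {
    st <- if (inactive[b]) rep(0L, n_steps + 1) else group_state[, group_of[b]]
    speed <- rest_speed + (active_speed - rest_speed) * st[-1] +
      rnorm(n_steps, sd = noise_sd)
    speed[speed < 0] <- 0
    heading <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n_steps, sd = 0.5)))
    dx <- speed * cos(heading[-1])
    dy <- speed * sin(heading[-1])
    x <- reflect_path(cumsum(c(runif(1, 0, arena[1]), dx)), arena[1])
    y <- reflect_path(cumsum(c(runif(1, 0, arena[2]), dy)), arena[2])
    tibble::tibble(individual_id = ids[b], timestamp = times, x = x, y = y)
  })
  out <- dplyr::bind_rows(per_bee)
  if (dropout_fraction > 0) {
    keep <- runif(nrow(out)) >= dropout_fraction
    out <- out[keep, , drop = FALSE]
  }
  attr(out, "groups") <- tibble::tibble(individual_id = ids,
                                        group = group_of, inactive = inactive)
  attr(out, "config") <- config
  out
}

# fold an unbounded coordinate path into [0, w] by reflection
reflect_path <- function(z, w) {
  z <- z %% (2 * w)
  ifelse(z > w, 2 * w - z, z)
}

#' Deterministic fixture bundle for the analysis surface
#'
#' Writes a small set of hand-checkable plain-text fixtures — a toy
#' two-detection track, a 6-node correlation matrix, a disjoint 5-clique +
#' 3-clique edge list, the 3-element series `(1, 3, 2)` with hand-checkable
#' deviations `(-1, 1, 0)` around its mean, and a tiny hive detection file —
#' byte-stable for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed (default 1).
#' @return Named character vector of the file paths, invisibly; the
#'   in-memory objects are returned in the `objects` attribute.
#' @export
fixture_suite <- function(dir = tempfile("fixtures"), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    toy_track = file.path(dir, "toy_track.csv"),
    corr6 = file.path(dir, "corr6.csv"),
    cliques = file.path(dir, "cliques.tsv"),
    series3 = file.path(dir, "series3.csv"),
    hive = file.path(dir, "hive_small.csv")
  )
  toy <- tibble::tibble(individual_id = c("a", "a", "b", "b", "b"),
                        timestamp = c(0, 2, 0, 1, 2),
                        x = c(0, 4, 0, 1, 1), y = c(0, 0, 0, 0, 2))
  write_detections(toy, paths["toy_track"])
  set.seed(seed)
  r6 <- matrix(round(runif(36, -0.5, 0.9), 3), 6, 6)
  r6 <- (r6 + t(r6)) / 2
  diag(r6) <- 1
  utils::write.csv(as.data.frame(r6), paths["corr6"], row.names = FALSE)
  cl <- rbind(t(utils::combn(1:5, 2)), t(utils::combn(6:8, 2)))
  utils::write.table(cl, paths["cliques"], sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  utils::write.csv(data.frame(t = 1:3, value = c(1, 3, 2)), paths["series3"],
                   row.names = FALSE, quote = FALSE)
  hive <- generate_hive(n_bees = 12, n_groups = 2, duration = 120, dt = 1,
                        dropout_fraction = 0.05, seed = seed)
  write_detections(hive, paths["hive"])
  attr(paths, "objects") <- list(toy_track = toy, corr6 = r6, cliques = cl,
                                 series3 = c(1, 3, 2), hive = hive)
  invisible(paths)
}
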