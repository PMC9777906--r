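#' Exact critical temperature of the 2D Ising model
#'
#' Returns the analytic (thermodynamic-limit) critical temperature of the
#' two-dimensional zero-field Ising model with coupling `J = 1` and
#' `k_B = 1`: \eqn{T_c = 2 / \log(1 + \sqrt{2}) \approx 2.2692}. Finite-size
#' simulations in this package follow the common practice of using the
#' rounded value 2.3 as the "critical" temperature of desk-scale lattices.
#'
#' @return A single numeric value.
#' @export
#' @examples
#' ising_critical_temperature()
ising_critical_temperature <- function() {
  2 / log(1 + sqrt(2))
}

new_lattice <- function(spins, L) {
  stopifnot(length(spins) == L * L, all(spins %in% c(-1L, 1L)))
  structure(list(spins = as.integer(spins), L = as.integer(L)),
            class = "ising_lattice")
}

#' Create an Ising lattice state
#'
#' Builds an `L x L` toroidal lattice of spins, either from supplied values
#' or initialised uniformly at random ("hot" start).
#'
#' @param L Lattice side length (integer, >= 2).
#' @param spins Optional integer vector of length `L*L` with values -1/+1,
#'   in row-major site order. If `NULL`, spins are drawn uniformly at random
#'   (seed the session RNG for reproducibility).
#' @return An `ising_lattice` object: a list with elements `spins`
#'   (integer vector, row-major) and `L`.
#' @export
#' @examples
#' set.seed(1)
#' lat <- ising_lattice(4)
#' magnetization(lat)
ising_lattice <- function(L, spins = NULL) {
  L <- as.integer(L)
  if (L < 2) abort("L must be at least 2")
  if (is.null(spins)) {
    spins <- sample(c(-1L, 1L), L * L, replace = TRUE)
  }
  if (!all(spins %in% c(-1L, 1L))) abort("spins must be -1 or +1")
  new_lattice(as.integer(spins), L)
}

#' @export
print.ising_lattice <- function(x, ...) {
  cat(sprintf("<ising_lattice> %d x %d torus, M = %.4f\n",
              x$L, x$L, magnetization(x)))
  invisible(x)
}

#' Magnetization (order parameter) of a lattice state
#'
#' The mean spin \eqn{M = N^{-1} \sum_i s_i}, in `[-1, 1]`.
#'
#' @param state An `ising_lattice`.
#' @return A single numeric value.
#' @export
magnetization <- function(state) {
  stopifnot(inherits(state, "ising_lattice"))
  mean(state$spins)
}

#' Configuration energy of a lattice state
#'
#' Zero-field nearest-neighbour Hamiltonian on the torus with `J = 1`,
#' counting each of the `2N` bonds once:
#' \eqn{E = -J \sum_{\langle i j \rangle} s_i s_j}. Under this pair-once
#' convention the all-aligned ground state has `E = -2*N`.
#'
#' @param state An `ising_lattice`.
#' @return A single numeric value (integer-valued).
#' @export
#' @examples
#' lat <- ising_lattice(4, spins = rep(1L, 16))
#' lattice_energy(lat)  # -32
lattice_energy <- function(state) {
  stopifnot(inherits(state, "ising_lattice"))
  L <- state$L
  s <- matrix(state$spins, L, L, byrow = TRUE)
  right <- s[, c(2:L, 1), drop = FALSE]
  down <- s[c(2:L, 1), , drop = FALSE]
  -sum(s * right) - sum(s * down)
}

#' One Metropolis sweep over the lattice
#'
#' Performs `n_sweeps` Metropolis sweeps, each consisting of `N = L*L`
#' single-site update attempts at uniformly random sites; a proposed flip of
#' spin `i` is accepted with probability `min(1, exp(-dE/T))` where
#' `dE = 2 * s_i * sum(neighbours)`. The input state is not modified.
#'
#' @param state An `ising_lattice`.
#' @param T Temperature (> 0), in units of `J/k_B`.
#' @param n_sweeps Number of sweeps (default 1).
#' @return The updated `ising_lattice`, with attribute `delta_energy`
#'   holding the total accumulated energy change (exact integer bookkeeping).
#' @export
metropolis_step <- function(state, T, n_sweeps = 1L) {
  stopifnot(inherits(state, "ising_lattice"), T > 0)
  out <- ising_sweep_cpp(state$spins, state$L, T, as.integer(n_sweeps))
  res <- new_lattice(out$spins, state$L)
  attr(res, "delta_energy") <- out$delta_energy
  res
}

#' Simulate the 2D Ising model with Metropolis dynamics
#'
#' Runs the standard thermalize-then-record protocol on an `L x L` torus:
#' spins are initialised uniformly at random (hot start), `n_therm` sweeps
#' are applied without recording, then `n_record` consecutive configurations,
#' each separated by exactly one sweep, are stored together with their
#' magnetization.
#'
#' @param L Lattice side length.
#' @param T Temperature in units of `J/k_B` (`J = 1`). Typical study points
#'   are 2.0 (ordered), 2.3 (near-critical for finite lattices) and 3.0
#'   (disordered).
#' @param n_therm Thermalization sweeps discarded before recording
#'   (default 10000).
#' @param n_record Number of recorded configurations (default 2000).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param init `"hot"` (spins uniformly at random; default), `"cold"`
#'   (all spins up), or `"auto"` (cold below the exact critical temperature,
#'   hot at or above it). Below \eqn{T_c} a hot start frequently quenches
#'   into long-lived striped domain states that Metropolis dynamics cannot
#'   anneal within any practical thermalization budget, leaving the system
#'   far from the ordered equilibrium ("quiescent") phase; a cold start
#'   reaches it directly. Above \eqn{T_c} the choice is immaterial after
#'   thermalization.
#' @return An `ising_run` object: list with `config` (list of the call
#'   parameters), `configurations` (integer matrix, `n_record` rows x `N`
#'   columns, row-major site order), and `magnetization` (tibble with
#'   columns `step`, `M`).
#' @export
#' @examples
#' run <- simulate_ising(L = 8, T = 2.3, n_therm = 200, n_record = 50, seed = 1)
#' run
simulate_ising <- function(L, T, n_therm = 10000L, n_record = 2000L, seed = 1L,
                           init = c("hot", "cold", "auto")) {
  stopifnot(L >= 2, T > 0, n_therm >= 0, n_record >= 0)
  init <- match.arg(init)
  if (init == "auto")
    init <- if (T < ising_critical_temperature()) "cold" else "hot"
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  spins0 <- if (init == "cold") rep(1L, L * L) else
    sample(c(-1L, 1L), L * L, replace = TRUE)
  rec <- ising_run_cpp(spins0, as.integer(L), T,
                       as.integer(n_therm), as.integer(n_record))
  M <- if (n_record > 0) rowMeans(rec) else numeric(0)
  structure(
    list(
      config = list(L = as.integer(L), T = T, n_therm = as.integer(n_therm),
                    n_record = as.integer(n_record), seed = as.integer(seed),
                    init = init),
      configurations = rec,
      magnetization = tibble::tibble(step = seq_len(n_record), M = M)
    ),
    class = "ising_run"
  )
}

#' @export
print.ising_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ising_run> L = %d (N = %d), T = %.3f, %d therm + %d recorded sweeps, seed %d\n",
    cfg$L, cfg$L^2, cfg$T, cfg$n_therm, cfg$n_record, cfg$seed))
  if (cfg$n_record > 0)
    cat(sprintf("  mean M = %.4f, mean |M| = %.4f\n",
                mean(x$magnetization$M), mean(abs(x$magnetization$M))))
  invisible(x)
}

#' Per-site spin time-series of a recorded run
#'
#' Extracts the matrix of site time-series from an `ising_run`: one column
#' per lattice site (row-major order, stable), one row per recorded sweep.
#' This is the node-series input for [pearson_matrix()].
#'
#' @param run An `ising_run` with `n_record >= 1`.
#' @return An integer matrix, `n_record` x `N`, with column names `s1..sN`.
#' @export
site_series <- function(run) {
  stopifnot(inherits(run, "ising_run"))
  if (run$config$n_record < 1) abort("run has no recorded configurations")
  m <- run$configurations
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}
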