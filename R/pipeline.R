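# End-to-end orchestration: Ising-side and trajectory-side analyses with
# derived per-stage seeds, JSON reports and a run manifest.

derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Default configuration for the Ising-side analysis
#'
#' The study conditions: an `L = 100` torus (`N = 10000` sites) at
#' temperatures 2.0 (ordered), 2.3 (near-critical) and 3.0 (disordered),
#' 10000 thermalization sweeps, 2000 recorded sweeps, networks matched at
#' mean degree 110.
#'
#' @param L,temperatures,n_therm,n_record,target_k,n_er Override any field.
#' @return A named list.
#' @export
ising_pipeline_config <- function(L = 100, temperatures = c(2.0, 2.3, 3.0),
                                  n_therm = 10000, n_record = 2000,
                                  target_k = 110, n_er = 10) {
  list(L = L, temperatures = temperatures, n_therm = n_therm,
       n_record = n_record, target_k = target_k, n_er = n_er)
}

#' Run the full Ising-side analysis
#'
#' For each configured temperature: simulate the lattice, build the Pearson
#' correlation matrix of site time-series, threshold it to the target mean
#' degree, fit heavy-tailed degree distributions, compute small-world
#' metrics against an Erdős–Rényi reference, and estimate the Hurst exponent
#' of the magnetization series. All randomness derives from `seed` via
#' per-stage seeds, so each stage is independently reproducible.
#'
#' @param config List from [ising_pipeline_config()].
#' @param seed Top-level integer seed (default 1).
#' @param out_dir Optional directory for JSON reports and series files.
#' @param compute_er Compute the Erdős–Rényi reference ensemble (default
#'   TRUE; the ensemble dominates runtime for large lattices).
#' @param quiet Suppress progress messages (default FALSE).
#' @return A list with one entry per temperature (each holding
#'   `threshold`, `degree_fit`, `metrics`, `hurst`, `n_zero_variance`) plus
#'   `summary` (tibble over temperatures) and `manifest`.
#' @export
run_ising_pipeline <- function(config = ising_pipeline_config(), seed = 1,
                               out_dir = NULL, compute_er = TRUE,
                               quiet = FALSE) {
  if (config$n_record < 3)
    abort("n_record must be at least 3 to correlate site series")
  t_start <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  reports <- list()
  for (Tv in config$temperatures) {
    stage_seed <- derive_seed(seed, paste0("ising_T", Tv))
    say("simulating L=%d at T=%.2f (seed %d)", config$L, Tv, stage_seed)
    run <- simulate_ising(config$L, Tv, config$n_therm, config$n_record,
                          seed = stage_seed, init = "auto")
    say("correlating %d site series", config$L^2)
    corr <- pearson_matrix(site_series(run))
    thr <- choose_threshold(corr, config$target_k)
    g <- build_network(corr, thr$p)
    fit <- fit_degree_distribution(degree_sequence(g))
    say("threshold p=%.4f (k=%.1f); best family %s", thr$p, thr$achieved_k,
        fit$best_family)
    gc0 <- giant_component(g)
    pm <- path_metrics(gc0, seed = derive_seed(seed, paste0("paths_T", Tv)))
    metrics <- tibble::tibble(
      n_giant = igraph::vcount(gc0),
      k_mean = mean(igraph::degree(gc0)),
      C = clustering_coefficient(gc0), L = pm$L, D = pm$D)
    if (compute_er) {
      er <- er_reference(metrics$n_giant, metrics$k_mean,
                         n_graphs = config$n_er,
                         seed = derive_seed(seed, paste0("er_T", Tv)))
      metrics$C_rand <- er$C_rand; metrics$L_rand <- er$L_rand
      metrics$D_rand <- er$D_rand
    }
    hu <- estimate_hurst(run$magnetization$M, min_length = 64)
    reports[[paste0("T", Tv)]] <- list(
      temperature = Tv, threshold = thr, degree_fit = fit, metrics = metrics,
      hurst = hu, n_zero_variance = length(corr$zero_variance_nodes),
      seed = stage_seed)
    rm(run, corr, g, gc0); gc(verbose = FALSE)
  }
  summary <- purrr::map_dfr(reports, function(r) {
    dplyr::bind_cols(
      tibble::tibble(temperature = r$temperature,
                     threshold = r$threshold$p,
                     best_family = r$degree_fit$best_family,
                     alpha = r$degree_fit$fits$truncated_power_law$alpha,
                     xmin = r$degree_fit$xmin,
                     H = r$hurst$H),
      r$metrics)
  })
  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("hivecrit")),
                   elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  out <- c(reports, list(summary = summary, manifest = manifest))
  if (!is.null(out_dir)) write_pipeline_reports(out, out_dir)
  out
}

#' Run the trajectory-side analysis
#'
#' Resamples raw detections to a uniform grid, filters poorly tracked or
#' immobile individuals, converts movement to kinetic energy, and then per
#' time window: builds the Pearson correlation network at the target mean
#' degree, fits degree distributions and computes small-world metrics.
#' The colony-level activity series gets a Hurst estimate plus shuffle
#' control.
#'
#' @param detections Detections tibble (or a file path readable by
#'   [read_detections()]).
#' @param dt Resampling interval, seconds (default 1).
#' @param min_coverage,min_total_displacement Passed to
#'   [filter_inactive()].
#' @param target_k Target mean degree for network matching (default 110).
#' @param windows Optional window tibble for [partition_windows()]; default
#'   a single window spanning the data.
#' @param n_er Erdős–Rényi ensemble size (default 10).
#' @param seed Top-level integer seed (default 1).
#' @param out_dir Optional directory for JSON reports.
#' @return A list with `windows` (per-window network reports), `hurst`,
#'   `hurst_shuffled`, `track_summary` and `manifest`.
#' @export
run_trajectory_pipeline <- function(detections, dt = 1, min_coverage = 0.8,
                                    min_total_displacement = 0,
                                    target_k = 110, windows = NULL,
                                    n_er = 10, seed = 1, out_dir = NULL) {
  if (is.character(detections)) detections <- read_detections(detections)
  tracks <- resample_tracks(detections, dt = dt)
  tracks <- filter_inactive(tracks, min_coverage, min_total_displacement)
  if (nrow(tracks) == 0) abort("no tracks survived the inactivity filters")
  energies <- kinetic_energy(tracks)
  if (is.null(windows)) {
    windows <- tibble::tibble(label = "all", start = min(energies$t),
                              end = max(energies$t) + dt)
  }
  segs <- partition_windows(energies, windows)
  window_reports <- purrr::map(unique(segs$window), function(w) {
    seg <- segs[segs$window == w, , drop = FALSE]
    corr <- pearson_matrix(seg)
    thr <- choose_threshold(corr, min(target_k, length(corr$node_ids) - 1))
    g <- build_network(corr, thr$p)
    fit <- tryCatch(fit_degree_distribution(degree_sequence(g)),
                    error = function(e) NULL)
    metrics <- metrics_report(g, n_er = n_er,
                              seed = derive_seed(seed, paste0("win_", w)))
    list(window = w, threshold = thr, degree_fit = fit, metrics = metrics,
         n_zero_variance = length(corr$zero_variance_nodes))
  })
  names(window_reports) <- unique(segs$window)
  activity <- hive_activity(energies)
  hu <- estimate_hurst(activity$value)
  hu_sh <- shuffle_control(activity$value, seed = derive_seed(seed, "shuffle"))
  out <- list(
    windows = window_reports, hurst = hu, hurst_shuffled = hu_sh,
    activity = activity, track_summary = track_stats(tracks),
    manifest = list(dt = dt, min_coverage = min_coverage,
                    min_total_displacement = min_total_displacement,
                    target_k = target_k, seed = seed,
                    n_tracks = length(unique(tracks$individual_id)),
                    package_version = as.character(utils::packageVersion("hivecrit"))))
  if (!is.null(out_dir)) write_pipeline_reports(out, out_dir)
  out
}

serialize_report <- function(x) {
  if (inherits(x, "hurst_fit") || inherits(x, "degree_fit_set"))
    return(unclass(x))
  if (inherits(x, "igraph")) return(NULL)
  if (is.list(x) && !is.data.frame(x)) return(purrr::map(x, serialize_report))
  x
}

write_pipeline_reports <- function(reports, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(serialize_report(reports),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' Write a scalar time-series with JSON sidecar metadata
#'
#' @param series Tibble with columns `t`, `value` (e.g. [hive_activity()]).
#' @param path Output CSV path; metadata goes to `path` + `.json`.
#' @param meta Named list of extra metadata fields.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, meta = list()) {
  utils::write.csv(series[, c("t", "value")], path, row.names = FALSE,
                   quote = FALSE)
  meta <- c(meta, list(
    n = nrow(series),
    n_individuals = attr(series, "n_individuals"),
    aggregate = attr(series, "aggregate")))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scalar time-series written by [write_series()]
#'
#' @param path CSV path with columns `t,value`.
#' @return A tibble with columns `t`, `value`.
#' @export
read_series <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
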