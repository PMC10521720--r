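#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected
#' so typos fail before any stage runs; every default is echoed to the log
#' at run time.
#'
#' @param config Named list (e.g. parsed from YAML with
#'   [yaml::read_yaml()]) overriding the defaults; see Details.
#' @details Recognized keys: `seed`; `timecourse` (`days`, `n_per_day`),
#'   `kinetics` (`f_max`, `k`, `shape`, `heterogeneity_sd0`,
#'   `heterogeneity_decay`), `simulation` (`grid_min`, `grid_max`,
#'   `grid_step`, `snr`, `spike_rate`), `classify` (`k_sd`,
#'   `min_shift_cm1`, `min_snr`), `steady_state` (`tol`), `binning`
#'   (`genomes` — a list of [genome_spec()] argument lists —, `min_len_bp`,
#'   `method`, `min_samples`, `k`), `out_dir`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- list(
    seed = 1,
    out_dir = NULL,
    timecourse = list(days = 0:5, n_per_day = 45),
    kinetics = list(f_max = 1.0, k = log(2)^0.4, shape = 2.5,
                    heterogeneity_sd0 = 0.15, heterogeneity_decay = 0.3),
    simulation = list(grid_min = 600, grid_max = 1800, grid_step = 1,
                      snr = 20, spike_rate = 0.1),
    classify = list(k_sd = 3, min_shift_cm1 = 4, min_snr = 5),
    steady_state = list(tol = 2),
    binning = list(
      genomes = list(
        list(name = "sar11_like", gc = 0.293, n_contigs = 25,
             min_bp = 5000, max_bp = 10000),
        list(name = "alteromonas_like", gc = 0.60, n_contigs = 25,
             min_bp = 5000, max_bp = 10000)),
      min_len_bp = 2000, method = "dbscan", min_samples = 5, k = 2))
  merged <- defaults
  for (key in names(config)) {
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", key)
    if (is.list(defaults[[key]])) {
      sub <- config[[key]]
      for (k2 in names(sub)) {
        if (!k2 %in% names(defaults[[key]]))
          stop(sprintf("unknown configuration key: %s$%s", key, k2))
        merged[[key]][[k2]] <- sub[[k2]]
      }
    } else merged[[key]] <- config[[key]]
  }
  structure(merged, class = "pipeline_config")
}

log_msg <- function(...) message(sprintf("[ramansip] %s", sprintf(...)))

#' Run the end-to-end in-silico Raman-SIP pipeline
#'
#' Chain: simulate a labeling time course -> preprocess spectra -> build
#' the 12C reference from day 0 -> fit bands and classify every cell with
#' the two-band criterion -> per-day summaries and steady-state detection
#' -> simulate contigs and bin them by tetranucleotide composition.
#' Deterministic given the configuration (all randomness is seeded from
#' `config$seed`). When `out_dir` is set, each stage writes its artifacts
#' (TSVs, JSON manifest) as it completes, so a partial failure leaves
#' completed stage outputs intact.
#'
#' @param config A [pipeline_config()], or a named list / YAML file path
#'   coerced through it.
#' @return List with `summary` (per-day data.frame), `steady_state_day`,
#'   `steady_state_hours`, `decisions` (a [sort_run()] per day, rbound),
#'   `reference`, `bins` (a [cluster_bins()] result), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 2)

  kin <- do.call(kinetics_params, config$kinetics)
  sim <- do.call(spectrum_sim_params, config$simulation)
  log_msg("simulating time course: days %s, %d cells/day, snr %g",
          paste(config$timecourse$days, collapse = ","),
          config$timecourse$n_per_day, sim$snr)
  tc <- simulate_timecourse(days = config$timecourse$days,
                            n_per_day = config$timecourse$n_per_day,
                            kinetics = kin, sim = sim, seed = seeds[[1]])
  log_msg("preprocessing %d spectra", sum(lengths(tc)))
  tc <- lapply(tc, preprocess_cells)
  ref <- build_reference(tc[[1]], min_snr = config$classify$min_snr)
  log_msg("12C reference: v1 %.2f, v2 %.2f cm^-1 (n=%d)",
          ref$mean$v1, ref$mean$v2, ref$n_control)

  fits <- lapply(tc, analyze_bands, reference = ref,
                 min_snr = config$classify$min_snr)
  decisions <- do.call(rbind, lapply(fits, function(f)
    as.data.frame(sort_run(f, ref, k_sd = config$classify$k_sd,
                           min_shift_cm1 = config$classify$min_shift_cm1))))
  rownames(decisions) <- NULL
  summary_tab <- summarize_timecourse(fits, ref)
  ss_day <- detect_steady_state(summary_tab, tol = config$steady_state$tol)
  log_msg("steady state reached at day %g (%g h)", ss_day, 24 * ss_day)

  genomes <- lapply(config$binning$genomes, function(g) do.call(genome_spec, g))
  cs <- simulate_contigs(genomes, seed = seeds[[2]])
  cs <- filter_contigs(cs, min_len_bp = config$binning$min_len_bp)
  fm <- feature_matrix(cs)
  bins <- cluster_bins(fm, cs, method = config$binning$method,
                       min_samples = config$binning$min_samples,
                       k = config$binning$k)
  log_msg("binning: %d contigs -> %d bin(s), purity %.3f", nrow(cs),
          nrow(attr(bins, "bins")), attr(bins, "purity"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("ramansip")),
    config = unclass(config),
    n_cells = sum(vapply(tc, length, integer(1))),
    n_contigs = nrow(cs),
    counts = as.list(attr(
      sort_run(do.call(rbind, fits), ref,
               k_sd = config$classify$k_sd,
               min_shift_cm1 = config$classify$min_shift_cm1), "counts")))
  if (!is.null(out_dir)) {
    utils::write.table(summary_tab, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(decisions, file.path(out_dir, "decisions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(bins), file.path(out_dir, "bins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(summary = summary_tab, steady_state_day = ss_day,
       steady_state_hours = 24 * ss_day, decisions = decisions,
       reference = ref, bins = bins, manifest = manifest)
}
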