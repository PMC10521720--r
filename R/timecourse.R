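#' Per-day labeling summary
#'
#' Aggregates band shifts and estimated 13C fractions over the
#' carotenoid-positive cells of one timepoint. The per-cell 13C fraction is
#' the simple mean of the nu1- and nu2-derived estimates from
#' [estimate_f()].
#'
#' @param cells List of preprocessed [spectrum()] objects for one day, or a
#'   data.frame from [analyze_bands()] computed against a reference.
#' @param ref A [build_reference()] result (used when `cells` are spectra).
#' @param model A [band_model()] for the fraction inversion.
#' @param day Day value recorded in the summary; taken from cell metadata
#'   when missing.
#' @return One-row data.frame: `day`, `n_cells`, `mean_v1_shift`,
#'   `sd_v1_shift`, `mean_v2_shift`, `sd_v2_shift`, `mean_f_hat`,
#'   `single_cell` (flag: sds reported as 0 from a single cell).
#' @export
summarize_day <- function(cells, ref, model = default_band_model(),
                          day = NULL) {
  tab <- if (is.data.frame(cells)) cells
         else analyze_bands(cells, reference = ref)
  if (is.null(day))
    day <- if ("day" %in% names(tab)) tab$day[1] else NA_real_
  tab <- tab[tab$carotenoid & is.finite(tab$v1_shift) &
               is.finite(tab$v2_shift), , drop = FALSE]
  if (nrow(tab) == 0) stop("no carotenoid-positive cells to summarize")
  f1 <- estimate_f(tab$v1_center, model, "v1")
  f2 <- estimate_f(tab$v2_center, model, "v2")
  f_hat <- (f1 + f2) / 2
  single <- nrow(tab) == 1
  sdz <- function(x) if (single) 0 else stats::sd(x)
  data.frame(day = day, n_cells = nrow(tab),
             mean_v1_shift = mean(tab$v1_shift), sd_v1_shift = sdz(tab$v1_shift),
             mean_v2_shift = mean(tab$v2_shift), sd_v2_shift = sdz(tab$v2_shift),
             mean_f_hat = mean(f_hat), single_cell = single)
}

#' Summarize a whole labeling time course
#'
#' @param timecourse Named list of per-day cell lists, as returned by
#'   [simulate_timecourse()] (names are day values), already preprocessed,
#'   or a list of per-day [analyze_bands()] tables.
#' @param ref,model See [summarize_day()].
#' @return data.frame of per-day summaries ordered by day.
#' @export
summarize_timecourse <- function(timecourse, ref,
                                 model = default_band_model()) {
  days <- as.numeric(names(timecourse))
  out <- do.call(rbind, lapply(seq_along(timecourse), function(i)
    summarize_day(timecourse[[i]], ref, model = model, day = days[i])))
  out[order(out$day), , drop = FALSE]
}

#' Detect the steady-state timepoint
#'
#' The labeling is declared steady from the earliest day `d` such that the
#' mean nu1 shift of every day from `d` onward stays within `tol` of the
#' final day's mean nu1 shift. The default tolerance of 2 cm^-1 is about
#' twice the band-fit sd at moderate SNR.
#'
#' @param summaries data.frame from [summarize_timecourse()] (>= 2 rows).
#' @param tol Tolerance in cm^-1.
#' @return The `day` value at which steady state is first reached.
#' @export
#' @examples
#' s <- data.frame(day = 0:5,
#'                 mean_v1_shift = c(0, 10, 19.5, 20, 20.2, 19.8))
#' detect_steady_state(s, tol = 1)  # day 2
detect_steady_state <- function(summaries, tol = 2) {
  if (nrow(summaries) < 2) stop("need at least 2 timepoints")
  if (tol < 0) stop("`tol` must be >= 0")
  s <- summaries[order(summaries$day), ]
  m <- s$mean_v1_shift
  last <- m[length(m)]
  within <- abs(m - last) <= tol
  # earliest index from which all later days stay within tol of the last
  ok_from <- rev(cumprod(rev(within))) == 1
  s$day[which(ok_from)[1]]
}
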