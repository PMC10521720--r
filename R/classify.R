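#' Build the 12C control reference
#'
#' Carotenoid band positions of cells from an unlabeled (12C) sample serve
#' as the control distribution against which shifts are measured. The
#' reference holds the per-band mean and sd of the estimated nu1/nu2
#' centers over carotenoid-positive control cells only; at least 5 such
#' cells are required.
#'
#' @param control_cells List of preprocessed [spectrum()] objects from the
#'   12C sample, or a data.frame from [analyze_bands()].
#' @param min_snr Carotenoid detection threshold.
#' @return An object of class `sip_reference` with `mean`, `sd` (each a
#'   list with `v1`, `v2`) and `n_control`.
#' @export
build_reference <- function(control_cells, min_snr = 5) {
  tab <- if (is.data.frame(control_cells)) control_cells
         else analyze_bands(control_cells, min_snr = min_snr)
  tab <- tab[tab$carotenoid & is.finite(tab$v1_center) &
               is.finite(tab$v2_center), , drop = FALSE]
  if (nrow(tab) < 5)
    stop("need at least 5 carotenoid-positive control cells, got ", nrow(tab))
  structure(list(
    mean = list(v1 = mean(tab$v1_center), v2 = mean(tab$v2_center)),
    sd = list(v1 = stats::sd(tab$v1_center), v2 = stats::sd(tab$v2_center)),
    n_control = nrow(tab)), class = "sip_reference")
}

#' @export
print.sip_reference <- function(x, ...) {
  cat(sprintf(
    "<sip_reference> n = %d controls | v1: %.2f +/- %.2f | v2: %.2f +/- %.2f cm^-1\n",
    x$n_control, x$mean$v1, x$sd$v1, x$mean$v2, x$sd$v2))
  invisible(x)
}

#' Two-band sorting decision for one cell
#'
#' Implements the simultaneous two-band criterion used to identify
#' 13C-incorporating (CO2-fixing candidate) cells for sorting: a
#' carotenoid-positive cell is `positive` iff BOTH its nu1 and nu2 red
#' shifts meet their thresholds; a single-band shift is not sufficient.
#' The per-band threshold is `max(k_sd * control sd, min_shift_cm1)`:
#' significance against the control distribution, floored at an absolute
#' shift that exceeds grid and fit noise.
#'
#' @param shift A list/row with `v1_shift`, `v2_shift` (cm^-1) and
#'   optionally `carotenoid` and `cell_id`.
#' @param ref A [build_reference()] result.
#' @param k_sd Multiple of the control sd (default 3).
#' @param min_shift_cm1 Absolute shift floor in cm^-1 (default 4, below
#'   the smallest day-1 shift of ~7 cm^-1 for nu2 and above fit noise).
#' @return A one-row data.frame: `cell_id`, `label` (`"positive"`,
#'   `"negative"` or `"not_carotenoid"`), `v1_shift`, `v2_shift`,
#'   `v1_threshold`, `v2_threshold`.
#' @export
classify_cell <- function(shift, ref, k_sd = 3, min_shift_cm1 = 4) {
  stopifnot(inherits(ref, "sip_reference"))
  thr1 <- max(k_sd * ref$sd$v1, min_shift_cm1)
  thr2 <- max(k_sd * ref$sd$v2, min_shift_cm1)
  car <- shift$carotenoid %||% TRUE
  label <- if (!isTRUE(car)) "not_carotenoid"
  else if (isTRUE(is.finite(shift$v1_shift) && is.finite(shift$v2_shift) &&
                    shift$v1_shift >= thr1 && shift$v2_shift >= thr2))
    "positive" else "negative"
  data.frame(cell_id = shift$cell_id %||% NA_character_, label = label,
             v1_shift = shift$v1_shift %||% NA_real_,
             v2_shift = shift$v2_shift %||% NA_real_,
             v1_threshold = thr1, v2_threshold = thr2)
}

#' Batch sorting run
#'
#' Applies [classify_cell()] to every cell and tallies the decisions.
#' Deterministic given its inputs.
#'
#' @param cells List of preprocessed [spectrum()] objects, or a data.frame
#'   from [analyze_bands()] (must contain shifts, i.e. have been computed
#'   against a reference).
#' @param ref A [build_reference()] result; also used to compute shifts
#'   when `cells` are spectra.
#' @param k_sd,min_shift_cm1 See [classify_cell()].
#' @param min_snr Carotenoid detection threshold for spectra input.
#' @return An object of class `sort_run`: a data.frame of per-cell
#'   decisions with a `counts` attribute
#'   (`positive`/`negative`/`not_carotenoid`).
#' @export
sort_run <- function(cells, ref, k_sd = 3, min_shift_cm1 = 4, min_snr = 5) {
  tab <- if (is.data.frame(cells)) cells
         else analyze_bands(cells, reference = ref, min_snr = min_snr)
  decisions <- if (nrow(tab) == 0)
    data.frame(cell_id = character(), label = character(),
               v1_shift = numeric(), v2_shift = numeric(),
               v1_threshold = numeric(), v2_threshold = numeric())
  else do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    classify_cell(tab[i, ], ref, k_sd = k_sd, min_shift_cm1 = min_shift_cm1)))
  if ("species" %in% names(tab) && nrow(tab) > 0)
    decisions$species <- tab$species
  counts <- c(positive = sum(decisions$label == "positive"),
              negative = sum(decisions$label == "negative"),
              not_carotenoid = sum(decisions$label == "not_carotenoid"))
  structure(decisions, counts = counts, class = c("sort_run", "data.frame"))
}

#' @export
print.sort_run <- function(x, ...) {
  n <- attr(x, "counts")
  cat(sprintf(
    "<sort_run> %d cells: %d positive, %d negative, %d not carotenoid\n",
    nrow(x), n["positive"], n["negative"], n["not_carotenoid"]))
  if (nrow(x) > 0)
    print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.sort_run <- function(object, ...) {
  n <- attr(object, "counts")
  pos <- as.data.frame(object)[object$label == "positive", , drop = FALSE]
  out <- list(counts = n,
              positive_rate = if (nrow(object)) unname(n["positive"]) / nrow(object) else NA,
              mean_positive_shifts = if (nrow(pos))
                c(v1 = mean(pos$v1_shift), v2 = mean(pos$v2_shift))
              else c(v1 = NA_real_, v2 = NA_real_))
  class(out) <- "summary.sort_run"
  out
}

#' @export
print.summary.sort_run <- function(x, ...) {
  cat("Sorting run summary\n")
  cat(sprintf("  positive: %d  negative: %d  not_carotenoid: %d\n",
              x$counts["positive"], x$counts["negative"],
              x$counts["not_carotenoid"]))
  cat(sprintf("  positive rate: %.3f\n", x$positive_rate))
  if (is.finite(x$mean_positive_shifts["v1"]))
    cat(sprintf("  mean shifts among positives: v1 %.2f, v2 %.2f cm^-1\n",
                x$mean_positive_shifts["v1"], x$mean_positive_shifts["v2"]))
  invisible(x)
}
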