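#' Read spectra from a TSV file
#'
#' Accepts both dialects: wide (first column `wavenumber_cm-1`, one column
#' per cell id) and long (columns `cell_id`, `wavenumber`, `intensity`).
#' The dialect is detected from the header. Wavenumbers must be strictly
#' increasing within each cell; a violation is reported with the offending
#' row.
#'
#' @param path TSV file path.
#' @return List of [spectrum()] objects.
#' @export
read_spectra <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  long <- all(c("cell_id", "wavenumber", "intensity") %in% names(tab))
  if (long) {
    return(lapply(split(tab, factor(tab$cell_id, levels = unique(tab$cell_id))),
                  function(d) {
      bad <- which(diff(d$wavenumber) <= 0)
      if (length(bad))
        stop(sprintf("non-monotone wavenumber for cell '%s' at row %d",
                     d$cell_id[1], bad[1] + 1))
      spectrum(d$wavenumber, d$intensity, cell_id = d$cell_id[1])
    }))
  }
  wn <- tab[[1]]
  bad <- which(diff(wn) <= 0)
  if (length(bad))
    stop(sprintf("non-monotone wavenumber column at row %d", bad[1] + 1))
  cells <- names(tab)[-1]
  lapply(stats::setNames(cells, cells), function(id)
    spectrum(wn, tab[[id]], cell_id = id))
}

#' Write spectra to a TSV file
#'
#' @param cells List of [spectrum()] objects; for `format = "wide"` all
#'   must share a common grid.
#' @param path Output TSV path.
#' @param format `"wide"` (default, `wavenumber_cm-1` + one column per
#'   cell) or `"long"` (`cell_id`, `wavenumber`, `intensity`).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(cells, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    grid <- cells[[1]]$wavenumber
    for (s in cells)
      if (!isTRUE(all.equal(s$wavenumber, grid)))
        stop("wide format needs a common grid; resample first or use long format")
    tab <- data.frame(`wavenumber_cm-1` = grid, check.names = FALSE)
    for (s in cells) tab[[s$cell_id]] <- s$intensity
  } else {
    tab <- do.call(rbind, lapply(cells, function(s)
      data.frame(cell_id = s$cell_id, wavenumber = s$wavenumber,
                 intensity = s$intensity)))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the simulation ground-truth sidecar
#'
#' JSON map from cell id to `{is_carotenoid, true_f, species, day}`.
#'
#' @param cells List of [spectrum()] objects with truth metadata.
#' @param path JSON path.
#' @return `path` (write) or a data.frame (read).
#' @export
write_truth <- function(cells, path) {
  truth <- lapply(cells, function(s)
    list(is_carotenoid = s$meta$is_carotenoid %||% NA,
         true_f = s$meta$true_f %||% NA,
         species = s$meta$species %||% NA,
         day = s$meta$day %||% NA))
  names(truth) <- vapply(cells, function(s) s$cell_id, character(1))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path)
  out <- do.call(rbind, lapply(names(truth), function(id)
    data.frame(cell_id = id,
               is_carotenoid = truth[[id]]$is_carotenoid %||% NA,
               true_f = truth[[id]]$true_f %||% NA,
               species = truth[[id]]$species %||% NA,
               day = truth[[id]]$day %||% NA)))
  out
}

#' Read contigs from a FASTA file
#'
#' Tolerates mixed case and `N`; duplicate record ids are an error; an
#' empty file yields an empty contig set with a warning.
#'
#' @param path FASTA path.
#' @return A [contig_set()] (no truth labels).
#' @export
read_fasta_contigs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) {
    warning("empty FASTA file: ", path)
    return(contig_set(data.frame(contig_id = character(),
                                 sequence = character())))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  contig_set(data.frame(contig_id = ids,
                        sequence = toupper(as.character(seqs))))
}

#' Write contigs to a FASTA file (80-column wrap)
#'
#' When the contig set has truth labels, a TSV sidecar
#' (`<path>.truth.tsv`: contig_id, genome, length, gc) is written next to
#' the FASTA.
#'
#' @param cs A [contig_set()].
#' @param path Output FASTA path.
#' @param truth_sidecar Write the sidecar when labels are present.
#' @return `path`, invisibly.
#' @export
write_fasta_contigs <- function(cs, path, truth_sidecar = TRUE) {
  stopifnot(inherits(cs, "contig_set"))
  seqs <- Biostrings::DNAStringSet(cs$sequence)
  names(seqs) <- cs$contig_id
  Biostrings::writeXStringSet(seqs, path, width = 80)
  if (truth_sidecar && !is.null(cs$genome))
    utils::write.table(
      data.frame(contig_id = cs$contig_id, genome = cs$genome,
                 length = cs$length, gc = cs$gc),
      paste0(path, ".truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  invisible(path)
}
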