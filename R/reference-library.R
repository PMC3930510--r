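#' Reference metabolite spectrum (peak list)
#'
#' A reference spectrum is the peak-list summary of a metabolite's 1D
#' 1H-NMR spectrum: chemical-shift positions (ppm) and relative peak
#' intensities in (0, 1], as exported by peak-list databases such as HMDB.
#'
#' @param metabolite_id Identifier string (e.g. `"HMDB0000001"` or a
#'   synthetic id).
#' @param name Human-readable metabolite name.
#' @param peak_ppm Numeric vector of peak positions in ppm.
#' @param rel_intensity Relative intensities in (0, 1]; recycled to the
#'   number of peaks if length 1. Carried for plotting/reporting; the
#'   metabomatching score weights all peaks equally.
#' @return An object of class `reference_spectrum`.
#' @export
reference_spectrum <- function(metabolite_id, name = metabolite_id,
                               peak_ppm, rel_intensity = 1) {
  peak_ppm <- as.numeric(peak_ppm)
  if (length(peak_ppm) < 1L)
    stop("a reference spectrum needs at least one peak", call. = FALSE)
  if (any(!is.finite(peak_ppm)))
    stop("peak positions must be finite", call. = FALSE)
  rel_intensity <- rep_len(as.numeric(rel_intensity), length(peak_ppm))
  if (any(rel_intensity <= 0 | rel_intensity > 1))
    stop("relative intensities must lie in (0, 1]", call. = FALSE)
  o <- order(peak_ppm)
  structure(
    list(metabolite_id = as.character(metabolite_id),
         name = as.character(name),
         peaks = data.frame(ppm = peak_ppm[o],
                            rel_intensity = rel_intensity[o])),
    class = "reference_spectrum")
}

#' @export
print.reference_spectrum <- function(x, ...) {
  cat(sprintf("<reference_spectrum> %s (%s): %d peak(s) at %s ppm\n",
              x$name, x$metabolite_id, nrow(x$peaks),
              paste(sprintf("%.4f", x$peaks$ppm), collapse = "/")))
  invisible(x)
}

#' Read / write a peak-list library CSV
#'
#' The on-disk convention is a long-format CSV with columns
#' `metabolite_id,name,peak_ppm,rel_intensity`, one row per peak.
#'
#' @param path CSV file path.
#' @return `read_library()`: a named list of [reference_spectrum()]
#'   objects (names are metabolite ids).
#' @export
read_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "name", "peak_ppm", "rel_intensity")
  if (!all(need %in% names(df)))
    stop("library CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  split_df <- split(df, df$metabolite_id)
  lib <- lapply(split_df, function(d)
    reference_spectrum(d$metabolite_id[1L], d$name[1L],
                       d$peak_ppm, d$rel_intensity))
  lib[unique(df$metabolite_id)]
}

#' @rdname read_library
#' @param library A list of [reference_spectrum()] objects.
#' @export
write_library <- function(library, path) {
  rows <- lapply(library, function(r)
    data.frame(metabolite_id = r$metabolite_id, name = r$name,
               peak_ppm = r$peaks$ppm,
               rel_intensity = r$peaks$rel_intensity))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
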