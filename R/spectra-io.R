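#' Construct an MS/MS spectrum object
#'
#' A centroided tandem (MS2) spectrum: precursor information plus a peak
#' list. Peaks are stored sorted by ascending m/z.
#'
#' @param scan_id character scan identifier.
#' @param precursor_mz precursor m/z (Th).
#' @param precursor_charge integer precursor charge state.
#' @param peaks data.frame with numeric columns `mz` (> 0) and
#'   `intensity` (>= 0); rows are reordered by ascending `mz`.
#' @param retention_time optional retention time in seconds.
#' @return An object of class `ms2_spectrum`.
#' @examples
#' s <- ms2_spectrum("scan=1", 1000, 2,
#'                   data.frame(mz = c(204.0866, 138.055), intensity = c(10, 5)))
#' s$peaks
#' @export
ms2_spectrum <- function(scan_id, precursor_mz, precursor_charge, peaks,
                         retention_time = NA_real_) {
  .assert(is.data.frame(peaks) && all(c("mz", "intensity") %in% names(peaks)),
          "`peaks` must be a data.frame with columns mz and intensity")
  .assert(nrow(peaks) >= 1L, "spectrum must contain at least one peak")
  .assert(all(peaks$mz > 0), "all peak m/z must be > 0")
  .assert(all(peaks$intensity >= 0), "all peak intensities must be >= 0")
  peaks <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
  rownames(peaks) <- NULL
  structure(
    list(
      scan_id = as.character(scan_id),
      precursor_mz = as.numeric(precursor_mz),
      precursor_charge = as.integer(precursor_charge),
      retention_time = as.numeric(retention_time),
      peaks = peaks
    ),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum %s> precursor %.4f Th (%d+), %d peaks\n",
              x$scan_id, x$precursor_mz, x$precursor_charge, nrow(x$peaks)))
  invisible(x)
}

#' Read centroided MS/MS spectra
#'
#' Reads MS2 scans from MGF, mzML or mzXML. MS1 scans are skipped; spectra
#' whose precursor charge falls outside `charge_range` (mirroring
#' acquisition-time charge screening, which rejects unassigned, singly and
#' more-than-eight protonated ions) are dropped and the drop count reported
#' via [message()] and the `"n_dropped"` attribute. Empty scans are dropped
#' with a warning.
#'
#' mzML/mzXML reading goes through the `mzR` package; spectra flagged as
#' profile mode there trigger a warning and are passed through unchanged.
#'
#' @param path path to the spectrum file.
#' @param format one of `"auto"`, `"mgf"`, `"mzml"`, `"mzxml"`; `"auto"`
#'   picks by file extension.
#' @param charge_range integer length-2 inclusive charge window; use
#'   `NULL` to disable charge screening.
#' @return list of [ms2_spectrum] objects with attribute `n_dropped`.
#' @export
read_spectra <- function(path, format = c("auto", "mgf", "mzml", "mzxml"),
                         charge_range = c(2L, 8L)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      mgf = "mgf", mzml = "mzml", mzxml = "mzxml",
      stop("cannot infer spectrum format from extension: ", ext, call. = FALSE)
    )
  }
  spectra <- if (format == "mgf") .read_mgf(path) else .read_mzr(path)
  n_in <- length(spectra)
  if (!is.null(charge_range)) {
    keep <- vapply(spectra, function(s) {
      !is.na(s$precursor_charge) &&
        s$precursor_charge >= charge_range[1] &&
        s$precursor_charge <= charge_range[2]
    }, logical(1))
    spectra <- spectra[keep]
  }
  n_dropped <- n_in - length(spectra)
  if (n_dropped > 0) {
    message(n_dropped, " spectra dropped by charge screening [",
            charge_range[1], ", ", charge_range[2], "]")
  }
  attr(spectra, "n_dropped") <- n_dropped
  spectra
}

.read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  out <- vector("list", length(starts))
  n_empty <- 0L
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    is_kv <- grepl("^[A-Z]+=", block)
    kv <- block[is_kv]
    key <- sub("=.*$", "", kv)
    val <- sub("^[A-Z]+=", "", kv)
    title <- if ("TITLE" %in% key) val[key == "TITLE"][1] else paste0("index=", i)
    pepmass <- if ("PEPMASS" %in% key) {
      as.numeric(strsplit(val[key == "PEPMASS"][1], "\\s+")[[1]][1])
    } else {
      NA_real_
    }
    charge <- NA_integer_
    if ("CHARGE" %in% key) {
      cs <- val[key == "CHARGE"][1]
      sign <- if (grepl("-", cs)) -1L else 1L
      charge <- sign * as.integer(gsub("[^0-9]", "", cs))
    }
    rt <- if ("RTINSECONDS" %in% key) as.numeric(val[key == "RTINSECONDS"][1]) else NA_real_
    pk_lines <- block[!is_kv]
    pk_lines <- pk_lines[nzchar(trimws(pk_lines))]
    if (length(pk_lines) == 0L) {
      n_empty <- n_empty + 1L
      next
    }
    con <- textConnection(pk_lines)
    pk <- utils::read.table(con, col.names = c("mz", "intensity"),
                            colClasses = "numeric", fill = FALSE)
    close(con)
    out[[i]] <- ms2_spectrum(title, pepmass, charge, pk, rt)
  }
  if (n_empty > 0) warning(n_empty, " MGF block(s) with no peaks dropped")
  out[!vapply(out, is.null, logical(1))]
}

.read_mzr <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("mzML/mzXML reading requires the mzR package", call. = FALSE)
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  ms2 <- which(hd$msLevel == 2L)
  if (any(!is.na(hd$centroided[ms2]) & !hd$centroided[ms2])) {
    warning("profile-mode MS2 spectra detected; passed through unchanged")
  }
  out <- vector("list", length(ms2))
  n_empty <- 0L
  for (j in seq_along(ms2)) {
    i <- ms2[j]
    pk <- mzR::peaks(fh, i)
    if (is.null(dim(pk)) || nrow(pk) == 0L) {
      n_empty <- n_empty + 1L
      next
    }
    chg <- hd$precursorCharge[i]
    out[[j]] <- ms2_spectrum(
      scan_id = paste0("scan=", hd$acquisitionNum[i]),
      precursor_mz = hd$precursorMZ[i],
      precursor_charge = if (is.na(chg) || chg == 0L) NA_integer_ else chg,
      peaks = data.frame(mz = pk[, 1], intensity = pk[, 2]),
      retention_time = hd$retentionTime[i]
    )
  }
  if (n_empty > 0) warning(n_empty, " empty MS2 scan(s) dropped")
  out[!vapply(out, is.null, logical(1))]
}

#' Write spectra to an MGF file
#'
#' @param spectra list of [ms2_spectrum] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$scan_id),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      sprintf("CHARGE=%d+", s$precursor_charge),
      if (!is.na(s$retention_time)) sprintf("RTINSECONDS=%.3f", s$retention_time),
      sprintf("%.6f %.17g", s$peaks$mz, s$peaks$intensity),
      "END IONS",
      ""
    ), con)
  }
  invisible(path)
}

# rank peaks best-to-worst: intensity descending, ties by m/z descending,
# so among equal intensities the lowest-m/z peak is dropped first
.peak_rank_order <- function(peaks) {
  order(-peaks$intensity, -peaks$mz)
}

#' Remove the lowest-intensity fraction of peaks
#'
#' Drops the `floor(fraction * n)` least intense peaks as low-quality
#' (default: the bottom 10%). Ties are broken deterministically: among
#' equal intensities the lowest-m/z peak is dropped first.
#'
#' @param spectrum an [ms2_spectrum].
#' @param fraction proportion of peaks to remove, in `[0, 1)`.
#' @return The filtered [ms2_spectrum] (m/z order preserved).
#' @export
remove_bottom_fraction <- function(spectrum, fraction = 0.10) {
  .assert(fraction >= 0 && fraction < 1, "`fraction` must be in [0, 1)")
  n <- nrow(spectrum$peaks)
  n_drop <- floor(fraction * n)
  if (n_drop == 0L) return(spectrum)
  ord <- .peak_rank_order(spectrum$peaks)
  keep <- sort(ord[seq_len(n - n_drop)])
  spectrum$peaks <- spectrum$peaks[keep, , drop = FALSE]
  rownames(spectrum$peaks) <- NULL
  spectrum
}

#' Most intense fraction of peaks
#'
#' Returns the `ceiling(fraction * n)` most intense peaks, so any nonzero
#' fraction of a nonempty spectrum retains at least one peak. Ties are
#' broken toward retaining the higher-m/z peak.
#'
#' @param spectrum an [ms2_spectrum].
#' @param fraction proportion in `(0, 1]`.
#' @return data.frame of peaks (mz, intensity), sorted by ascending m/z.
#' @export
top_fraction_peaks <- function(spectrum, fraction) {
  .assert(fraction > 0 && fraction <= 1, "`fraction` must be in (0, 1]")
  n <- nrow(spectrum$peaks)
  n_keep <- ceiling(fraction * n)
  ord <- .peak_rank_order(spectrum$peaks)
  keep <- sort(ord[seq_len(n_keep)])
  out <- spectrum$peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Neutral (uncharged, deprotonated) precursor mass
#'
#' `(precursor_mz - m_proton) * z`, with the proton mass 1.007276 Da.
#'
#' @param spectrum an [ms2_spectrum] with known precursor charge.
#' @return neutral monoisotopic mass in Da.
#' @export
precursor_neutral_mass <- function(spectrum) {
  z <- spectrum$precursor_charge
  if (is.na(z) || z < 1L) {
    stop("precursor charge missing or < 1", call. = FALSE)
  }
  (spectrum$precursor_mz - .PROTON_MASS) * z
}
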