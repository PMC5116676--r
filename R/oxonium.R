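#' The 10 diagnostic oxonium ions
#'
#' Glycan oxonium ions monitored in HCD glycopeptide spectra, keyed by
#' their nominal integer m/z labels: HexNAc-derived ions at 138, 168, 186
#' and 204; hexose-derived ions at 145, 163 and 325; Neu5Ac ions at 274
#' and 292; and the HexHexNAc disaccharide ion at 366. Exact m/z values
#' are monoisotopic singly protonated masses (residue mass + proton,
#' minus water losses where applicable).
#'
#' @return data.frame with columns `name`, `nominal_mz`, `parent_sugar`,
#'   `exact_mz`.
#' @export
oxonium_ion_table <- function() {
  hexnac <- .GLYCAN_RESIDUE_MASS[["HexNAc"]] + .PROTON_MASS   # 204.086649
  hex <- .GLYCAN_RESIDUE_MASS[["Hex"]] + .PROTON_MASS         # 163.060100
  neuac <- .GLYCAN_RESIDUE_MASS[["NeuAc"]] + .PROTON_MASS     # 292.102693
  w <- .WATER_MASS
  # 138 is the HexNAc cross-ring/internal fragment C7H8NO2+
  frag138 <- .formula_mass(c(C = 7, H = 7, N = 1, O = 2)) + .PROTON_MASS
  out <- data.frame(
    name = c("HexNAc_frag", "Hex-H2O", "Hex", "HexNAc-2H2O", "HexNAc-H2O",
             "HexNAc", "Neu5Ac-H2O", "Neu5Ac", "Hex2", "HexHexNAc"),
    nominal_mz = c(138L, 145L, 163L, 168L, 186L, 204L, 274L, 292L, 325L, 366L),
    parent_sugar = c("HexNAc", "Hex", "Hex", "HexNAc", "HexNAc", "HexNAc",
                     "Neu5Ac", "Neu5Ac", "Hex", "HexHexNAc"),
    exact_mz = c(frag138, hex - w, hex, hexnac - 2 * w, hexnac - w,
                 hexnac, neuac - w, neuac,
                 hex + .GLYCAN_RESIDUE_MASS[["Hex"]],
                 hexnac + .GLYCAN_RESIDUE_MASS[["Hex"]]),
    stringsAsFactors = FALSE
  )
  stopifnot(all(abs(out$exact_mz - out$nominal_mz) < 0.5))
  out
}

# labels of the 9 normalized features, in fixed model order
.FEATURE_IONS <- c(138L, 145L, 163L, 168L, 186L, 274L, 292L, 325L, 366L)
.FEATURE_NAMES <- paste0("r", .FEATURE_IONS)

#' Intensity of the ion nearest a query m/z
#'
#' Returns the intensity of the most intense peak within `tol_ppm` of
#' `exact_mz`, or 0 when no peak falls in the window. Vectorized over
#' `exact_mz`.
#'
#' @param spectrum an [ms2_spectrum].
#' @param exact_mz query m/z value(s) in Th.
#' @param tol_ppm matching tolerance in ppm (MS2 default 20).
#' @return numeric vector of intensities.
#' @export
ion_intensity <- function(spectrum, exact_mz, tol_ppm = 20) {
  mz <- spectrum$peaks$mz
  int <- spectrum$peaks$intensity
  win <- .ppm_window(exact_mz, tol_ppm)
  lo <- findInterval(win[, "lo"], mz, left.open = TRUE) + 1L
  hi <- findInterval(win[, "hi"], mz)
  vapply(seq_along(exact_mz), function(i) {
    if (lo[i] > hi[i]) 0 else max(int[lo[i]:hi[i]])
  }, numeric(1))
}

#' Oxonium-ion spectrum filter
#'
#' A spectrum qualifies for glycopeptide search when at least `min_ions`
#' of the 10 diagnostic oxonium ions are found (at `tol_ppm`) among its
#' `top_fraction` most intense peaks, with the HexNAc ion at m/z 204
#' mandatory when `require_204` is set. The glycoprotein-standard filter
#' uses the top 5% of peaks; serum searches relax this to the top 10%.
#'
#' @param spectrum an [ms2_spectrum].
#' @param top_fraction fraction of most intense peaks examined.
#' @param min_ions minimum number of distinct oxonium ions (default 2).
#' @param require_204 must m/z 204 be among the matched ions?
#' @param tol_ppm matching tolerance in ppm.
#' @return logical.
#' @export
is_oxonium_spectrum <- function(spectrum, top_fraction = 0.05, min_ions = 2L,
                                require_204 = TRUE, tol_ppm = 20) {
  .assert(nrow(spectrum$peaks) > 0, "spectrum is empty")
  top <- top_fraction_peaks(spectrum, top_fraction)
  sub <- spectrum
  sub$peaks <- top
  ions <- oxonium_ion_table()
  found <- ion_intensity(sub, ions$exact_mz, tol_ppm) > 0
  sum(found) >= min_ions && (!require_204 || found[ions$nominal_mz == 204L])
}

#' Extract the 9 normalized oxonium features
#'
#' Intensities of the nine non-reference oxonium ions (138, 145, 163,
#' 168, 186, 274, 292, 325, 366), each divided by the intensity of the
#' HexNAc ion at m/z 204 — the near-universal reference peak of
#' glycopeptide spectra. Normalization makes the features transferable
#' across instruments and intensity units. Absent ions give ratio 0; an
#' absent 204 ion is an error (the spectrum is unclassifiable).
#'
#' By default the bottom 10% of peaks are removed first, matching the
#' preprocessing used during identification; disable with
#' `preprocess = FALSE`.
#'
#' @param spectrum an [ms2_spectrum].
#' @param tol_ppm matching tolerance in ppm.
#' @param preprocess remove the bottom 10% of peaks first?
#' @param log1p return `log1p`-transformed ratios? Default `FALSE` (raw
#'   ratios, as modeled).
#' @return object of class `oxonium_features`: list with `ratios` (named
#'   numeric of length 9, names `r138` ... `r366`) and `intensity_204`.
#' @export
extract_features <- function(spectrum, tol_ppm = 20, preprocess = TRUE,
                             log1p = FALSE) {
  if (preprocess) spectrum <- remove_bottom_fraction(spectrum, 0.10)
  ions <- oxonium_ion_table()
  ints <- ion_intensity(spectrum, ions$exact_mz, tol_ppm)
  i204 <- ints[ions$nominal_mz == 204L]
  if (i204 <= 0) {
    stop("no peak at m/z 204: spectrum cannot be feature-extracted",
         call. = FALSE)
  }
  keep <- ions$nominal_mz != 204L
  ratios <- ints[keep] / i204
  names(ratios) <- paste0("r", ions$nominal_mz[keep])
  ratios <- ratios[.FEATURE_NAMES]
  if (log1p) ratios <- log1p(ratios)
  structure(list(ratios = ratios, intensity_204 = i204),
            class = "oxonium_features")
}

#' Per-spectrum oxonium feature table
#'
#' Applies the oxonium filter and [extract_features()] across a list of
#' spectra, returning one row per spectrum that passes.
#'
#' @param spectra list of [ms2_spectrum] objects.
#' @param top_fraction,min_ions,require_204,tol_ppm filter settings, see
#'   [is_oxonium_spectrum()].
#' @param preprocess remove the bottom 10% of peaks before extraction?
#' @return data.frame with columns `scan_id`, `r138` ... `r366`, `i204`.
#' @export
extract_feature_table <- function(spectra, top_fraction = 0.05,
                                  min_ions = 2L, require_204 = TRUE,
                                  tol_ppm = 20, preprocess = TRUE) {
  rows <- lapply(spectra, function(s) {
    if (!is_oxonium_spectrum(s, top_fraction, min_ions, require_204, tol_ppm)) {
      return(NULL)
    }
    f <- extract_features(s, tol_ppm, preprocess)
    cbind(data.frame(scan_id = s$scan_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(f$ratios)),
          data.frame(i204 = f$intensity_204))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character(0)), rep(list(numeric(0)), 10L)),
      c("scan_id", .FEATURE_NAMES, "i204")
    ))
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
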