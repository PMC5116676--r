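# Shared fixtures and independent oracles, built in code at test time.

toy_spectrum <- function(mz, intensity, precursor_mz = 1000, charge = 2L,
                         scan_id = "toy") {
  ms2_spectrum(scan_id, precursor_mz, charge,
               data.frame(mz = mz, intensity = intensity))
}

# frozen reference masses, independent of the package's elemental tables
ORACLE_AA <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
ORACLE_WATER <- 18.010565
ORACLE_PROTON <- 1.007276
ORACLE_CAM <- 57.021464
ORACLE_OX <- 15.994915
ORACLE_GLYCAN <- c(HexNAc = 203.079373, Hex = 162.052824,
                   Fuc = 146.057909, NeuAc = 291.095417)

oracle_peptide_mass <- function(seq, n_ox = 0) {
  aa <- strsplit(seq, "")[[1]]
  sum(ORACLE_AA[aa]) + ORACLE_WATER + n_ox * ORACLE_OX +
    sum(aa == "C") * ORACLE_CAM
}

# brute-force tryptic digestion: enumerate all substrings bounded by
# valid cleavage points (after K/R not before P) with <= max_missed
# internal sites, within the length window
oracle_digest <- function(seq, max_missed = 2, min_len = 1, max_len = 1000) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  sites <- which(aa %in% c("K", "R"))
  sites <- sites[sites == n | aa[pmin(sites + 1, n)] != "P"]
  bounds <- unique(c(0, sites, n))
  peps <- character(0)
  for (i in seq_along(bounds)) {
    for (j in seq_along(bounds)) {
      if (j <= i) next
      if (j - i - 1 > max_missed) next
      len <- bounds[j] - bounds[i]
      if (len < min_len || len > max_len) next
      peps <- c(peps, paste(aa[(bounds[i] + 1):bounds[j]], collapse = ""))
    }
  }
  sort(peps)
}

# brute-force GPSM scorer: recompute all theoretical ion m/z from the
# frozen oracle mass tables, then do naive all-pairs matching (each ion
# to its nearest in-tolerance peak), oxonium exclusion from scratch
oracle_score <- function(spectrum, sequence, comp, tol_ppm = 20) {
  aa <- strsplit(sequence, "")[[1]]
  res <- ORACLE_AA[aa] + (aa == "C") * ORACLE_CAM
  n <- length(aa)
  theo <- c(
    cumsum(res)[-n] + ORACLE_PROTON,                             # b
    rev(cumsum(rev(res)))[-1] + ORACLE_WATER + ORACLE_PROTON     # y
  )
  pep_mass <- sum(res) + ORACLE_WATER
  y_theo <- c()
  for (kn in 0:comp$n_hexnac) for (kh in 0:comp$n_hex)
    for (kf in 0:comp$n_fuc) for (ks in 0:comp$n_neuac) {
      y_theo <- c(y_theo, pep_mass + kn * ORACLE_GLYCAN["HexNAc"] +
                    kh * ORACLE_GLYCAN["Hex"] + kf * ORACLE_GLYCAN["Fuc"] +
                    ks * ORACLE_GLYCAN["NeuAc"] + ORACLE_PROTON)
    }
  theo <- c(theo, y_theo)
  mz <- spectrum$peaks$mz
  int <- spectrum$peaks$intensity
  matched_peaks <- integer(0)
  n_matched <- 0L
  for (t in theo) {
    d <- abs(mz - t)
    ok <- which(d <= t * tol_ppm * 1e-6)
    if (length(ok) > 0) {
      n_matched <- n_matched + 1L
      matched_peaks <- c(matched_peaks, ok[which.min(d[ok])])
    }
  }
  matched_peaks <- unique(matched_peaks)
  oxo_mz <- c(138.055031, 145.049535, 163.060100, 168.065519, 186.076084,
              204.086649, 274.092128, 292.102693, 325.112923, 366.139472)
  is_oxo <- rep(FALSE, length(mz))
  for (o in oxo_mz) is_oxo <- is_oxo | abs(mz - o) <= o * tol_ppm * 1e-6
  denom <- sum(int) - sum(int[is_oxo])
  num <- sum(int[setdiff(matched_peaks, which(is_oxo))])
  frac <- if (denom <= 0) 0 else num / denom
  n_matched + frac
}

# noiseless generator settings: fixed ratios at the class medians, no
# jitter, no noise, every fragment emitted
noiseless_config <- function(...) {
  generator_config(ratio_sdlog = 0, by_efficiency = 1, y_efficiency = 1,
                   n_noise_peaks = 0L, mz_jitter_ppm = 0, ...)
}

# minimal non-indexed mzML writer (64-bit little-endian, uncompressed)
# for exercising the mzR-backed reader without binary fixtures
write_tiny_mzml <- function(path, spectra) {
  enc <- function(x) jsonlite::base64_enc(writeBin(x, raw(), size = 8,
                                                   endian = "little"))
  one <- function(i, s) {
    mzb <- enc(s$peaks$mz); inb <- enc(s$peaks$intensity)
    paste0(
      sprintf('<spectrum index="%d" id="%s" defaultArrayLength="%d">',
              i - 1L, s$scan_id, nrow(s$peaks)),
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>',
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>',
      sprintf('<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%.6f"/>',
              s$precursor_mz),
      sprintf('<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>',
              s$precursor_charge),
      '</selectedIon></selectedIonList><activation/></precursor></precursorList>',
      '<binaryDataArrayList count="2">',
      sprintf('<binaryDataArray encodedLength="%d">', nchar(mzb)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      sprintf('<binary>%s</binary></binaryDataArray>', mzb),
      sprintf('<binaryDataArray encodedLength="%d">', nchar(inb)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      sprintf('<binary>%s</binary></binaryDataArray>', inb),
      '</binaryDataArrayList></spectrum>'
    )
  }
  body <- paste(vapply(seq_along(spectra),
                       function(i) one(i, spectra[[i]]), character(1)),
                collapse = "")
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="x"/></cvList>',
    sprintf('<run id="r"><spectrumList count="%d" defaultDataProcessingRef="dp">',
            length(spectra)),
    body, '</spectrumList></run></mzML>'
  )
  writeLines(xml, path)
  invisible(path)
}
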