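# Built-in synthetic peptide/glycan pools. These are invented tryptic-like
# sequences and common composition classes, not measured data: N-pool
# peptides carry an N-sequon, O-pool peptides carry S/T and no sequon.
.SYNTH_N_PEPTIDES <- c(
  "LVNDSAIK", "TVLNETLLR", "AGFNCSVEK", "EILNVTHPK", "DLQNGTFVR",
  "SMVNITAGLK", "LCPDCPLLAPLNDSR"
)
.SYNTH_O_PEPTIDES <- c(
  "ASTPAPVER", "TGSSLVTK", "VPTSEPAAK", "GLTSDQVK", "APVSTEHLR", "TTEAPSIR"
)
.SYNTH_N_GLYCANS <- c(
  "N2H5F0S0", "N2H7F0S0", "N4H5F0S1", "N4H5F0S2", "N4H4F1S0", "N3H4F0S1"
)
.SYNTH_O_GLYCANS <- c(
  "N1H1F0S0", "N1H1F0S1", "N1H1F0S2", "N2H2F0S0", "N2H2F0S1", "N3H3F0S1"
)

#' Configuration of the synthetic HCD glycopeptide spectrum generator
#'
#' The generator emulates the phenomenology of HCD glycopeptide spectra:
#' singly charged b/y backbone ions, a Y-ion ladder (peptide plus a
#' growing partial glycan), the 10 diagnostic oxonium ions with
#' class-conditional 204-normalized intensity ratios, ppm-scale m/z
#' jitter and random noise peaks. Ratio medians default to values
#' consistent with the qualitative N/O contrasts of real spectra —
#' O-linked: high 186/204 and high Neu5Ac ions; N-linked: high hexose
#' ions and high 366 — and are synthetic settings, not measurements.
#' Ratios are drawn log-normally (positive, heavy right tail, as ion
#' intensities are).
#'
#' @param seed integer RNG seed; a fixed seed reproduces the dataset
#'   byte-identically.
#' @param n_n,n_o spectra per class (defaults 872 N / 527 O, the class
#'   split emulated for classifier work).
#' @param n_ratio_medians,o_ratio_medians named length-9 vectors of
#'   median 204-normalized ratios per class.
#' @param ratio_sdlog log-normal dispersion of the ratios (0 = fixed at
#'   the medians).
#' @param by_efficiency,y_efficiency per-ion emission probability of b/y
#'   and Y-ladder ions (1 = all emitted).
#' @param by_intensity_scale,y_intensity_scale median intensities of b/y
#'   and Y peaks (arbitrary units).
#' @param n_noise_peaks,noise_intensity_scale number of uniform-m/z noise
#'   peaks and their exponential mean intensity.
#' @param mz_jitter_ppm 1-sigma Gaussian m/z jitter in ppm (default 5).
#' @param base_intensity intensity of the reference 204 ion.
#' @param charges precursor charge states sampled uniformly.
#' @param n_peptides,o_peptides,n_glycans,o_glycans candidate pools the
#'   planted identities are drawn from.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L, n_n = 872L, n_o = 527L,
    n_ratio_medians = c(r138 = 0.8, r145 = 0.2, r163 = 0.2, r168 = 0.3,
                        r186 = 0.12, r274 = 0.1, r292 = 0.1, r325 = 0.2,
                        r366 = 0.5),
    o_ratio_medians = c(r138 = 0.4, r145 = 0.02, r163 = 0.02, r168 = 0.15,
                        r186 = 0.9, r274 = 0.5, r292 = 0.6, r325 = 0.02,
                        r366 = 0.15),
    ratio_sdlog = 0.3,
    by_efficiency = 0.7, y_efficiency = 0.8,
    by_intensity_scale = 5e4, y_intensity_scale = 1.5e5,
    n_noise_peaks = 30L, noise_intensity_scale = 5e3,
    mz_jitter_ppm = 5, base_intensity = 1e6,
    charges = c(2L, 3L),
    n_peptides = .SYNTH_N_PEPTIDES, o_peptides = .SYNTH_O_PEPTIDES,
    n_glycans = .SYNTH_N_GLYCANS, o_glycans = .SYNTH_O_GLYCANS) {
  .assert(all(n_ratio_medians > 0) && all(o_ratio_medians > 0),
          "ratio medians must be positive")
  .assert(ratio_sdlog >= 0, "ratio_sdlog must be >= 0")
  .assert(setequal(names(n_ratio_medians), .FEATURE_NAMES) &&
            setequal(names(o_ratio_medians), .FEATURE_NAMES),
          "ratio medians must be named r138 ... r366")
  structure(as.list(environment()), class = "generator_config")
}

#' Generate one synthetic glycopeptide HCD spectrum
#'
#' Draws from the RNG in its current state (seed control happens in
#' [generate_dataset()]). Emits oxonium ions at their exact m/z with the
#' class-conditional planted ratios (204 at `base_intensity`), a random
#' subset of b/y ions, a Y-ion ladder built by adding one residue at a
#' time (HexNAc, then Hex, Fuc, Neu5Ac), noise peaks, and applies
#' Gaussian ppm jitter to every m/z including the precursor.
#'
#' @param sequence peptide sequence.
#' @param glycan one-row composition data.frame.
#' @param glyco_type `"N"` or `"O"` (selects the ratio medians).
#' @param config a [generator_config()].
#' @param scan_id scan identifier for the emitted spectrum.
#' @return list with `spectrum` (an [ms2_spectrum]) and `truth` (one-row
#'   data.frame: identity plus the planted ratios).
#' @export
generate_spectrum <- function(sequence, glycan, glyco_type, config,
                              scan_id = "synth") {
  medians <- if (glyco_type == "N") config$n_ratio_medians else
    config$o_ratio_medians
  medians <- medians[.FEATURE_NAMES]
  ratios <- if (config$ratio_sdlog > 0) {
    stats::rlnorm(9L, meanlog = log(medians), sdlog = config$ratio_sdlog)
  } else {
    medians
  }
  names(ratios) <- .FEATURE_NAMES
  ions <- oxonium_ion_table()
  oxo_int <- numeric(nrow(ions))
  oxo_int[ions$nominal_mz == 204L] <- config$base_intensity
  oxo_int[ions$nominal_mz != 204L] <-
    ratios[paste0("r", ions$nominal_mz[ions$nominal_mz != 204L])] *
    config$base_intensity
  mz <- ions$exact_mz
  intensity <- oxo_int

  theo <- theoretical_ions(sequence, glycan, n_oxidations = 0L)
  by <- theo[theo$kind %in% c("b", "y"), , drop = FALSE]
  if (nrow(by) > 0) {
    keep <- stats::runif(nrow(by)) < config$by_efficiency
    by <- by[keep, , drop = FALSE]
    if (nrow(by) > 0) {
      mz <- c(mz, by$mz)
      intensity <- c(intensity, if (config$ratio_sdlog > 0) {
        stats::rlnorm(nrow(by), log(config$by_intensity_scale), 0.5)
      } else {
        rep(config$by_intensity_scale, nrow(by))
      })
    }
  }

  # Y ladder: strip the glycan one residue at a time (Neu5Ac, Fuc, Hex,
  # HexNAc removed last), i.e. emit peptide + 0..k leading residues
  pep_mass <- peptide_monoisotopic_mass(sequence)
  ladder_residues <- c(
    rep(.GLYCAN_RESIDUE_MASS[["HexNAc"]], glycan$n_hexnac),
    rep(.GLYCAN_RESIDUE_MASS[["Hex"]], glycan$n_hex),
    rep(.GLYCAN_RESIDUE_MASS[["Fuc"]], glycan$n_fuc),
    rep(.GLYCAN_RESIDUE_MASS[["NeuAc"]], glycan$n_neuac)
  )
  y_mz <- pep_mass + c(0, cumsum(ladder_residues)) + .PROTON_MASS
  keep <- stats::runif(length(y_mz)) < config$y_efficiency
  y_mz <- y_mz[keep]
  if (length(y_mz) > 0) {
    mz <- c(mz, y_mz)
    intensity <- c(intensity, if (config$ratio_sdlog > 0) {
      stats::rlnorm(length(y_mz), log(config$y_intensity_scale), 0.5)
    } else {
      rep(config$y_intensity_scale, length(y_mz))
    })
  }

  z <- if (length(config$charges) > 1L) sample(config$charges, 1L) else
    config$charges
  neutral <- pep_mass + glycan_mass(glycan)
  precursor_mz <- (neutral + z * .PROTON_MASS) / z

  if (config$n_noise_peaks > 0L) {
    noise_mz <- stats::runif(config$n_noise_peaks, 120, precursor_mz)
    mz <- c(mz, noise_mz)
    intensity <- c(intensity,
                   stats::rexp(config$n_noise_peaks,
                               rate = 1 / config$noise_intensity_scale))
  }

  if (config$mz_jitter_ppm > 0) {
    mz <- mz * (1 + stats::rnorm(length(mz)) * config$mz_jitter_ppm * 1e-6)
    precursor_mz <- precursor_mz *
      (1 + stats::rnorm(1L) * config$mz_jitter_ppm * 1e-6)
  }

  spectrum <- ms2_spectrum(scan_id, precursor_mz, z,
                           data.frame(mz = mz, intensity = intensity))
  truth <- cbind(
    data.frame(scan_id = scan_id, sequence = sequence,
               glycan = glycan$composition, glyco_type = glyco_type,
               precursor_charge = z, stringsAsFactors = FALSE),
    as.data.frame(as.list(ratios))
  )
  list(spectrum = spectrum, truth = truth)
}

#' Generate a labeled synthetic spectrum dataset
#'
#' Emits `n_n` N-linked and `n_o` O-linked spectra (planted identities
#' drawn uniformly from the config's peptide/glycan pools), together
#' with the ground-truth table, the measured oxonium feature table and
#' the class labels. Reproducible: the whole dataset is a deterministic
#' function of the config (including its seed).
#'
#' @param config a [generator_config()].
#' @param out_dir optional directory; when given, writes `spectra.mgf`,
#'   `truth.tsv`, `features.tsv` and `labels.tsv` there.
#' @return list with `spectra` (list of [ms2_spectrum]), `truth`
#'   (data.frame, one row per spectrum), `features` (measured feature
#'   table; a rare spectrum whose 204 reference peak jitters out of the
#'   matching window is unclassifiable and is omitted here) and `labels`
#'   (character vector aligned with `features`).
#' @export
generate_dataset <- function(config = generator_config(), out_dir = NULL) {
  plan <- data.frame(
    glyco_type = rep(c("N", "O"), c(config$n_n, config$n_o)),
    stringsAsFactors = FALSE
  )
  results <- .with_seed(config$seed, {
    lapply(seq_len(nrow(plan)), function(i) {
      type <- plan$glyco_type[i]
      pep <- if (type == "N") config$n_peptides else config$o_peptides
      gly <- if (type == "N") config$n_glycans else config$o_glycans
      sequence <- if (length(pep) > 1L) sample(pep, 1L) else pep
      glycan <- parse_composition(if (length(gly) > 1L) sample(gly, 1L) else gly)
      generate_spectrum(sequence, glycan, type, config,
                        scan_id = sprintf("synth_%s_%05d", type, i))
    })
  })
  spectra <- lapply(results, `[[`, "spectrum")
  truth <- if (length(results) > 0) {
    do.call(rbind, lapply(results, `[[`, "truth"))
  } else {
    data.frame(scan_id = character(0), sequence = character(0),
               glycan = character(0), glyco_type = character(0))
  }
  rows <- lapply(spectra, function(s) {
    # under m/z jitter a rare spectrum can lose its 204 reference peak;
    # such spectra are unclassifiable and are left out of the feature
    # table (their truth rows remain)
    f <- tryCatch(extract_features(s, preprocess = TRUE),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    cbind(data.frame(scan_id = s$scan_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(f$ratios)),
          data.frame(i204 = f$intensity_204))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  features <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    as.data.frame(stats::setNames(
      c(list(character(0)), rep(list(numeric(0)), 10L)),
      c("scan_id", .FEATURE_NAMES, "i204")
    ))
  }
  labels <- truth$glyco_type[match(features$scan_id, truth$scan_id)]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mgf(spectra, file.path(out_dir, "spectra.mgf"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(features, file.path(out_dir, "features.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(scan_id = features$scan_id, label = labels),
      file.path(out_dir, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  }
  list(spectra = spectra, truth = truth, features = features,
       labels = labels)
}

#' Search databases matching the generator's planted pools
#'
#' Builds a `glyco_databases` bundle whose target peptides and glycan
#' compositions are the generator's pools, so searches over generated
#' spectra can be checked against the planted truth.
#'
#' @param config a [generator_config()].
#' @param decoy_seed seed for the shuffle-decoy set.
#' @return a `glyco_databases` object.
#' @export
synth_search_databases <- function(config = generator_config(),
                                   decoy_seed = 1L) {
  seqs <- c(config$n_peptides, config$o_peptides)
  ids <- rep(c("SYN_N", "SYN_O"),
             c(length(config$n_peptides), length(config$o_peptides)))
  peptides <- .annotate_peptides(.peptide_entry_df(
    seqs, ids, rep(NA_integer_, length(seqs)),
    rep(0L, length(seqs)), rep(0L, length(seqs))
  ))
  n_gly <- do.call(rbind, lapply(config$n_glycans, parse_composition))
  o_gly <- do.call(rbind, lapply(config$o_glycans, parse_composition))
  build_glyco_databases(peptides, n_gly, o_gly, decoy_seed = decoy_seed)
}
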