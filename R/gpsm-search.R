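#' Search configuration
#'
#' Bundles the tolerances and filters of a glycopeptide search: 10 ppm
#' precursor (MS1) and 20 ppm fragment (MS2) tolerances, 1% FDR, the
#' oxonium filter fraction (top 5% of peaks; serum searches relax to top
#' 10%), the mandatory-204 rule, and the intact-peptide-ion rule for
#' short peptides. `serum_mode = TRUE` applies the serum relaxations
#' (top fraction 0.10, intact-ion rule disabled).
#'
#' @param ms1_tol_ppm precursor mass tolerance (ppm).
#' @param ms2_tol_ppm fragment mass tolerance (ppm).
#' @param fdr target false discovery rate, in (0, 1).
#' @param top_fraction oxonium-filter peak fraction.
#' @param min_ions minimum oxonium ions in the top peaks.
#' @param require_204 is the 204 ion mandatory?
#' @param min_peptide_len_requiring_intact_ion peptides shorter than this
#'   must have a matched intact peptide (Y-series) ion.
#' @param require_intact_ion apply the intact-ion rule at all?
#' @param mode `"conventional"` (search both glycan spaces) or
#'   `"preclassify"` (classify first, search the assigned space only).
#' @param serum_mode apply the serum-search relaxations?
#' @return list of class `search_config`.
#' @export
search_config <- function(ms1_tol_ppm = 10, ms2_tol_ppm = 20, fdr = 0.01,
                          top_fraction = 0.05, min_ions = 2L,
                          require_204 = TRUE,
                          min_peptide_len_requiring_intact_ion = 11L,
                          require_intact_ion = TRUE,
                          mode = c("conventional", "preclassify"),
                          serum_mode = FALSE) {
  mode <- match.arg(mode)
  .assert(ms1_tol_ppm > 0 && ms2_tol_ppm > 0, "tolerances must be positive")
  .assert(fdr > 0 && fdr < 1, "fdr must be in (0, 1)")
  if (serum_mode) {
    top_fraction <- 0.10
    require_intact_ion <- FALSE
  }
  structure(
    list(
      ms1_tol_ppm = ms1_tol_ppm, ms2_tol_ppm = ms2_tol_ppm, fdr = fdr,
      top_fraction = top_fraction, min_ions = min_ions,
      require_204 = require_204,
      min_peptide_len_requiring_intact_ion = min_peptide_len_requiring_intact_ion,
      require_intact_ion = require_intact_ion,
      mode = mode, serum_mode = serum_mode
    ),
    class = "search_config"
  )
}

# flat (peptide x glycan) candidate index over one glycan space.
# N-glycans pair only with sequon-bearing peptides, O-glycans only with
# S/T-bearing peptides; decoy sequences are gated by the same rules.
.candidate_pairs <- function(peptides, glycans, glyco_type, is_decoy) {
  eligible <- if (glyco_type == "N") peptides$has_n_motif else peptides$has_st
  pep <- peptides[eligible, , drop = FALSE]
  if (nrow(pep) == 0L || nrow(glycans) == 0L) return(NULL)
  gmass <- glycans$mass
  data.frame(
    sequence = rep(pep$sequence, times = nrow(glycans)),
    protein_id = rep(pep$protein_id, times = nrow(glycans)),
    start = rep(pep$start, times = nrow(glycans)),
    n_oxidations = rep(pep$n_oxidations, times = nrow(glycans)),
    peptide_mass = rep(pep$monoisotopic_mass, times = nrow(glycans)),
    glycan = rep(glycans$composition, each = nrow(pep)),
    n_hexnac = rep(glycans$n_hexnac, each = nrow(pep)),
    n_hex = rep(glycans$n_hex, each = nrow(pep)),
    n_fuc = rep(glycans$n_fuc, each = nrow(pep)),
    n_neuac = rep(glycans$n_neuac, each = nrow(pep)),
    glycan_mass = rep(gmass, each = nrow(pep)),
    glyco_type = glyco_type,
    is_decoy = is_decoy,
    stringsAsFactors = FALSE
  )
}

.candidate_index <- function(dbs) {
  idx <- rbind(
    .candidate_pairs(dbs$peptides, dbs$n_glycans, "N", FALSE),
    .candidate_pairs(dbs$peptides, dbs$o_glycans, "O", FALSE),
    .candidate_pairs(dbs$decoy_peptides, dbs$n_glycans, "N", TRUE),
    .candidate_pairs(dbs$decoy_peptides, dbs$o_glycans, "O", TRUE)
  )
  .assert(!is.null(idx) && nrow(idx) > 0, "no eligible peptide-glycan pairs")
  idx$total_mass <- idx$peptide_mass + idx$glycan_mass
  idx <- idx[order(idx$total_mass), , drop = FALSE]
  rownames(idx) <- NULL
  idx
}

.index_window <- function(idx, neutral_mass, ms1_tol_ppm, types) {
  delta <- neutral_mass * ms1_tol_ppm * 1e-6
  lo <- findInterval(neutral_mass - delta, idx$total_mass, left.open = TRUE) + 1L
  hi <- findInterval(neutral_mass + delta, idx$total_mass)
  if (lo > hi) return(idx[0L, , drop = FALSE])
  out <- idx[lo:hi, , drop = FALSE]
  out[out$glyco_type %in% types, , drop = FALSE]
}

#' Candidate glycopeptides for a precursor mass
#'
#' All (peptide, glycan composition) pairs whose summed monoisotopic mass
#' falls within `ms1_tol_ppm` of the observed neutral precursor mass.
#' N-glycan pairings require a sequon-bearing peptide, O-glycan pairings
#' an S/T-bearing peptide; decoy peptides are paired under the same rules.
#'
#' @param neutral_mass observed neutral precursor mass (Da), e.g. from
#'   [precursor_neutral_mass()].
#' @param dbs a `glyco_databases` bundle from [build_glyco_databases()].
#' @param glyco_type_filter `"N"`, `"O"` or `"both"`.
#' @param ms1_tol_ppm precursor tolerance (ppm).
#' @param include_decoys include decoy pairings?
#' @return data.frame of candidates (peptide fields, glycan counts and
#'   composition string, `glyco_type`, `is_decoy`, `total_mass`).
#' @export
generate_candidates <- function(neutral_mass, dbs,
                                glyco_type_filter = c("both", "N", "O"),
                                ms1_tol_ppm = 10, include_decoys = TRUE) {
  glyco_type_filter <- match.arg(glyco_type_filter)
  types <- if (glyco_type_filter == "both") c("N", "O") else glyco_type_filter
  idx <- .candidate_index(dbs)
  out <- .index_window(idx, neutral_mass, ms1_tol_ppm, types)
  if (!include_decoys) out <- out[!out$is_decoy, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Theoretical fragment ions of a glycopeptide candidate
#'
#' Singly protonated b and y backbone ions (indices 1..len-1, with fixed
#' carbamidomethyl-Cys and the candidate's Met oxidations applied — the
#' oxidations are placed on the first methionines), plus the Y-ion
#' series: the intact peptide retaining every sub-composition of the
#' glycan, from Y0 (bare peptide) up to the full glycan. The Y series is
#' enumerated smallest-first and capped at `max_y` ions.
#'
#' @param sequence peptide sequence.
#' @param glycan one-row composition data.frame (or `NULL` for a bare
#'   peptide, which still yields Y0).
#' @param n_oxidations number of oxidized methionines.
#' @param carbamidomethyl fixed Cys modification.
#' @param max_y cap on the number of Y-series ions (default 400).
#' @return data.frame with columns `kind` (`"b"`, `"y"`, `"Y"`), `index`
#'   (fragment index, NA for Y), `glycan` (sub-composition string, NA for
#'   b/y), `mz`.
#' @export
theoretical_ions <- function(sequence, glycan = NULL, n_oxidations = 0L,
                             carbamidomethyl = TRUE, max_y = 400L) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  res <- unname(.AA_MASS[aa])
  if (carbamidomethyl) res <- res + (aa == "C") * .CARBAMIDOMETHYL_MASS
  if (n_oxidations > 0L) {
    met <- which(aa == "M")
    .assert(length(met) >= n_oxidations,
            "n_oxidations exceeds the number of methionines")
    res[met[seq_len(n_oxidations)]] <- res[met[seq_len(n_oxidations)]] +
      .OXIDATION_MASS
  }
  pep_mass <- sum(res) + .WATER_MASS
  ions <- list()
  if (n >= 2L) {
    i <- seq_len(n - 1L)
    ions$b <- data.frame(kind = "b", index = i, glycan = NA_character_,
                         mz = cumsum(res)[i] + .PROTON_MASS,
                         stringsAsFactors = FALSE)
    ions$y <- data.frame(kind = "y", index = i, glycan = NA_character_,
                         mz = rev(cumsum(rev(res)))[n - i + 1L][i] +
                           .WATER_MASS + .PROTON_MASS,
                         stringsAsFactors = FALSE)
  }
  sub <- if (is.null(glycan)) {
    expand.grid(kn = 0L, kh = 0L, kf = 0L, ks = 0L)
  } else {
    expand.grid(kn = 0:glycan$n_hexnac, kh = 0:glycan$n_hex,
                kf = 0:glycan$n_fuc, ks = 0:glycan$n_neuac)
  }
  sub <- sub[order(sub$kn + sub$kh + sub$kf + sub$ks), , drop = FALSE]
  if (nrow(sub) > max_y) sub <- sub[seq_len(max_y), , drop = FALSE]
  gm <- sub$kn * .GLYCAN_RESIDUE_MASS[["HexNAc"]] +
    sub$kh * .GLYCAN_RESIDUE_MASS[["Hex"]] +
    sub$kf * .GLYCAN_RESIDUE_MASS[["Fuc"]] +
    sub$ks * .GLYCAN_RESIDUE_MASS[["NeuAc"]]
  ions$Y <- data.frame(
    kind = "Y", index = NA_integer_,
    glycan = sprintf("N%dH%dF%dS%d", sub$kn, sub$kh, sub$kf, sub$ks),
    mz = pep_mass + gm + .PROTON_MASS,
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, ions)
  rownames(out) <- NULL
  out
}

# peak indices (into the sorted peak list) lying within tol of any of the
# 10 oxonium ions
.oxonium_peak_idx <- function(spectrum, tol_ppm = 20) {
  ions <- oxonium_ion_table()
  mz <- spectrum$peaks$mz
  win <- .ppm_window(ions$exact_mz, tol_ppm)
  hits <- integer(0)
  for (i in seq_len(nrow(win))) {
    lo <- findInterval(win[i, "lo"], mz, left.open = TRUE) + 1L
    hi <- findInterval(win[i, "hi"], mz)
    if (lo <= hi) hits <- c(hits, lo:hi)
  }
  unique(hits)
}

#' Score a glycopeptide-spectral match (modified Morpheus score)
#'
#' Integer part: the number of distinct theoretical ions (b, y, and
#' intact-peptide Y ions with or without partial glycans) matched within
#' the fragment tolerance, each theoretical ion matching its nearest
#' in-tolerance peak. Fractional part: the fraction of spectrum intensity
#' explained by the matched peaks, computed after removing the oxonium
#' ion intensity from both numerator and denominator (each matched peak
#' counts once even when several ions hit it). Excluding the oxonium
#' intensity keeps the disproportionately intense oxonium ions of
#' N-glycopeptide spectra from dominating the score.
#'
#' @param spectrum a preprocessed [ms2_spectrum] (bottom 10% removed).
#' @param candidate one-row candidate data.frame from
#'   [generate_candidates()] (fields `sequence`, `n_oxidations`, glycan
#'   counts, `glyco_type`, `is_decoy`, ...).
#' @param ms2_tol_ppm fragment tolerance (ppm).
#' @return one-row data.frame: identification fields plus
#'   `n_matched_ions`, `intensity_fraction`, `score`
#'   (`n_matched_ions + intensity_fraction`), `total_spectrum_intensity`,
#'   `intensity_coverage`, `intact_ion_matched`, `peptide_length`.
#' @export
score_gpsm <- function(spectrum, candidate, ms2_tol_ppm = 20) {
  glycan <- data.frame(n_hexnac = candidate$n_hexnac, n_hex = candidate$n_hex,
                       n_fuc = candidate$n_fuc, n_neuac = candidate$n_neuac)
  ions <- theoretical_ions(candidate$sequence, glycan,
                           candidate$n_oxidations)
  mz <- spectrum$peaks$mz
  int <- spectrum$peaks$intensity
  hit <- .nearest_peak(mz, ions$mz, ms2_tol_ppm)
  n_matched <- sum(!is.na(hit))
  matched_peaks <- unique(hit[!is.na(hit)])
  oxo <- .oxonium_peak_idx(spectrum, ms2_tol_ppm)
  total <- sum(int)
  denom <- total - sum(int[oxo])
  num <- sum(int[setdiff(matched_peaks, oxo)])
  if (denom <= 0) {
    warning("spectrum intensity is entirely oxonium ions; ",
            "intensity fraction set to 0")
    fraction <- 0
  } else {
    fraction <- num / denom
  }
  data.frame(
    scan_id = spectrum$scan_id,
    sequence = candidate$sequence,
    protein_id = candidate$protein_id,
    start = candidate$start,
    n_oxidations = candidate$n_oxidations,
    glycan = candidate$glycan,
    glycan_residues = candidate$n_hexnac + candidate$n_hex +
      candidate$n_fuc + candidate$n_neuac,
    glyco_type = candidate$glyco_type,
    is_decoy = candidate$is_decoy,
    n_matched_ions = n_matched,
    intensity_fraction = fraction,
    score = n_matched + fraction,
    total_spectrum_intensity = total,
    intensity_coverage = fraction,
    intact_ion_matched = any(ions$kind == "Y" & !is.na(hit)),
    peptide_length = nchar(candidate$sequence),
    stringsAsFactors = FALSE
  )
}

#' Intact-peptide-ion rule for short peptides
#'
#' For peptides shorter than `min_len` residues, a matched intact peptide
#' ion — the bare peptide or the peptide retaining a partial glycan (any
#' Y-series ion) — is mandatory. Longer peptides pass unconditionally.
#'
#' @param gpsm a scored GPSM row from [score_gpsm()].
#' @param min_len length threshold (default 11).
#' @return logical.
#' @export
passes_intact_ion_rule <- function(gpsm, min_len = 11L) {
  gpsm$peptide_length >= min_len | gpsm$intact_ion_matched
}

#' Target-decoy FDR filter
#'
#' Sweeps a descending score threshold over the per-spectrum best GPSMs,
#' estimating FDR at each cut as `#decoy / max(#target, 1)`, and accepts
#' the largest target set whose estimate does not exceed `fdr`. On tied
#' scores decoys are counted before targets (conservative).
#'
#' @param gpsms data.frame of scored GPSMs (one row per spectrum —
#'   its top match), with `score` and `is_decoy` columns.
#' @param fdr acceptable FDR (default 0.01).
#' @return list with `accepted` (target rows passing), `threshold`
#'   (lowest accepted score; `Inf` when nothing passes) and
#'   `n_decoys_above` (decoys at or above the threshold).
#' @export
fdr_filter <- function(gpsms, fdr = 0.01) {
  if (nrow(gpsms) == 0L || !any(!gpsms$is_decoy)) {
    return(list(accepted = gpsms[0L, , drop = FALSE], threshold = Inf,
                n_decoys_above = 0L))
  }
  ord <- order(-gpsms$score, -as.integer(gpsms$is_decoy))
  g <- gpsms[ord, , drop = FALSE]
  cum_decoy <- cumsum(g$is_decoy)
  cum_target <- cumsum(!g$is_decoy)
  est <- cum_decoy / pmax(cum_target, 1L)
  ok <- which(est <= fdr)
  if (length(ok) == 0L) {
    return(list(accepted = gpsms[0L, , drop = FALSE], threshold = Inf,
                n_decoys_above = 0L))
  }
  k <- max(ok)
  prefix <- g[seq_len(k), , drop = FALSE]
  accepted <- prefix[!prefix$is_decoy, , drop = FALSE]
  rownames(accepted) <- NULL
  list(accepted = accepted, threshold = min(accepted$score),
       n_decoys_above = cum_decoy[k])
}

#' Curate high-confidence training GPSMs
#'
#' Applies the training-set quality filters to FDR-accepted GPSMs: the
#' peptide must overlap a known glycosylation site, intensity coverage
#' must be at least `min_coverage` (default 10%), total spectrum
#' intensity at least `min_total_intensity` (default 5e5), and O-linked
#' GPSMs must sit on peptides lacking any N-sequon (so their class label
#' cannot be confounded).
#'
#' @param gpsms data.frame of scored, FDR-accepted target GPSMs.
#' @param known_glycosites data.frame with columns `protein_id` and
#'   `position` (1-based protein coordinate of the modified residue).
#' @param min_coverage minimum intensity coverage.
#' @param min_total_intensity minimum summed spectrum intensity.
#' @return the filtered GPSM data.frame.
#' @export
curate_training_gpsms <- function(gpsms, known_glycosites,
                                  min_coverage = 0.10,
                                  min_total_intensity = 5e5) {
  if (nrow(gpsms) == 0L) return(gpsms)
  overlaps <- vapply(seq_len(nrow(gpsms)), function(i) {
    s <- gpsms$start[i]
    if (is.na(s)) return(FALSE)
    e <- s + gpsms$peptide_length[i] - 1L
    any(known_glycosites$protein_id == gpsms$protein_id[i] &
          known_glycosites$position >= s & known_glycosites$position <= e)
  }, logical(1))
  o_clean <- gpsms$glyco_type != "O" |
    !vapply(gpsms$sequence, function(s) length(find_n_motifs(s)) > 0,
            logical(1))
  keep <- overlaps &
    gpsms$intensity_coverage >= min_coverage &
    gpsms$total_spectrum_intensity >= min_total_intensity &
    o_clean
  out <- gpsms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run a glycopeptide search
#'
#' End-to-end identification: preprocesses each spectrum (bottom 10% of
#' peaks removed), keeps oxonium-ion-containing spectra, generates
#' precursor-mass-matched candidates, scores them with the modified
#' Morpheus score, applies the intact-ion rule, keeps the best GPSM per
#' spectrum and controls FDR against the shuffle decoys.
#'
#' In `"conventional"` mode every oxonium spectrum is searched against
#' both the N- and O-glycan spaces. In `"preclassify"` mode the fitted
#' classifier assigns each spectrum a glycosylation type first and only
#' that space is searched — roughly halving the search work.
#'
#' @param spectra list of [ms2_spectrum] objects.
#' @param dbs a `glyco_databases` bundle.
#' @param config a [search_config()].
#' @param model a fitted `glyco_logit`; required in preclassify mode.
#' @return object of class `gpsm_search_report`: `gpsms` (FDR-accepted
#'   target GPSMs), `top_gpsms` (per-spectrum best, targets and decoys),
#'   `threshold`, `per_spectrum` (scan-level log: searched spaces,
#'   candidate counts, classifier call), and `summary` (assigned
#'   spectra, unique glycopeptides, peptide backbones, glycan
#'   compositions).
#' @export
run_search <- function(spectra, dbs, config = search_config(), model = NULL) {
  if (config$mode == "preclassify" && is.null(model)) {
    stop("preclassify mode requires a fitted classifier model", call. = FALSE)
  }
  idx <- .candidate_index(dbs)
  top_rows <- list()
  log_rows <- list()
  for (s in spectra) {
    s2 <- remove_bottom_fraction(s, 0.10)
    if (!is_oxonium_spectrum(s2, config$top_fraction, config$min_ions,
                             config$require_204, config$ms2_tol_ppm)) {
      next
    }
    call <- NA_character_
    prob <- NA_real_
    if (config$mode == "preclassify") {
      feats <- tryCatch(
        extract_features(s2, config$ms2_tol_ppm, preprocess = FALSE),
        error = function(e) NULL
      )
      if (!is.null(feats)) {
        pr <- predict(model, feats)
        call <- pr$call
        prob <- pr$probability
        types <- call
      } else {
        types <- c("N", "O")
      }
    } else {
      types <- c("N", "O")
    }
    nm <- precursor_neutral_mass(s2)
    cand <- .index_window(idx, nm, config$ms1_tol_ppm, types)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      scan_id = s2$scan_id,
      searched_n = "N" %in% types, searched_o = "O" %in% types,
      n_candidates = nrow(cand), classifier_call = call,
      classifier_probability = prob, stringsAsFactors = FALSE
    )
    if (nrow(cand) == 0L) next
    scored <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      score_gpsm(s2, cand[i, , drop = FALSE], config$ms2_tol_ppm)
    }))
    if (config$require_intact_ion) {
      scored <- scored[
        passes_intact_ion_rule(scored,
                               config$min_peptide_len_requiring_intact_ion),
        , drop = FALSE
      ]
    }
    if (nrow(scored) == 0L) next
    # best per spectrum; ties: decoy over target (conservative), then
    # smaller glycan, then lexicographic peptide
    ord <- order(-scored$score, -as.integer(scored$is_decoy),
                 scored$glycan_residues, scored$sequence)
    top_rows[[length(top_rows) + 1L]] <- scored[ord[1L], , drop = FALSE]
  }
  top <- if (length(top_rows) > 0) do.call(rbind, top_rows) else
    idx[0L, , drop = FALSE]
  fdr_res <- if (nrow(top) > 0) fdr_filter(top, config$fdr) else
    list(accepted = top, threshold = Inf, n_decoys_above = 0L)
  acc <- fdr_res$accepted
  per_spectrum <- if (length(log_rows) > 0) do.call(rbind, log_rows) else NULL
  structure(
    list(
      gpsms = acc,
      top_gpsms = top,
      threshold = fdr_res$threshold,
      n_decoys_above = fdr_res$n_decoys_above,
      per_spectrum = per_spectrum,
      config = config,
      summary = list(
        assigned_spectra = nrow(acc),
        unique_glycopeptides = if (nrow(acc))
          length(unique(paste(acc$sequence, acc$glycan))) else 0L,
        peptide_backbones = if (nrow(acc))
          length(unique(acc$sequence)) else 0L,
        glycan_compositions = if (nrow(acc))
          length(unique(acc$glycan)) else 0L
      )
    ),
    class = "gpsm_search_report"
  )
}

#' @export
print.gpsm_search_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<gpsm_search_report> %s mode: %d assigned spectra, ",
           "%d unique glycopeptides (%d backbones, %d compositions) at ",
           "%.0f%% FDR\n"),
    x$config$mode, s$assigned_spectra, s$unique_glycopeptides,
    s$peptide_backbones, s$glycan_compositions, 100 * x$config$fdr
  ))
  invisible(x)
}

#' Write GPSM results to TSV
#'
#' @param report a `gpsm_search_report`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gpsm_tsv <- function(report, path) {
  utils::write.table(report$gpsms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
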