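#' Monoisotopic mass of a peptide
#'
#' Sum of residue monoisotopic masses plus water, with fixed
#' carbamidomethylation (+57.021464 Da) on every cysteine (iodoacetamide
#' alkylation) and variable methionine oxidation (+15.994915 Da each).
#'
#' @param sequence peptide sequence, uppercase standard one-letter codes.
#' @param n_oxidations number of oxidized methionines (must not exceed the
#'   number of M residues).
#' @param carbamidomethyl apply the fixed Cys modification? Default `TRUE`.
#' @return monoisotopic mass in Da.
#' @examples
#' peptide_monoisotopic_mass("G")   # 75.032028
#' peptide_monoisotopic_mass("C")   # 178.041213 (Cys + CAM + water)
#' @export
peptide_monoisotopic_mass <- function(sequence, n_oxidations = 0L,
                                      carbamidomethyl = TRUE) {
  .assert(is.character(sequence) && length(sequence) == 1L && nzchar(sequence),
          "`sequence` must be a nonempty string")
  aa <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(aa, names(.AA_MASS))
  if (length(unknown) > 0) {
    stop("unknown residue(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  }
  n_met <- sum(aa == "M")
  .assert(n_oxidations <= n_met,
          "n_oxidations exceeds the number of methionines")
  mass <- sum(.AA_MASS[aa]) + .WATER_MASS + n_oxidations * .OXIDATION_MASS
  if (carbamidomethyl) mass <- mass + sum(aa == "C") * .CARBAMIDOMETHYL_MASS
  unname(mass)
}

#' Find N-glycosylation sequons
#'
#' Scans for the consensus motif N-X-\[S/T/C/V\] where X is any residue
#' except proline. Returns 1-based positions of the motif asparagine.
#'
#' @param sequence peptide or protein sequence.
#' @return integer vector of sequon start positions (possibly empty).
#' @examples
#' find_n_motifs("LNDSR")  # 2 (NDS)
#' find_n_motifs("NPS")    # none: X may not be proline
#' @export
find_n_motifs <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 3L) return(integer(0))
  i <- seq_len(n - 2L)
  i[aa[i] == "N" & aa[i + 1L] != "P" & aa[i + 2L] %in% c("S", "T", "C", "V")]
}

.valid_sequence <- function(sequence) {
  nzchar(sequence) && !grepl(paste0("[^", paste(names(.AA_MASS), collapse = ""), "]"),
                             sequence)
}

.peptide_entry_df <- function(sequence, protein_id, start, missed, n_ox,
                              carbamidomethyl = TRUE) {
  data.frame(
    sequence = sequence,
    protein_id = protein_id,
    start = start,
    missed_cleavages = missed,
    n_oxidations = n_ox,
    monoisotopic_mass = vapply(
      seq_along(sequence),
      function(i) peptide_monoisotopic_mass(sequence[i], n_ox[i], carbamidomethyl),
      numeric(1)
    ),
    stringsAsFactors = FALSE
  )
}

.annotate_peptides <- function(df) {
  df$n_motifs <- I(lapply(df$sequence, find_n_motifs))
  df$has_n_motif <- lengths(df$n_motifs) > 0L
  df$has_st <- grepl("[ST]", df$sequence)
  df
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K/R except before proline, emitting every peptide
#' with up to `max_missed` missed cleavages inside the length window, each
#' expanded into variants with 0..`max_ox` oxidized methionines. Sequences
#' containing non-standard residues are skipped with a warning.
#'
#' @param protein_sequence protein sequence (one-letter codes).
#' @param protein_id identifier carried into the output.
#' @param max_missed maximum missed cleavages (default 2).
#' @param max_ox maximum variable Met oxidations per peptide (default 2).
#' @param min_len,max_len peptide length window (defaults 5 and 70).
#' @param carbamidomethyl fixed Cys carbamidomethylation (default `TRUE`).
#' @return data.frame of peptide entries: `sequence`, `protein_id`,
#'   `start` (1-based position in the protein), `missed_cleavages`,
#'   `n_oxidations`, `monoisotopic_mass`, plus sequon annotations
#'   (`n_motifs` list column, `has_n_motif`, `has_st`).
#' @export
tryptic_digest <- function(protein_sequence, protein_id = "protein",
                           max_missed = 2L, max_ox = 2L,
                           min_len = 5L, max_len = 70L,
                           carbamidomethyl = TRUE) {
  if (!.valid_sequence(protein_sequence)) {
    warning("skipping sequence with non-standard residues: ", protein_id)
    return(.annotate_peptides(.peptide_entry_df(
      character(0), character(0), integer(0), integer(0), integer(0)
    )))
  }
  aa <- strsplit(protein_sequence, "")[[1]]
  n <- length(aa)
  # cleavage points: after position i when aa[i] in {K,R} and aa[i+1] != P
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)  # segment boundaries
  n_seg <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(n_seg)) {
    for (m in 0:min(max_missed, n_seg - i)) {
      from <- bounds[i] + 1L
      to <- bounds[i + 1L + m]
      len <- to - from + 1L
      if (len < min_len || len > max_len) next
      seq_i <- paste(aa[from:to], collapse = "")
      n_met <- sum(aa[from:to] == "M")
      for (ox in 0:min(max_ox, n_met)) {
        rows[[length(rows) + 1L]] <-
          .peptide_entry_df(seq_i, protein_id, from, m, ox, carbamidomethyl)
      }
    }
  }
  out <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    .peptide_entry_df(character(0), character(0), integer(0), integer(0),
                      integer(0))
  }
  rownames(out) <- NULL
  .annotate_peptides(out)
}

#' Read proteins from a FASTA file
#'
#' UniProt-style headers are parsed: when the record name is
#' pipe-delimited (`db|ACCESSION|NAME`), the accession is used as the
#' protein identifier.
#'
#' @param path FASTA file path.
#' @return named character vector of protein sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("FASTA reading requires the Biostrings package", call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1)
  parts <- strsplit(ids, "|", fixed = TRUE)
  ids <- vapply(parts, function(p) if (length(p) >= 2) p[2] else p[1],
                character(1))
  stats::setNames(toupper(as.character(aa)), ids)
}

#' Glycan composition
#'
#' Counts of the four residue classes searched here: HexNAc (N), hexose
#' (H), fucose/deoxyhexose (F) and Neu5Ac sialic acid (S). Canonical text
#' form is `"N{n}H{h}F{f}S{s}"`.
#'
#' @param n_hexnac,n_hex,n_fuc,n_neuac nonnegative residue counts; at
#'   least one must be positive.
#' @return one-row data.frame with the four counts and a `composition`
#'   string column.
#' @export
glycan_composition <- function(n_hexnac = 0L, n_hex = 0L, n_fuc = 0L,
                               n_neuac = 0L) {
  counts <- c(n_hexnac, n_hex, n_fuc, n_neuac)
  .assert(all(counts >= 0) && all(counts == round(counts)),
          "residue counts must be nonnegative integers")
  .assert(sum(counts) > 0, "empty glycan composition")
  data.frame(
    n_hexnac = as.integer(n_hexnac), n_hex = as.integer(n_hex),
    n_fuc = as.integer(n_fuc), n_neuac = as.integer(n_neuac),
    composition = format_composition(n_hexnac, n_hex, n_fuc, n_neuac),
    stringsAsFactors = FALSE
  )
}

#' @rdname glycan_composition
#' @export
format_composition <- function(n_hexnac, n_hex, n_fuc, n_neuac) {
  sprintf("N%dH%dF%dS%d", n_hexnac, n_hex, n_fuc, n_neuac)
}

#' Parse a canonical glycan composition string
#'
#' @param text composition string such as `"N4H5F0S1"`.
#' @return one-row data.frame as returned by [glycan_composition()].
#' @examples
#' parse_composition("N3H3F0S1")
#' @export
parse_composition <- function(text) {
  m <- regmatches(text, regexec("^N([0-9]+)H([0-9]+)F([0-9]+)S([0-9]+)$", text))[[1]]
  if (length(m) != 5L) {
    stop("malformed glycan composition string: ", text, call. = FALSE)
  }
  counts <- as.integer(m[-1])
  glycan_composition(counts[1], counts[2], counts[3], counts[4])
}

#' Monoisotopic mass of a glycan composition
#'
#' Sum of anhydro residue masses: HexNAc 203.079373, Hex 162.052824,
#' Fuc 146.057909, Neu5Ac 291.095417 Da.
#'
#' @param comp data.frame of compositions (columns `n_hexnac`, `n_hex`,
#'   `n_fuc`, `n_neuac`), e.g. from [parse_composition()]; vectorized over
#'   rows.
#' @return numeric vector of masses in Da.
#' @export
glycan_mass <- function(comp) {
  comp$n_hexnac * .GLYCAN_RESIDUE_MASS[["HexNAc"]] +
    comp$n_hex * .GLYCAN_RESIDUE_MASS[["Hex"]] +
    comp$n_fuc * .GLYCAN_RESIDUE_MASS[["Fuc"]] +
    comp$n_neuac * .GLYCAN_RESIDUE_MASS[["NeuAc"]]
}

#' Read a glycan composition database
#'
#' Accepts either a TSV with header columns `N H F S` or a file with one
#' canonical composition string (`N#H#F#S#`) per line.
#'
#' @param path input file.
#' @return data.frame of compositions with a `mass` column.
#' @export
read_glycan_db <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^N\\s+H\\s+F\\s+S", first) || grepl("^N\tH\tF\tS", first)) {
    tab <- utils::read.table(path, header = TRUE, colClasses = "integer")
    comps <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
      glycan_composition(tab$N[i], tab$H[i], tab$F[i], tab$S[i])
    }))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines[nzchar(trimws(lines))])
    comps <- do.call(rbind, lapply(lines, parse_composition))
  }
  comps$mass <- glycan_mass(comps)
  comps
}

#' Generate shuffle decoy peptides
#'
#' Concatenates every target sequence, shuffles the pooled amino acids
#' with a seeded RNG, and cuts the shuffled string back into peptides
#' whose lengths are exactly the target length multiset. The pooled
#' amino-acid composition of the decoy set therefore equals the target
#' set's exactly. Decoy entries carry `protein_id = "DECOY"`, no protein
#' coordinate and no oxidation.
#'
#' @param targets peptide data.frame from [tryptic_digest()] (only the
#'   `sequence` column is used).
#' @param seed integer RNG seed; the same seed reproduces the same decoys.
#' @param carbamidomethyl fixed Cys modification for decoy masses.
#' @return data.frame of decoy peptide entries, same number of rows as
#'   `targets`.
#' @export
generate_decoy_peptides <- function(targets, seed,
                                    carbamidomethyl = TRUE) {
  .assert(nrow(targets) > 0, "target peptide list is empty")
  pool <- strsplit(paste(targets$sequence, collapse = ""), "")[[1]]
  shuffled <- .with_seed(seed, sample(pool))
  lens <- nchar(targets$sequence)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  decoy_seq <- vapply(seq_along(lens), function(i) {
    paste(shuffled[starts[i]:ends[i]], collapse = "")
  }, character(1))
  out <- .peptide_entry_df(decoy_seq, "DECOY", NA_integer_, 0L,
                           rep(0L, length(decoy_seq)), carbamidomethyl)
  .annotate_peptides(out)
}

#' Assemble target/decoy peptide and glycan databases
#'
#' Digests the supplied proteins, builds the shuffle-decoy peptide set and
#' attaches the N- and O-glycan composition tables, producing the search
#' database bundle used by [run_search()].
#'
#' @param proteins named character vector of protein sequences (e.g. from
#'   [read_protein_fasta()]), or an already-digested peptide data.frame.
#' @param n_glycans,o_glycans glycan composition data.frames (e.g. from
#'   [read_glycan_db()] or [parse_composition()]).
#' @param decoy_seed seed for decoy generation.
#' @param ... passed to [tryptic_digest()].
#' @return object of class `glyco_databases`: list with `peptides`,
#'   `decoy_peptides`, `n_glycans`, `o_glycans`.
#' @export
build_glyco_databases <- function(proteins, n_glycans, o_glycans,
                                  decoy_seed = 1L, ...) {
  peptides <- if (is.data.frame(proteins)) {
    proteins
  } else {
    ids <- names(proteins)
    if (is.null(ids)) ids <- paste0("protein", seq_along(proteins))
    do.call(rbind, lapply(seq_along(proteins), function(i) {
      tryptic_digest(proteins[[i]], ids[i], ...)
    }))
  }
  .assert(nrow(peptides) > 0, "digestion produced no peptides")
  if (is.null(n_glycans$mass)) n_glycans$mass <- glycan_mass(n_glycans)
  if (is.null(o_glycans$mass)) o_glycans$mass <- glycan_mass(o_glycans)
  structure(
    list(
      peptides = peptides,
      decoy_peptides = generate_decoy_peptides(peptides, decoy_seed),
      n_glycans = n_glycans,
      o_glycans = o_glycans
    ),
    class = "glyco_databases"
  )
}

#' @export
print.glyco_databases <- function(x, ...) {
  cat(sprintf(
    "<glyco_databases> %d target / %d decoy peptides; %d N-glycans, %d O-glycans\n",
    nrow(x$peptides), nrow(x$decoy_peptides),
    nrow(x$n_glycans), nrow(x$o_glycans)
  ))
  invisible(x)
}
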