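# Monoisotopic mass bookkeeping used throughout the package.
# All masses in Da; m/z in Th. Values derived from CODATA/IUPAC atomic masses.

.atomic_mass <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

.ELECTRON_MASS <- 0.00054857990946
.PROTON_MASS <- 1.007276

.WATER_MASS <- 2 * .atomic_mass[["H"]] + .atomic_mass[["O"]]          # 18.010565
.OXIDATION_MASS <- .atomic_mass[["O"]]                                 # 15.994915
.CARBAMIDOMETHYL_MASS <- 57.021464                                     # iodoacetamide on Cys

# residue (i.e. dehydrated) elemental formulas of the 20 standard amino acids
.aa_formula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

.formula_mass <- function(counts) {
  sum(.atomic_mass[names(counts)] * counts)
}

# named vector of residue monoisotopic masses
.AA_MASS <- vapply(.aa_formula, .formula_mass, numeric(1))

# glycan residue (anhydro) monoisotopic masses
.GLYCAN_RESIDUE_MASS <- c(
  HexNAc = .formula_mass(c(C = 8, H = 13, N = 1, O = 5)),   # 203.079373
  Hex    = .formula_mass(c(C = 6, H = 10, O = 5)),          # 162.052824
  Fuc    = .formula_mass(c(C = 6, H = 10, O = 4)),          # 146.057909
  NeuAc  = .formula_mass(c(C = 11, H = 17, N = 1, O = 8))   # 291.095417
)

.ppm_window <- function(mz, tol_ppm) {
  delta <- mz * tol_ppm * 1e-6
  cbind(lo = mz - delta, hi = mz + delta)
}
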