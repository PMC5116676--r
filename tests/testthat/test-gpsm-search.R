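make_candidate <- function(sequence, comp_txt, glyco_type = "N",
                           is_decoy = FALSE, n_ox = 0L) {
  comp <- parse_composition(comp_txt)
  data.frame(
    sequence = sequence, protein_id = "TEST", start = 1L,
    n_oxidations = n_ox, peptide_mass = peptide_monoisotopic_mass(sequence, n_ox),
    glycan = comp$composition, n_hexnac = comp$n_hexnac, n_hex = comp$n_hex,
    n_fuc = comp$n_fuc, n_neuac = comp$n_neuac, glycan_mass = glycan_mass(comp),
    glyco_type = glyco_type, is_decoy = is_decoy, stringsAsFactors = FALSE
  )
}

test_that("candidate generation matches precursor mass and motif gates", {
  prot <- c(FETUIN = "MKLCPDCPLLAPLNDSRAGKTTEAPSIRKAVLDK")
  ng <- rbind(parse_composition("N4H5F0S1"), parse_composition("N2H5F0S0"))
  og <- rbind(parse_composition("N1H1F0S1"), parse_composition("N2H2F0S1"))
  dbs <- build_glyco_databases(prot, ng, og, decoy_seed = 2L)

  nm <- peptide_monoisotopic_mass("LCPDCPLLAPLNDSR") +
    glycan_mass(parse_composition("N4H5F0S1"))
  cand <- generate_candidates(nm, dbs, "N")
  hit <- cand[!cand$is_decoy & cand$sequence == "LCPDCPLLAPLNDSR" &
                cand$glycan == "N4H5F0S1", ]
  expect_equal(nrow(hit), 1L)

  # 50 ppm off every pair: empty
  expect_equal(nrow(generate_candidates(nm * (1 + 50e-6), dbs, "both")), 0L)

  # peptides without a sequon are never paired with N-glycans, and
  # peptides without S/T never with O-glycans
  all_cand <- do.call(rbind, lapply(
    c(dbs$peptides$monoisotopic_mass + glycan_mass(ng)[1],
      dbs$peptides$monoisotopic_mass + glycan_mass(og)[1]),
    generate_candidates, dbs = dbs, glyco_type_filter = "both"
  ))
  n_side <- all_cand[all_cand$glyco_type == "N" & !all_cand$is_decoy, ]
  expect_true(all(vapply(n_side$sequence,
                         function(s) length(find_n_motifs(s)) > 0,
                         logical(1))))
  o_side <- all_cand[all_cand$glyco_type == "O" & !all_cand$is_decoy, ]
  expect_true(all(grepl("[ST]", o_side$sequence)))
})

test_that("theoretical ions enumerate b/y and the Y sub-composition series", {
  gk <- theoretical_ions("GK")
  expect_equal(nrow(gk), 3L)
  expect_setequal(gk$kind, c("b", "y", "Y"))
  expect_equal(gk$mz[gk$kind == "b"], 57.021464 + 1.007276, tolerance = 1e-5)
  expect_equal(gk$mz[gk$kind == "y"], 128.09496 + 18.010565 + 1.007276,
               tolerance = 1e-5)
  expect_equal(gk$mz[gk$kind == "Y"],
               57.021464 + 128.09496 + 18.010565 + 1.007276, tolerance = 1e-4)

  ions <- theoretical_ions("AGFNCSVEK", parse_composition("N2H1F0S0"))
  expect_equal(sum(ions$kind == "Y"), 6L)  # (2+1) x (1+1) sub-compositions
  expect_equal(sum(ions$kind == "b"), 8L)
  expect_equal(sum(ions$kind == "y"), 8L)  # y_len excluded: full peptide is Y0
  expect_false("N0H1F0S0" %in% ions$glycan[ions$kind == "Y"][1])  # Y0 first

  # oxidation shifts the ion series by 15.994915 per oxidized Met
  i0 <- theoretical_ions("SMVNITAGLK", parse_composition("N1H0F0S0"))
  i1 <- theoretical_ions("SMVNITAGLK", parse_composition("N1H0F0S0"),
                         n_oxidations = 1L)
  expect_equal(i1$mz[i1$kind == "Y" & i1$glycan == "N0H0F0S0"],
               i0$mz[i0$kind == "Y" & i0$glycan == "N0H0F0S0"] + 15.994915,
               tolerance = 1e-5)
  expect_equal(i1$mz[i1$kind == "b" & i1$index == 1],
               i0$mz[i0$kind == "b" & i0$index == 1])  # b1 = S, unshifted
})

test_that("the modified Morpheus score counts ions plus intensity fraction", {
  cand <- make_candidate("AGFNCSVEK", "N1H0F0S0")
  theo <- theoretical_ions(cand$sequence, parse_composition(cand$glycan))
  b2 <- theo$mz[theo$kind == "b" & theo$index == 2]
  y3 <- theo$mz[theo$kind == "y" & theo$index == 3]

  s <- toy_spectrum(c(b2, y3), c(300, 700))
  g <- score_gpsm(s, cand)
  expect_equal(g$n_matched_ions, 2L)
  expect_equal(g$score, 3.0)

  # unmatched noise carrying half the non-oxonium intensity
  s2 <- toy_spectrum(c(b2, y3, 900.77), c(300, 700, 1000))
  expect_equal(score_gpsm(s2, cand)$score, 2.5)

  # spectrum that is all oxonium ions: excluded intensity, zero score
  oxo <- oxonium_ion_table()
  s3 <- toy_spectrum(oxo$exact_mz, rep(100, 10))
  expect_warning(g3 <- score_gpsm(s3, cand), "oxonium")
  expect_equal(g3$score, 0.0)
})

test_that("scoring equals the brute-force oracle on random synthetic cases", {
  cfg <- generator_config(n_n = 10L, n_o = 10L, seed = 77L)
  d <- generate_dataset(cfg)
  set.seed(78)
  for (i in seq_along(d$spectra)) {
    s <- d$spectra[[i]]
    type <- d$truth$glyco_type[i]
    # the planted candidate plus one random wrong candidate
    cands <- list(
      make_candidate(d$truth$sequence[i], d$truth$glycan[i], type),
      make_candidate(sample(cfg$n_peptides, 1), sample(cfg$n_glycans, 1), "N")
    )
    for (cand in cands) {
      got <- score_gpsm(s, cand)
      want <- oracle_score(s, cand$sequence, parse_composition(cand$glycan))
      expect_equal(got$score, want, tolerance = 1e-9)
      expect_identical(floor(got$score), as.numeric(got$n_matched_ions))
    }
  }
})

test_that("the intact-ion rule gates only peptides shorter than 11 residues", {
  cand9 <- make_candidate("TGSSLVTK", "N1H1F0S1", "O")   # 8-mer
  theo <- theoretical_ions(cand9$sequence, parse_composition(cand9$glycan))
  y1_mz <- theo$mz[theo$kind == "Y" & theo$glycan == "N1H0F0S0"]
  with_y <- score_gpsm(toy_spectrum(c(y1_mz, 900), c(500, 100)), cand9)
  expect_true(passes_intact_ion_rule(with_y))
  b2 <- theo$mz[theo$kind == "b" & theo$index == 2]
  only_by <- score_gpsm(toy_spectrum(c(b2, 900), c(500, 100)), cand9)
  expect_false(passes_intact_ion_rule(only_by))

  cand15 <- make_candidate("LCPDCPLLAPLNDSR", "N2H5F0S0")  # 15-mer
  no_y <- score_gpsm(toy_spectrum(c(900.5), c(10)), cand15)
  expect_true(passes_intact_ion_rule(no_y))
})

test_that("target-decoy FDR accepts the largest clean prefix", {
  g <- data.frame(score = c(seq(100, 2, length.out = 99), 1),
                  is_decoy = c(rep(FALSE, 99), TRUE))
  res <- fdr_filter(g, 0.01)
  expect_equal(nrow(res$accepted), 99L)

  worst <- data.frame(score = c(10, 9, 2, 1), is_decoy = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(nrow(fdr_filter(worst, 0.01)$accepted), 0L)

  clean <- data.frame(score = c(5, 4, 3), is_decoy = FALSE)
  res2 <- fdr_filter(clean, 0.01)
  expect_equal(nrow(res2$accepted), 3L)
  expect_equal(res2$threshold, 3)

  # monotone: stricter fdr never accepts more
  set.seed(80)
  mixed <- data.frame(score = runif(300, 0, 10),
                      is_decoy = runif(300) < 0.3)
  sizes <- vapply(c(0.001, 0.01, 0.05, 0.2, 0.5),
                  function(q) nrow(fdr_filter(mixed, q)$accepted), numeric(1))
  expect_true(!is.unsorted(sizes))
})

test_that("training-set curation applies the quality and motif filters", {
  base <- data.frame(
    scan_id = "s", sequence = "TTEAPSIR", protein_id = "P1", start = 10L,
    glycan = "N1H1F0S1", glyco_type = "O", is_decoy = FALSE,
    intensity_coverage = 0.5, total_spectrum_intensity = 1e6,
    peptide_length = 8L, stringsAsFactors = FALSE
  )
  sites <- data.frame(protein_id = "P1", position = 12L)
  expect_equal(nrow(curate_training_gpsms(base, sites)), 1L)

  low_cov <- base; low_cov$intensity_coverage <- 0.09
  expect_equal(nrow(curate_training_gpsms(low_cov, sites)), 0L)

  low_int <- base; low_int$total_spectrum_intensity <- 4.9e5
  expect_equal(nrow(curate_training_gpsms(low_int, sites)), 0L)

  o_with_sequon <- base
  o_with_sequon$sequence <- "LNDSAIKT"; o_with_sequon$peptide_length <- 8L
  expect_equal(nrow(curate_training_gpsms(o_with_sequon, sites)), 0L)
  # the same peptide is fine when the GPSM is N-linked
  n_with_sequon <- o_with_sequon; n_with_sequon$glyco_type <- "N"
  expect_equal(nrow(curate_training_gpsms(n_with_sequon, sites)), 1L)

  off_site <- base; off_site$start <- 100L
  expect_equal(nrow(curate_training_gpsms(off_site, sites)), 0L)
})

test_that("search modes honor their space contracts and recover the truth", {
  cfg <- noiseless_config(n_n = 20L, n_o = 20L, seed = 41L)
  d <- generate_dataset(cfg)
  dbs <- synth_search_databases(cfg, decoy_seed = 4L)
  train <- generate_dataset(generator_config(n_n = 120L, n_o = 120L, seed = 42L))
  model <- suppressWarnings(train_classifier(train$features, train$labels))

  conv <- run_search(d$spectra, dbs, search_config(mode = "conventional"))
  pre <- run_search(d$spectra, dbs, search_config(mode = "preclassify"),
                    model = model)

  expect_true(all(conv$per_spectrum$searched_n & conv$per_spectrum$searched_o))
  expect_true(all(xor(pre$per_spectrum$searched_n, pre$per_spectrum$searched_o)))

  # preclassify never searches more candidates than conventional
  j <- merge(conv$per_spectrum, pre$per_spectrum, by = "scan_id")
  expect_true(all(j$n_candidates.y <= j$n_candidates.x))

  # noiseless planted identifications recovered at 1% FDR
  for (rep in list(conv, pre)) {
    hit <- merge(rep$gpsms, d$truth, by = "scan_id")
    correct <- hit$sequence.x == hit$sequence.y & hit$glycan.x == hit$glycan.y
    expect_gte(sum(correct) / length(d$spectra), 0.95)
    expect_false(any(rep$gpsms$is_decoy))
  }

  expect_error(run_search(d$spectra, dbs, search_config(mode = "preclassify")),
               "model")
})

test_that("serum mode relaxes the filter fraction and the intact-ion rule", {
  cfg <- search_config(serum_mode = TRUE)
  expect_equal(cfg$top_fraction, 0.10)
  expect_false(cfg$require_intact_ion)
  expect_equal(search_config()$top_fraction, 0.05)
})
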