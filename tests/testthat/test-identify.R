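lib <- build_species_library(default_species_panel())

test_that("candidate matching respects the ppm tolerance and ordering", {
  target <- lib[lib$name == "PC(16:0/18:1)", ]
  hits <- candidate_species(target$mz, "+", lib, tol_ppm = 10)
  expect_true(target$name %in% hits$name)
  expect_equal(hits$error_ppm[hits$name == target$name], 0, tolerance = 1e-9)
  expect_equal(hits$error_ppm, hits$error_ppm[order(abs(hits$error_ppm))])

  # offset by twice the tolerance: nothing matches
  off <- target$mz * (1 + 20e-6)
  expect_equal(nrow(candidate_species(off, "+", lib, tol_ppm = 10)), 0)

  # two exactly isobaric molecular species are both returned
  iso <- candidate_species(lib$mz[lib$name == "PC(16:1/18:1)"], "+", lib,
                           tol_ppm = 5)
  expect_true(all(c("PC(16:1/18:1)", "PC(16:0/18:2)") %in% iso$name))

  expect_error(candidate_species(700, "+", lib[0, ], 10),
               class = "EmptyLibrary")
})

test_that("tolerance shrinkage never enlarges the candidate set", {
  ms <- generate_msms(default_species_panel(), mass_error_ppm = 5,
                      decoy_fraction = 0, seed = 11)
  for (s in ms$spectra[seq(1, 123, by = 10)]) {
    prev <- Inf
    for (tol in c(20, 10, 5, 2)) {
      n <- nrow(candidate_species(s$precursor_mz, s$polarity, lib, tol))
      expect_lte(n, prev)
      prev <- n
    }
  }
})

test_that("confirmation requires class-diagnostic evidence", {
  rules <- fragmentation_rules()
  sp <- "PC(16:0/18:1)"
  prec <- lib$mz[lib$name == sp]
  frag <- expected_fragments(parse_lipid_name(sp), prec, rules)
  cand <- list(name = sp, adduct = "[M+H]+", error_ppm = 0)

  # spectrum with the phosphocholine head group and acyl evidence: confirmed
  good <- spectrum_record(prec, "+",
                          cbind(frag$mz[frag$role == "required"], 1000))
  hit <- confirm_hit(good, cand, rules)
  expect_equal(hit$status, "confirmed")
  expect_equal(hit$score, 1)

  # the diagnostic head-group ion is the C5H15NO4P+ cation
  expect_equal(min(abs(frag$mz - 184.0733)), 0, tolerance = 1e-3)

  # empty spectrum: rejected with score 0
  empty <- spectrum_record(prec, "+", matrix(numeric(0), ncol = 2))
  hit0 <- confirm_hit(empty, cand, rules)
  expect_equal(hit0$status, "rejected")
  expect_equal(hit0$score, 0)

  # decoy: right precursor, wrong class fragments -> rejected
  tg_frag <- expected_fragments(parse_lipid_name("TG(16:0/16:0/18:1)"), prec,
                                rules)
  decoy <- spectrum_record(prec, "+",
                           cbind(tg_frag$mz[tg_frag$role == "required"], 500))
  expect_equal(confirm_hit(decoy, cand, rules)$status, "rejected")

  # no rule for the class -> MissingRule
  expect_error(confirm_hit(good, cand, rules[rules$class != "PC", ]),
               class = "MissingRule")
})

test_that("dataset identification meets the benchmark and is deterministic", {
  ms <- generate_msms(default_species_panel(), mass_error_ppm = 5,
                      decoy_fraction = 0.2, seed = 7)
  hits <- identify_dataset(ms$spectra, lib)
  conf <- hits[hits$status == "confirmed", ]
  # at most one confirmed species per spectrum
  expect_lte(max(table(conf$spectrum)), 1)

  merged <- merge(conf, ms$truth, by.x = "spectrum", by.y = "title")
  tp <- sum(!merged$decoy & merged$species.x == merged$species.y)
  precision <- tp / nrow(conf)
  recall <- tp / sum(!ms$truth$decoy)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)

  # duplicate run gives identical hits (determinism)
  hits2 <- identify_dataset(ms$spectra, lib)
  expect_identical(as.data.frame(hits), as.data.frame(hits2))

  # near-zero tolerance with nonzero mass noise: no confirmations
  tiny <- identify_dataset(ms$spectra[1:20], lib, tol_ppm = 1e-6)
  expect_equal(sum(tiny$status == "confirmed"), 0)
})

test_that("noise-free generation is recalled perfectly", {
  ms <- generate_msms(default_species_panel(), mass_error_ppm = 0,
                      decoy_fraction = 0, seed = 1)
  hits <- identify_dataset(ms$spectra, lib)
  conf <- hits[hits$status == "confirmed", ]
  merged <- merge(conf, ms$truth, by.x = "spectrum", by.y = "title")
  expect_equal(sum(merged$species.x == merged$species.y), nrow(ms$truth))
})

test_that("decoy-only input yields no confirmations", {
  ms <- generate_msms(default_species_panel(), mass_error_ppm = 0,
                      decoy_fraction = 1, seed = 3)
  decoys <- ms$spectra[ms$truth$decoy]
  hits <- identify_dataset(decoys, lib)
  expect_equal(sum(hits$status == "confirmed"), 0)
})

test_that("MGF round-trips spectra", {
  ms <- generate_msms(default_species_panel()[1:5], seed = 2,
                      decoy_fraction = 0)
  path <- tempfile(fileext = ".mgf")
  write_mgf(ms$spectra, path)
  back <- read_mgf(path)
  expect_length(back, length(ms$spectra))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$precursor_mz, ms$spectra[[i]]$precursor_mz,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$polarity, ms$spectra[[i]]$polarity)
    expect_equal(back[[i]]$peaks[, "mz"], ms$spectra[[i]]$peaks[, "mz"],
                 tolerance = 1e-5, ignore_attr = TRUE)
    expect_equal(back[[i]]$title, ms$spectra[[i]]$title)
  }
})
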