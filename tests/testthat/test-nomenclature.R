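test_that("shorthand names parse to the expected species structure", {
  sm <- parse_lipid_name("SM(d34:1)")
  expect_equal(sm$lipid_class, "SM")
  expect_equal(sm$sphingoid_hydroxyls, 2L)
  expect_equal(c(sm$sum_carbons, sm$sum_double_bonds), c(34L, 1L))
  expect_equal(sm$resolution, "species-sum")

  tg <- parse_lipid_name("TG(17:0/17:0/17:0)")
  expect_equal(tg$lipid_class, "TG")
  expect_length(tg$acyls, 3)
  expect_equal(c(tg$sum_carbons, tg$sum_double_bonds), c(51L, 0L))
  expect_equal(tg$resolution, "molecular-acyl")

  dha <- parse_fatty_acid("C22:6n3")
  expect_equal(c(dha$carbons, dha$double_bonds, dha$n_position), c(22L, 6L, 3L))
})

test_that("whitespace and O- placement variants are accepted", {
  canonical <- parse_lipid_name("PC(O-34:1)")
  for (variant in c("PC O-34:1", "PC O-(34:1)", "PC-O(34:1)", " PC( O-34:1 ) ",
                    "PCO-(34:1)")) {
    expect_identical(parse_lipid_name(variant), canonical, label = variant)
  }
  expect_identical(parse_lipid_name("SM (d34:1)"), parse_lipid_name("SM(d34:1)"))
})

test_that("malformed and unknown names raise classed errors", {
  expect_error(parse_lipid_name("XX(12:0)"), class = "UnknownLipidClass")
  expect_error(parse_lipid_name("PC(34)"), class = "ParseError")
  expect_error(parse_lipid_name("PC(34:40)"), class = "ParseError")  # db > C/2
  expect_error(parse_lipid_name(""), class = "ParseError")
  expect_error(parse_lipid_name("PC(16:0/18:1/18:1)"), class = "ParseError")
  expect_error(mz_for_adduct(700, "[M+K]+"), class = "UnknownAdduct")
})

test_that("formatting canonicalizes and round-trips", {
  # the spiked ceramide standard is written without the d prefix in protocols;
  # the parser canonicalizes to the d form
  expect_equal(format_lipid_name(parse_lipid_name("Cer(18:1/17:0)")),
               "Cer(d18:1/17:0)")
  expect_equal(format_lipid_name(parse_lipid_name("PC(34:1)")), "PC(34:1)")

  # property: parse . format is the identity over the whole packaged panel
  for (nm in c(default_species_panel(), default_standard_map()$standard)) {
    sp <- parse_lipid_name(nm)
    expect_identical(parse_lipid_name(format_lipid_name(sp)), sp, label = nm)
  }
})

test_that("saturation classes follow the >=3 double-bond PUFA rule", {
  expect_equal(as.character(saturation_class(c("16:0", "16:1", "18:2", "22:6n3",
                                               "20:3"))),
               c("SFA", "MUFA", "DUFA", "PUFA", "PUFA"))
  # partition property: every acyl falls in exactly one bucket
  db <- 0:10
  counts <- table(saturation_class(db))
  expect_equal(sum(counts), length(db))
  # configurable threshold: classic 2-bond PUFA definition
  expect_equal(as.character(saturation_class("18:2",
                thresholds = c(MUFA = 1, DUFA = 2, PUFA = 2))), "PUFA")
})

test_that("elemental compositions match literature formulas", {
  comp <- elemental_composition("PC(16:0/16:0)")
  expect_equal(unname(comp$counts[c("C", "H", "N", "O", "P")]),
               c(40L, 80L, 1L, 8L, 1L))
  for (nm in names(REFERENCE_FORMULAS)) {
    expect_equal(monoisotopic_mass(nm),
                 oracle_formula_mass(REFERENCE_FORMULAS[[nm]]),
                 tolerance = 1e-4 / 700, label = nm)
  }
})

test_that("mass is built from CH2 and H2 increments", {
  ch2 <- 12 + 2 * 1.00782503207
  h2 <- 2 * 1.00782503207
  expect_equal(monoisotopic_mass("PC(34:1)") - monoisotopic_mass("PC(33:1)"),
               ch2, tolerance = 1e-10)
  expect_equal(monoisotopic_mass("PC(34:1)"),
               monoisotopic_mass("PC(34:0)") - h2, tolerance = 1e-10)
  # strict monotonicity in carbons at fixed double bonds, constant step
  masses <- sapply(sprintf("PC(%d:1)", 30:40), monoisotopic_mass)
  expect_true(all(diff(masses) > 0))
  expect_equal(max(abs(diff(masses) - ch2)), 0, tolerance = 1e-10)
})

test_that("adduct m/z arithmetic is consistent", {
  proton <- 1.00782503207 - 0.00054857990946
  m <- monoisotopic_mass("PC(34:1)")
  expect_equal(mz_for_adduct(m, "[M+H]+"), m + proton, tolerance = 1e-10)
  expect_equal(mz_for_adduct(m, "[M-H]-"), m - proton, tolerance = 1e-10)
  # [M+NH4]+ minus [M+H]+ is the monoisotopic NH3 mass
  nh3 <- 14.0030740048 + 3 * 1.00782503207
  expect_equal(mz_for_adduct(m, "[M+NH4]+") - mz_for_adduct(m, "[M+H]+"),
               nh3, tolerance = 1e-9)
})

test_that("unregistered classes are rejected with UnsupportedClass", {
  fake <- parse_lipid_name("PC(34:1)")
  fake$lipid_class <- "CL"
  expect_error(elemental_composition(fake), class = "UnsupportedClass")
})
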