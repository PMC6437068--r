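make_tiny_table <- function() {
  feats <- data.frame(
    name = c("PC(34:1)", "PC(36:2)", "TG(16:0/16:0/18:1)", "Cer(d18:1/16:0)",
             "PC(17:0/17:0)", "TG(17:0/17:0/17:0)", "Cer(d18:1/17:0)"),
    class = c("PC", "PC", "TG", "Cer", "PC", "TG", "Cer"),
    is_standard = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  ints <- rbind(
    c(2000, 1000), c(1000, 4000), c(5000, 5000), c(300, 150),
    c(2000, 2000), c(10000, 10000), c(300, 300)
  )
  samples <- data.frame(sample_id = c("s1", "s2"),
                        group = c("Adherent", "Sphere"),
                        protein_ug = c(1, 2), stringsAsFactors = FALSE)
  peak_table(ints, feats, samples)
}

test_that("internal-standard normalization follows the spiked-amount rule", {
  tab <- make_tiny_table()
  am <- is_normalize(tab)
  # feature at the same intensity as its class standard maps to the spike
  expect_equal(am["PC(34:1)", "s1"], 400)   # PC standard spiked at 400 ng
  # TG at half its standard's intensity, standard spiked 2000 ng -> 1000 ng
  expect_equal(am["TG(16:0/16:0/18:1)", "s1"], 5000 / 10000 * 2000)
  # standards removed from the output
  expect_false(any(rownames(am) %in% default_standard_map()$standard))

  # scale invariance: multiplying one sample's intensities by 10 changes nothing
  tab10 <- tab
  tab10$intensities[, 1] <- tab10$intensities[, 1] * 10
  expect_equal(is_normalize(tab10), am)

  # reordering features leaves amounts unchanged
  perm <- sample(nrow(tab$intensities))
  am_perm <- is_normalize(tab[perm, ])
  expect_equal(am_perm[rownames(am), ], am[rownames(am), ])
})

test_that("missing or zero standards raise MissingStandard with context", {
  tab <- make_tiny_table()
  tab$intensities[tab$features$name == "PC(17:0/17:0)", 2] <- 0
  err <- expect_error(is_normalize(tab), class = "MissingStandard")
  expect_match(conditionMessage(err), "PC")
  expect_match(conditionMessage(err), "s2")

  tab2 <- make_tiny_table()[make_tiny_table()$features$name != "Cer(d18:1/17:0)", ]
  expect_error(is_normalize(tab2), class = "MissingStandard")
})

test_that("protein normalization is element-wise and validated", {
  am <- is_normalize(make_tiny_table())
  expect_equal(protein_normalize(am, c(1, 1)), am)
  halved <- protein_normalize(am, c(0.5, 0.5))
  expect_equal(halved, am * 2)
  expect_error(protein_normalize(am, c(1, 0)), class = "InvalidProtein")
})

test_that("compositions close to 100% and behave under aggregation", {
  am <- is_normalize(make_tiny_table())
  cc <- class_composition(am)
  expect_equal(colSums(cc), c(s1 = 100, s2 = 100))

  # single class -> 100%
  one <- am[attr(am, "features")$class == "PC", , drop = FALSE]
  expect_equal(unname(class_composition(one, classes = c("PC", "PC"))[1, ]),
               c(100, 100))

  # equal amounts over 8 classes -> 12.5% each
  m8 <- matrix(3, nrow = 8, ncol = 2,
               dimnames = list(paste0("sp", 1:8), c("a", "b")))
  expect_true(all(class_composition(m8, classes = paste0("cl", 1:8)) == 12.5))

  # species composition at total scope aggregates back to class composition
  sc <- species_composition(am, scope = "total")
  agg <- rowsum(sc, attr(am, "features")$class)
  expect_equal(agg, cc)

  # within-class percentages sum to 100 per class
  wc <- species_composition(am, scope = "within-class")
  for (cl in unique(attr(am, "features")$class)) {
    sums <- colSums(wc[attr(am, "features")$class == cl, , drop = FALSE])
    expect_equal(unname(sums), rep(100, 2))
  }

  expect_error(class_composition(matrix(0, 2, 2), classes = c("a", "b")),
               class = "DegenerateSample")
})

test_that("FAME composition applies relative response factors and closes", {
  areas <- rbind("16:0" = c(100, 200), "18:1" = c(50, 100),
                 "23:0" = c(100, 200))
  colnames(areas) <- c("s1", "s2")
  prof <- suppressWarnings(fame_composition(areas, rrf = c("16:0" = 1, "18:1" = 1)))
  # rrf 1, area equal to the 5 ug IS area -> 5 ug before closure;
  # composition is area closure
  expect_equal(unname(prof["16:0", ]), c(100 * 100 / 150, 100 * 100 / 150))
  expect_equal(unname(colSums(prof)), c(100, 100))

  # doubling all areas changes nothing (already covered by s2 = 2 x s1)
  expect_equal(prof[, "s1"], prof[, "s2"])

  # rrf reweights amounts
  prof2 <- fame_composition(areas, rrf = c("16:0" = 2, "18:1" = 1))
  expect_equal(unname(prof2["16:0", "s1"]), 50 / 100 * 100)

  # missing rrf defaults to 1 with a classed warning
  expect_warning(fame_composition(areas, rrf = c("16:0" = 1)),
                 class = "MissingRRF")
  expect_error(fame_composition(areas[1:2, ], rrf = NULL),
               class = "MissingStandard")
})

test_that("lipidome decomposition counts acyl occurrences", {
  am <- matrix(c(30, 60), nrow = 1,
               dimnames = list("TG(16:0/16:0/18:1)", c("s1", "s2")))
  prof <- lipidome_to_fa_profile(am)
  expect_equal(unname(prof["16:0", ]), c(200 / 3, 200 / 3))
  expect_equal(unname(prof["18:1", ]), c(100 / 3, 100 / 3))

  # species-sum rows are excluded with a warning
  am2 <- rbind(am, "PC(34:1)" = c(10, 10))
  expect_warning(prof2 <- lipidome_to_fa_profile(am2),
                 class = "UnresolvedSpecies")
  expect_equal(unclass(prof2), unclass(prof), ignore_attr = TRUE)

  # all-unresolved input: empty profile plus warning
  am3 <- matrix(c(1, 1), 1, dimnames = list("PC(34:1)", c("s1", "s2")))
  expect_warning(prof3 <- lipidome_to_fa_profile(am3))
  expect_equal(nrow(prof3), 0)

  # duplicated samples preserve the profile
  am4 <- cbind(am, s3 = am[, "s1"])
  prof4 <- lipidome_to_fa_profile(am4)
  expect_equal(prof4[, "s3"], prof4[, "s1"])
})
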