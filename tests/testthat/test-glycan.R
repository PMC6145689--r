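test_that("composition strings parse to counts and round-trip", {
  expect_equal(
    unlist(parse_composition("HexNAc(5)Hex(6)Fuc(1)NeuAc(3)")),
    c(hexnac = 5L, hex = 6L, fuc = 1L, neuac = 3L, neugc = 0L))
  expect_equal(unlist(parse_composition("HexNAc(2)Hex(2)")),
               c(hexnac = 2L, hex = 2L, fuc = 0L, neuac = 0L, neugc = 0L))
  # order-insensitive parse, canonical order on write
  expect_equal(format_composition("NeuAc(3)Fuc(1)Hex(6)HexNAc(5)"),
               "HexNAc(5)Hex(6)Fuc(1)NeuAc(3)")
  set.seed(11)
  for (i in 1:50) {
    cnt <- tibble::tibble(hexnac = sample(0:9, 1), hex = sample(0:10, 1),
                          fuc = sample(0:3, 1), neuac = sample(0:4, 1),
                          neugc = sample(0:1, 1))
    if (sum(cnt) == 0) cnt$hexnac <- 1L
    s <- format_composition(cnt)
    expect_equal(unlist(parse_composition(s)),
                 unlist(lapply(cnt, as.integer)))
  }
})

test_that("malformed, duplicated, unknown and empty compositions are rejected", {
  expect_error(parse_composition("Hex(0)"), "empty")
  expect_error(parse_composition("HexNAc(2)Pent(1)"), "Pent")
  expect_error(parse_composition("Hex(2)Hex(1)"), "duplicated")
  expect_error(parse_composition("Hex(1.5)"), "count")
  expect_error(parse_composition("Hex(-1)"), "count|malformed")
  expect_error(parse_composition("Hex(2"), "malformed")
})

test_that("composition masses are additive and match hand sums", {
  expect_equal(composition_mass("HexNAc(2)Hex(3)"), 892.31722, tolerance = 1e-7)
  # the Fuc+NeuGc vs Hex+NeuAc isobaric identity
  m <- composition_mass(c("Fuc(1)NeuGc(1)", "Hex(1)NeuAc(1)"))
  expect_lt(abs(m[1] - m[2]), 1e-4)
  expect_equal(m[1], 453.14824, tolerance = 1e-5)
  # empty composition has zero mass
  empty <- tibble::tibble(hexnac = 0L, hex = 0L, fuc = 0L, neuac = 0L,
                          neugc = 0L)
  expect_equal(composition_mass(empty), 0)
  # additivity over random compositions
  set.seed(21)
  for (i in 1:25) {
    a <- tibble::tibble(hexnac = sample(0:5, 1), hex = sample(0:5, 1),
                        fuc = sample(0:2, 1), neuac = sample(0:3, 1),
                        neugc = sample(0:1, 1))
    b <- tibble::tibble(hexnac = sample(0:5, 1), hex = sample(0:5, 1),
                        fuc = sample(0:2, 1), neuac = sample(0:3, 1),
                        neugc = sample(0:1, 1))
    expect_equal(composition_mass(a) + composition_mass(b),
                 composition_mass(a + b))
  }
})

test_that("modification and residue masses reproduce the printed values", {
  mods <- modification_mass()
  expect_equal(unname(mods["tmt"]), 229.163, tolerance = 1e-3)
  expect_equal(unname(mods["carbamidomethyl"]), 57.021, tolerance = 1e-3)
  expect_equal(unname(mods["oxidation"]), 15.994, tolerance = 1e-3)
  expect_equal(unname(mods["deamidation"]), 0.984, tolerance = 1e-3)
  # NeuGc differs from NeuAc by exactly one oxidation
  res <- glycan_residue_mass()
  expect_lt(abs((res["neugc"] - res["neuac"]) - mods["oxidation"]), 1e-4)
  expect_error(modification_mass("phospho"), "unknown")
})

test_that("glycopeptide m/z matches an independent mass-summation oracle", {
  # Lys residue + water + proton
  expect_equal(glycopeptide_mz("K"), 147.11280, tolerance = 1e-5)
  # frozen from an independent proteomics mass calculator:
  # monoisotopic M(SVVAPATDGGLNLTSTFLR) = 1918.015991 Da
  expect_equal(
    glycopeptide_mz("SVVAPATDGGLNLTSTFLR", mods = "tmt",
                    comp = "HexNAc(5)Hex(6)Fuc(1)NeuAc(3)", charge = 3),
    1719.08624, tolerance = 1e-5)
  # monotone decreasing in charge
  mzs <- glycopeptide_mz("TAVNCSSDFDACLITK", comp = "HexNAc(2)Hex(2)",
                         charge = 1:4)
  expect_true(all(diff(mzs) < 0))
  expect_error(glycopeptide_mz("KZR"), "residue")
})

test_that("glycan classification is a total five-way partition", {
  expect_equal(classify_glycan("HexNAc(2)Hex(9)"), "high-mannose")
  expect_equal(classify_glycan("HexNAc(5)Hex(6)Fuc(1)NeuAc(3)"), "C/H+Fuc/Sia")
  expect_equal(classify_glycan("HexNAc(2)Hex(2)"), "C/H")
  expect_equal(classify_glycan("HexNAc(4)Hex(5)NeuAc(2)"), "C/H+NeuAc")
  expect_equal(classify_glycan("HexNAc(4)Hex(6)Fuc(2)"), "C/H+Fuc")
  # NeuGc counts as sialylated
  expect_equal(classify_glycan("HexNAc(4)Hex(5)NeuGc(1)"), "C/H+NeuAc")
  # exhaustive small grid: every nonempty composition gets exactly one class
  grid <- expand.grid(hexnac = 0:4, hex = 0:6, fuc = 0:2, neuac = 0:2,
                      neugc = 0:1)
  grid <- tibble::as_tibble(grid[rowSums(grid) >= 1, ])
  cls <- classify_glycan(grid)
  expect_true(all(cls %in% glycan_classes()))
  expect_false(anyNA(cls))
  expect_error(classify_glycan(tibble::tibble(hexnac = 0L, hex = 0L, fuc = 0L,
                                              neuac = 0L, neugc = 0L)),
               "empty")
})

test_that("oxonium ion m/z values match residue + proton arithmetic", {
  neuac <- oxonium_ions("NeuAc")
  expect_equal(neuac$mz, c(292.10269, 274.09213), tolerance = 1e-5)
  neugc <- oxonium_ions("NeuGc")
  expect_equal(neugc$mz, c(308.09761, 290.08704), tolerance = 1e-5)
  hexnac <- oxonium_ions("HexNAc")
  expect_equal(hexnac$mz, c(204.08665, 186.07608), tolerance = 1e-5)
  # composition input returns ions of all constituent monosaccharides
  ions <- oxonium_ions("HexNAc(4)Hex(5)NeuAc(1)")
  expect_setequal(unique(ions$unit), c("HexNAc", "Hex", "NeuAc"))
  expect_error(oxonium_ions("Xyl"), "unknown|unsupported")
})

test_that("isobaric collision enumeration finds the NeuGc/NeuAc confounds", {
  hits <- find_isobaric_collisions("HexNAc(5)Hex(7)NeuAc(3)")
  expect_true("HexNAc(5)Hex(6)Fuc(1)NeuAc(2)NeuGc(1)" %in% hits$composition)
  hits2 <- find_isobaric_collisions("HexNAc(4)Hex(6)NeuAc(2)")
  expect_true("HexNAc(4)Hex(5)Fuc(1)NeuAc(1)NeuGc(1)" %in% hits2$composition)
  # symmetric relation
  back <- find_isobaric_collisions("HexNAc(5)Hex(6)Fuc(1)NeuAc(2)NeuGc(1)")
  expect_true("HexNAc(5)Hex(7)NeuAc(3)" %in% back$composition)
  # no alternative inside a capped space
  none <- find_isobaric_collisions(
    "HexNAc(2)Hex(3)",
    space = c(hexnac = 2L, hex = 3L, fuc = 0L, neuac = 0L, neugc = 0L))
  expect_equal(nrow(none), 0)
  # holds at tight tolerance too
  tight <- find_isobaric_collisions("HexNAc(5)Hex(7)NeuAc(3)", tol_ppm = 0.1)
  expect_true("HexNAc(5)Hex(6)Fuc(1)NeuAc(2)NeuGc(1)" %in% tight$composition)
})

test_that("sequon detection matches a lookahead-regex oracle", {
  expect_equal(find_sequons("LNAENNATFYFK")$position, 6L)
  expect_equal(find_sequons("TAVNCSSDFDACLITK")$position, 4L)
  expect_equal(nrow(find_sequons("NPT")), 0)
  expect_equal(nrow(find_sequons("NA")), 0)
  oracle <- function(s) {
    m <- gregexpr("N(?=[^P][STC])", s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:1000) {
    s <- paste(sample(aa, sample(3:25, 1), replace = TRUE), collapse = "")
    got <- find_sequons(s)
    expect_equal(if (nrow(got) == 0) integer(0) else got$position, oracle(s),
                 info = s)
  }
})
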