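test_that("de-N evidence corroborates intact glycosites", {
  intact <- tibble::tibble(
    feature_id = c("a", "b", "c"),
    protein = c("PTGDS", "PTGDS", "ORPHAN"),
    peptide = c("SVVAPATDGGLNLTSTFLR", "WFSAGLASNSSWLR", "LNAENNATFYFK"))
  den <- tibble::tibble(
    protein = c("PTGDS", "PTGDS"),
    peptide = c("SVVAPATDGGLN(de)LTSTFLR", "WFSAGLASN(de)SSWLR"),
    ratio = c(0.93, 0.34))
  out <- corroborate_sites(intact, den)
  expect_equal(out$corroborated, c(TRUE, TRUE, FALSE))
  expect_equal(out$den_peptide[1], "SVVAPATDGGLN(de)LTSTFLR")
  expect_equal(out$den_ratio[1:2], c(0.93, 0.34))
})

test_that("deamidation off a sequon cannot corroborate", {
  intact <- tibble::tibble(feature_id = "a", protein = "P1",
                           peptide = "LNPSKNATR")
  # the (de) mark sits on N2, which is followed by P: not a sequon
  den <- tibble::tibble(protein = "P1", peptide = "LN(de)PSKNATR")
  out <- corroborate_sites(intact, den)
  expect_false(out$corroborated)
  # the same peptide deamidated at the true sequon (N6) corroborates
  den2 <- tibble::tibble(protein = "P1", peptide = "LNPSKN(de)ATR")
  expect_true(corroborate_sites(intact, den2)$corroborated)
})

test_that("protein coordinates match sites across different peptides", {
  # missed-cleavage variant: KEDALNETR (de-N) vs EDALNETR (intact)
  seqs <- c(CLU = "MKTLLLFVGLLLTWESGQVLGDQTVSDNELQEMSNQGSKEDALNETRESETK")
  intact <- tibble::tibble(feature_id = "a", protein = "CLU",
                           peptide = "EDALNETR")
  den <- tibble::tibble(protein = "CLU", peptide = "KEDALN(de)ETR")
  # string fallback fails (different peptides) ...
  expect_false(corroborate_sites(intact, den)$corroborated)
  # ... but protein-coordinate matching succeeds
  expect_true(corroborate_sites(intact, den,
                                protein_seqs = seqs)$corroborated)
})

test_that("the reference panel passes the four gates intact", {
  fix <- load_table1_fixture()
  diff <- tibble::tibble(
    feature_id = as.character(fix$entry_id), protein = fix$protein,
    peptide = fix$peptide, composition = fix$composition,
    q = fix$q, ratio = fix$ratio)
  corr <- tibble::tibble(feature_id = diff$feature_id, corroborated = TRUE,
                         den_peptide = fix$den_peptide)
  panel <- select_panel(diff, corr)
  expect_equal(nrow(panel), 56)
  expect_setequal(panel$direction, c("Up", "Down"))
  # direction labels agree with the printed table
  expect_equal(sum(panel$direction == "Up"), sum(fix$direction == "Up"))
  lut <- stats::setNames(fix$direction, as.character(fix$entry_id))
  expect_equal(panel$direction, unname(lut[panel$feature_id]))
})

test_that("each gate excludes independently and order does not matter", {
  base <- tibble::tibble(
    feature_id = letters[1:5],
    protein = "P", peptide = "LNAENNATFYFK",
    composition = "HexNAc(6)Hex(7)Fuc(1)NeuAc(4)",
    q = c(0.10, 0.26, 0.10, 0.10, 0.25),
    ratio = c(1.25, 2.0, 2.0, 2.0, 0.76))
  corr <- tibble::tibble(feature_id = letters[1:5],
                         corroborated = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                         den_peptide = "LNAENN(de)ATFYFK")
  wl <- c("HexNAc(6)Hex(7)Fuc(1)NeuAc(4)")
  panel <- select_panel(base, corr, whitelist = wl)
  # a: FC gate (1.25 inside the band); b: q gate; c: corroboration;
  # d passes; e: ratio 0.76 at q 0.25 is included as Down
  expect_setequal(panel$feature_id, c("d", "e"))
  expect_equal(panel$direction[panel$feature_id == "e"], "Down")
  # whitelist gate
  off_list <- select_panel(base, corr, whitelist = "HexNAc(2)Hex(9)")
  expect_equal(nrow(off_list), 0)
  # intersection of predicates: manual order-permuted application agrees
  manual <- base |>
    dplyr::left_join(corr, by = "feature_id") |>
    dplyr::filter(.data$composition %in% wl) |>
    dplyr::filter(.data$corroborated) |>
    dplyr::filter(.data$ratio > 1.3 | .data$ratio < 0.77) |>
    dplyr::filter(.data$q <= 0.25)
  expect_setequal(panel$feature_id, manual$feature_id)
})

test_that("protein-level cross-referencing flags glyco-specific regulation", {
  panel <- tibble::tibble(
    feature_id = c("cd59", "ambp", "orphan"),
    protein = c("CD59", "AMBP", "NOVEL"),
    ratio = c(1.7, 1.6, 2.0),
    q = 0.2, corroborated = TRUE,
    composition = "HexNAc(2)Hex(2)",
    direction = c("Up", "Up", "Up"))
  nonmod <- tibble::tibble(
    protein = c(rep("CD59", 7), rep("AMBP", 10)),
    ratio = c(rep(1.0, 7), rep(2.4, 10)))
  out <- crossref_protein_level(panel, nonmod)
  # glycopeptide up while protein unaltered: glyco-specific
  expect_true(out$glyco_specific[out$protein == "CD59"])
  expect_equal(out$n_nonmod[out$protein == "CD59"], 7L)
  # protein itself up: regulation not glyco-specific
  expect_false(out$glyco_specific[out$protein == "AMBP"])
  # absent from the non-modified data
  expect_equal(out$protein_evidence[out$protein == "NOVEL"], "none")
  expect_true(is.na(out$glyco_specific[out$protein == "NOVEL"]))
})
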