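# Shorthand parser: hierarchical representation, levels, normalization.

test_that("oxidised sn-resolved names parse to the documented structure", {
  x <- parse_lipid_name("PC 18:2/20:4;O")
  expect_equal(x$headgroup, "PC")
  expect_equal(x$class_code, "GP01")
  expect_equal(x$category, "GP")
  expect_equal(x$level, "SN_POSITION")
  expect_length(x$chains, 2L)
  expect_equal(vapply(x$chains, `[[`, 1L, "carbons"), c(18L, 20L))
  expect_equal(vapply(x$chains, `[[`, 1L, "double_bonds"), c(2L, 4L))
  expect_equal(vapply(x$chains, `[[`, 1L, "oxygens"), c(0L, 1L))
  expect_equal(vapply(x$chains, `[[`, 1L, "sn"), c(1L, 2L))
  expect_equal(c(x$total_c, x$total_db, x$total_o), c(38L, 6L, 1L))

  y <- parse_lipid_name("PE 16:0/20:4(5,8,10,14);OH")
  expect_equal(y$level, "STRUCTURE_DEFINED")
  expect_equal(y$chains[[2]]$db_positions, c(5L, 8L, 10L, 14L))
  expect_equal(y$chains[[2]]$db_geometry, rep("", 4L))
  expect_equal(y$chains[[2]]$functional_groups, c(OH = 1L))
  expect_equal(y$total_o, 1L)
})

test_that("species-level names carry totals only", {
  x <- parse_lipid_name("PC 36:2")
  expect_equal(x$level, "SPECIES")
  expect_length(x$chains, 0L)
  expect_equal(c(x$total_c, x$total_db, x$total_o), c(36L, 2L, 0L))
})

test_that("mixed-level names are coerced to the closest valid level", {
  x <- parse_lipid_name("PC 16:1(7)_16:1(9)")
  expect_true(x$coerced)
  expect_equal(x$level, "MOLECULAR_SPECIES")
  expect_equal(x$name, "PC 16:1_16:1")
  expect_identical(normalize_name(x, "MOLECULAR_SPECIES"), "PC 16:1_16:1")
  # positions on only one of two unsaturated sn-resolved chains: same rule
  y <- parse_lipid_name("PE 18:1/20:4(5,8,11,14)")
  expect_true(y$coerced)
  expect_equal(y$level, "SN_POSITION")
})

test_that("separator and annotation depth determine the level", {
  expect_equal(determine_level(parse_lipid_name("PC 18:1_18:1")),
               "MOLECULAR_SPECIES")
  expect_equal(determine_level(parse_lipid_name("PC 18:1/18:1")),
               "SN_POSITION")
  expect_equal(determine_level(parse_lipid_name("PC 36:2")), "SPECIES")
  expect_equal(determine_level(parse_lipid_name("PC 18:1(9)/18:1(9)")),
               "STRUCTURE_DEFINED")
  expect_equal(determine_level(parse_lipid_name("PC 18:1(9Z)/18:1(9E)")),
               "FULL_STRUCTURE")
  # cis/trans tokens are accepted and mapped onto Z/E
  z <- parse_lipid_name("PC 18:1(9cis)/18:1(9trans)")
  expect_equal(z$level, "FULL_STRUCTURE")
  expect_equal(z$chains[[1]]$db_geometry, "Z")
  expect_equal(z$chains[[2]]$db_geometry, "E")
  # unlocated oxygens cap the level below full structure
  expect_equal(determine_level(parse_lipid_name("PC 18:1(9Z)/18:1(9Z);O")),
               "STRUCTURE_DEFINED")
})

test_that("normalization drops information down to the target level", {
  x <- parse_lipid_name("PC 18:2/20:4;O")
  expect_identical(normalize_name(x, "SPECIES"), "PC 38:6;O")
  expect_identical(normalize_name(x, "MOLECULAR_SPECIES"), "PC 18:2_20:4;O")
  y <- parse_lipid_name("PE 16:0/20:4(5,8,10,14);OH")
  expect_identical(normalize_name(y, "SN_POSITION"), "PE 16:0/20:4;OH")
  expect_identical(normalize_name(y, "CLASS"),
                   "Glycerophosphoethanolamines [GP02]")
  expect_identical(normalize_name(y, "CATEGORY"),
                   "Glycerophospholipids [GP]")
  expect_error(normalize_name(x, "STRUCTURE_DEFINED"),
               class = "lipidenrich_level_unavailable")
})

test_that("parsing round-trips through the canonical name on the panel", {
  panel <- read.delim(test_path("goslin-panel.tsv"), stringsAsFactors = FALSE)
  for (nm in panel$name) {
    x <- parse_lipid_name(nm)
    y <- parse_lipid_name(normalize_name(x, x$level))
    expect_identical(y$name, x$name, label = nm)
    expect_identical(y$level, x$level, label = nm)
    expect_identical(c(y$total_c, y$total_db, y$total_o),
                     c(x$total_c, x$total_db, x$total_o), label = nm)
  }
})

test_that("normalization is monotone and preserves totals at species level or above", {
  panel <- read.delim(test_path("goslin-panel.tsv"), stringsAsFactors = FALSE)
  sub <- panel$name[panel$level %in% c("SN_POSITION", "STRUCTURE_DEFINED",
                                       "FULL_STRUCTURE")]
  lv_chain <- c("SPECIES", "MOLECULAR_SPECIES", "SN_POSITION")
  for (nm in sub[seq(1, length(sub), by = 2)]) {
    x <- parse_lipid_name(nm)
    for (i in seq_along(lv_chain)) {
      for (j in seq_len(i)) {
        via <- normalize_name(parse_lipid_name(normalize_name(x, lv_chain[i])),
                              lv_chain[j])
        expect_identical(via, normalize_name(x, lv_chain[j]),
                         label = paste(nm, lv_chain[i], "->", lv_chain[j]))
      }
      at <- parse_lipid_name(normalize_name(x, lv_chain[i]))
      expect_identical(c(at$total_c, at$total_db, at$total_o),
                       c(x$total_c, x$total_db, x$total_o), label = nm)
    }
  }
})

test_that("category, class and level agree with the curated reference panel", {
  panel <- read.delim(test_path("goslin-panel.tsv"), stringsAsFactors = FALSE)
  got <- lapply(panel$name, parse_lipid_name)
  expect_identical(vapply(got, `[[`, "", "level"), panel$level)
  expect_identical(vapply(got, `[[`, "", "category"), panel$category)
  expect_identical(vapply(got, `[[`, "", "class_code"), panel$class_code)
})

test_that("adduct annotations are stripped before parsing", {
  expect_identical(parse_lipid_name("PC 34:1 [M+H]+")$name, "PC 34:1")
  expect_identical(parse_lipid_name("PE 16:0_18:1 [M-H]-")$name,
                   "PE 16:0_18:1")
})

test_that("unparseable names and unsupported grammars raise typed errors", {
  expect_error(parse_lipid_name(""), class = "lipidenrich_unparseable")
  expect_error(parse_lipid_name("XX 34:1"), class = "lipidenrich_unparseable")
  expect_error(parse_lipid_name("PC 16:0/18:1;XYZ"),
               class = "lipidenrich_unparseable")
  expect_error(parse_lipid_name("PC 18:2(9,12)/20:4"),  # cross-chain partial
               NA)                                      # positions: coerced
  expect_error(parse_lipid_name("PC 18:2(9)/18:1"),     # within-chain count
               class = "lipidenrich_unparseable")       # mismatch: rejected
  expect_error(parse_lipid_name("PC 18:2(9,12,15)/18:1"),
               class = "lipidenrich_unparseable")  # 3 positions, 2 bonds
  expect_error(parse_lipid_name("PC 34:1", grammar = "lipidmaps"),
               class = "lipidenrich_unsupported_grammar")
})

test_that("batch parsing collects errors and reports duplicates", {
  b <- parse_batch(c("PC 36:2", "PC 36:2"))
  expect_length(b$lipids, 1L)
  expect_equal(nrow(b$duplicates), 1L)

  b2 <- parse_batch(c("PC 36:2", "not_a_lipid"))
  expect_length(b2$lipids, 1L)
  expect_equal(b2$errors$name, "not_a_lipid")

  # canonical duplicates: same molecular species written in two orders
  b3 <- parse_batch(c("PC 16:0_18:1", "PC 18:1_16:0"))
  expect_length(b3$lipids, 1L)

  # order preserved
  b4 <- parse_batch(c("PE 34:1", "PC 36:2", "PG 34:2"))
  expect_identical(vapply(b4$lipids, `[[`, "", "raw_name"),
                   c("PE 34:1", "PC 36:2", "PG 34:2"))
})
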