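# Structural term enumeration and membership counting.

test_that("chain bins partition carbons and saturation as documented", {
  x <- parse_lipid_name("PC 16:1_20:4")
  g1 <- chain_group_terms(x$chains[[1]])  # 16:1
  g2 <- chain_group_terms(x$chains[[2]])  # 20:4
  expect_equal(g1$value[g1$classifier == "C_GROUP"], "16-18")
  expect_equal(g1$value[g1$classifier == "DB_GROUP"], "monounsaturated")
  expect_equal(g2$value[g2$classifier == "C_GROUP"], ">18")
  expect_equal(g2$value[g2$classifier == "DB_GROUP"], "polyunsaturated")
  y <- parse_lipid_name("PC 14:0_16:0")
  g3 <- chain_group_terms(y$chains[[1]])  # 14:0
  expect_equal(g3$value, c("<16", "saturated"))

  # partition property: every chain falls in exactly one bin of each kind
  fx <- demo_lipidome(n_query = 10, n_reference = 60, seed = 5)
  for (lp in parse_batch(fx$reference)$lipids) {
    for (ch in lp$chains) {
      if (ch$carbons == 0L) next
      g <- chain_group_terms(ch)
      expect_equal(sum(g$classifier == "C_GROUP"), 1L)
      expect_equal(sum(g$classifier == "DB_GROUP"), 1L)
    }
  }
})

test_that("enumeration emits the documented term families", {
  ref <- parse_batch("PC 16:1/18:0")$lipids
  tm <- enumerate_terms(ref)
  labels <- tm$display_label
  expect_true("Glycerophospholipids [GP]" %in% labels)
  expect_true("Glycerophosphocholines [GP01]" %in% labels)
  expect_true("Acyls 16:1" %in% labels)
  expect_true(any(tm$classifier == "CHAIN_AT_SN" & tm$value == "sn-1:16:1"))
  expect_true(any(tm$classifier == "C_GROUP"))
  expect_true(any(tm$classifier == "DB_GROUP"))
  expect_true(any(tm$classifier == "CHAIN" & tm$value == "16:1" &
                    !is.na(tm$condition) & tm$condition == "GP"))
  expect_true(any(tm$classifier == "CHAIN" & tm$value == "16:1" &
                    !is.na(tm$condition) & tm$condition == "GP01"))
  # conditioned display labels use the "within" phrasing
  expect_true("Acyls 16:1 within Glycerophosphocholines [GP01]" %in% labels)

  expect_equal(nrow(enumerate_terms(list())), 0L)
})

test_that("species-only single-class references yield no chain terms", {
  ref <- parse_batch(c("PC 34:1", "PC 36:2", "PC 38:4"))$lipids
  tm <- enumerate_terms(ref)
  expect_equal(sum(tm$classifier == "CATEGORY"), 1L)
  expect_equal(sum(tm$classifier == "CLASS"), 1L)
  expect_false(any(tm$classifier %in% c("CHAIN", "CHAIN_AT_SN", "C_GROUP",
                                        "DB_GROUP")))
  expect_true(all(tm$classifier %in% c("CATEGORY", "CLASS", "TOTAL_C",
                                       "TOTAL_DB", "TOTAL_O")))
})

test_that("term identity keys are unique within an enumeration", {
  fx <- demo4_fixture(verify = FALSE)
  tm <- enumerate_terms(parse_batch(fx$reference)$lipids)
  expect_false(any(duplicated(tm$term_id)))
})

test_that("membership counts carriers once and respects level eligibility", {
  q <- parse_batch(c("PC 18:2/20:4;O", "PC 20:4_20:4", "PC 36:4"))$lipids
  r <- parse_batch(c("PC 18:2/20:4;O", "PC 16:0_18:1", "PC 36:4",
                     "PE 16:0/20:4"))$lipids
  tm <- enumerate_terms(r)
  chain204 <- tm[tm$classifier == "CHAIN" & tm$value == "20:4" &
                   is.na(tm$condition), ]
  ms <- membership(chain204, q, r)
  # a lipid with 20:4 counts once, even with two 20:4 chains; the
  # species-level "PC 36:4" is never a member
  expect_setequal(ms$query_members, c("PC 18:2/20:4;O", "PC 20:4_20:4"))
  expect_setequal(ms$reference_members, c("PC 18:2/20:4;O", "PE 16:0/20:4"))
  # fixed universes count all lipids regardless of level
  expect_equal(ms$query_universe, 3L)
  expect_equal(ms$reference_universe, 4L)
  # evaluable universes drop lipids below the term level
  ev <- membership(chain204, q, r,
                   options = term_options(universe = "evaluable"))
  expect_equal(ev$query_universe, 2L)
  expect_equal(ev$reference_universe, 3L)
  # adding species-level lipids changes nothing but the fixed universe
  r2 <- parse_batch(c("PC 18:2/20:4;O", "PC 16:0_18:1", "PC 36:4",
                     "PE 16:0/20:4", "PC 34:1", "PE 36:2"))$lipids
  ms2 <- membership(chain204, q, r2)
  expect_equal(length(ms2$reference_members), length(ms$reference_members))
  expect_equal(ms2$reference_universe, 6L)
  ev2 <- membership(chain204, q, r2,
                    options = term_options(universe = "evaluable"))
  expect_equal(ev2$reference_universe, 3L)
})

test_that("sn-resolved chain terms match only the stated sn index", {
  r <- parse_batch(c("PC 16:0/20:4", "PC 20:4/16:0", "PC 16:0_20:4"))$lipids
  tm <- enumerate_terms(r)
  sn2 <- tm[tm$classifier == "CHAIN_AT_SN" & tm$value == "sn-2:20:4" &
              is.na(tm$condition), ]
  ms <- membership(sn2, r, r)
  expect_identical(ms$query_members, "PC 16:0/20:4")
})

test_that("conditioned memberships are subsets with smaller universes", {
  fx <- demo4_fixture(verify = FALSE)
  q <- parse_batch(fx$query)$lipids
  r <- parse_batch(fx$reference)$lipids
  tm <- enumerate_terms(r)
  counted <- lipidenrich:::count_memberships(tm, q, r)
  cond <- counted[!is.na(counted$condition), ]
  for (j in seq_len(nrow(cond))) {
    parent <- counted[is.na(counted$condition) &
                        counted$classifier == cond$classifier[j] &
                        counted$value == cond$value[j] &
                        counted$level == cond$level[j], ]
    expect_equal(nrow(parent), 1L)
    expect_lte(cond$a[j], parent$a)
    expect_lte(cond$c_ref[j], parent$c_ref)
    expect_lte(cond$q_universe[j], parent$q_universe)
    expect_lte(cond$r_universe[j], parent$r_universe)
  }
  # conditioned universes equal the class/category sizes
  gp01 <- counted[!is.na(counted$condition) & counted$condition == "GP01", ][1, ]
  expect_equal(gp01$q_universe, 26L)
  expect_equal(gp01$r_universe, 148L)
})

test_that("removing all carriers removes the term from the enumeration", {
  ref <- parse_batch(c("PC 16:1_18:0", "PC 16:0_18:1", "PE 34:1"))$lipids
  tm <- enumerate_terms(ref)
  expect_true(any(tm$classifier == "CHAIN" & tm$value == "16:1"))
  ref2 <- ref[-1]
  tm2 <- enumerate_terms(ref2)
  expect_false(any(tm2$classifier == "CHAIN" & tm2$value == "16:1"))
})

test_that("term option toggles prune the corresponding families", {
  ref <- parse_batch(c("PC 16:0/18:1(9)", "PC O-16:0_18:1",
                       "PC 16:0_18:1;OH"))$lipids
  all_on <- enumerate_terms(ref)
  expect_true(any(all_on$classifier == "DB_POSITION"))
  expect_true(any(all_on$classifier == "BOND_TYPE"))
  expect_true(any(all_on$classifier == "MODIFICATION"))
  off <- enumerate_terms(ref, term_options(grouped_bins = FALSE,
                                           conditioned = FALSE,
                                           db_positions = FALSE,
                                           modifications = FALSE,
                                           bond_types = FALSE))
  expect_false(any(off$classifier %in% c("C_GROUP", "DB_GROUP",
                                         "DB_POSITION", "BOND_TYPE",
                                         "MODIFICATION")))
  expect_true(all(is.na(off$condition)))
  cat_only <- enumerate_terms(ref, term_options(condition_depth = "category"))
  expect_true(all(cat_only$condition[!is.na(cat_only$condition)] == "GP"))
})
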