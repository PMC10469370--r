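# Deterministic technical-demo fixture.
#
# Constructs a 68-lipid query and a 556-lipid reference (the query is a
# subset of the reference, as in a real study where the reference is the
# whole detected lipidome) whose structural-term marginals reproduce the
# seven-row over-represented term table of the technical demo:
#
#   Acyls 16:1 | MOLECULAR SPECIES                      13/68  18/556
#   Acyls 20:4 | MOLECULAR SPECIES                      15/68  26/556
#   Acyls 20:4 | SN POSITION                            13/68  19/556
#   Acyls 16:1 within GP | MOLECULAR SPECIES            13/68  17/448
#   Acyls 20:4 within GP | MOLECULAR SPECIES            15/68  24/448
#   Acyls 20:4 within GP | SN POSITION                  13/68  18/448
#   Acyls 16:1 within GP01 | MOLECULAR SPECIES          11/26  14/148
#
# plus the joint "green cluster": the 13 query lipids carrying 20:4 at the
# sn-2 position share one term profile across the four 20:4 terms.
# Background composition is mirrored proportionally between query and
# reference so that no term covering only part of the green cluster comes
# anywhere near significance; all joint structure beyond the printed
# marginals is a choice of this fixture.

# background pair catalogue (partner chains common in mammalian membranes)
.bg_pairs <- list(
  A = c("16:0", "18:1"), B = c("18:0", "18:1"), C = c("18:1", "18:1"),
  D = c("16:0", "16:0"), E = c("18:2", "18:2"), F = c("16:0", "18:0"),
  G = c("16:0", "18:2"), H = c("18:1", "18:2"))

bg_pair_name <- function(headgroup, pair_id, mod = "", sep = "_") {
  p <- .bg_pairs[[pair_id]]
  paste0(headgroup, " ", p[1], sep, p[2], mod)
}

#' Deterministic demo-scale fixture with printed marginals
#'
#' Builds the 68/556 query/reference pair described above. Construction is
#' fixed (no randomness) and verified internally: the seven term
#' memberships are recounted through the parser and membership machinery,
#' and the construction stops if any recount disagrees.
#'
#' @param verify recount the seven marginals after construction
#'   (default `TRUE`).
#' @return list with character vectors `query` and `reference`.
#' @export
demo4_fixture <- function(verify = TRUE) {
  ## --- query (68 lipids; all glycerophospholipids: 26 PC, 30 PE, 12 PG)
  green <- c(
    "PC 16:0/20:4", "PC 16:0/20:4;O", "PC 16:0/20:4;OH",
    "PC 16:0/20:4(5,8,10,14)",
    "PE 16:0/20:4", "PE 16:0/20:4;O", "PE 16:0/20:4;OH",
    "PE 16:0/20:4(5,8,10,14)", "PE 16:0/20:4(5,8,10,14);OH",
    "PE 16:0/20:4;OOH",
    "PG 16:0/20:4", "PG 16:0/20:4;O", "PG 16:0/20:4;OH")
  q_204_ms <- c("PC 16:0_20:4", "PE 18:1_20:4")
  q_161 <- c(
    "PC 16:1_16:0", "PC 16:1_18:0", "PC 16:1_18:1", "PC 16:1_16:1",
    "PC 16:1_16:0;O", "PC 16:1_18:0;O", "PC 16:1_18:1;O", "PC 16:1_16:1;O",
    "PC 16:1_16:0;OH", "PC 16:1_18:0;OH", "PC 16:1_18:1;OH",
    "PE 16:1_16:0", "PE 16:1_18:1")
  q_bg_pc <- c(vapply(names(.bg_pairs), bg_pair_name, "", headgroup = "PC"),
               "PC 34:1", "PC 36:2")
  q_bg_pe <- c(vapply(names(.bg_pairs), bg_pair_name, "", headgroup = "PE"),
               vapply(c("A", "B", "C", "D", "E"), bg_pair_name, "",
                      headgroup = "PE", mod = ";O"),
               paste("PE", c("34:1", "36:2", "36:1", "34:2",
                             "32:0", "34:0", "36:4", "36:3")))
  q_bg_pg <- c(vapply(names(.bg_pairs)[1:7], bg_pair_name, "", headgroup = "PG"),
               "PG 34:1", "PG 36:2")
  query <- c(green, q_204_ms, q_161, q_bg_pc, q_bg_pe, q_bg_pg)

  ## --- reference extras (488 lipids; reference = query + extras)
  r_161 <- c("PC 16:1_18:2", "PC 16:1_16:1;OH", "PC 14:0_16:1",
             "PG 16:1_16:0", "TG 16:1_16:0_18:1")
  r_204 <- c("PC 18:1/20:4", "PC 18:2/20:4;O", "PC 18:0_20:4",
             "PE 18:1/20:4", "PE 18:2/20:4", "PE 18:1/20:4;O",
             "PE 16:0_20:4", "PE 18:2_20:4",
             "PG 18:1_20:4",
             "TG 16:0/20:4/18:1", "TG 16:0_20:4_18:1")

  # class backgrounds: cycle pair catalogue x modification x separator so
  # that feature proportions mirror the query side
  expand_bg <- function(headgroup, recipes, n) {
    out <- unique(unlist(recipes))
    if (length(out) < n) {
      stop(sprintf("demo fixture: %s background too small (%d < %d)",
                   headgroup, length(out), n))
    }
    out[seq_len(n)]
  }

  mods3 <- c("", ";O", ";OH")
  sn_led <- function(hg, partners, mods) {
    unlist(lapply(mods, function(m) paste0(hg, " 16:0/", partners, m)))
  }
  pair_cycle <- function(hg, mods, sep = "_", ids = names(.bg_pairs)) {
    unlist(lapply(mods, function(m) vapply(ids, bg_pair_name, "",
                                           headgroup = hg, mod = m, sep = sep)))
  }
  # molecular-species backgrounds with longer / odd partner chains
  # (reference-only chain values are free: terms without query members are
  # never tested)
  long_ms <- function(hg, leads, partners, mods = "") {
    unlist(lapply(mods, function(m)
      unlist(lapply(leads, function(l) paste0(hg, " ", l, "_", partners, m)))))
  }

  pc_bg <- expand_bg("PC", list(
    sn_led("PC", c("18:1", "18:2", "18:0", "16:0", "22:6"), mods3),    # 15
    pair_cycle("PC", mods3, sep = "/"),                                # 24
    pair_cycle("PC", c(";O", ";OH")),                                  # 16
    paste0("PC ", c("18:2/18:1", "18:0/22:6", "18:0/16:0", "18:0/18:0",
                    "18:1/20:3", "16:0/20:1", "18:0/20:1", "16:0/19:0")), # 8
    paste("PC", c("32:1", "34:0", "36:1", "36:3", "36:4", "32:0",
                  "38:4", "38:6", "40:6", "34:2")),                    # 10
    paste0("PC O-", c("16:0_18:1", "16:0_18:2", "18:1_18:1", "16:0_16:0")),
    paste0("PC P-", c("16:0_18:1", "18:0_18:1")),                      # 6
    c(paste0("PC 18:1(9)/18:2(9,12)", c("", ";O")),
      "PC 18:1(9Z)/18:2(9Z,12Z)"),                                     # 3
    c(paste0("PC 18:1/", c("16:0", "18:0"), rep(c("", ";O"), each = 2)),
      paste0("PC 18:2/", c("16:0", "18:0"), rep(c("", ";O"), each = 2))), # 8
    long_ms("PC", c("18:0", "16:0"), c("20:0", "22:6", "20:3", "22:4"),
            c("", ";O")),                                              # 16
    long_ms("PC", c("18:1", "17:0"), c("20:1", "19:0"), c("", ";OH")), # 8
    long_ms("PC", "18:1", c("22:6", "20:3", "22:4"), c("", ";O")),     # 6
    paste("PC", c("30:0", "30:1", "40:4", "38:5", "40:5", "38:3",
                  "42:6", "36:5"))                                     # 8
  ), 116)
  pe_bg <- expand_bg("PE", list(
    sn_led("PE", c("18:1", "18:2", "18:0", "16:0", "22:6"), mods3),    # 15
    pair_cycle("PE", mods3, sep = "/"),                                # 24
    pair_cycle("PE", ";OH"),                                           # 8
    paste0("PE ", c("18:2/18:1", "18:0/22:6", "18:0/16:0", "18:0/18:0",
                    "18:1/20:3", "16:0/20:1", "18:0/20:1", "16:0/19:0")), # 8
    paste("PE", c("32:1", "36:0", "38:4", "38:6", "40:6", "38:5",
                  "40:4", "34:3", "32:2", "30:0", "40:5", "38:3")),    # 12
    paste0("PE O-", c("16:0_18:1", "16:0_18:2", "18:1_18:1")),
    paste0("PE P-", c("16:0_18:1", "18:0_18:1", "16:0_18:2")),         # 6
    c(paste0("PE 18:1(9)/18:2(9,12)", c("", ";O")),
      "PE 16:0/18:2(9,12)", "PE 18:1(9Z)/18:1(9Z)"),                   # 4
    c(paste0("PE 18:1/", c("16:0", "18:0"), rep(c("", ";O"), each = 2)),
      paste0("PE 18:2/", c("16:0", "18:0"), rep(c("", ";O"), each = 2))), # 8
    long_ms("PE", c("18:0", "16:0"), c("20:0", "22:6", "20:3", "22:5"),
            c("", ";O")),                                              # 16
    long_ms("PE", c("18:1", "17:0"), c("20:1", "19:0"), c("", ";OH")), # 8
    long_ms("PE", "18:1", c("22:6", "20:3", "22:4"), c("", ";O")),     # 6
    long_ms("PE", "18:2", c("22:6", "20:3"), c("", ";O")),             # 4
    paste("PE", c("30:1", "42:6", "36:5", "40:7", "42:7", "34:4",
                  "44:6", "44:12"))                                    # 8
  ), 115)
  pg_bg <- expand_bg("PG", list(
    sn_led("PG", c("18:1", "18:2", "18:0", "16:0"), mods3),            # 12
    pair_cycle("PG", mods3, sep = "/"),                                # 24
    pair_cycle("PG", c(";O", ";OH")),                                  # 16
    paste("PG", c("32:1", "34:0", "36:1", "36:3", "36:4", "32:0",
                  "38:6", "34:2", "36:0", "30:0")),                    # 10
    c(paste0("PG 18:1/", c("16:0", "18:0")),
      paste0("PG 18:2/", c("16:0", "18:0"))),                          # 4
    long_ms("PG", c("18:0", "16:0"), c("22:6", "20:3"), c("", ";OH")), # 8
    long_ms("PG", "18:1", c("20:1", "19:0"), c("", ";O")),             # 4
    paste0("PG ", c("18:2/18:1", "18:0/22:6", "18:0/16:0", "18:0/18:0",
                    "18:1/20:3", "16:0/20:1", "18:1/20:1", "16:0/19:0")), # 8
    long_ms("PG", "18:1", c("22:6", "20:3"), c("", ";O")),             # 4
    paste("PG", c("38:4", "40:6", "32:2", "34:3", "38:5", "30:1",
                  "40:4", "36:5", "42:6", "38:3"))                     # 10
  ), 86)
  ps_bg <- expand_bg("PS", list(
    sn_led("PS", c("18:1", "18:2", "18:0"), mods3),                    # 9
    pair_cycle("PS", c("", ";O", ";OH")),                              # 24
    paste("PS", c("34:1", "36:2", "36:1", "38:4", "40:6", "32:0",
                  "38:6", "34:2")),                                    # 8
    long_ms("PS", "18:0", c("22:6", "20:3"), c("", ";O")),             # 4
    pair_cycle("PS", "", sep = "/")                                    # 8
  ), 50)
  tg_bg <- expand_bg("TG", list(
    unlist(lapply(c("", ";O"), function(m)
      paste0("TG ", c("16:0_18:1_18:1", "16:0_16:0_18:1", "18:1_18:1_18:1",
                      "16:0_18:2_18:1", "18:2_18:2_18:1", "16:0_18:0_18:1",
                      "16:0_18:2_18:2", "18:0_18:1_18:2"), m))),       # 16
    paste0("TG ", c("16:0/18:1/18:1", "16:0/18:2/18:1", "16:0/16:0/18:1",
                    "18:1/18:1/18:1", "16:0/18:2/18:2", "16:0/18:0/18:1")),
    paste("TG", c("50:1", "52:2", "54:3", "50:2", "52:3", "54:6", "48:1",
                  "52:4", "54:4", "50:3", "48:0", "52:1", "54:2", "56:7",
                  "50:0", "54:5", "48:2", "56:8", "50:4", "52:5",
                  "54:1", "56:6", "48:3", "46:1", "46:0")),            # 25
    unlist(lapply(c("20:3", "22:6"), function(p)
      paste0("TG 16:0_18:1_", p, c("", ";O")))),                       # 4
    paste0("TG ", c("18:0_18:0_18:1", "16:0_16:0_16:0", "16:0_16:0_18:0",
                    "18:0_18:1_18:1", "16:0_18:1_20:1", "16:0_17:0_18:1"))
  ), 55)
  cer_bg <- expand_bg("Cer", list(
    unlist(lapply(c("16:0", "18:0", "20:0", "22:0", "24:0", "24:1", "26:1"),
                  function(acyl) paste0("Cer 18:1;O2/", acyl, c("", ";OH")))),
    unlist(lapply(c("16:0", "18:0", "22:0", "24:0", "24:1", "26:0"),
                  function(acyl) paste0("Cer 18:1;O2_", acyl, c("", ";OH")))),
    paste0("Cer ", c("34:1;O2", "36:1;O2", "40:1;O2", "42:1;O2", "42:2;O2",
                     "44:2;O2", "38:1;O2", "40:2;O2", "34:2;O2", "36:2;O2",
                     "44:1;O2", "46:2;O2", "32:1;O2", "38:2;O2", "46:1;O2",
                     "42:3;O2", "48:1;O2", "48:2;O2", "44:3;O2", "40:3;O2",
                     "36:3;O2", "34:0;O2", "38:0;O2", "42:0;O2"))      # 24
  ), 50)

  reference <- c(query, r_161, r_204, pc_bg, pe_bg, pg_bg, ps_bg, tg_bg, cer_bg)
  fixture <- list(query = query, reference = reference)
  if (verify) verify_demo4(fixture)
  fixture
}

# recount the seven printed marginals through the package machinery
verify_demo4 <- function(fixture) {
  q <- parse_batch(fixture$query)
  r <- parse_batch(fixture$reference)
  stopifnot(nrow(q$errors) == 0L, nrow(r$errors) == 0L,
            nrow(q$duplicates) == 0L, nrow(r$duplicates) == 0L,
            length(q$lipids) == 68L, length(r$lipids) == 556L)
  qs <- q$lipids; rs <- r$lipids
  n_gp <- function(lip) sum(vapply(lip, function(x) x$category == "GP", TRUE))
  n_gp01 <- function(lip) sum(vapply(lip, function(x) x$class_code == "GP01", TRUE))
  stopifnot(n_gp(qs) == 68L, n_gp(rs) == 448L,
            n_gp01(qs) == 26L, n_gp01(rs) == 148L)

  term <- function(classifier, value, level, condition = NA_character_) {
    data.frame(term_id = term_id(classifier, value, level, condition),
               classifier = classifier, value = value, level = level,
               condition = condition,
               display_label = term_display(classifier, value, condition),
               stringsAsFactors = FALSE)
  }
  targets <- rbind(
    cbind(term("CHAIN", "16:1", "MOLECULAR_SPECIES"), a = 13L, c = 18L),
    cbind(term("CHAIN", "20:4", "MOLECULAR_SPECIES"), a = 15L, c = 26L),
    cbind(term("CHAIN_AT_SN", "sn-2:20:4", "SN_POSITION"), a = 13L, c = 19L),
    cbind(term("CHAIN", "16:1", "MOLECULAR_SPECIES", "GP"), a = 13L, c = 17L),
    cbind(term("CHAIN", "20:4", "MOLECULAR_SPECIES", "GP"), a = 15L, c = 24L),
    cbind(term("CHAIN_AT_SN", "sn-2:20:4", "SN_POSITION", "GP"), a = 13L, c = 18L),
    cbind(term("CHAIN", "16:1", "MOLECULAR_SPECIES", "GP01"), a = 11L, c = 14L))
  counted <- count_memberships(targets[, 1:6], qs, rs)
  ok <- counted$a == targets$a & counted$c_ref == targets$c
  if (!all(ok)) {
    stop("demo fixture marginal recount failed for: ",
         paste(targets$display_label[!ok], collapse = "; "),
         " (got ", paste(sprintf("%d/%d", counted$a[!ok], counted$c_ref[!ok]),
                         collapse = ", "), ")")
  }
  invisible(TRUE)
}
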