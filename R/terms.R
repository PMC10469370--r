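# Structural term enumeration and membership counting.
#
# A term is one structural classifier instance (a class, a chain
# composition, an sn-resolved chain, a carbon/double-bond bin, ...) at the
# minimum nomenclature level a lipid must reach to be evaluable for it,
# optionally conditioned on a category or class ("Acyls 16:1 within
# Glycerophosphocholines [GP01]"). Terms are represented as data.frame rows
# keyed by (classifier, value, level, condition).

#' Term enumeration options
#'
#' @param grouped_bins emit per-chain carbon bins (`<16`, `16-18`, `>18`)
#'   and saturation bins (saturated / monounsaturated / polyunsaturated).
#' @param conditioned also cross every term with each observed category and
#'   class as a condition ("X within Y").
#' @param condition_depth `"class"` conditions on categories and classes,
#'   `"category"` on categories only.
#' @param db_positions emit double-bond position terms (for lipids resolved
#'   at `STRUCTURE_DEFINED` or above) and geometry terms (at
#'   `FULL_STRUCTURE`).
#' @param modifications emit named functional-group terms (e.g. `OH`);
#'   positions of modifications are never used.
#' @param bond_types emit ester / ether-O / ether-P bond-type terms for
#'   glycerolipid-like lipids.
#' @param universe `"fixed"` uses the full query/reference sizes (within the
#'   condition) as universes regardless of term level; `"evaluable"`
#'   restricts universes to lipids resolved deeply enough for the term.
#' @return a list of class `term_options`.
#' @export
term_options <- function(grouped_bins = TRUE, conditioned = TRUE,
                         condition_depth = c("class", "category"),
                         db_positions = TRUE, modifications = TRUE,
                         bond_types = TRUE, universe = c("fixed", "evaluable")) {
  structure(list(grouped_bins = isTRUE(grouped_bins),
                 conditioned = isTRUE(conditioned),
                 condition_depth = match.arg(condition_depth),
                 db_positions = isTRUE(db_positions),
                 modifications = isTRUE(modifications),
                 bond_types = isTRUE(bond_types),
                 universe = match.arg(universe)),
            class = "term_options")
}

# carbon-number bin of one chain: <16, 16-18, >18
c_group <- function(carbons) {
  ifelse(carbons < 16L, "<16", ifelse(carbons <= 18L, "16-18", ">18"))
}

# saturation bin of one chain
db_group <- function(double_bonds) {
  ifelse(double_bonds == 0L, "saturated",
         ifelse(double_bonds == 1L, "monounsaturated", "polyunsaturated"))
}

#' Grouped-bin terms of one chain
#'
#' Every chain falls in exactly one carbon bin (fewer than 16 carbons,
#' 16 to 18, more than 18) and exactly one saturation bin (saturated,
#' monounsaturated with one double bond, polyunsaturated with two or more).
#'
#' @param chain one chain record from a `parsed_lipid`.
#' @return data.frame with one `C_GROUP` and one `DB_GROUP` row.
#' @examples
#' x <- parse_lipid_name("PC 16:1_20:4")
#' chain_group_terms(x$chains[[1]])
#' @export
chain_group_terms <- function(chain) {
  stopifnot(is.list(chain), chain$carbons > 0L)
  data.frame(classifier = c("C_GROUP", "DB_GROUP"),
             value = c(c_group(chain$carbons), db_group(chain$double_bonds)),
             level = "MOLECULAR_SPECIES", stringsAsFactors = FALSE)
}

# structural features instantiated by one parsed lipid, as parallel
# vectors (classifier, value, level), deduplicated on (classifier, value)
lipid_features_vec <- function(lipid, options = term_options()) {
  cl <- c("CATEGORY", "CLASS", "TOTAL_C", "TOTAL_DB", "TOTAL_O")
  va <- c(lipid$category, lipid$class_code, as.character(lipid$total_c),
          as.character(lipid$total_db), as.character(lipid$total_o))
  lv <- c("CATEGORY", "CLASS", "SPECIES", "SPECIES", "SPECIES")

  chains <- lipid$chains
  real <- chains[vapply(chains, function(ch) ch$carbons > 0L, TRUE)]
  if (length(real)) {
    for (ch in real) {
      cd <- sprintf("%d:%d", ch$carbons, ch$double_bonds)
      cl <- c(cl, "CHAIN"); va <- c(va, cd); lv <- c(lv, "MOLECULAR_SPECIES")
      if (options$grouped_bins) {
        cl <- c(cl, "C_GROUP", "DB_GROUP")
        va <- c(va, c_group(ch$carbons), db_group(ch$double_bonds))
        lv <- c(lv, "MOLECULAR_SPECIES", "MOLECULAR_SPECIES")
      }
      if (!is.na(ch$sn) && level_geq(lipid$level, "SN_POSITION")) {
        cl <- c(cl, "CHAIN_AT_SN"); va <- c(va, sprintf("sn-%d:%s", ch$sn, cd))
        lv <- c(lv, "SN_POSITION")
      }
      if (options$modifications && length(ch$functional_groups)) {
        cl <- c(cl, rep("MODIFICATION", length(ch$functional_groups)))
        va <- c(va, names(ch$functional_groups))
        lv <- c(lv, rep("MOLECULAR_SPECIES", length(ch$functional_groups)))
      }
      if (options$db_positions && length(ch$db_positions) &&
          level_geq(lipid$level, "STRUCTURE_DEFINED")) {
        pv <- sprintf("%s(%d)", cd, ch$db_positions)
        cl <- c(cl, rep("DB_POSITION", length(pv))); va <- c(va, pv)
        lv <- c(lv, rep("STRUCTURE_DEFINED", length(pv)))
        geo <- nzchar(ch$db_geometry)
        if (any(geo)) {
          gv <- sprintf("%s(%d%s)", cd, ch$db_positions[geo], ch$db_geometry[geo])
          cl <- c(cl, rep("DB_POSITION", length(gv))); va <- c(va, gv)
          lv <- c(lv, rep("FULL_STRUCTURE", length(gv)))
        }
      }
    }
    if (options$bond_types && !any(vapply(real, function(ch) ch$bond == "sphingoid", TRUE))) {
      bonds <- vapply(real, function(ch) ch$bond, "")
      bt <- if ("alkenyl" %in% bonds) "ether-P" else
            if ("alkyl" %in% bonds) "ether-O" else "ester"
      cl <- c(cl, "BOND_TYPE"); va <- c(va, bt); lv <- c(lv, "MOLECULAR_SPECIES")
    }
  }
  keep <- !duplicated(paste(cl, va))
  list(classifier = cl[keep], value = va[keep], level = lv[keep])
}

# long feature table over a lipid list: one row per (lipid, feature),
# annotated with the lipid's own level rank, category and class, plus a
# prebuilt key -> row-index map for fast membership counting
feature_table <- function(lipids, options = term_options()) {
  if (length(lipids) == 0L) {
    out <- list(idx = integer(), classifier = character(),
                value = character(), level = character(),
                lrank = integer(), category = character(),
                class_code = character(), key = character(),
                by_key = list())
    return(out)
  }
  fl <- lapply(lipids, lipid_features_vec, options = options)
  n <- vapply(fl, function(f) length(f$classifier), 1L)
  cl <- unlist(lapply(fl, `[[`, "classifier"), use.names = FALSE)
  va <- unlist(lapply(fl, `[[`, "value"), use.names = FALSE)
  lv <- unlist(lapply(fl, `[[`, "level"), use.names = FALSE)
  key <- paste(cl, va)
  out <- list(idx = rep(seq_along(lipids), n),
              classifier = cl, value = va, level = lv,
              lrank = rep(vapply(lipids, function(x) level_rank(x$level), 1L), n),
              category = rep(vapply(lipids, function(x) x$category, ""), n),
              class_code = rep(vapply(lipids, function(x) x$class_code, ""), n),
              key = key,
              by_key = split(seq_along(key), key))
  out
}

# display label of a term row ("Acyls 16:1 within Glycerophosphocholines [GP01]")
term_display <- function(classifier, value, condition = NA_character_) {
  base <- switch(classifier,
    CATEGORY = category_display(value),
    CLASS = class_display(value),
    TOTAL_C = paste0("Total #C ", value),
    TOTAL_DB = paste0("Total #DB ", value),
    TOTAL_O = paste0("Total #O ", value),
    CHAIN = paste0("Acyls ", value),
    CHAIN_AT_SN = paste0("Acyls ", sub("^sn-[0-9]+:", "", value)),
    C_GROUP = paste0("Acyls C ", value),
    DB_GROUP = paste0("Acyls ", value),
    BOND_TYPE = paste0("Bond type ", value),
    MODIFICATION = paste0("Modification ", value),
    DB_POSITION = paste0("Double bond ", value),
    paste(classifier, value))
  if (!is.na(condition)) {
    cond_lab <- if (condition %in% names(.categories)) {
      category_display(condition)
    } else {
      class_display(condition)
    }
    base <- paste0(base, " within ", cond_lab)
  }
  base
}

term_id <- function(classifier, value, level, condition) {
  paste(classifier, value, level, ifelse(is.na(condition), "", condition),
        sep = "|")
}

#' Enumerate the structural-term universe of a reference lipidome
#'
#' Emits every term instantiated by at least one reference lipid:
#' unconditioned terms plus, when enabled, each term crossed with each
#' observed category and class as a condition. Category and class terms are
#' never conditioned on themselves.
#'
#' @param lipids list of `parsed_lipid` (typically the reference lipidome).
#' @param options a [term_options()] object.
#' @return data.frame with columns `term_id`, `classifier`, `value`,
#'   `level` (minimum evaluable level), `condition` (`NA` or a category /
#'   class code), `display_label`.
#' @examples
#' ref <- parse_batch(c("PC 16:1/18:0", "PE 36:2"))$lipids
#' enumerate_terms(ref)$display_label
#' @export
enumerate_terms <- function(lipids, options = term_options(),
                            features = NULL) {
  ft <- if (is.null(features)) feature_table(lipids, options) else features
  empty <- data.frame(term_id = character(), classifier = character(),
                      value = character(), level = character(),
                      condition = character(), display_label = character(),
                      stringsAsFactors = FALSE)
  if (length(ft$idx) == 0L) return(empty)

  take <- function(keep) {
    w <- which(keep)
    w <- w[!duplicated(ft$key[w])]
    data.frame(classifier = ft$classifier[w], value = ft$value[w],
               level = ft$level[w], stringsAsFactors = FALSE)
  }
  out <- take(rep(TRUE, length(ft$idx)))
  out$condition <- NA_character_

  conds <- character()
  if (options$conditioned) {
    conds <- unique(ft$category)
    if (options$condition_depth == "class") {
      conds <- c(conds, unique(ft$class_code))
    }
  }
  for (cd in conds) {
    in_cond <- if (cd %in% names(.categories)) ft$category == cd else ft$class_code == cd
    keep <- in_cond & !(ft$classifier %in% c("CATEGORY", "CLASS"))
    if (!any(keep)) next
    cb <- take(keep)
    cb$condition <- cd
    out <- rbind(out, cb)
  }
  out$term_id <- term_id(out$classifier, out$value, out$level, out$condition)
  out$display_label <- mapply(term_display, out$classifier, out$value,
                              out$condition, USE.NAMES = FALSE)
  rownames(out) <- NULL
  out[, c("term_id", "classifier", "value", "level", "condition", "display_label")]
}

# which lipids (indices) fall inside a term's condition
cond_mask <- function(lipids, condition) {
  if (is.na(condition)) return(rep(TRUE, length(lipids)))
  if (condition %in% names(.categories)) {
    vapply(lipids, function(x) x$category == condition, TRUE)
  } else {
    vapply(lipids, function(x) x$class_code == condition, TRUE)
  }
}

# row indices of `ft` matching term j (feature key, level eligibility,
# condition)
term_hits <- function(ft, terms, j, trank = level_rank(terms$level)) {
  rows <- ft$by_key[[paste(terms$classifier[j], terms$value[j])]]
  if (is.null(rows)) return(integer())
  rows <- rows[ft$lrank[rows] >= trank[j]]
  if (!is.na(terms$condition[j]) && length(rows)) {
    cd <- terms$condition[j]
    rows <- if (cd %in% names(.categories)) {
      rows[ft$category[rows] == cd]
    } else {
      rows[ft$class_code[rows] == cd]
    }
  }
  rows
}

# vectorised membership counting for all terms over query and reference.
# Returns `terms` with columns a (query members), c_ref (reference members),
# q_universe, r_universe appended.
count_memberships <- function(terms, query, reference,
                              options = term_options(),
                              query_features = NULL, ref_features = NULL) {
  trank <- level_rank(terms$level)
  count_side <- function(ft) {
    vapply(seq_len(nrow(terms)),
           function(j) length(unique(ft$idx[term_hits(ft, terms, j, trank)])),
           1L)
  }
  universe_side <- function(lipids) {
    lrank <- vapply(lipids, function(x) level_rank(x$level), 1L)
    cat_ <- vapply(lipids, function(x) x$category, "")
    cls_ <- vapply(lipids, function(x) x$class_code, "")
    vapply(seq_len(nrow(terms)), function(j) {
      keep <- rep(TRUE, length(lipids))
      if (!is.na(terms$condition[j])) {
        cd <- terms$condition[j]
        keep <- if (cd %in% names(.categories)) cat_ == cd else cls_ == cd
      }
      if (options$universe == "evaluable") keep <- keep & lrank >= trank[j]
      sum(keep)
    }, 1L)
  }
  if (is.null(query_features)) query_features <- feature_table(query, options)
  if (is.null(ref_features)) ref_features <- feature_table(reference, options)
  terms$a <- count_side(query_features)
  terms$c_ref <- count_side(ref_features)
  terms$q_universe <- universe_side(query)
  terms$r_universe <- universe_side(reference)
  terms
}

#' Query/reference membership of one term
#'
#' A lipid is a member of a term when it instantiates the term's classifier
#' value, is resolved at or above the term's level, and lies inside the
#' term's condition (if any). A `CHAIN` term matches any chain with the
#' given composition regardless of sn position; a `CHAIN_AT_SN` term
#' matches only the chain at its stated sn index. Universes follow the
#' `universe` term option: `"fixed"` counts all lipids inside the condition,
#' `"evaluable"` only those resolved deeply enough for the term.
#'
#' @param term one row of an [enumerate_terms()] data.frame.
#' @param query,reference lists of `parsed_lipid`.
#' @param options a [term_options()] object.
#' @return a list of class `term_membership` with the term row, the member
#'   canonical names on each side, and the two universe sizes.
#' @export
membership <- function(term, query, reference, options = term_options()) {
  stopifnot(is.data.frame(term), nrow(term) == 1L)
  counted <- count_memberships(term, query, reference, options)
  side_names <- function(lipids) {
    ft <- feature_table(lipids, options)
    rows <- term_hits(ft, term, 1L)
    vapply(lipids[sort(unique(ft$idx[rows]))], function(x) x$name, "")
  }
  structure(list(term = term,
                 query_members = side_names(query),
                 reference_members = side_names(reference),
                 query_universe = counted$q_universe,
                 reference_universe = counted$r_universe),
            class = "term_membership")
}
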