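# Shorthand lipid-name parser.
#
# Implements the shorthand dialect: "HG tC:tD[;O]" at species level,
# "HG c1 _ c2" at molecular-species level, "HG c1 / c2" with known sn
# positions, plus per-chain double-bond position lists "(5,8,10,14)" with
# optional geometry "(9Z,12Z)" and oxygen modifications ";O", ";O2", ";OH",
# ";(OH)2", ";oxo", ";OOH", ";Ep", ";COOH". Ether chains carry an "O-"
# (alkyl) or "P-" (alkenyl) prefix. Positions of modifications and
# stereo/enantiomer annotations are not interpreted.

# oxygen atoms contributed by one instance of each named functional group
.fg_oxygens <- c(OH = 1L, oxo = 1L, OOH = 2L, COOH = 2L, Ep = 1L)

.err <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "lipidenrich_error")))
}

err_unparseable <- function(name, why) {
  .err("lipidenrich_unparseable",
       sprintf("cannot parse lipid name '%s': %s", name, why), name = name)
}

new_chain <- function(bond = "acyl", carbons = 0L, double_bonds = 0L,
                      db_positions = integer(), db_geometry = character(),
                      oxygens = 0L, functional_groups = integer(), sn = NA_integer_) {
  list(bond = bond, carbons = as.integer(carbons),
       double_bonds = as.integer(double_bonds),
       db_positions = as.integer(db_positions),
       db_geometry = as.character(db_geometry),
       oxygens = as.integer(oxygens),
       functional_groups = functional_groups,
       sn = as.integer(sn))
}

# parse one chain token, e.g. "O-18:1(9Z);OH" -> chain list (sn filled later)
parse_chain_token <- function(token, name) {
  m <- regmatches(token,
    regexec("^(O-|P-|d|t)?([0-9]+):([0-9]+)(\\(([^()]*)\\))?((;.+)?)$", token))[[1]]
  if (length(m) == 0) err_unparseable(name, sprintf("bad chain token '%s'", token))
  prefix <- m[2]
  carbons <- as.integer(m[3])
  db <- as.integer(m[4])
  bond <- switch(prefix, "O-" = "alkyl", "P-" = "alkenyl", "acyl")
  extra_o <- if (prefix == "d") 2L else if (prefix == "t") 3L else 0L
  if (prefix %in% c("d", "t")) bond <- "sphingoid"

  db_pos <- integer()
  db_geo <- character()
  if (nzchar(m[5])) {
    if (!nzchar(m[6])) err_unparseable(name, "empty double-bond position list")
    specs <- strsplit(m[6], ",", fixed = TRUE)[[1]]
    pm <- regmatches(specs, regexec("^\\s*([0-9]+)\\s*(E|Z|cis|trans)?\\s*$", specs))
    bad <- vapply(pm, length, 1L) == 0L
    if (any(bad)) err_unparseable(name, sprintf("bad double-bond spec in '%s'", token))
    db_pos <- vapply(pm, function(x) as.integer(x[2]), 1L)
    db_geo <- vapply(pm, function(x) x[3], "")
    db_geo[db_geo == "cis"] <- "Z"
    db_geo[db_geo == "trans"] <- "E"
    if (length(db_pos) != db) {
      err_unparseable(name, sprintf(
        "%d double-bond positions given for %d double bonds in '%s'",
        length(db_pos), db, token))
    }
    o <- order(db_pos)
    db_pos <- db_pos[o]
    db_geo <- db_geo[o]
  }

  oxy <- extra_o
  fgs <- integer()
  mods <- m[7]
  if (nzchar(mods)) {
    toks <- strsplit(sub("^;", "", mods), ";", fixed = TRUE)[[1]]
    for (tk in toks) {
      om <- regmatches(tk, regexec("^O([0-9]+)?$", tk))[[1]]
      if (length(om)) {
        oxy <- oxy + if (nzchar(om[2])) as.integer(om[2]) else 1L
        next
      }
      fm <- regmatches(tk, regexec("^\\(?([A-Za-z]+)\\)?([0-9]+)?$", tk))[[1]]
      if (length(fm) == 0 || !(fm[2] %in% names(.fg_oxygens))) {
        err_unparseable(name, sprintf("unknown modification ';%s'", tk))
      }
      cnt <- if (nzchar(fm[3])) as.integer(fm[3]) else 1L
      fgs[fm[2]] <- (if (fm[2] %in% names(fgs)) fgs[[fm[2]]] else 0L) + cnt
      oxy <- oxy + .fg_oxygens[[fm[2]]] * cnt
    }
  }
  new_chain(bond = bond, carbons = carbons, double_bonds = db,
            db_positions = db_pos, db_geometry = db_geo,
            oxygens = oxy, functional_groups = fgs)
}

#' Parse a shorthand lipid name
#'
#' Translates one shorthand lipid name into its hierarchical structural
#' representation: headgroup, category and class (from the built-in table,
#' see [lipid_class_table()]), the individual chains with double-bond
#' positions/geometry and oxygen modifications, the summed totals, and the
#' nomenclature level the name resolves to.
#'
#' Separator semantics follow the shorthand convention: `"/"` means sn
#' positions are known, `"_"` means they are not; a name without chain
#' separators carries totals only (species level). Names that mix levels
#' (for example double-bond positions together with the `"_"` separator,
#' `"PC 16:1(7)_16:1(9)"`) are coerced down to the closest valid level
#' (`"PC 16:1_16:1"`) and flagged via the `coerced` field rather than
#' rejected. Trailing adduct annotations (`"[M+H]+"`) are stripped.
#'
#' @param name a single lipid name, e.g. `"PC 18:2/20:4;O"`.
#' @param grammar nomenclature dialect. Only `"shorthand"` is implemented;
#'   the other selectors are recognised but raise an unsupported-grammar
#'   error.
#' @return an object of class `parsed_lipid`: a list with fields
#'   `raw_name`, `name` (canonical form at the lipid's own level),
#'   `headgroup`, `category`, `class_code`, `chains` (list of chain records
#'   with `bond`, `carbons`, `double_bonds`, `db_positions`, `db_geometry`,
#'   `oxygens`, `functional_groups`, `sn`), `level`, `total_c`, `total_db`,
#'   `total_o`, and `coerced`.
#' @seealso [parse_batch()] for lists, [normalize_name()] for rewriting at
#'   a lower level, [determine_level()].
#' @examples
#' x <- parse_lipid_name("PE 16:0/20:4(5,8,10,14);OH")
#' x$level
#' x$total_c
#' @export
parse_lipid_name <- function(name, grammar = c("shorthand", "lipidmaps",
                                               "swisslipids", "hmdb")) {
  grammar <- match.arg(grammar)
  if (grammar != "shorthand") {
    .err("lipidenrich_unsupported_grammar",
         sprintf("grammar '%s' is not implemented; use 'shorthand'", grammar))
  }
  raw <- name
  if (!is.character(name) || length(name) != 1L) {
    err_unparseable(paste(deparse(name), collapse = ""), "not a single string")
  }
  name <- trimws(name)
  if (!nzchar(name)) err_unparseable(raw, "empty name")
  # strip trailing adduct annotation, e.g. "[M+H]+", "[M-H]-", "[M+NH4]+"
  name <- trimws(sub("\\s*\\[M[^]]*\\][0-9]*[+-]?$", "", name))
  if (!nzchar(name)) err_unparseable(raw, "nothing left after adduct removal")

  hm <- regmatches(name, regexec("^([A-Za-z][A-Za-z0-9]*)\\s+(.+)$", name))[[1]]
  if (length(hm) == 0) err_unparseable(raw, "expected 'Headgroup chains'")
  headgroup <- hm[2]
  body <- gsub("\\s*([/_])\\s*", "\\1", hm[3])  # whitespace-insensitive separators
  hrow <- .headgroups[match(headgroup, .headgroups$headgroup), ]
  if (is.na(hrow$class_code)) {
    err_unparseable(raw, sprintf("unknown headgroup '%s'", headgroup))
  }

  sep <- if (grepl("/", body, fixed = TRUE)) "/" else
         if (grepl("_", body, fixed = TRUE)) "_" else ""
  tokens <- if (sep == "") body else strsplit(body, sep, fixed = TRUE)[[1]]
  chains <- lapply(tokens, parse_chain_token, name = raw)

  coerced <- FALSE
  if (sep == "") {
    # species-level: totals only; positions on a totals name are mixed-level
    agg <- chains[[1]]
    if (length(agg$db_positions)) {
      agg$db_positions <- integer(); agg$db_geometry <- character()
      coerced <- TRUE
    }
    if (length(agg$functional_groups)) {
      # species level carries only the oxygen count
      agg$functional_groups <- integer()
    }
    lipid <- list(raw_name = raw, headgroup = headgroup,
                  category = hrow$category, class_code = hrow$class_code,
                  chains = list(), level = "SPECIES",
                  species_prefix = switch(agg$bond, alkyl = "O-", alkenyl = "P-", ""),
                  total_c = agg$carbons, total_db = agg$double_bonds,
                  total_o = agg$oxygens, coerced = coerced)
    class(lipid) <- "parsed_lipid"
    lipid$name <- format_lipid(lipid, lipid$level)
    return(lipid)
  }

  real <- vapply(chains, function(ch) ch$carbons > 0L, TRUE)
  if (!any(real)) err_unparseable(raw, "no real chain (all slots empty)")
  if (any(vapply(chains[real], function(ch) ch$carbons < 2L, TRUE))) {
    err_unparseable(raw, "chains must have at least 2 carbons")
  }
  if (hrow$sphingoid && chains[[1]]$bond == "acyl") chains[[1]]$bond <- "sphingoid"

  if (sep == "_") {
    sn <- rep(NA_integer_, length(chains))
    has_pos <- vapply(chains, function(ch) length(ch$db_positions) > 0L, TRUE)
    if (any(has_pos)) {
      # mixed level: positional information with unknown sn assignment
      chains <- lapply(chains, function(ch) {
        ch$db_positions <- integer(); ch$db_geometry <- character(); ch
      })
      coerced <- TRUE
    }
    level <- "MOLECULAR_SPECIES"
  } else {
    sn <- seq_along(chains)
    with_db <- vapply(chains, function(ch) ch$double_bonds > 0L, TRUE)
    has_pos <- vapply(chains, function(ch) length(ch$db_positions) > 0L, TRUE)
    if (any(has_pos) && !all(has_pos[with_db])) {
      # positions on some but not all unsaturated chains: coerce down
      chains <- lapply(chains, function(ch) {
        ch$db_positions <- integer(); ch$db_geometry <- character(); ch
      })
      has_pos <- rep(FALSE, length(chains))
      coerced <- TRUE
    }
    if (any(with_db) && all(has_pos[with_db])) {
      geo <- unlist(lapply(chains, function(ch) ch$db_geometry))
      all_geo <- length(geo) > 0L && all(nzchar(geo))
      if (!all_geo && any(nzchar(geo))) {
        # partial geometry: strip it, keep positions
        chains <- lapply(chains, function(ch) {
          ch$db_geometry <- rep("", length(ch$db_positions)); ch
        })
        coerced <- TRUE
        all_geo <- FALSE
      }
      unpositioned_o <- sum(vapply(chains, function(ch) ch$oxygens, 1L)) > 0L
      level <- if (all_geo && !unpositioned_o) "FULL_STRUCTURE" else "STRUCTURE_DEFINED"
    } else {
      level <- "SN_POSITION"
    }
  }
  for (i in seq_along(chains)) chains[[i]]$sn <- sn[i]

  rc <- chains[real]
  lipid <- list(raw_name = raw, headgroup = headgroup,
                category = hrow$category, class_code = hrow$class_code,
                chains = chains, level = level, species_prefix = "",
                total_c = sum(vapply(rc, function(ch) ch$carbons, 1L)),
                total_db = sum(vapply(rc, function(ch) ch$double_bonds, 1L)),
                total_o = sum(vapply(rc, function(ch) ch$oxygens, 1L)),
                coerced = coerced)
  class(lipid) <- "parsed_lipid"
  lipid$name <- format_lipid(lipid, lipid$level)
  lipid
}

#' Nomenclature level of a parsed lipid
#'
#' Returns the highest level fully supported by the information present in
#' the name (separator kind, double-bond positions, geometry). The level is
#' resolved during parsing; this accessor exposes it.
#'
#' @param lipid a `parsed_lipid`.
#' @return one of [lipid_levels].
#' @examples
#' determine_level(parse_lipid_name("PC 18:1_18:1"))  # MOLECULAR_SPECIES
#' determine_level(parse_lipid_name("PC 18:1/18:1"))  # SN_POSITION
#' @export
determine_level <- function(lipid) {
  stopifnot(inherits(lipid, "parsed_lipid"))
  lipid$level
}

# format one chain at a given target level
format_chain <- function(ch, target) {
  prefix <- switch(ch$bond, alkyl = "O-", alkenyl = "P-", "")
  s <- sprintf("%s%d:%d", prefix, ch$carbons, ch$double_bonds)
  if (level_geq(target, "STRUCTURE_DEFINED") && length(ch$db_positions)) {
    keep_geo <- level_geq(target, "FULL_STRUCTURE")
    specs <- paste0(ch$db_positions, if (keep_geo) ch$db_geometry else "")
    s <- paste0(s, "(", paste(specs, collapse = ","), ")")
  }
  plain_o <- ch$oxygens -
    sum(.fg_oxygens[names(ch$functional_groups)] * ch$functional_groups)
  if (plain_o > 0L) s <- paste0(s, ";O", if (plain_o > 1L) plain_o else "")
  if (length(ch$functional_groups)) {
    fg <- ch$functional_groups[order(names(ch$functional_groups))]
    s <- paste0(s, paste0(";", ifelse(fg > 1L, paste0("(", names(fg), ")", fg),
                                      names(fg)), collapse = ""))
  }
  s
}

# canonical name of `lipid` at `target` level (no availability check here)
format_lipid <- function(lipid, target) {
  if (target == "CATEGORY") return(category_display(lipid$category))
  if (target == "CLASS") return(class_display(lipid$class_code))
  if (target == "SPECIES" || length(lipid$chains) == 0L) {
    prefix <- lipid$species_prefix
    if (length(lipid$chains)) {
      bonds <- vapply(lipid$chains, function(ch) ch$bond, "")
      prefix <- if ("alkyl" %in% bonds) "O-" else if ("alkenyl" %in% bonds) "P-" else ""
    }
    s <- sprintf("%s %s%d:%d", lipid$headgroup, prefix, lipid$total_c, lipid$total_db)
    if (lipid$total_o > 0L) {
      s <- paste0(s, ";O", if (lipid$total_o > 1L) lipid$total_o else "")
    }
    return(s)
  }
  chains <- lipid$chains
  if (target == "MOLECULAR_SPECIES") {
    toks <- vapply(chains, format_chain, "", target = target)
    ord <- order(
      -vapply(chains, function(ch) ch$bond == "sphingoid", TRUE),
      -vapply(chains, function(ch) ch$bond %in% c("alkyl", "alkenyl"), TRUE),
      vapply(chains, function(ch) ch$carbons, 1L),
      vapply(chains, function(ch) ch$double_bonds, 1L),
      vapply(chains, function(ch) ch$oxygens, 1L),
      toks)
    return(paste0(lipid$headgroup, " ", paste(toks[ord], collapse = "_")))
  }
  # sn-resolved representations keep the stated chain order
  toks <- vapply(chains, format_chain, "", target = target)
  paste0(lipid$headgroup, " ", paste(toks, collapse = "/"))
}

#' Rewrite a lipid name at a lower nomenclature level
#'
#' Produces the canonical shorthand name of `lipid` at `target_level`,
#' dropping the information above that level: double-bond geometry above
#' `STRUCTURE_DEFINED`, double-bond positions above `SN_POSITION`, sn
#' assignments above `MOLECULAR_SPECIES` (the separator becomes `"_"` and
#' chains are put in canonical order), and individual chains above
#' `SPECIES` (chains are summed into totals and named oxygen modifications
#' collapse into the total oxygen count).
#'
#' @param lipid a `parsed_lipid`.
#' @param target_level a level at or below the lipid's own level.
#' @return the canonical name (a string).
#' @examples
#' normalize_name(parse_lipid_name("PC 18:2/20:4;O"), "SPECIES")  # "PC 38:6;O"
#' @export
normalize_name <- function(lipid, target_level) {
  stopifnot(inherits(lipid, "parsed_lipid"))
  target_level <- match.arg(target_level, lipid_levels)
  if (!level_geq(lipid$level, target_level)) {
    .err("lipidenrich_level_unavailable",
         sprintf("'%s' resolves to %s; level %s is not available",
                 lipid$name, lipid$level, target_level))
  }
  format_lipid(lipid, target_level)
}

#' @export
print.parsed_lipid <- function(x, ...) {
  cat(sprintf("<parsed_lipid> %s\n", x$name))
  cat(sprintf("  %s, %s, level %s; C%d:DB%d;O%d%s\n",
              category_display(x$category), class_display(x$class_code),
              level_label(x$level), x$total_c, x$total_db, x$total_o,
              if (isTRUE(x$coerced)) " (coerced)" else ""))
  if (length(x$chains)) {
    for (ch in x$chains) {
      cat(sprintf("  chain sn-%s: %s [%s]\n",
                  ifelse(is.na(ch$sn), "?", ch$sn),
                  format_chain(ch, "FULL_STRUCTURE"), ch$bond))
    }
  }
  invisible(x)
}

#' Parse a list of lipid names
#'
#' Order-preserving batch parser. Unparseable names are collected, never
#' fatal; duplicates (identical canonical names at each lipid's own level)
#' are reported and removed, keeping the first occurrence.
#'
#' @param names character vector of lipid names.
#' @param grammar see [parse_lipid_name()].
#' @return a list with components `lipids` (list of `parsed_lipid`),
#'   `errors` (data.frame `name`/`message`), and `duplicates` (data.frame
#'   `name`/`canonical` of dropped repeats).
#' @examples
#' parse_batch(c("PC 36:2", "PC 36:2", "not_a_lipid"))
#' @export
parse_batch <- function(names, grammar = "shorthand") {
  lipids <- vector("list", length(names))
  errs_name <- character()
  errs_msg <- character()
  ok <- logical(length(names))
  for (i in seq_along(names)) {
    res <- tryCatch(parse_lipid_name(names[[i]], grammar = grammar),
                    lipidenrich_unparseable = function(e) e)
    if (inherits(res, "parsed_lipid")) {
      lipids[[i]] <- res
      ok[i] <- TRUE
    } else {
      errs_name <- c(errs_name, names[[i]])
      errs_msg <- c(errs_msg, conditionMessage(res))
    }
  }
  lipids <- lipids[ok]
  keys <- vapply(lipids, function(x) x$name, "")
  dup <- duplicated(keys)
  duplicates <- data.frame(name = vapply(lipids[dup], function(x) x$raw_name, ""),
                           canonical = keys[dup], stringsAsFactors = FALSE)
  list(lipids = lipids[!dup],
       errors = data.frame(name = errs_name, message = errs_msg,
                           stringsAsFactors = FALSE),
       duplicates = duplicates)
}
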