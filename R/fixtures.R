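# Synthetic lipidome generator with planted structural enrichment.
#
# Generates grammar-valid shorthand names for a query/reference pair. The
# generator emulates an LC-MS mammalian lipidome: a class mixture over
# glycerophospholipids, glycerolipids and ceramides, chains drawn from a
# frequency pool of common fatty acyls, a mix of nomenclature levels
# (species / molecular species / sn-position / structure-defined), and
# sparse oxygen modifications. Planted terms force a chain composition
# into a chosen fraction of each list so that enrichment recovery and
# type-I error behaviour can be studied under known truth.

#' Specification of a synthetic lipidome
#'
#' Defaults reproduce the technical demo scale: 68 query lipids against a
#' 556-lipid reference with a composition typical of LC-MS studies.
#'
#' @param n_reference,n_query list sizes.
#' @param classes named weights over headgroups from [lipid_class_table()].
#' @param chain_pool data.frame `chain` ("C:D" strings) and `weight`;
#'   partner chains are drawn from it.
#' @param level_mix named weights over `SPECIES`, `MOLECULAR_SPECIES`,
#'   `SN_POSITION`, `STRUCTURE_DEFINED`.
#' @param mod_prob probability that a lipid carries one `;O` / `;OH`
#'   modification (split evenly).
#' @param planted optional data.frame with columns `value` (a "C:D" chain),
#'   `query_prev`, `ref_prev`: each row plants that chain into the given
#'   fraction of each list (at molecular-species level or above). Planted
#'   chain values are removed from the background pool.
#' @param seed integer seed; generation is a pure function of the spec.
#' @return list of class `lipidome_spec`.
#' @export
lipidome_spec <- function(n_reference = 556L, n_query = 68L,
                          classes = c(PC = 0.26, PE = 0.26, PG = 0.14,
                                      PS = 0.09, TG = 0.14, Cer = 0.11),
                          chain_pool = data.frame(
                            chain = c("16:0", "18:1", "18:2", "18:0",
                                      "20:4", "22:6", "16:1", "20:3",
                                      "20:5", "22:5", "22:4", "17:0",
                                      "14:0", "20:1", "24:1", "24:0"),
                            weight = c(0.17, 0.16, 0.12, 0.09,
                                       0.06, 0.05, 0.05, 0.04,
                                       0.03, 0.03, 0.03, 0.03,
                                       0.03, 0.03, 0.04, 0.04),
                            stringsAsFactors = FALSE),
                          level_mix = c(SPECIES = 0.15,
                                        MOLECULAR_SPECIES = 0.55,
                                        SN_POSITION = 0.22,
                                        STRUCTURE_DEFINED = 0.08),
                          mod_prob = 0.10,
                          planted = NULL,
                          seed = 1L) {
  stopifnot(n_reference >= 1L, n_query >= 1L,
            all(names(classes) %in% .headgroups$headgroup),
            all(chain_pool$weight >= 0), all(level_mix >= 0),
            mod_prob >= 0, mod_prob <= 1)
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("value", "query_prev", "ref_prev") %in% names(planted)))
    if (any(planted$query_prev < 0 | planted$query_prev > 1 |
            planted$ref_prev < 0 | planted$ref_prev > 1)) {
      .err("lipidenrich_infeasible_spec", "prevalences must lie in [0, 1]")
    }
    if (sum(round(planted$query_prev * n_query)) > n_query ||
        sum(round(planted$ref_prev * n_reference)) > n_reference) {
      .err("lipidenrich_infeasible_spec",
           "planted prevalences exceed the list sizes")
    }
  }
  structure(list(n_reference = as.integer(n_reference),
                 n_query = as.integer(n_query),
                 classes = classes / sum(classes),
                 chain_pool = chain_pool,
                 level_mix = level_mix / sum(level_mix),
                 mod_prob = mod_prob,
                 planted = planted,
                 seed = as.integer(seed)),
            class = "lipidome_spec")
}

# double-bond positions for a C:D chain at structure-defined level:
# methylene-interrupted pattern starting near the carboxyl end
db_position_string <- function(carbons, db) {
  if (db == 0L) return("")
  start <- max(2L, carbons - 3L * db - 2L)
  paste0("(", paste(seq(start, by = 3L, length.out = db), collapse = ","), ")")
}

split_cd <- function(chain) {
  parts <- strsplit(chain, ":", fixed = TRUE)[[1]]
  c(as.integer(parts[1]), as.integer(parts[2]))
}

# assemble one shorthand name from class row, chain strings, level, mod
assemble_name <- function(headgroup, chains, level, mod) {
  hrow <- .headgroups[match(headgroup, .headgroups$headgroup), ]
  if (level == "SPECIES") {
    cd <- vapply(chains, split_cd, integer(2))
    tot <- rowSums(cd)
    extra_o <- if (hrow$sphingoid) 2L else 0L
    o <- extra_o + (mod != "")
    return(sprintf("%s %d:%d%s", headgroup, tot[1], tot[2],
                   if (o > 0L) paste0(";O", if (o > 1L) o else "") else ""))
  }
  if (hrow$sphingoid) chains[1] <- paste0(chains[1], ";O2")
  if (level == "STRUCTURE_DEFINED") {
    chains <- vapply(chains, function(ch) {
      cd <- split_cd(sub(";.*$", "", ch))
      paste0(sub(";.*$", "", ch), db_position_string(cd[1], cd[2]),
             sub("^[^;]*", "", ch))
    }, "")
  }
  sep <- if (level == "MOLECULAR_SPECIES") "_" else "/"
  body <- paste(chains, collapse = sep)
  if (mod != "") body <- paste0(body, mod)
  paste(headgroup, body)
}

# canonical collision key: molecular-species chains are order-free
name_key <- function(name) {
  vapply(name, function(nm) {
    if (!grepl("_", nm, fixed = TRUE)) return(nm)
    hg <- sub(" .*$", "", nm)
    body <- sub("^\\S+ ", "", nm)
    paste(hg, paste(sort(strsplit(body, "_", fixed = TRUE)[[1]]),
                    collapse = "_"))
  }, "", USE.NAMES = FALSE)
}

draw_batch <- function(n, spec, prefix_pool) {
  hg <- sample(names(spec$classes), n, replace = TRUE, prob = spec$classes)
  lv <- sample(names(spec$level_mix), n, replace = TRUE, prob = spec$level_mix)
  out <- character(n)
  for (i in seq_len(n)) {
    hrow <- .headgroups[match(hg[i], .headgroups$headgroup), ]
    k <- hrow$n_chains
    chains <- sample(prefix_pool$chain, k, replace = TRUE,
                     prob = prefix_pool$weight)
    if (hrow$sphingoid) chains[1] <- "18:1"  # sphingoid backbone
    level <- lv[i]
    # structure-defined needs at least one unsaturated chain
    if (level == "STRUCTURE_DEFINED" &&
        all(vapply(chains, function(ch) split_cd(ch)[2], 1L) == 0L)) {
      level <- "SN_POSITION"
    }
    if (hrow$n_chains == 1L && level != "SPECIES") level <- "SPECIES"
    mod <- if (stats::runif(1) < spec$mod_prob) {
      if (stats::runif(1) < 0.5) ";O" else ";OH"
    } else ""
    out[i] <- assemble_name(hg[i], chains, level, mod)
  }
  out
}

# draw until n canonically distinct names are collected
draw_lipids <- function(n, spec, prefix_pool) {
  out <- character(0)
  for (round in 1:50) {
    fresh <- draw_batch(max(n, 32L), spec, prefix_pool)
    out <- c(out, fresh)
    out <- out[!duplicated(name_key(out))]
    if (length(out) >= n) return(out[seq_len(n)])
  }
  .err("lipidenrich_infeasible_spec",
       "cannot draw enough distinct lipid names; widen the chain pool")
}

#' Generate a synthetic query/reference lipidome pair
#'
#' Deterministic under the spec's seed. All emitted names are grammar
#' valid; realized planted-term counts are exact on the lipids selected
#' for planting (selection is random, so term membership is exact while
#' the joint structure varies by seed). Duplicate names can arise and are
#' deduplicated downstream by [parse_batch()], so realized list sizes are
#' within sampling error of the spec.
#'
#' @param spec a [lipidome_spec()].
#' @return list with character vectors `query` and `reference`, and the
#'   realized planted counts in `planted_counts`.
#' @export
generate_lipidome <- function(spec) {
  stopifnot(inherits(spec, "lipidome_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  pool <- spec$chain_pool
  if (!is.null(spec$planted)) {
    pool <- pool[!(pool$chain %in% spec$planted$value), , drop = FALSE]
  }
  query <- draw_lipids(spec$n_query, spec, pool)
  reference <- draw_lipids(spec$n_reference, spec, pool)

  planted_counts <- NULL
  if (!is.null(spec$planted)) {
    plant <- function(names_vec, value, k, used) {
      # plant into molecular-species-or-better names not planted before
      eligible <- setdiff(which(grepl("[_/]", names_vec)), used)
      if (length(eligible) < k) {
        .err("lipidenrich_infeasible_spec",
             "not enough eligible lipids to plant the requested prevalence")
      }
      idx <- sample(eligible, k)
      for (i in idx) {
        sep <- if (grepl("_", names_vec[i], fixed = TRUE)) "_" else "/"
        parts <- strsplit(sub("^\\S+ ", "", names_vec[i]), sep, fixed = TRUE)[[1]]
        hgname <- sub(" .*$", "", names_vec[i])
        slot <- if (length(parts) > 1L) 2L else 1L
        # keep the ';...' modifications, drop old double-bond positions
        keep_mod <- sub("^[^;]*", "", gsub("\\([^)]*\\)", "", parts[slot]))
        parts[slot] <- paste0(value, keep_mod)
        names_vec[i] <- paste(hgname, paste(parts, collapse = sep))
      }
      list(names = names_vec, idx = idx)
    }
    planted_counts <- data.frame(value = spec$planted$value,
                                 query = round(spec$planted$query_prev * spec$n_query),
                                 reference = round(spec$planted$ref_prev * spec$n_reference))
    used_q <- integer(); used_r <- integer()
    for (r in seq_len(nrow(spec$planted))) {
      pq <- plant(query, spec$planted$value[r], planted_counts$query[r], used_q)
      query <- pq$names; used_q <- c(used_q, pq$idx)
      pr <- plant(reference, spec$planted$value[r], planted_counts$reference[r], used_r)
      reference <- pr$names; used_r <- c(used_r, pr$idx)
    }
  }
  list(query = query, reference = reference, planted_counts = planted_counts)
}

#' Convenience generator
#'
#' @param n_query,n_reference,seed passed to [lipidome_spec()].
#' @param ... further [lipidome_spec()] arguments.
#' @return see [generate_lipidome()].
#' @export
demo_lipidome <- function(n_query = 68L, n_reference = 556L, seed = 1L, ...) {
  generate_lipidome(lipidome_spec(n_reference = n_reference,
                                  n_query = n_query, seed = seed, ...))
}
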