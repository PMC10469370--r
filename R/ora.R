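# Enrichment statistics: Fisher's exact test on the 2x2 term-by-list
# table, the hypergeometric tail, multiple-testing adjustment, and the
# assembly of the over-represented term table.
#
# Contingency orientation: query and reference are treated as two
# independent groups with counts exactly as supplied (the reference is not
# reduced by its overlap with the query):
#
#               with term   without term
#   query           a            b         (a + b = query universe)
#   reference       c            d         (c + d = reference universe)

check_table <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    .err("lipidenrich_invalid_table",
         "contingency entries must be nonnegative integers")
  }
  stats::setNames(as.integer(round(v)), names(v))
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' The odds ratio is the sample cross-product ratio (a*d)/(b*c), reported
#' as `Inf` when `b*c == 0` with `a*d > 0` and as `NaN` when both products
#' are zero. P-values come from the exact conditional hypergeometric
#' distribution; the two-sided p sums all outcome probabilities at most
#' the observed one (with a `1 + 1e-7` relative tie tolerance, the usual
#' exact-test convention).
#'
#' @param a,b query lipids with / without the term.
#' @param c,d reference lipids with / without the term.
#' @param alternative `"two-sided"`, `"less"` or `"greater"`.
#' @return list with `odds_ratio` and `p_value`.
#' @examples
#' fisher_exact(13, 55, 18, 538)$odds_ratio  # 7.0646
#' @export
fisher_exact <- function(a, b, c, d,
                         alternative = c("two-sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  v <- check_table(a, b, c, d)
  a <- v[["a"]]; b <- v[["b"]]; c <- v[["c"]]; d <- v[["d"]]
  ad <- as.numeric(a) * d
  bc <- as.numeric(b) * c
  odds_ratio <- if (bc == 0 && ad == 0) NaN else ad / bc

  N <- a + b + c + d
  K <- a + c   # lipids with the term
  n <- a + b   # query universe (draws)
  lo <- max(0L, n - (N - K))
  hi <- min(n, K)
  p_value <- if (N == 0L) {
    1
  } else if (alternative == "less") {
    stats::phyper(a, K, N - K, n)
  } else if (alternative == "greater") {
    stats::phyper(a - 1L, K, N - K, n, lower.tail = FALSE)
  } else {
    dens <- stats::dhyper(lo:hi, K, N - K, n)
    sum(dens[dens <= dens[a - lo + 1L] * (1 + 1e-7)])
  }
  list(odds_ratio = odds_ratio, p_value = min(1, p_value))
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability P(X >= a) for drawing `a` term-carrying lipids in
#' a query of size `a + b` from a population of size `a + b + c + d`
#' containing `a + c` carriers. Identical to the one-sided (`"greater"`)
#' Fisher exact p on the same table.
#'
#' @inheritParams fisher_exact
#' @return the tail probability.
#' @export
hypergeom_p <- function(a, b, c, d) {
  v <- check_table(a, b, c, d)
  a <- v[["a"]]; b <- v[["b"]]; c <- v[["c"]]; d <- v[["d"]]
  stats::phyper(a - 1L, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Multiple-testing adjustment
#'
#' Wraps [stats::p.adjust()]: Bonferroni (`min(1, m*p)`), Holm's step-down,
#' or Benjamini-Hochberg step-up (the classic false discovery rate).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param method `"bonferroni"`, `"holm"`, `"benjamini-hochberg"` (alias
#'   `"BH"`), or `"none"`.
#' @return adjusted p-values, clipped to `[0, 1]`, in input order.
#' @examples
#' adjust_pvalues(c(0.001, 0.002, 0.02, 0.8), "benjamini-hochberg")
#' @export
adjust_pvalues <- function(p_values,
                           method = c("benjamini-hochberg", "bonferroni",
                                      "holm", "BH", "none")) {
  method <- match.arg(method)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    .err("lipidenrich_invalid_p", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = switch(method,
    "benjamini-hochberg" = "BH", "BH" = "BH",
    "bonferroni" = "bonferroni", "holm" = "holm", "none" = "none"))
}

#' ORA parameters
#'
#' @param test `"fisher"` (with selectable alternative) or
#'   `"hypergeometric"` (upper tail).
#' @param alternative Fisher alternative; ignored for the hypergeometric
#'   test.
#' @param correction multiple-testing procedure, see [adjust_pvalues()].
#' @param alpha significance threshold on the adjusted p-value.
#' @param family_scope correction family: `"all_terms"` adjusts all tested
#'   terms together; `"per_level"` adjusts within each nomenclature level;
#'   `"per_classifier"` within each (classifier, level) family, which
#'   corrects each structural family for its own size.
#' @param include_zero_query also test terms with no query members
#'   (enlarges the correction family; off by default).
#' @return list of class `ora_params`.
#' @export
ora_params <- function(test = c("fisher", "hypergeometric"),
                       alternative = c("two-sided", "less", "greater"),
                       correction = c("benjamini-hochberg", "bonferroni",
                                      "holm", "none"),
                       alpha = 0.05,
                       family_scope = c("all_terms", "per_level",
                                        "per_classifier"),
                       include_zero_query = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  structure(list(test = match.arg(test),
                 alternative = match.arg(alternative),
                 correction = match.arg(correction),
                 alpha = alpha,
                 family_scope = match.arg(family_scope),
                 include_zero_query = isTRUE(include_zero_query)),
            class = "ora_params")
}

as_parsed_list <- function(x, what) {
  if (is.character(x)) x <- parse_batch(x)
  if (is.list(x) && !is.null(x$lipids)) {
    return(list(lipids = x$lipids,
                errors = if (is.null(x$errors)) data.frame() else x$errors,
                duplicates = if (is.null(x$duplicates)) data.frame() else x$duplicates))
  }
  if (is.list(x) && all(vapply(x, inherits, TRUE, "parsed_lipid"))) {
    return(list(lipids = x, errors = data.frame(), duplicates = data.frame()))
  }
  stop(what, " must be a character vector of lipid names, a parse_batch() ",
       "result, or a list of parsed_lipid objects")
}

#' Lipid over-representation analysis
#'
#' The central fitting function. Parses the query and reference lipid
#' lists, enumerates the structural-term universe from the reference,
#' counts query/reference membership for every term, tests each term with
#' at least one query member, adjusts for multiple testing inside the
#' configured family scope, and returns the ranked term table together
#' with everything needed for intersection/VIL analysis and reporting.
#'
#' Results are sorted by ascending adjusted p, then raw p, then display
#' label, so identical inputs always produce identical tables.
#'
#' @param query,reference character vectors of lipid names (parsed
#'   internally), [parse_batch()] results, or lists of `parsed_lipid`.
#'   The reference is the codomain: the full detected lipidome against
#'   which enrichment of the query is measured.
#' @param params an [ora_params()] object.
#' @param options a [term_options()] object.
#' @return an object of class `lipid_ora` with components `results` (the
#'   term table: term identity columns, the 2x2 counts `a`, `b`, `c`, `d`,
#'   `p_value`, `odds_ratio`, `adjusted_p`, `significant`), `query` /
#'   `reference` (parsed lipid lists), `parse_info`, `params`, `options`.
#' @examples
#' fx <- demo_lipidome(n_query = 20, n_reference = 80, seed = 1)
#' fit <- lipid_ora(fx$query, fx$reference)
#' head(summary(fit))
#' @export
lipid_ora <- function(query, reference, params = ora_params(),
                      options = term_options()) {
  stopifnot(inherits(params, "ora_params"), inherits(options, "term_options"))
  q <- as_parsed_list(query, "query")
  r <- as_parsed_list(reference, "reference")
  if (length(q$lipids) == 0L) .err("lipidenrich_empty_query",
                                   "no parseable query lipids")
  if (length(r$lipids) == 0L) .err("lipidenrich_empty_reference",
                                   "no parseable reference lipids")

  ft_q <- feature_table(q$lipids, options)
  ft_r <- feature_table(r$lipids, options)
  terms <- enumerate_terms(r$lipids, options, features = ft_r)
  terms <- count_memberships(terms, q$lipids, r$lipids, options,
                             query_features = ft_q, ref_features = ft_r)
  if (!params$include_zero_query) terms <- terms[terms$a > 0L, ]

  n <- nrow(terms)
  p <- numeric(n)
  or <- numeric(n)
  for (j in seq_len(n)) {
    a <- terms$a[j]; b <- terms$q_universe[j] - a
    c <- terms$c_ref[j]; d <- terms$r_universe[j] - c
    if (params$test == "fisher") {
      ft <- fisher_exact(a, b, c, d, alternative = params$alternative)
      p[j] <- ft$p_value; or[j] <- ft$odds_ratio
    } else {
      p[j] <- hypergeom_p(a, b, c, d)
      ad <- as.numeric(a) * d; bc <- as.numeric(b) * c
      or[j] <- if (bc == 0 && ad == 0) NaN else ad / bc
    }
  }
  terms$b <- terms$q_universe - terms$a
  terms$d <- terms$r_universe - terms$c_ref
  terms$p_value <- p
  terms$odds_ratio <- or

  fam <- switch(params$family_scope,
    all_terms = rep("all", n),
    per_level = terms$level,
    per_classifier = paste(terms$classifier, terms$level))
  adj <- numeric(n)
  for (f in unique(fam)) {
    i <- fam == f
    adj[i] <- adjust_pvalues(p[i], params$correction)
  }
  terms$adjusted_p <- adj
  crit <- if (params$correction == "none") terms$p_value else terms$adjusted_p
  # alpha = 1 disables the threshold entirely (p-values never exceed 1)
  terms$significant <- if (params$alpha >= 1) rep(TRUE, n) else crit < params$alpha

  ord <- order(terms$adjusted_p, terms$p_value, terms$display_label)
  terms <- terms[ord, ]
  rownames(terms) <- NULL
  names(terms)[names(terms) == "c_ref"] <- "c"

  structure(list(results = terms,
                 query = q$lipids, reference = r$lipids,
                 parse_info = list(query_errors = q$errors,
                                   query_duplicates = q$duplicates,
                                   reference_errors = r$errors,
                                   reference_duplicates = r$duplicates),
                 params = params, options = options),
            class = "lipid_ora")
}

#' Significant terms of a fitted ORA
#'
#' @param x a `lipid_ora` object.
#' @return the rows of `x$results` flagged significant.
#' @export
significant_terms <- function(x) {
  stopifnot(inherits(x, "lipid_ora"))
  x$results[x$results$significant, , drop = FALSE]
}

# result table in the printed layout: Term, Goslin-style level, counts,
# p-value, odds ratio and the adjusted-p ("FDR") column rounded to 4 d.p.
ora_table <- function(x, significant_only = TRUE) {
  res <- if (significant_only) significant_terms(x) else x$results
  data.frame(
    Term = res$display_label,
    Level = level_label(res$level),
    `No..Query` = sprintf("%d/%d", res$a, res$q_universe),
    `No..Reference` = sprintf("%d/%d", res$c, res$r_universe),
    `p.value` = signif(res$p_value, 3),
    `Odds.Ratio` = round(res$odds_ratio, 4),
    FDR = round(res$adjusted_p, 4),
    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @export
print.lipid_ora <- function(x, ...) {
  cat(sprintf("Lipid over-representation analysis (%s test, %s, %s)\n",
              x$params$test, x$params$alternative, x$params$correction))
  cat(sprintf("  query: %d lipids, reference: %d lipids, %d terms tested\n",
              length(x$query), length(x$reference), nrow(x$results)))
  sig <- significant_terms(x)
  cat(sprintf("  %d significant terms at alpha %g\n\n",
              nrow(sig), x$params$alpha))
  if (nrow(sig)) print(ora_table(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.lipid_ora <- function(object, significant_only = TRUE, ...) {
  ora_table(object, significant_only = significant_only)
}

#' @export
as.data.frame.lipid_ora <- function(x, ...) x$results
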