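# UpSet-style exclusive intersections of significant terms and Very
# Important Lipids.
#
# Exclusive semantics: each query lipid belongs to exactly one
# intersection record, the one given by its full membership profile over
# the retained terms. A VIL is a query lipid belonging to the maximum
# number of significant terms.

#' Term-by-lipid membership matrix over significant terms
#'
#' Builds the boolean incidence matrix of significant terms (rows) by
#' query lipids (columns). At most `max_terms` terms are retained, chosen
#' by ascending adjusted p, then raw p, then display label; enumerating
#' all intersections of many more sets grows exponentially, so the cap
#' keeps the analysis tractable.
#'
#' @param x a fitted [lipid_ora()] object.
#' @param max_terms maximum number of terms to retain (default 13).
#' @param terms optional character vector of term ids or display labels to
#'   restrict the matrix to (applied before the cap).
#' @return an object of class `membership_matrix`: a list with `terms`
#'   (the retained result rows) and `incidence` (logical term x lipid
#'   matrix, columns named by canonical query lipid names).
#' @export
build_membership <- function(x, max_terms = 13L, terms = NULL) {
  stopifnot(inherits(x, "lipid_ora"))
  sig <- significant_terms(x)
  if (!is.null(terms)) {
    sig <- sig[sig$term_id %in% terms | sig$display_label %in% terms, ,
               drop = FALSE]
  }
  if (nrow(sig) == 0L) {
    .err("lipidenrich_no_significant_terms", "no significant terms to intersect")
  }
  sig <- sig[order(sig$adjusted_p, sig$p_value, sig$display_label), , drop = FALSE]
  if (nrow(sig) > max_terms) sig <- sig[seq_len(max_terms), , drop = FALSE]

  ft <- feature_table(x$query, x$options)
  lipid_names <- vapply(x$query, function(l) l$name, "")
  inc <- matrix(FALSE, nrow(sig), length(x$query),
                dimnames = list(sig$term_id, lipid_names))
  for (j in seq_len(nrow(sig))) {
    inc[j, unique(ft$idx[term_hits(ft, sig, j)])] <- TRUE
  }
  structure(list(terms = sig, incidence = inc), class = "membership_matrix")
}

#' Exclusive UpSet intersections of a membership matrix
#'
#' Groups query lipids by their identical term profile. Each lipid that
#' belongs to at least one retained term falls in exactly one record; the
#' union of all records is the set of covered lipids (partition property).
#' Records are sorted by descending degree (number of terms in the
#' profile), then descending cardinality (number of lipids), then by the
#' concatenated term labels.
#'
#' @param matrix a [build_membership()] result.
#' @param sort_by `"degree"` (degree, then cardinality) or `"cardinality"`
#'   (cardinality, then degree).
#' @return data.frame with one row per non-empty profile: `profile_id`,
#'   `degree`, `cardinality`, `term_ids` (list column), `term_labels`
#'   (collapsed label string), `lipids` (list column of canonical names).
#' @export
enumerate_intersections <- function(matrix, sort_by = c("degree", "cardinality")) {
  stopifnot(inherits(matrix, "membership_matrix"))
  sort_by <- match.arg(sort_by)
  inc <- matrix$incidence
  covered <- colSums(inc) > 0L
  if (!any(covered)) {
    return(data.frame(profile_id = character(), degree = integer(),
                      cardinality = integer(), term_labels = character(),
                      stringsAsFactors = FALSE))
  }
  inc <- inc[, covered, drop = FALSE]
  profile <- apply(inc, 2, function(col) paste(which(col), collapse = ","))
  groups <- split(colnames(inc), profile)
  keys <- names(groups)
  term_sets <- lapply(strsplit(keys, ",", fixed = TRUE), as.integer)
  degree <- vapply(term_sets, length, 1L)
  cardinality <- vapply(groups, length, 1L)
  labels <- vapply(term_sets, function(i) {
    paste(sort(matrix$terms$display_label[i]), collapse = " & ")
  }, "")
  out <- data.frame(profile_id = keys, degree = degree,
                    cardinality = cardinality, term_labels = labels,
                    stringsAsFactors = FALSE)
  out$term_ids <- lapply(term_sets, function(i) matrix$terms$term_id[i])
  out$lipids <- unname(groups)
  ord <- if (sort_by == "degree") {
    order(-out$degree, -out$cardinality, out$term_labels)
  } else {
    order(-out$cardinality, -out$degree, out$term_labels)
  }
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}

#' Very Important Lipids
#'
#' A VIL is a query lipid that belongs to the maximum number of
#' significant terms (its degree, the column sum of the membership
#' matrix). All lipids achieving the maximum are flagged; ties are all
#' retained.
#'
#' @param matrix a [build_membership()] result.
#' @return data.frame `lipid`, `degree`, `is_vil`, sorted by descending
#'   degree then lipid name.
#' @export
select_vils <- function(matrix) {
  stopifnot(inherits(matrix, "membership_matrix"))
  degree <- colSums(matrix$incidence)
  out <- data.frame(lipid = colnames(matrix$incidence),
                    degree = as.integer(degree),
                    stringsAsFactors = FALSE)
  out$is_vil <- out$degree == max(out$degree) & out$degree > 0L
  out <- out[order(-out$degree, out$lipid), ]
  rownames(out) <- NULL
  out
}

#' Lipids of one intersection record
#'
#' @param record one row of an [enumerate_intersections()] result.
#' @param matrix the [build_membership()] result it came from.
#' @return data.frame with one row per lipid in the intersection and the
#'   shared term labels.
#' @export
intersection_table <- function(record, matrix) {
  stopifnot(is.data.frame(record), nrow(record) == 1L,
            inherits(matrix, "membership_matrix"))
  lipids <- record$lipids[[1]]
  data.frame(lipid = lipids,
             degree = rep(record$degree, length(lipids)),
             shared_terms = rep(record$term_labels, length(lipids)),
             stringsAsFactors = FALSE)
}

#' Tidy long-format export of an UpSet membership structure
#'
#' @param matrix a [build_membership()] result.
#' @return data.frame `profile_id`, `degree`, `cardinality`, `lipid`, one
#'   row per (intersection, lipid).
#' @export
upset_long <- function(matrix) {
  rec <- enumerate_intersections(matrix)
  if (nrow(rec) == 0L) {
    return(data.frame(profile_id = character(), degree = integer(),
                      cardinality = integer(), lipid = character(),
                      stringsAsFactors = FALSE))
  }
  n <- vapply(rec$lipids, length, 1L)
  data.frame(profile_id = rep(rec$profile_id, n),
             degree = rep(rec$degree, n),
             cardinality = rep(rec$cardinality, n),
             lipid = unlist(rec$lipids),
             stringsAsFactors = FALSE)
}
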