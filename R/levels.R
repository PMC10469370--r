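#' Nomenclature levels of the shorthand lipid hierarchy
#'
#' Shorthand lipid names encode information depth: a name resolves to exactly
#' one level, from the lipid category down to the complete structure with
#' stereochemistry. Levels form a total order; [level_rank()] gives the rank
#' used for comparisons, lowest (CATEGORY) first.
#'
#' The eight levels, in increasing order of structural resolution, are
#' `CATEGORY`, `CLASS`, `SPECIES` (totals only, e.g. `"PC 36:2"`),
#' `MOLECULAR_SPECIES` (chains known, sn positions unknown, `"_"` separator),
#' `SN_POSITION` (chains at known sn positions, `"/"` separator),
#' `STRUCTURE_DEFINED` (double-bond positions known),
#' `FULL_STRUCTURE` (double-bond geometry known), and
#' `COMPLETE_STRUCTURE` (full stereochemistry; not produced by this parser,
#' which does not interpret enantiomer annotations).
#'
#' @format `lipid_levels` is a character vector of the eight level names in
#'   ascending order.
#' @export
lipid_levels <- c(
  "CATEGORY", "CLASS", "SPECIES", "MOLECULAR_SPECIES",
  "SN_POSITION", "STRUCTURE_DEFINED", "FULL_STRUCTURE", "COMPLETE_STRUCTURE"
)

#' Rank of a nomenclature level
#'
#' @param level character vector of level names (see [lipid_levels]).
#' @return integer rank, 1 = `CATEGORY` ... 8 = `COMPLETE_STRUCTURE`.
#' @examples
#' level_rank("SPECIES") < level_rank("SN_POSITION")
#' @export
level_rank <- function(level) {
  r <- match(level, lipid_levels)
  if (anyNA(r)) {
    stop("unknown nomenclature level: ",
         paste(unique(level[is.na(r)]), collapse = ", "))
  }
  r
}

#' Compare two nomenclature levels
#'
#' `level_geq(a, b)` is `TRUE` where level `a` carries at least as much
#' structural information as level `b`.
#'
#' @param a,b character vectors of level names.
#' @return logical vector.
#' @export
level_geq <- function(a, b) level_rank(a) >= level_rank(b)

# display form used in result tables ("MOLECULAR SPECIES", "SN POSITION", ...)
level_label <- function(level) gsub("_", " ", level, fixed = TRUE)
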