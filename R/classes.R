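# Built-in headgroup table.
#
# Curated mapping headgroup -> (LIPID MAPS-style class code, category code,
# expected chain count). Covers the classes typical of LC-MS mammalian
# lipidomes: diacyl glycerophospholipids and their lyso forms, glycerolipids,
# common sphingolipids, free fatty acids and steryl esters. Ether (O-/P-)
# variants share the headgroup row; the chain prefix carries the bond kind.
.headgroups <- local({
  hg <- function(headgroup, class_code, class_label, category, n_chains,
                 sphingoid = FALSE) {
    data.frame(headgroup = headgroup, class_code = class_code,
               class_label = class_label, category = category,
               n_chains = n_chains, sphingoid = sphingoid,
               stringsAsFactors = FALSE)
  }
  rbind(
    hg("PC",  "GP01", "Glycerophosphocholines",      "GP", 2L),
    hg("PE",  "GP02", "Glycerophosphoethanolamines", "GP", 2L),
    hg("PS",  "GP03", "Glycerophosphoserines",       "GP", 2L),
    hg("PG",  "GP04", "Glycerophosphoglycerols",     "GP", 2L),
    hg("PI",  "GP06", "Glycerophosphoinositols",     "GP", 2L),
    hg("PA",  "GP10", "Glycerophosphates",           "GP", 2L),
    hg("LPC", "GP01", "Glycerophosphocholines",      "GP", 1L),
    hg("LPE", "GP02", "Glycerophosphoethanolamines", "GP", 1L),
    hg("LPS", "GP03", "Glycerophosphoserines",       "GP", 1L),
    hg("LPG", "GP04", "Glycerophosphoglycerols",     "GP", 1L),
    hg("LPI", "GP06", "Glycerophosphoinositols",     "GP", 1L),
    hg("LPA", "GP10", "Glycerophosphates",           "GP", 1L),
    hg("MG",  "GL01", "Monoradylglycerols",          "GL", 1L),
    hg("DG",  "GL02", "Diradylglycerols",            "GL", 2L),
    hg("TG",  "GL03", "Triradylglycerols",           "GL", 3L),
    hg("SM",  "SP03", "Phosphosphingolipids",        "SP", 2L, sphingoid = TRUE),
    hg("Cer", "SP02", "Ceramides",                   "SP", 2L, sphingoid = TRUE),
    hg("HexCer", "SP05", "Neutral glycosphingolipids", "SP", 2L, sphingoid = TRUE),
    hg("FA",  "FA01", "Fatty acids and conjugates",  "FA", 1L),
    hg("CE",  "ST01", "Steryl esters",               "ST", 1L),
    hg("ChE", "ST01", "Steryl esters",               "ST", 1L)
  )
})

.categories <- c(
  GP = "Glycerophospholipids",
  GL = "Glycerolipids",
  SP = "Sphingolipids",
  FA = "Fatty acyls",
  ST = "Sterol lipids"
)

#' Supported headgroups and their classification
#'
#' The built-in table mapping shorthand headgroups to a LIPID MAPS-style
#' class code, class label, category code and the expected number of radyl
#' chains. Parsing a name whose headgroup is not in this table raises an
#' unparseable-name error.
#'
#' @return data.frame with columns `headgroup`, `class_code`, `class_label`,
#'   `category`, `n_chains`, `sphingoid`.
#' @examples
#' head(lipid_class_table())
#' @export
lipid_class_table <- function() .headgroups

# "Glycerophosphocholines [GP01]" -- the display form used in term labels
class_display <- function(class_code) {
  i <- match(class_code, .headgroups$class_code)
  paste0(.headgroups$class_label[i], " [", class_code, "]")
}

category_display <- function(category) {
  paste0(.categories[category], " [", category, "]")
}
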