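# Lipidome hierarchy tree and phyloXML export.
#
# The parsed lipidome is arranged as a rooted pseudophylogenetic tree:
# root -> category -> class -> species-level name -> finer names, with each
# lipid appearing as exactly one leaf at its resolved level. Branch lengths
# are differences of fixed per-level radii, so a radial drawing places each
# hierarchy level on its own ring. Only CATEGORY and CLASS internal nodes
# carry labels; leaves carry the lipid name.

default_radii <- function() {
  stats::setNames(seq_along(lipid_levels), lipid_levels)
}

#' Build the lipidome hierarchy tree
#'
#' @param lipids list of `parsed_lipid` (duplicates by canonical name are
#'   collapsed).
#' @param radii named numeric vector of per-level radial distances
#'   (monotone increasing; default 1..8 for CATEGORY..COMPLETE_STRUCTURE).
#' @return object of class `lipidome_tree`: a node table with `id`,
#'   `parent` (0 for the root's parent), `level`, `label` (non-empty only
#'   for CATEGORY/CLASS internal nodes and leaves), `branch_length`,
#'   `is_leaf`.
#' @examples
#' tr <- build_tree(parse_batch(c("PC 36:2", "PE 38:4"))$lipids)
#' sum(tr$nodes$is_leaf)
#' @export
build_tree <- function(lipids, radii = default_radii()) {
  stopifnot(length(lipids) >= 1L)
  stopifnot(all(lipid_levels %in% names(radii)), !is.unsorted(radii[lipid_levels]))
  keys <- vapply(lipids, function(x) x$name, "")
  lipids <- lipids[!duplicated(keys)]

  nodes <- data.frame(id = 1L, parent = 0L, level = "ROOT", label = "",
                      branch_length = 0, is_leaf = FALSE,
                      stringsAsFactors = FALSE)
  # path key -> node id, to share internal nodes between lipids
  index <- new.env(parent = emptyenv())
  radius <- function(level) if (level == "ROOT") 0 else radii[[level]]

  add_node <- function(parent, level, label, key, leaf) {
    if (!leaf && !is.null(index[[key]])) return(index[[key]])
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, parent, level, label,
                         radius(level) - radius(nodes$level[parent]), leaf)
    if (!leaf) index[[key]] <- id
    id
  }

  for (lp in lipids) {
    path_levels <- lipid_levels[seq_len(level_rank(lp$level))]
    parent <- 1L
    key <- ""
    for (lev in path_levels) {
      nm <- format_lipid(lp, lev)
      key <- paste(key, nm, sep = "\r")
      leaf <- lev == lp$level
      label <- if (lev %in% c("CATEGORY", "CLASS") || leaf) nm else ""
      parent <- add_node(parent, lev, label, key, leaf)
    }
  }
  structure(list(nodes = nodes, radii = radii), class = "lipidome_tree")
}

#' @export
print.lipidome_tree <- function(x, ...) {
  cat(sprintf("<lipidome_tree> %d nodes, %d leaves\n",
              nrow(x$nodes), sum(x$nodes$is_leaf)))
  invisible(x)
}

#' Convert a lipidome tree to an ape "phylo" object
#'
#' Internal nodes of degree one (chains of single-child nodes) are kept,
#' which ape tolerates for plotting after `ape::collapse.singles()`.
#'
#' @param x a `lipidome_tree`.
#' @param ... unused.
#' @return an object of class `phylo`.
#' @method as.phylo lipidome_tree
#' @export
as.phylo.lipidome_tree <- function(x, ...) {
  nodes <- x$nodes
  leaves <- nodes$id[nodes$is_leaf]
  internals <- nodes$id[!nodes$is_leaf]
  new_id <- integer(nrow(nodes))
  new_id[leaves] <- seq_along(leaves)
  new_id[internals] <- length(leaves) + seq_along(internals)
  has_parent <- nodes$parent > 0L
  edge <- cbind(new_id[nodes$parent[has_parent]], new_id[nodes$id[has_parent]])
  phy <- structure(list(
    edge = edge,
    edge.length = nodes$branch_length[has_parent],
    tip.label = nodes$label[nodes$is_leaf],
    node.label = nodes$label[!nodes$is_leaf],
    Nnode = length(internals)), class = "phylo")
  ape::collapse.singles(phy)
}

xml_clade <- function(parent_xml, tree, id) {
  nodes <- tree$nodes
  row <- nodes[id, ]
  clade <- xml2::xml_add_child(parent_xml, "clade")
  if (row$parent > 0L) {
    xml2::xml_set_attr(clade, "branch_length",
                       format(row$branch_length, digits = 10))
  }
  if (nzchar(row$label)) xml2::xml_add_child(clade, "name", row$label)
  for (child in nodes$id[nodes$parent == id]) xml_clade(clade, tree, child)
  clade
}

#' Write a lipidome tree as phyloXML
#'
#' Emits a rooted phyloXML phylogeny (namespace
#' `http://www.phyloxml.org`). Branch lengths are per-level radius
#' differences; names appear on CATEGORY/CLASS internal nodes and on
#' leaves only.
#'
#' @param tree a `lipidome_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phyloxml <- function(tree, path) {
  stopifnot(inherits(tree, "lipidome_tree"))
  doc <- xml2::xml_new_root("phyloxml",
    "xmlns" = "http://www.phyloxml.org",
    "xmlns:xsi" = "http://www.w3.org/2001/XMLSchema-instance",
    "xsi:schemaLocation" =
      "http://www.phyloxml.org http://www.phyloxml.org/1.10/phyloxml.xsd")
  phy <- xml2::xml_add_child(doc, "phylogeny", rooted = "true")
  xml2::xml_add_child(phy, "name", "lipidome hierarchy")
  xml_clade(phy, tree, 1L)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a phyloXML lipidome tree back into a node table
#'
#' Round-trip companion of [write_phyloxml()]; used to verify that the
#' export preserves topology, labels and branch lengths.
#'
#' @param path a phyloXML file.
#' @return data.frame `id`, `parent`, `label`, `branch_length`, `is_leaf`.
#' @export
read_phyloxml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(px = "http://www.phyloxml.org")
  root <- xml2::xml_find_first(doc, ".//px:phylogeny/px:clade", ns)
  nodes <- data.frame(id = integer(), parent = integer(), label = character(),
                      branch_length = numeric(), is_leaf = logical(),
                      stringsAsFactors = FALSE)
  walk <- function(clade, parent) {
    id <- nrow(nodes) + 1L
    name <- xml2::xml_find_first(clade, "./px:name", ns)
    bl <- xml2::xml_attr(clade, "branch_length")
    children <- xml2::xml_find_all(clade, "./px:clade", ns)
    nodes[id, ] <<- list(id, parent,
                         if (inherits(name, "xml_missing")) "" else xml2::xml_text(name),
                         if (is.na(bl)) 0 else as.numeric(bl),
                         length(children) == 0L)
    for (ch in children) walk(ch, id)
  }
  walk(root, 0L)
  nodes
}
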