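# Base-graphics visualisations: an UpSet-style intersection plot for the
# significant terms and a radial drawing of the lipidome hierarchy.

#' UpSet-style plot of significant-term intersections
#'
#' Draws exclusive intersections (cardinality bars on top, term-membership
#' dot matrix below, per-term query counts as side bars). Intersections
#' are ordered as in [enumerate_intersections()].
#'
#' @param x a fitted [lipid_ora()] object.
#' @param max_terms term cap passed to [build_membership()].
#' @param max_intersections show at most this many intersections.
#' @param ... unused.
#' @return the intersection table, invisibly.
#' @export
plot.lipid_ora <- function(x, max_terms = 13L, max_intersections = 20L, ...) {
  mm <- build_membership(x, max_terms = max_terms)
  rec <- enumerate_intersections(mm)
  if (nrow(rec) > max_intersections) rec <- rec[seq_len(max_intersections), ]
  terms <- mm$terms
  nt <- nrow(terms)
  ni <- nrow(rec)
  term_sizes <- rowSums(mm$incidence)

  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  graphics::layout(matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE),
                   widths = c(2.2, 3), heights = c(1.4, 2))
  graphics::par(mar = c(0.5, 0.5, 2, 2))
  bp <- graphics::barplot(rec$cardinality, col = "grey30", border = NA,
                          ylab = "", main = "intersection size")
  graphics::text(bp, rec$cardinality, labels = rec$cardinality, pos = 3,
                 xpd = NA, cex = 0.8)

  graphics::par(mar = c(1, 0.5, 0.5, 0))
  graphics::barplot(rev(term_sizes), horiz = TRUE, col = "grey60",
                    border = NA, names.arg = rev(substr(terms$display_label,
                                                        1, 40)),
                    las = 1, cex.names = 0.7, main = "")

  graphics::par(mar = c(1, 0.5, 0.5, 2))
  graphics::plot(NULL, xlim = c(0.5, ni + 0.5), ylim = c(0.5, nt + 0.5),
                 axes = FALSE, xlab = "", ylab = "")
  for (j in seq_len(ni)) {
    idx <- match(rec$term_ids[[j]], terms$term_id)
    yy <- nt + 1L - seq_len(nt)
    graphics::points(rep(j, nt), yy, pch = 21, cex = 1.3,
                     bg = ifelse(seq_len(nt) %in% idx, "grey20", "grey90"),
                     col = "grey50")
    if (length(idx) > 1L) {
      graphics::segments(j, min(nt + 1L - idx), j, max(nt + 1L - idx),
                         lwd = 2, col = "grey20")
    }
  }
  invisible(rec)
}

#' Radial plot of the lipidome hierarchy
#'
#' @param tree a [build_tree()] result.
#' @param ... passed to [ape::plot.phylo()].
#' @return invisibly, the `phylo` object drawn.
#' @export
plot_lipidome_tree <- function(tree, ...) {
  phy <- as.phylo.lipidome_tree(tree)
  ape::plot.phylo(phy, type = "fan", cex = 0.5, no.margin = TRUE,
                  show.node.label = TRUE, ...)
  invisible(phy)
}
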