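# Reading lipid lists and writing the report bundle.

#' Read a lipid name list
#'
#' Plain text (one name per line; blank lines skipped) or a CSV with a
#' `Name` column. Order is preserved.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"txt"` or `"csv"`.
#' @return character vector of names.
#' @export
read_lipid_list <- function(path, format = c("auto", "txt", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    .err("lipidenrich_file_missing", sprintf("file not found: %s", path))
  }
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "txt"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"Name" %in% names(df)) {
      .err("lipidenrich_missing_column",
           sprintf("no 'Name' column in %s", path))
    }
    names_out <- trimws(as.character(df$Name))
  } else {
    names_out <- trimws(readLines(path, warn = FALSE))
  }
  names_out <- names_out[nzchar(names_out)]
  if (length(names_out) == 0L) {
    .err("lipidenrich_empty_file", sprintf("no lipid names in %s", path))
  }
  names_out
}

# per-name normalization report (one row per parsed name)
parse_report <- function(batch_result) {
  lip <- batch_result$lipids
  data.frame(
    name = vapply(lip, function(x) x$raw_name, ""),
    canonical = vapply(lip, function(x) x$name, ""),
    level = vapply(lip, function(x) level_label(x$level), ""),
    category = vapply(lip, function(x) x$category, ""),
    class = vapply(lip, function(x) x$class_code, ""),
    coerced = vapply(lip, function(x) isTRUE(x$coerced), TRUE),
    stringsAsFactors = FALSE)
}

# hierarchy node/edge tables down to the class level, with per-node counts
network_tables <- function(lipids) {
  cats <- vapply(lipids, function(x) x$category, "")
  cls <- vapply(lipids, function(x) x$class_code, "")
  cat_counts <- table(cats)
  cls_counts <- table(paste(cats, cls, sep = "|"))
  cls_key <- strsplit(names(cls_counts), "|", fixed = TRUE)
  nodes <- rbind(
    data.frame(id = "root", label = "lipidome", level = "ROOT",
               count = length(lipids), stringsAsFactors = FALSE),
    data.frame(id = names(cat_counts),
               label = category_display(names(cat_counts)),
               level = "CATEGORY", count = as.integer(cat_counts),
               stringsAsFactors = FALSE),
    data.frame(id = vapply(cls_key, `[`, "", 2),
               label = class_display(vapply(cls_key, `[`, "", 2)),
               level = "CLASS", count = as.integer(cls_counts),
               stringsAsFactors = FALSE))
  edges <- rbind(
    data.frame(from = "root", to = names(cat_counts), stringsAsFactors = FALSE),
    data.frame(from = vapply(cls_key, `[`, "", 1),
               to = vapply(cls_key, `[`, "", 2), stringsAsFactors = FALSE))
  list(nodes = nodes, edges = edges)
}

params_snapshot <- function(x) {
  list(test = x$params$test,
       alternative = x$params$alternative,
       correction = x$params$correction,
       alpha = x$params$alpha,
       family_scope = x$params$family_scope,
       include_zero_query = x$params$include_zero_query,
       term_options = unclass(x$options),
       n_query = length(x$query),
       n_reference = length(x$reference),
       n_terms_tested = nrow(x$results),
       n_significant = sum(x$results$significant))
}

html_summary <- function(x, out_file) {
  sig <- ora_table(x)
  rows <- if (nrow(sig)) {
    paste0("<tr><td>", apply(sig, 1, paste, collapse = "</td><td>"),
           "</td></tr>", collapse = "\n")
  } else {
    "<tr><td colspan='7'>no significant terms</td></tr>"
  }
  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Lipid ORA report</title></head><body>",
    "<h1>Lipid over-representation analysis</h1>",
    sprintf("<p>query: %d lipids; reference: %d lipids; %d terms tested; %d significant at alpha %g (%s, %s).</p>",
            length(x$query), length(x$reference), nrow(x$results),
            sum(x$results$significant), x$params$alpha, x$params$test,
            x$params$correction),
    "<table border='1'><tr><th>", paste(names(sig), collapse = "</th><th>"),
    "</th></tr>", rows, "</table></body></html>")
  writeLines(html, out_file)
}

#' Write a full report bundle
#'
#' Writes all analysis artefacts into a directory and packages them as a
#' single tar archive: the parameter snapshot (JSON), the full and
#' significant ORA tables (CSV, printed-table column layout), the VIL
#' table, per-intersection tables, the UpSet long table, the lipidome tree
#' (phyloXML, plus SVG when plotting is enabled), and hierarchy node/edge
#' tables. Reruns with identical inputs produce byte-identical archives
#' (member timestamps are fixed to the epoch).
#'
#' @param x a fitted [lipid_ora()] object.
#' @param out_dir output directory (created; must not exist or be empty).
#' @param max_terms UpSet term cap, see [build_membership()].
#' @param archive create `<out_dir>.tar` next to the directory.
#' @param plot also render the UpSet plot and tree to SVG.
#' @return the bundle directory path, invisibly.
#' @export
write_bundle <- function(x, out_dir, max_terms = 13L, archive = TRUE,
                         plot = FALSE) {
  stopifnot(inherits(x, "lipid_ora"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, file) {
    utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
  }
  snap <- params_snapshot(x)

  mm <- tryCatch(build_membership(x, max_terms = max_terms),
                 lipidenrich_no_significant_terms = function(e) NULL)
  snap$empty_tables <- is.null(mm)
  jsonlite::write_json(snap, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  wcsv(ora_table(x, significant_only = FALSE), "ora_results_full.csv")
  wcsv(ora_table(x, significant_only = TRUE), "ora_results_significant.csv")

  if (!is.null(mm)) {
    vils <- select_vils(mm)
    rec <- enumerate_intersections(mm)
    wcsv(vils, "vil_table.csv")
    wcsv(upset_long(mm), "upset_long.csv")
    dir.create(file.path(out_dir, "intersections"), showWarnings = FALSE)
    for (i in seq_len(nrow(rec))) {
      wcsv(intersection_table(rec[i, ], mm),
           file.path("intersections", sprintf("intersection_%03d.csv", i)))
    }
    if (plot) {
      grDevices::svg(file.path(out_dir, "upset.svg"), width = 9, height = 6)
      plot(x, max_terms = max_terms)
      grDevices::dev.off()
    }
  } else {
    wcsv(data.frame(lipid = character(), degree = integer(),
                    is_vil = logical()), "vil_table.csv")
    wcsv(data.frame(profile_id = character(), degree = integer(),
                    cardinality = integer(), lipid = character()),
         "upset_long.csv")
  }

  tree <- build_tree(x$reference)
  write_phyloxml(tree, file.path(out_dir, "lipidome_tree.phyloxml"))
  if (plot) {
    grDevices::svg(file.path(out_dir, "lipidome_tree.svg"), width = 8, height = 8)
    plot_lipidome_tree(tree)
    grDevices::dev.off()
  }

  net <- network_tables(x$reference)
  wcsv(net$nodes, "network_nodes.csv")
  wcsv(net$edges, "network_edges.csv")
  wcsv(parse_report(list(lipids = x$query)), "query_parsed.csv")
  wcsv(parse_report(list(lipids = x$reference)), "reference_parsed.csv")
  html_summary(x, file.path(out_dir, "summary.html"))

  if (archive) {
    tarfile <- paste0(normalizePath(sub("/+$", "", out_dir)), ".tar")
    old <- setwd(out_dir)
    on.exit(setwd(old), add = TRUE)
    # fixed timestamps so identical inputs give identical archives
    Sys.setFileTime(list.files(".", recursive = TRUE, include.dirs = TRUE),
                    as.POSIXct("2000-01-01", tz = "UTC"))
    utils::tar(tarfile = tarfile, files = sort(list.files(".", recursive = TRUE)),
               tar = "internal")
  }
  invisible(out_dir)
}
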