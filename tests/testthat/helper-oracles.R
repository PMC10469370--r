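# Shared test helpers: independent oracles and small generators.

# brute-force exclusive-intersection oracle: for every non-empty subset of
# terms, the lipids whose profile is exactly that subset
brute_force_intersections <- function(incidence) {
  m <- nrow(incidence)
  out <- list()
  for (mask in seq_len(2^m - 1L)) {
    members <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1L)))
    in_set <- apply(incidence, 2, function(col) identical(unname(col), members))
    if (any(in_set)) {
      out[[length(out) + 1L]] <- list(
        terms = which(members),
        lipids = sort(colnames(incidence)[in_set]))
    }
  }
  out
}

# random 2x2 tables with moderate margins
random_tables <- function(n, seed) {
  set.seed(seed)
  data.frame(a = sample(0:30, n, TRUE), b = sample(0:60, n, TRUE),
             c = sample(0:40, n, TRUE), d = sample(0:500, n, TRUE))
}

# random term-by-lipid incidence matrix wrapped as a membership_matrix
random_membership <- function(n_terms, n_lipids, seed, p = 0.3) {
  set.seed(seed)
  inc <- matrix(stats::runif(n_terms * n_lipids) < p, n_terms, n_lipids,
                dimnames = list(paste0("T", seq_len(n_terms)),
                                sprintf("lip%03d", seq_len(n_lipids))))
  terms <- data.frame(term_id = paste0("T", seq_len(n_terms)),
                      classifier = "CHAIN",
                      value = paste0("v", seq_len(n_terms)),
                      level = "MOLECULAR_SPECIES",
                      condition = NA_character_,
                      display_label = paste0("term ", seq_len(n_terms)),
                      adjusted_p = seq_len(n_terms) / 100,
                      p_value = seq_len(n_terms) / 100,
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, incidence = inc), class = "membership_matrix")
}

# the seven printed rows of the demo over-represented term table
demo_table1 <- function() {
  data.frame(
    label = c("Acyls 16:1", "Acyls 20:4", "Acyls 20:4",
              "Acyls 16:1 within Glycerophospholipids [GP]",
              "Acyls 20:4 within Glycerophospholipids [GP]",
              "Acyls 20:4 within Glycerophospholipids [GP]",
              "Acyls 16:1 within Glycerophosphocholines [GP01]"),
    level = c("MOLECULAR_SPECIES", "MOLECULAR_SPECIES", "SN_POSITION",
              "MOLECULAR_SPECIES", "MOLECULAR_SPECIES", "SN_POSITION",
              "MOLECULAR_SPECIES"),
    a = c(13L, 15L, 13L, 13L, 15L, 13L, 11L),
    qU = c(68L, 68L, 68L, 68L, 68L, 68L, 26L),
    cc = c(18L, 26L, 19L, 17L, 24L, 18L, 14L),
    rU = c(556L, 556L, 556L, 448L, 448L, 448L, 148L),
    p_printed = c(4.30e-06, 5.44e-06, 6.63e-06, 2.36e-05, 2.86e-05,
                  3.64e-05, 1.00e-04),
    or_printed = c(7.0646, 5.7692, 6.6804, 5.9925, 5.0000, 5.6465, 7.0190),
    stringsAsFactors = FALSE)
}

run_cli <- function(args) {
  script <- system.file("cli", "lipidenrich.R", package = "lipidenrich")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(
    system2(rscript, c(shQuote(script), args), stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(output = out, status = attr(out, "status") %||% 0L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
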