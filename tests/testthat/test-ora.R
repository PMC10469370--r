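# Enrichment statistics and the ORA assembly.

test_that("fisher exact matches the stats::fisher.test oracle on random tables", {
  tabs <- random_tables(1000, seed = 42)
  for (i in seq_len(nrow(tabs))) {
    a <- tabs$a[i]; b <- tabs$b[i]; c <- tabs$c[i]; d <- tabs$d[i]
    if (a + b == 0L || c + d == 0L) next
    m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
    for (alt in c("two-sided", "less", "greater")) {
      got <- fisher_exact(a, b, c, d, alternative = alt)
      want <- stats::fisher.test(m, alternative = sub("-", ".", alt))$p.value
      expect_equal(got$p_value, want, tolerance = 1e-12,
                   label = sprintf("p(%d,%d,%d,%d,%s)", a, b, c, d, alt))
    }
    or <- fisher_exact(a, b, c, d)$odds_ratio
    if (b * c == 0 && a * d == 0) {
      expect_true(is.nan(or))
    } else {
      expect_identical(or, (as.numeric(a) * d) / (as.numeric(b) * c))
    }
  }
})

test_that("degenerate tables give p = 1 and flagged odds ratios", {
  e <- fisher_exact(0, 10, 0, 100)
  expect_equal(e$p_value, 1)
  expect_true(is.nan(e$odds_ratio))
  expect_equal(fisher_exact(0, 10, 0, 100, "less")$p_value, 1)
  expect_equal(fisher_exact(5, 0, 0, 10)$odds_ratio, Inf)
  expect_error(fisher_exact(-1, 5, 5, 5), class = "lipidenrich_invalid_table")
})

test_that("hypergeometric tail equals the one-sided fisher p", {
  tabs <- random_tables(1000, seed = 7)
  for (i in seq_len(nrow(tabs))) {
    a <- tabs$a[i]; b <- tabs$b[i]; c <- tabs$c[i]; d <- tabs$d[i]
    if (a + b == 0L || c + d == 0L) next
    expect_equal(hypergeom_p(a, b, c, d),
                 fisher_exact(a, b, c, d, alternative = "greater")$p_value,
                 tolerance = 1e-12)
  }
  # brute-force tail on the first demo table: sum dhyper over k = 13..31
  brute <- sum(stats::dhyper(13:31, 31, 593, 68))
  expect_equal(hypergeom_p(13, 55, 18, 538), brute, tolerance = 1e-12)
  # all successes in the query: single most extreme table
  expect_equal(hypergeom_p(3, 7, 0, 90),
               stats::dhyper(3, 3, 97, 10), tolerance = 1e-12)
  expect_equal(hypergeom_p(0, 10, 50, 50), 1)
})

test_that("two-sided p is never below either one-sided p", {
  tabs <- random_tables(1000, seed = 99)
  for (i in seq_len(nrow(tabs))) {
    a <- tabs$a[i]; b <- tabs$b[i]; c <- tabs$c[i]; d <- tabs$d[i]
    if (a + b == 0L || c + d == 0L) next
    two <- fisher_exact(a, b, c, d)$p_value
    less <- fisher_exact(a, b, c, d, "less")$p_value
    greater <- fisher_exact(a, b, c, d, "greater")$p_value
    expect_gte(two + 1e-12, min(less, greater))
  }
})

test_that("p-value adjustment reproduces the closed forms", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(0.01, "holm"), 0.01)
  expect_equal(adjust_pvalues(0.01, "benjamini-hochberg"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  # hand-computed step-up: p * m / rank with a cumulative minimum
  expect_equal(adjust_pvalues(c(0.001, 0.002, 0.02, 0.8), "benjamini-hochberg"),
               c(0.004, 0.004, 0.02 * 4 / 3, 0.8))
  # holm step-down with running maximum
  expect_equal(adjust_pvalues(c(0.01, 0.04, 0.03), "holm"),
               c(0.03, 0.06, 0.06))
  expect_equal(adjust_pvalues(c(0.9, 0.95), "bonferroni"), c(1, 1))
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "lipidenrich_invalid_p")
})

test_that("BH adjustment is permutation invariant and dominates raw p", {
  set.seed(31)
  for (rep in 1:20) {
    p <- stats::runif(25)^2
    adj <- adjust_pvalues(p, "benjamini-hochberg")
    expect_true(all(adj >= p - 1e-15))
    perm <- sample(length(p))
    expect_equal(adjust_pvalues(p[perm], "benjamini-hochberg"), adj[perm])
    # monotone in the ranks of the input
    o <- order(p)
    expect_true(!is.unsorted(adj[o]))
  }
})

test_that("a query identical to the reference yields no enrichment", {
  nm <- c("PC 16:0_18:1", "PC 16:1_18:1", "PE 16:0_20:4", "PE 34:1",
          "PG 16:0/18:1", "PC 36:2", "PE 16:0/20:4;OH", "PC 14:0_16:1")
  fit <- lipid_ora(nm, nm, params = ora_params(alpha = 0.5))
  expect_equal(sum(fit$results$significant), 0L)
  # proportional tables give two-sided p 1 throughout
  expect_true(all(fit$results$p_value > 0.999))
})

test_that("with no correction and alpha 1 every tested term is significant", {
  fx <- demo_lipidome(n_query = 15, n_reference = 60, seed = 3)
  fit <- lipid_ora(fx$query, fx$reference,
                   params = ora_params(correction = "none", alpha = 1))
  expect_true(all(fit$results$significant))
  expect_true(all(fit$results$a >= 1L))
})

test_that("the analysis is deterministic and sorted by adjusted then raw p", {
  fx <- demo_lipidome(n_query = 20, n_reference = 80, seed = 9)
  f1 <- lipid_ora(fx$query, fx$reference)
  f2 <- lipid_ora(fx$query, fx$reference)
  expect_identical(f1$results, f2$results)
  r <- f1$results
  expect_true(!is.unsorted(r$adjusted_p))
  ties <- which(diff(r$adjusted_p) == 0)
  expect_true(all(r$p_value[ties + 1L] >= r$p_value[ties]))
})

test_that("family scopes adjust within the declared families", {
  fx <- demo4_fixture(verify = FALSE)
  fit <- lipid_ora(fx$query, fx$reference,
                   params = ora_params(family_scope = "per_classifier"))
  r <- fit$results
  for (f in unique(paste(r$classifier, r$level))) {
    i <- paste(r$classifier, r$level) == f
    expect_equal(sort(r$adjusted_p[i]),
                 sort(adjust_pvalues(r$p_value[i], "benjamini-hochberg")))
  }
  glob <- lipid_ora(fx$query, fx$reference)
  expect_equal(sort(glob$results$adjusted_p),
               sort(adjust_pvalues(glob$results$p_value, "benjamini-hochberg")))
})

test_that("empty inputs raise typed errors", {
  expect_error(lipid_ora(character(0), "PC 34:1"))
  expect_error(lipid_ora("not_a_lipid", c("PC 34:1", "PE 34:2")),
               class = "lipidenrich_empty_query")
  expect_error(lipid_ora("PC 34:1", "not_a_lipid"),
               class = "lipidenrich_empty_reference")
})

test_that("the hypergeometric test option reproduces one-sided enrichment", {
  fx <- demo_lipidome(n_query = 20, n_reference = 80, seed = 13)
  fh <- lipid_ora(fx$query, fx$reference,
                  params = ora_params(test = "hypergeometric"))
  fg <- lipid_ora(fx$query, fx$reference,
                  params = ora_params(test = "fisher", alternative = "greater"))
  expect_equal(fh$results$p_value[order(fh$results$term_id)],
               fg$results$p_value[order(fg$results$term_id)],
               tolerance = 1e-12)
})
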