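# Build a pattern data frame directly from beta/p matrices.
make_patterns <- function(pvalues, betas = NULL,
                          mods = colnames(pvalues)) {
  n <- nrow(pvalues)
  if (is.null(betas)) betas <- matrix(0, n, ncol(pvalues))
  pairs <- data.frame(gene_i = sprintf("a%03d", seq_len(n)),
                      gene_j = sprintf("b%03d", seq_len(n)))
  out <- cbind(pairs,
               setNames(as.data.frame(betas), paste0("beta_", mods)),
               setNames(as.data.frame(pvalues), paste0("p_", mods)),
               intercept = 0)
  out
}

test_that("significance calls use a strict threshold", {
  pat <- make_patterns(matrix(c(0.04, 0.06, 0.05, 1.0), 2, byrow = TRUE,
                              dimnames = list(NULL, c("A", "B"))))
  calls <- call_significance(pat, alpha = 0.05)
  expect_identical(unname(calls$calls[1, ]), c(TRUE, FALSE))
  expect_identical(unname(calls$calls[2, ]), c(FALSE, FALSE))
  all_one <- call_significance(make_patterns(matrix(1, 4, 2,
                                                    dimnames = list(NULL, c("A", "B")))))
  expect_identical(sum(all_one$calls), 0L)
  expect_error(call_significance(pat, alpha = 0), "alpha")
})

test_that("tallies and per-pair counts match an element-by-element recount", {
  set.seed(30)
  p <- matrix(runif(100 * 4), 100, dimnames = list(NULL, LETTERS[1:4]))
  calls <- call_significance(make_patterns(p), alpha = 0.3)
  for (m in LETTERS[1:4]) {
    expect_equal(unname(calls$per_modulator[m]), sum(p[, m] < 0.3))
  }
  expect_equal(unname(calls$per_pair), unname(rowSums(p < 0.3)))
  tal <- modulator_tally(calls)
  expect_equal(tal$n_pairs[tal$modulator == "A"], sum(p[, "A"] < 0.3))
  expect_equal(tal$percentage, round(100 * tal$n_pairs / 100, 2))
  zero <- modulator_tally(call_significance(make_patterns(
    matrix(1, 3, 1, dimnames = list(NULL, "A")))))
  expect_identical(zero$percentage, 0)
})

test_that("signature groups partition the pairs exhaustively", {
  p <- matrix(1, 3, 2, dimnames = list(NULL, c("A", "B")))
  p[1, "A"] <- p[2, "A"] <- 0.01
  p[3, c("A", "B")] <- 0.01
  groups <- group_by_signature(call_significance(make_patterns(p)))
  labels <- vapply(groups, `[[`, character(1), "label")
  sizes <- vapply(groups, `[[`, numeric(1), "n_pairs")
  expect_identical(labels, c("A", "A+B"))
  expect_identical(sizes, c(2, 1))

  none <- group_by_signature(call_significance(make_patterns(
    matrix(1, 5, 2, dimnames = list(NULL, c("A", "B"))))))
  expect_identical(length(none), 1L)
  expect_identical(none[[1]]$label, "none")
  expect_identical(none[[1]]$n_pairs, 5L)

  # partition oracle on random calls
  set.seed(31)
  pr <- matrix(runif(100 * 4), 100, dimnames = list(NULL, LETTERS[1:4]))
  calls <- call_significance(make_patterns(pr), alpha = 0.4)
  groups <- group_by_signature(calls)
  expect_identical(sum(vapply(groups, `[[`, numeric(1), "n_pairs")), 100)
  dict <- table(apply(calls$calls, 1, function(row) {
    if (!any(row)) "none" else paste(sort(LETTERS[1:4][row]), collapse = "+")
  }))
  for (g in groups) {
    expect_identical(g$n_pairs, as.integer(dict[[g$label]]))
    # every member pair carries exactly the group signature
    ids <- paste(g$pairs$gene_i, g$pairs$gene_j, sep = "|")
    rows <- match(ids, paste(sprintf("a%03d", 1:100), sprintf("b%03d", 1:100), sep = "|"))
    for (r in rows) {
      expect_identical(sort(LETTERS[1:4][calls$calls[r, ]]),
                       sort(g$signature))
    }
  }
})

test_that("core pairs apply the Bonferroni rule", {
  # adjusted p = p * family: 1e-9 * 14084778 ~ 0.014 retained, 1e-6 removed
  p <- matrix(1, 3, 2, dimnames = list(NULL, c("A", "B")))
  p[1, "A"] <- 1e-9
  p[2, "A"] <- 1e-6
  p[3, "A"] <- 0.04
  pat <- make_patterns(p)
  core <- core_pairs(pat, "A", family_size = 14084778)
  expect_identical(core$n_pairs, 1L)
  expect_identical(core$pairs$gene_i, "a001")
  expect_identical(core$genes, c("a001", "b001"))

  # random small set against direct recomputation
  set.seed(32)
  pr <- matrix(runif(50 * 2, 0, 0.2), 50, dimnames = list(NULL, c("A", "B")))
  patr <- make_patterns(pr)
  fam <- 200
  core_a <- core_pairs(patr, "A", family_size = fam, alpha = 0.05)
  manual <- which(pr[, "A"] < 0.05 & pr[, "B"] >= 0.05 & pr[, "A"] * fam < 0.05)
  expect_identical(nrow(core_a$pairs), length(manual))
  expect_error(core_pairs(patr, character(0)), "at least one modulator")
  expect_error(core_pairs(patr, "nope"), "unknown modulators")
})

test_that("node degrees count first-order neighbours", {
  deg <- node_degrees(rbind(c("A", "B"), c("A", "C")))
  expect_identical(deg$degrees, c(A = 2L, B = 1L, C = 1L))
  expect_identical(length(node_degrees(matrix(character(0), 0, 2))$degrees), 0L)
  set.seed(33)
  genes <- sprintf("G%02d", 1:20)
  prs <- t(replicate(50, sample(genes, 2)))
  deg <- node_degrees(prs, top_k = 5)
  expect_identical(sum(deg$degrees), 100L) # 2 * n_pairs
  for (g in names(deg$degrees)) {
    expect_identical(unname(deg$degrees[g]), sum(prs == g))
  }
  # hub ties broken lexicographically
  tie <- node_degrees(rbind(c("Z", "B"), c("Z", "A"), c("A", "B")))
  expect_identical(names(tie$degrees), c("A", "B", "Z"))
})

test_that("fisher2x2 matches fisher.test and handles the diagonal table", {
  # both extreme tables carry the observed point probability, so the
  # two-sided sum is twice 1/choose(20, 10) -- exactly what fisher.test gives
  expect_equal(fisher2x2(10, 0, 0, 10), 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher2x2(10, 0, 0, 10),
               fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               tolerance = 1e-12)
  set.seed(34)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    cells <- as.vector(rmultinom(1, n, prob = runif(4, 0.05, 1)))
    p <- fisher2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p, min(ref, 1), tolerance = 1e-12)
  }
})

test_that("co-occurrence tests report direction and degenerate margins", {
  p <- matrix(1, 20, 2, dimnames = list(NULL, c("A", "B")))
  p[1:10, "A"] <- 0.01
  p[1:10, "B"] <- 0.01 # A and B perfectly co-occur
  calls <- call_significance(make_patterns(p))
  res <- cooccurrence_test(calls, "A", "B")
  expect_equal(res$pvalue, 2 / choose(20, 10), tolerance = 1e-12)
  expect_identical(res$odds_direction, "positive")
  expect_identical(sum(res$table), 20L)

  # observed count exactly at expectation: direction "none"
  p2 <- matrix(1, 4, 2, dimnames = list(NULL, c("A", "B")))
  p2[1:2, "A"] <- 0.01
  p2[c(1, 3), "B"] <- 0.01 # n11 = 1 = 2*2/4
  res2 <- cooccurrence_test(call_significance(make_patterns(p2)), "A", "B")
  expect_identical(res2$odds_direction, "none")

  p3 <- matrix(1, 6, 2, dimnames = list(NULL, c("A", "B")))
  p3[1:3, "B"] <- 0.01
  expect_warning(res3 <- cooccurrence_test(call_significance(make_patterns(p3)),
                                           "A", "B"),
                 "degenerate margin")
  expect_identical(res3$pvalue, 1)
  expect_error(cooccurrence_test(call_significance(make_patterns(p3)), "A", "A"),
               "must differ")
})

test_that("cooccurrence_matrix signs log10 p-values by direction", {
  set.seed(35)
  p <- matrix(runif(200 * 3), 200, dimnames = list(NULL, c("A", "B", "C")))
  p[, "B"] <- ifelse(p[, "A"] < 0.3, p[, "B"] * 0.2, p[, "B"])
  calls <- call_significance(p |> make_patterns(), alpha = 0.3)
  co <- cooccurrence_matrix(calls)
  expect_identical(dim(co$signed_log10p), c(3L, 3L))
  expect_equal(co$signed_log10p["A", "B"], co$signed_log10p["B", "A"])
  ab <- co$tests[co$tests$modulator_a == "A" & co$tests$modulator_b == "B", ]
  expect_equal(abs(co$signed_log10p["A", "B"]), -log10(ab$pvalue))
})

test_that("Wald proportion intervals follow the closed form", {
  ci <- proportion_ci(0.5, 100)
  expect_equal(unname(ci[1, ]), c(0.402, 0.598), tolerance = 1e-3)
  expect_equal(unname(proportion_ci(0, 50)[1, ]), c(0, 0))
  half <- 1.96 * sqrt(0.25 * 0.75 / 64)
  expect_equal(unname(proportion_ci(0.25, 64)[1, ]), c(0.25 - half, 0.25 + half))
  expect_error(proportion_ci(1.2, 10), "p_hat")
})

test_that("summary.comre ties the analysis layers together", {
  expr <- random_expr(10, 40, seed = 36)
  fit <- comre(expr, rownames(expr)[1:2])
  s <- summary(fit, alpha = 0.2)
  expect_s3_class(s, "summary.comre")
  expect_identical(s$n_pairs, 28L)
  expect_identical(sum(vapply(s$groups, `[[`, numeric(1), "n_pairs")), 28)
  expect_output(print(s), "co-modulation groups")
})
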