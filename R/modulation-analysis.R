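#' Call significant modulators for each gene pair
#'
#' A modulator is called significant for a pair when its regression p-value
#' is strictly below `alpha`.
#'
#' @param patterns A `"comre"` fit or a pattern data frame
#'   (see [read_patterns()]).
#' @param alpha Significance threshold in (0, 1), default 0.05.
#' @return An object of class `"comre_calls"`: a list with `calls` (logical
#'   pairs x M matrix), `pairs`, `alpha`, `per_pair` (number of significant
#'   modulators per pair), `per_modulator` (pairs modulated by each
#'   modulator), and `total_pairs`.
#' @export
call_significance <- function(patterns, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)")
  }
  parts <- .pattern_parts(patterns)
  calls <- parts$pvalues < alpha
  structure(list(calls = calls, pairs = parts$pairs, alpha = alpha,
                 per_pair = rowSums(calls), per_modulator = colSums(calls),
                 total_pairs = nrow(calls)), class = "comre_calls")
}

#' @export
print.comre_calls <- function(x, ...) {
  cat(sprintf("Significance calls at p < %g: %d pair(s) x %d modulator(s)\n",
              x$alpha, x$total_pairs, ncol(x$calls)))
  cat(sprintf("  pairs with >= 1 significant modulator: %d (%.2f%%)\n",
              sum(x$per_pair > 0), 100 * mean(x$per_pair > 0)))
  invisible(x)
}

#' Per-modulator tallies of modulated pairs
#'
#' @param calls A `"comre_calls"` object.
#' @param total_pairs Denominator for percentages (default: the number of
#'   pairs in `calls`).
#' @return Data frame with `modulator`, `n_pairs`, `fraction`, and
#'   `percentage` (fraction x 100 rounded to two decimals, the conventional
#'   reporting precision), sorted by `n_pairs` descending.
#' @export
modulator_tally <- function(calls, total_pairs = calls$total_pairs) {
  if (!inherits(calls, "comre_calls")) stop("calls must be a comre_calls object")
  if (total_pairs < 1) stop("total_pairs must be >= 1")
  n <- calls$per_modulator
  out <- data.frame(modulator = names(n), n_pairs = as.numeric(n),
                    fraction = as.numeric(n) / total_pairs,
                    stringsAsFactors = FALSE)
  out$percentage <- round(100 * out$fraction, 2)
  out <- out[order(-out$n_pairs, out$modulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Signature label: "+"-joined sorted modulator ids, or "none".
.signature_label <- function(mods) {
  if (!length(mods)) "none" else paste(sort(mods), collapse = "+")
}

#' Group gene pairs by co-modulation signature
#'
#' Partitions the pairs so that pairs significantly modulated by exactly the
#' same set of modulators fall in one group; pairs with no significant
#' modulator form the explicit `"none"` group.  The partition is exhaustive
#' and disjoint.
#'
#' @param calls A `"comre_calls"` object.
#' @return List of class `"comre_groups"`; each element is a list with
#'   `signature` (sorted modulator ids, possibly empty), `label`, `n_pairs`,
#'   `fraction`, `percentage`, `pairs` (data frame), `member_genes`, and
#'   `degrees` (named integer vector, see [node_degrees()]).  Groups are
#'   sorted by size descending, ties by label.
#' @export
group_by_signature <- function(calls) {
  if (!inherits(calls, "comre_calls")) stop("calls must be a comre_calls object")
  mods <- colnames(calls$calls)
  keys <- apply(calls$calls, 1L, function(row) .signature_label(mods[row]))
  total <- calls$total_pairs
  idx <- split(seq_len(total), keys)
  groups <- lapply(names(idx), function(key) {
    rows <- idx[[key]]
    prs <- calls$pairs[rows, , drop = FALSE]
    rownames(prs) <- NULL
    deg <- node_degrees(prs)
    list(signature = if (key == "none") character(0L) else strsplit(key, "+", fixed = TRUE)[[1L]],
         label = key, n_pairs = length(rows), fraction = length(rows) / total,
         percentage = round(100 * length(rows) / total, 2),
         pairs = prs, member_genes = names(deg$degrees), degrees = deg$degrees)
  })
  sizes <- vapply(groups, `[[`, numeric(1L), "n_pairs")
  labels <- vapply(groups, `[[`, character(1L), "label")
  groups <- groups[order(-sizes, labels)]
  class(groups) <- "comre_groups"
  groups
}

#' @export
print.comre_groups <- function(x, n = 10L, ...) {
  cat("Co-modulation groups (", length(x), " signatures)\n", sep = "")
  print(utils::head(group_table(x), n))
  invisible(x)
}

#' Tabulate co-modulation groups
#'
#' One row per group: signature label, pair count, percentage and the top
#' hub genes with their node degrees.
#'
#' @param groups A `"comre_groups"` list.
#' @param top_hubs How many hub genes to list per group (default 3).
#' @return Data frame sorted as `groups`.
#' @export
group_table <- function(groups, top_hubs = 3L) {
  if (!inherits(groups, "comre_groups")) stop("groups must be a comre_groups list")
  hubs <- vapply(groups, function(g) {
    h <- utils::head(g$degrees, top_hubs)
    paste(sprintf("%s (%d)", names(h), h), collapse = "; ")
  }, character(1L))
  data.frame(
    signature = vapply(groups, `[[`, character(1L), "label"),
    n_pairs = vapply(groups, `[[`, numeric(1L), "n_pairs"),
    percentage = vapply(groups, `[[`, numeric(1L), "percentage"),
    top_hubs = hubs, stringsAsFactors = FALSE)
}

#' Node degrees and hub genes of a pair set
#'
#' The node degree of a gene is its number of first-order (direct) neighbours
#' in the graph whose edges are the gene pairs; high-degree genes are the
#' hubs of the (co-)modulated network.
#'
#' @param pairs A pair specification (2-column matrix/data frame), a group
#'   from [group_by_signature()], or an empty set.
#' @param top_k Number of hubs to report (default 3).
#' @return List with `degrees` (named integer vector sorted by degree
#'   descending, ties by gene id) and `hubs` (the first `top_k` entries).
#' @export
node_degrees <- function(pairs, top_k = 3L) {
  if (is.list(pairs) && !is.null(pairs$pairs) && !is.data.frame(pairs)) {
    pairs <- pairs$pairs
  }
  p <- .as_pair_matrix(pairs)
  if (!nrow(p)) {
    deg <- integer(0L)
  } else {
    tab <- table(c(p[, 1L], p[, 2L]))
    deg <- as.integer(tab)
    names(deg) <- names(tab)
    deg <- deg[order(-deg, names(deg))]
  }
  list(degrees = deg, hubs = utils::head(deg, top_k))
}

#' Core pairs of a co-modulation group under Bonferroni adjustment
#'
#' Within the group whose significant-modulator set equals `signature`,
#' retains the pairs whose signature-modulator p-values survive Bonferroni
#' adjustment: `p * family_size < alpha`.  With `rule = "all"` (default)
#' every signature modulator must pass; `rule = "any"` requires at least one.
#'
#' @param patterns A `"comre"` fit or pattern data frame.
#' @param signature Character vector of modulator ids defining the group
#'   (must be non-empty; the `"none"` group has no p-values to adjust).
#' @param family_size Bonferroni family size; default the number of pairs
#'   tested.
#' @param alpha Threshold on the adjusted p-value (default 0.05) and on the
#'   raw p-values used for group membership.
#' @param rule `"all"` or `"any"` (see above).
#' @return List with `pairs` (data frame of surviving pairs), `genes`
#'   (member genes of the surviving pairs), `n_pairs` and `n_genes`.
#' @export
core_pairs <- function(patterns, signature, family_size = NULL, alpha = 0.05,
                       rule = c("all", "any")) {
  rule <- match.arg(rule)
  parts <- .pattern_parts(patterns)
  if (!length(signature)) {
    stop("signature must name at least one modulator")
  }
  if (!all(signature %in% parts$modulators)) {
    stop("unknown modulators in signature: ",
         paste(setdiff(signature, parts$modulators), collapse = ", "))
  }
  if (is.null(family_size)) family_size <- nrow(parts$pvalues)
  if (family_size < 1) stop("family_size must be >= 1")
  sig <- parts$pvalues < alpha
  in_group <- rowSums(sig[, signature, drop = FALSE]) == length(signature) &
    rowSums(sig) == length(signature)
  adj_pass <- parts$pvalues[, signature, drop = FALSE] * family_size < alpha
  pass <- if (rule == "all") rowSums(adj_pass) == length(signature)
          else rowSums(adj_pass) > 0L
  keep <- which(in_group & pass)
  prs <- parts$pairs[keep, , drop = FALSE]
  rownames(prs) <- NULL
  genes <- sort(unique(c(prs$gene_i, prs$gene_j)))
  list(pairs = prs, genes = genes, n_pairs = nrow(prs), n_genes = length(genes))
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Point-probability rule: the p-value is the sum of hypergeometric
#' probabilities of all tables (with the observed margins) whose probability
#' does not exceed that of the observed table (a relative tolerance of 1e-7
#' guards ties against rounding, the usual convention for this test).
#'
#' @param a,b,c,d Cell counts: `a` = both, `b` = first only, `c` = second
#'   only, `d` = neither.  Vectorised over tables.
#' @return Numeric vector of two-sided p-values.
#' @examples
#' fisher2x2(10, 0, 0, 10) # 1 / choose(20, 10)
#' @export
fisher2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  out <- numeric(n)
  for (i in seq_len(n)) {
    r1 <- a[i] + b[i]
    r2 <- c[i] + d[i]
    c1 <- a[i] + c[i]
    support <- max(0L, c1 - r2):min(r1, c1)
    probs <- stats::dhyper(support, r1, r2, c1)
    out[i] <- sum(probs[probs <= probs[support == a[i]] * (1 + 1e-7)])
  }
  pmin(out, 1)
}

#' Pairwise co-occurrence of two modulators across gene pairs
#'
#' Cross-tabulates the gene pairs by significance of the two modulators and
#' tests whether pairs modulated by one tend to be modulated by the other
#' (positive association) or to avoid it (negative), via the two-sided Fisher
#' exact test.
#'
#' @param calls A `"comre_calls"` object.
#' @param modulator_a,modulator_b Distinct modulator ids.
#' @return An object of class `"comre_cooccurrence"`: list with `table`
#'   (2x2 counts: both / a only / b only / neither), `pvalue`,
#'   `odds_direction` (`"positive"`, `"negative"` or `"none"`), `expected`
#'   (expected both-count under independence), and the modulator ids.
#'   Degenerate margins (a modulator significant for no or all pairs) give
#'   p = 1 with a warning.
#' @export
cooccurrence_test <- function(calls, modulator_a, modulator_b) {
  if (!inherits(calls, "comre_calls")) stop("calls must be a comre_calls object")
  if (modulator_a == modulator_b) stop("modulators must differ")
  for (m in c(modulator_a, modulator_b)) {
    if (!m %in% colnames(calls$calls)) stop("unknown modulator: ", m)
  }
  sa <- calls$calls[, modulator_a]
  sb <- calls$calls[, modulator_b]
  n11 <- sum(sa & sb); n10 <- sum(sa & !sb)
  n01 <- sum(!sa & sb); n00 <- sum(!sa & !sb)
  tab <- matrix(c(n11, n10, n01, n00), 2L, 2L, byrow = TRUE,
                dimnames = list(c(paste0(modulator_a, ":sig"), paste0(modulator_a, ":ns")),
                                c(paste0(modulator_b, ":sig"), paste0(modulator_b, ":ns"))))
  total <- calls$total_pairs
  expected <- (n11 + n10) * (n11 + n01) / total
  ra <- n11 + n10
  rb <- n11 + n01
  if (ra == 0 || ra == total || rb == 0 || rb == total) {
    warning("degenerate margin: ", if (ra %in% c(0, total)) modulator_a else modulator_b,
            " is significant for ", if (ra == 0 || rb == 0) "no" else "all", " pairs")
    p <- 1
  } else {
    p <- fisher2x2(n11, n10, n01, n00)
  }
  direction <- if (n11 > expected) "positive" else if (n11 < expected) "negative" else "none"
  structure(list(modulator_a = modulator_a, modulator_b = modulator_b,
                 table = tab, pvalue = p, odds_direction = direction,
                 expected = expected), class = "comre_cooccurrence")
}

#' @export
print.comre_cooccurrence <- function(x, ...) {
  cat(sprintf("Co-occurrence of %s and %s as significant modulators\n",
              x$modulator_a, x$modulator_b))
  print(x$table)
  cat(sprintf("  Fisher exact two-sided p = %.4g; association: %s\n",
              x$pvalue, x$odds_direction))
  invisible(x)
}

#' All-pairs modulator co-occurrence matrix
#'
#' Runs [cooccurrence_test()] for every unordered modulator pair and returns
#' a signed log10 p-value matrix (positive association positive, negative
#' association negative), the usual heat-map representation.
#'
#' @param calls A `"comre_calls"` object.
#' @return List with `signed_log10p` (M x M symmetric matrix, diagonal `NA`)
#'   and `tests` (data frame of modulator_a, modulator_b, pvalue, direction).
#' @export
cooccurrence_matrix <- function(calls) {
  mods <- colnames(calls$calls)
  m <- length(mods)
  mat <- matrix(NA_real_, m, m, dimnames = list(mods, mods))
  rows <- list()
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      tst <- cooccurrence_test(calls, mods[i], mods[j])
      s <- switch(tst$odds_direction, positive = 1, negative = -1, 0)
      v <- s * -log10(max(tst$pvalue, .Machine$double.xmin))
      mat[i, j] <- mat[j, i] <- v
      rows[[length(rows) + 1L]] <- data.frame(
        modulator_a = mods[i], modulator_b = mods[j], pvalue = tst$pvalue,
        direction = tst$odds_direction, stringsAsFactors = FALSE)
    }
  }
  list(signed_log10p = mat, tests = do.call(rbind, rows))
}

#' Wald confidence interval for a proportion
#'
#' The 95% interval `p_hat +/- 1.96 * sqrt(p_hat * (1 - p_hat) / n)`.
#'
#' @param p_hat Observed proportion(s) in \[0, 1\].
#' @param n Sample size(s), >= 1.
#' @param clip Clip the interval to \[0, 1\] (default `FALSE`: the raw Wald
#'   formula may exceed the unit interval near the boundary).
#' @return Matrix with columns `low` and `high`.
#' @export
proportion_ci <- function(p_hat, n, clip = FALSE) {
  if (any(p_hat < 0 | p_hat > 1)) stop("p_hat must lie in [0, 1]")
  if (any(n < 1)) stop("n must be >= 1")
  half <- 1.96 * sqrt(p_hat * (1 - p_hat) / n)
  out <- cbind(low = p_hat - half, high = p_hat + half)
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Summary of a CoMRe fit
#'
#' Applies the significance threshold, tallies modulators, and groups pairs
#' by co-modulation signature.
#'
#' @param object A `"comre"` fit.
#' @param alpha Significance threshold (default 0.05).
#' @param ... Unused.
#' @return An object of class `"summary.comre"` with the calls, tally,
#'   groups, and headline counts.
#' @export
summary.comre <- function(object, alpha = 0.05, ...) {
  calls <- call_significance(object, alpha = alpha)
  groups <- group_by_signature(calls)
  n_mod <- sum(calls$per_pair > 0)
  structure(list(
    fit = object, alpha = alpha, calls = calls,
    tally = modulator_tally(calls), groups = groups,
    n_pairs = calls$total_pairs, n_modulated = n_mod,
    total_calls = sum(calls$per_pair),
    mean_modulators_per_modulated = if (n_mod > 0) sum(calls$per_pair) / n_mod else NA_real_),
    class = "summary.comre")
}

#' @export
print.summary.comre <- function(x, n_groups = 10L, ...) {
  print(x$fit)
  cat(sprintf("At p < %g: %d of %d pairs (%.2f%%) have >= 1 significant modulator\n",
              x$alpha, x$n_modulated, x$n_pairs,
              100 * x$n_modulated / max(x$n_pairs, 1)))
  if (x$n_modulated > 0) {
    cat(sprintf("  mean significant modulators per modulated pair: %.2f\n",
                x$mean_modulators_per_modulated))
  }
  cat("\nPer-modulator tally:\n")
  print(x$tally)
  cat("\nTop co-modulation groups:\n")
  print(utils::head(group_table(x$groups), n_groups))
  invisible(x)
}
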