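#' Number of unordered gene pairs
#'
#' @param n_genes Number of genes, >= 2.
#' @return `n_genes * (n_genes - 1) / 2` as a double (exact for any gene count
#'   met in practice).
#' @examples
#' count_pairs(5308) # 14084778
#' @export
count_pairs <- function(n_genes) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 2 ||
      n_genes != floor(n_genes)) {
    stop("n_genes must be a single integer >= 2")
  }
  n_genes * (n_genes - 1) / 2
}

#' Build the shared modulator design matrix
#'
#' Extracts the modulator rows from the expression matrix, z-transforms each
#' across samples (so every regressor has mean 0 and sample sd 1, giving
#' standardized coefficients), and prepends an intercept column by default.
#' The same design is shared by every gene pair's regression.
#'
#' @param expr Expression matrix (genes x samples).
#' @param modulator_ids Character vector of modulator gene ids present in
#'   `expr`; duplicates are an error.
#' @param intercept Include an all-ones intercept column (default `TRUE`).
#' @return An object of class `"comre_design"`: a list with `X` (K x
#'   (M + intercept) numeric matrix), `modulator_ids`, `sample_ids` and
#'   `intercept`.
#' @export
build_design_matrix <- function(expr, modulator_ids, intercept = TRUE) {
  expr <- .check_expression_matrix(expr)
  if (anyDuplicated(modulator_ids)) {
    stop("duplicate modulator ids: ",
         paste(unique(modulator_ids[duplicated(modulator_ids)]), collapse = ", "))
  }
  missing <- setdiff(modulator_ids, rownames(expr))
  if (length(missing)) {
    stop("modulators absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  m <- length(modulator_ids)
  k <- ncol(expr)
  if (k <= m + 1L) {
    stop("need more samples than modulators plus one (K = ", k, ", M = ", m, ")")
  }
  z <- t(.zscore_rows(expr[modulator_ids, , drop = FALSE]))
  x <- if (intercept) cbind(`(Intercept)` = 1, z) else z
  structure(list(X = x, modulator_ids = modulator_ids,
                 sample_ids = colnames(expr), intercept = intercept),
            class = "comre_design")
}

# Batched ordinary least squares with the shared design.
#
# cmat: n_pairs x K response matrix (one covariability vector per row).
# Computes the pseudoinverse (X'X)^-1 X' once and applies it to every row;
# two-sided t-tests on each coefficient use K - p degrees of freedom.
.ols_batch <- function(cmat, design) {
  x <- design$X
  k <- nrow(x)
  p <- ncol(x)
  if (ncol(cmat) != k) {
    stop("response length ", ncol(cmat), " does not match design rows ", k)
  }
  qx <- qr(x)
  if (qx$rank < p) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):p]]
    stop("rank-deficient design: collinear columns ", paste(bad, collapse = ", "))
  }
  xtx <- crossprod(x)
  ev <- eigen(xtx, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) / min(ev) > 1e8) {
    stop("ill-conditioned design (condition number ",
         format(max(ev) / min(ev), digits = 3),
         "): modulators are nearly collinear")
  }
  xtxinv <- chol2inv(chol(xtx))
  pinv <- tcrossprod(xtxinv, x)            # p x K
  coefs <- tcrossprod(cmat, pinv)          # n x p, since (pinv %*% C')' = C %*% pinv'
  fitted <- tcrossprod(coefs, x)           # n x K
  rss <- rowSums((cmat - fitted)^2)
  df <- k - p
  sigma2 <- rss / df
  se <- sqrt(outer(sigma2, diag(xtxinv)))
  tstat <- coefs / se
  # se = 0 (perfect or constant fit): a coefficient at rounding-noise scale is
  # "no effect" (p = 1), a real one an exact effect (p = 0)
  degen <- which(se == 0)
  if (length(degen)) {
    tol <- sqrt(.Machine$double.eps) *
      pmax(1, apply(abs(cmat), 1L, max))[(degen - 1L) %% nrow(coefs) + 1L]
    tstat[degen] <- ifelse(abs(coefs[degen]) <= tol, 0,
                           sign(coefs[degen]) * Inf)
  }
  pvals <- 2 * stats::pt(-abs(tstat), df)
  colnames(coefs) <- colnames(pvals) <- colnames(x)
  list(coefficients = coefs, pvalues = pvals, sigma = sqrt(sigma2), df = df)
}

#' Fit the co-modulation regression for a single gene pair
#'
#' Ordinary least squares of one covariability vector on the z-transformed
#' modulator design, \eqn{C_{ij} = \sum_m \beta_m e_m + \varepsilon}, with
#' two-sided t-tests on each modulator coefficient.
#'
#' @param C Numeric covariability vector of length K (see [covariability()]).
#' @param X A `"comre_design"` from [build_design_matrix()].
#' @return A list of class `"comre_pattern"`: `betas` and `pvalues` (named by
#'   modulator), `intercept` (`NA` if the design has none), `sigma` (residual
#'   standard deviation) and `df`.
#' @export
fit_pair <- function(C, X) {
  if (!inherits(X, "comre_design")) stop("X must be a comre_design")
  fit <- .ols_batch(matrix(C, nrow = 1L), X)
  mods <- X$modulator_ids
  structure(list(
    betas = stats::setNames(fit$coefficients[1L, mods], mods),
    pvalues = stats::setNames(fit$pvalues[1L, mods], mods),
    intercept = if (X$intercept) unname(fit$coefficients[1L, "(Intercept)"]) else NA_real_,
    sigma = fit$sigma[1L], df = fit$df), class = "comre_pattern")
}

#' Fit co-modulation patterns for many gene pairs
#'
#' Applies the regression of [fit_pair()] to every requested pair, reusing
#' the single shared pseudoinverse of the design matrix and streaming over
#' pairs in chunks, so genome-scale pair sets are feasible on a desktop.
#'
#' @param expr Expression matrix (genes x samples).
#' @param modulator_ids Modulator gene ids (rows of `expr`), or the ids to
#'   label random regressors with when `random_baseline = TRUE`.
#' @param pairs Pair specification as in [covariability_profile()]; default
#'   all unordered pairs of `expr`'s genes.
#' @param chunk_size Pairs per chunk (default 10000).
#' @param intercept Include an intercept column (default `TRUE`).
#' @param random_baseline Replace each modulator column with i.i.d. standard
#'   normal draws — the calibration control in which no real modulator
#'   information enters the model.
#' @param seed Seed for the random baseline draws (required when
#'   `random_baseline = TRUE`).
#' @param out_file Optional path: stream the patterns to a TSV instead of
#'   (in addition to) returning them.
#' @return A data frame with one row per pair: `gene_i`, `gene_j`,
#'   `beta_<mod>` and `p_<mod>` per modulator, and `intercept`.
#' @export
fit_all_pairs <- function(expr, modulator_ids, pairs = NULL,
                          chunk_size = 10000L, intercept = TRUE,
                          random_baseline = FALSE, seed = NULL,
                          out_file = NULL) {
  fit <- comre(expr, modulator_ids, pairs = pairs, chunk_size = chunk_size,
               intercept = intercept, random_baseline = random_baseline,
               seed = seed, keep_covariability = FALSE)
  pat <- as.data.frame(fit)
  if (!is.null(out_file)) {
    utils::write.table(pat, out_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  pat
}

#' Covariability-based multiple regression across gene pairs
#'
#' The central fitting function: for every gene pair, the per-sample
#' covariability (the pair's per-sample contribution to its Pearson
#' correlation) is regressed on the z-transformed expression of M candidate
#' modulator genes,
#' \deqn{C_{ij} = \sum_{m \in M} \beta_m e_m + \varepsilon,}
#' giving each pair an M-length vector of standardized coefficients and
#' two-sided t-test p-values — its co-modulation pattern.  All pairs share
#' one design matrix, so the pseudoinverse is computed once and applied to
#' chunked blocks of covariability vectors.
#'
#' @inheritParams fit_all_pairs
#' @param keep_covariability Retain the covariability matrix in the fitted
#'   object (enables [residuals.comre()]; default: only when it would hold at
#'   most 5e6 values).
#' @return An object of class `"comre"`: a list with `pairs` (data frame of
#'   `gene_i`, `gene_j`), `betas` and `pvalues` (pairs x M matrices),
#'   `intercepts`, `sigma`, `df`, `K`, `design` (the `"comre_design"`), and
#'   optionally `covariability`.  Methods: `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate`, `plot`.
#' @examples
#' sim <- generate_modulated(simulation_scenario(
#'   n_genes = 10, n_modulators = 2, n_samples = 60,
#'   planted = data.frame(gene_i = "gp001_a", gene_j = "gp001_b",
#'                        modulator = "M01", beta = 0.4), seed = 1))
#' fit <- comre(sim$expr, c("M01", "M02"))
#' fit
#' head(coef(fit))
#' @export
comre <- function(expr, modulator_ids, pairs = NULL, chunk_size = 10000L,
                  intercept = TRUE, random_baseline = FALSE, seed = NULL,
                  keep_covariability = NULL) {
  expr <- .check_expression_matrix(expr)
  cl <- match.call()
  if (random_baseline) {
    if (is.null(seed)) stop("random_baseline = TRUE requires a seed")
    k <- ncol(expr)
    m <- length(modulator_ids)
    set.seed(seed)
    rand <- matrix(stats::rnorm(m * k), nrow = m,
                   dimnames = list(paste0("random_", seq_len(m)), colnames(expr)))
    design <- build_design_matrix(rand, rownames(rand), intercept = intercept)
  } else {
    design <- build_design_matrix(expr, modulator_ids, intercept = intercept)
  }
  if (is.null(pairs)) {
    pool <- setdiff(rownames(expr), if (random_baseline) character(0L) else modulator_ids)
    pairs <- all_pairs(pool)
  }
  pairs <- .as_pair_matrix(pairs)
  n <- nrow(pairs)
  mods <- design$modulator_ids
  if (is.null(keep_covariability)) {
    keep_covariability <- n * ncol(expr) <= 5e6
  }
  betas <- matrix(NA_real_, n, length(mods),
                  dimnames = list(pair_ids(pairs), mods))
  pvalues <- betas
  intercepts <- rep(NA_real_, n)
  sigma <- rep(NA_real_, n)
  cov_keep <- if (keep_covariability && n > 0L) {
    matrix(NA_real_, n, ncol(expr), dimnames = list(pair_ids(pairs), colnames(expr)))
  }
  df <- ncol(expr) - ncol(design$X)
  starts <- if (n > 0L) seq(1L, n, by = chunk_size) else integer(0L)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, n)
    cmat <- covariability_profile(expr, pairs[s:e, , drop = FALSE],
                                  chunk_size = chunk_size)
    fit <- tryCatch(.ols_batch(cmat, design), error = function(err) {
      stop("while fitting pairs ", s, "-", e, " (first pair ",
           pairs[s, 1L], "|", pairs[s, 2L], "): ", conditionMessage(err),
           call. = FALSE)
    })
    betas[s:e, ] <- fit$coefficients[, mods, drop = FALSE]
    pvalues[s:e, ] <- fit$pvalues[, mods, drop = FALSE]
    if (design$intercept) intercepts[s:e] <- fit$coefficients[, "(Intercept)"]
    sigma[s:e] <- fit$sigma
    df <- fit$df
    if (!is.null(cov_keep)) cov_keep[s:e, ] <- cmat
  }
  structure(list(
    pairs = data.frame(gene_i = pairs[, 1L], gene_j = pairs[, 2L],
                       stringsAsFactors = FALSE),
    betas = betas, pvalues = pvalues, intercepts = intercepts,
    sigma = sigma, df = df, K = ncol(expr), design = design,
    random_baseline = random_baseline,
    covariability = cov_keep, call = cl), class = "comre")
}

#' @export
print.comre <- function(x, ...) {
  cat("Covariability-based multiple regression (CoMRe)\n")
  cat(sprintf("  %d gene pair(s), %d modulator(s), %d sample(s)%s\n",
              nrow(x$pairs), length(x$design$modulator_ids), x$K,
              if (x$random_baseline) " [random-baseline regressors]" else ""))
  cat(sprintf("  intercept: %s; residual df: %d\n",
              if (x$design$intercept) "yes" else "no", x$df))
  invisible(x)
}

#' Coefficients of a CoMRe fit
#'
#' @param object A `"comre"` fit.
#' @param ... Unused.
#' @return Matrix (pairs x coefficients) of intercepts (if fitted) and
#'   modulator betas.
#' @export
coef.comre <- function(object, ...) {
  if (object$design$intercept) {
    cbind(`(Intercept)` = object$intercepts, object$betas)
  } else {
    object$betas
  }
}

#' Fitted covariability values
#' @param object A `"comre"` fit.
#' @param ... Unused.
#' @return Matrix (pairs x samples) of model-implied covariability.
#' @export
fitted.comre <- function(object, ...) {
  x <- object$design$X
  b <- coef.comre(object)
  out <- tcrossprod(b, x)
  dimnames(out) <- list(rownames(object$betas), object$design$sample_ids)
  out
}

#' Residuals of a CoMRe fit
#' @param object A `"comre"` fit created with `keep_covariability = TRUE`.
#' @param ... Unused.
#' @return Matrix (pairs x samples) of residual covariability.
#' @export
residuals.comre <- function(object, ...) {
  if (is.null(object$covariability)) {
    stop("covariability matrix was not retained; refit with keep_covariability = TRUE")
  }
  object$covariability - fitted.comre(object)
}

#' Simulate covariability responses from a fitted CoMRe model
#'
#' Draws new covariability vectors as fitted values plus Gaussian residual
#' noise at each pair's estimated residual standard deviation.
#'
#' @param object A `"comre"` fit.
#' @param nsim Number of simulated replicates.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return List of `nsim` matrices (pairs x samples).
#' @export
simulate.comre <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted.comre(object)
  lapply(seq_len(nsim), function(i) {
    mu + matrix(stats::rnorm(length(mu), sd = rep(object$sigma, ncol(mu))),
                nrow(mu), ncol(mu), dimnames = dimnames(mu))
  })
}

#' Histograms of a CoMRe fit
#'
#' Four-panel summary: covariability values (when retained), modulator beta
#' values, modulator p-values, and the per-pair count of significant
#' modulators.
#'
#' @param x A `"comre"` fit.
#' @param alpha Significance threshold for the modulator-count panel.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.comre <- function(x, alpha = 0.05, ...) {
  op <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(op))
  if (!is.null(x$covariability)) {
    graphics::hist(x$covariability, main = "Covariability",
                   xlab = "covariability", ...)
  } else {
    graphics::plot.new()
    graphics::title("Covariability not retained")
  }
  graphics::hist(x$betas, main = "Regression beta values", xlab = "beta", ...)
  graphics::hist(x$pvalues, main = "Regression p-values", xlab = "p-value", ...)
  nsig <- rowSums(x$pvalues < alpha)
  graphics::hist(nsig, breaks = seq(-0.5, length(x$design$modulator_ids) + 0.5),
                 main = sprintf("Significant modulators per pair (p < %g)", alpha),
                 xlab = "number of significant modulators", ...)
  invisible(x)
}

#' Export a CoMRe fit as a pattern table
#'
#' @param x A `"comre"` fit.
#' @param ... Unused.
#' @return Data frame with `gene_i`, `gene_j`, `beta_<mod>`, `p_<mod>` and
#'   `intercept` columns (the on-disk pattern format).
#' @export
as.data.frame.comre <- function(x, ...) {
  mods <- x$design$modulator_ids
  out <- x$pairs
  b <- as.data.frame(x$betas)
  names(b) <- paste0("beta_", mods)
  p <- as.data.frame(x$pvalues)
  names(p) <- paste0("p_", mods)
  out <- cbind(out, b, p, intercept = x$intercepts)
  rownames(out) <- NULL
  out
}

#' Read a pattern table written by [fit_all_pairs()] or the CLI
#'
#' @param path TSV path with `gene_i`, `gene_j`, `beta_*`, `p_*` and
#'   `intercept` columns.
#' @return Data frame of co-modulation patterns.
#' @export
read_patterns <- function(path) {
  pat <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_i", "gene_j")
  if (!all(need %in% names(pat)) || !any(startsWith(names(pat), "beta_"))) {
    stop("not a pattern table: expected gene_i, gene_j and beta_* columns")
  }
  pat
}

# Pull aligned beta/p matrices and pair table out of a comre fit or a pattern
# data frame; the shared accessor behind the analysis and validation layers.
.pattern_parts <- function(patterns) {
  if (inherits(patterns, "comre")) {
    return(list(pairs = patterns$pairs, betas = patterns$betas,
                pvalues = patterns$pvalues, intercepts = patterns$intercepts,
                modulators = patterns$design$modulator_ids))
  }
  if (is.data.frame(patterns)) {
    bcols <- grep("^beta_", names(patterns), value = TRUE)
    mods <- sub("^beta_", "", bcols)
    pcols <- paste0("p_", mods)
    if (!all(pcols %in% names(patterns))) {
      stop("pattern table lacks p_* columns matching its beta_* columns")
    }
    ids <- paste(patterns$gene_i, patterns$gene_j, sep = "|")
    return(list(
      pairs = data.frame(gene_i = patterns$gene_i, gene_j = patterns$gene_j,
                         stringsAsFactors = FALSE),
      betas = matrix(as.matrix(patterns[bcols]), ncol = length(mods),
                     dimnames = list(ids, mods)),
      pvalues = matrix(as.matrix(patterns[pcols]), ncol = length(mods),
                       dimnames = list(ids, mods)),
      intercepts = if ("intercept" %in% names(patterns)) patterns$intercept
                   else rep(NA_real_, nrow(patterns)),
      modulators = mods))
  }
  stop("patterns must be a comre fit or a pattern data frame")
}
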