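#' z-transform a vector
#'
#' Subtracts the sample mean and divides by the sample standard deviation
#' (n-1 denominator), so the result has mean 0 and sample sd 1.
#'
#' @param v Numeric vector, length >= 3, non-constant.
#' @param label Optional name used in error messages (e.g. the gene id).
#' @return Numeric vector of z-scores.
#' @examples
#' zscore(c(1, 2, 3)) # -1 0 1
#' @export
zscore <- function(v, label = NULL) {
  who <- if (is.null(label)) "input vector" else paste0("'", label, "'")
  if (length(v) < 3L) {
    stop("z-transform needs at least 3 values (", who, " has ", length(v), ")")
  }
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stop("zero variance: cannot z-transform ", who)
  }
  (v - mean(v)) / s
}

# Row-wise z-scores of an expression matrix; errors name the offending gene.
.zscore_rows <- function(expr) {
  k <- ncol(expr)
  mu <- rowMeans(expr)
  sd_ <- sqrt(rowSums((expr - mu)^2) / (k - 1L))
  zero <- which(sd_ == 0 | !is.finite(sd_))
  if (length(zero)) {
    stop("zero variance: cannot z-transform '", rownames(expr)[zero[1L]], "'")
  }
  (expr - mu) / sd_
}

#' Per-sample covariability of two expression vectors
#'
#' The covariability of genes i and j in sample k is the product of the two
#' genes' expression z-scores in that sample,
#' \deqn{C_{ij}^k = \frac{e_i^k - \mu_i}{\sigma_i} \cdot
#'                  \frac{e_j^k - \mu_j}{\sigma_j},}
#' the per-sample product-moment contribution to their Pearson correlation:
#' with the sample-sd convention used here,
#' \eqn{\sum_k C_{ij}^k = (K-1)\,\rho_{ij}}.  Large positive (negative)
#' values flag samples where the two genes deviate strongly in the same
#' (opposite) direction.
#'
#' @param e_i,e_j Numeric vectors of equal length K >= 3, both non-constant.
#' @param gene_i,gene_j Optional gene labels for error messages.
#' @return Numeric vector of length K of per-sample covariability values.
#' @examples
#' covariability(c(1, 2, 3), c(3, 2, 1)) # -1 0 -1; sums to (K-1) * r = -2
#' @export
covariability <- function(e_i, e_j, gene_i = NULL, gene_j = NULL) {
  if (length(e_i) != length(e_j)) {
    stop("expression vectors differ in length (", length(e_i), " vs ",
         length(e_j), ")")
  }
  zscore(e_i, label = gene_i) * zscore(e_j, label = gene_j)
}

# Normalise a pair specification to a 2-column character matrix.
.as_pair_matrix <- function(pairs) {
  if (is.null(pairs)) return(matrix(character(0L), 0L, 2L))
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (is.character(pairs) && is.null(dim(pairs)) && length(pairs) == 2L) {
    pairs <- matrix(pairs, 1L, 2L)
  }
  if (!is.matrix(pairs) || ncol(pairs) != 2L) {
    stop("pairs must be a 2-column matrix/data frame or a list of length-2 vectors")
  }
  storage.mode(pairs) <- "character"
  dimnames(pairs) <- list(NULL, c("gene_i", "gene_j"))
  pairs
}

#' Enumerate all unordered gene pairs
#'
#' @param gene_ids Character vector of gene ids (no duplicates).
#' @return 2-column character matrix of all n(n-1)/2 unordered pairs, with
#'   gene_i preceding gene_j in the input order.
#' @export
all_pairs <- function(gene_ids) {
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  n <- length(gene_ids)
  if (n < 2L) return(.as_pair_matrix(NULL))
  idx <- utils::combn(n, 2L)
  cbind(gene_i = gene_ids[idx[1L, ]], gene_j = gene_ids[idx[2L, ]])
}

#' Pair identifiers of the form "geneA|geneB"
#' @param pairs Pair specification (see [covariability_profile()]).
#' @return Character vector of pair ids.
#' @export
pair_ids <- function(pairs) {
  p <- .as_pair_matrix(pairs)
  paste(p[, 1L], p[, 2L], sep = "|")
}

#' Covariability profiles for a set of gene pairs
#'
#' Computes the per-sample covariability of each requested pair, processing
#' pairs in chunks so that memory stays bounded for large pair sets.
#'
#' @param expr Expression matrix (genes x samples).
#' @param pairs Pairs as a 2-column matrix/data frame of gene ids, a list of
#'   length-2 character vectors, or `NULL` for all unordered pairs of
#'   `expr`'s genes.  Self-pairs are allowed when given explicitly.
#' @param chunk_size Number of pairs per processing chunk (default 10000).
#' @return Numeric matrix (pairs x samples); row names are
#'   `"geneA|geneB"` pair ids.
#' @export
covariability_profile <- function(expr, pairs = NULL, chunk_size = 10000L) {
  expr <- .check_expression_matrix(expr)
  if (is.null(pairs)) pairs <- all_pairs(rownames(expr))
  pairs <- .as_pair_matrix(pairs)
  unknown <- setdiff(unique(c(pairs)), rownames(expr))
  if (length(unknown)) {
    stop("unknown gene ids: ", paste(unknown, collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = nrow(pairs), ncol = ncol(expr),
                dimnames = list(pair_ids(pairs), colnames(expr)))
  if (!nrow(pairs)) return(out)
  genes <- unique(c(pairs))
  z <- .zscore_rows(expr[genes, , drop = FALSE])
  starts <- seq(1L, nrow(pairs), by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, nrow(pairs))
    out[s:e, ] <- z[pairs[s:e, 1L], , drop = FALSE] *
      z[pairs[s:e, 2L], , drop = FALSE]
  }
  out
}
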