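#' Read a gene-by-sample expression matrix from delimited text
#'
#' Expects a header row of sample identifiers (with a corner label in the
#' first field) and one row per gene/probe, the first column holding the
#' identifier and the remaining columns log2 expression values.  All cells
#' must parse as finite numbers; missing values are rejected rather than
#' imputed because the covariability statistic and the downstream ordinary
#' least squares assume complete data.
#'
#' @param path Path to the delimited text file.
#' @param delimiter Field delimiter, default tab.
#' @return A numeric matrix (genes x samples) with gene ids as row names and
#'   sample ids as column names.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(6, 8), 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' write_expression_matrix(m, tf)
#' read_expression_matrix(tf)
#' @seealso [write_expression_matrix()], [filter_noninformative()],
#'   [collapse_probes_by_cv()]
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    stop("expression file not found: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression file must contain a header row and at least one data row: ", path)
  }
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  n_body_fields <- lengths(body)
  # tolerate headers written without a corner label
  n_values <- unique(n_body_fields) - 1L
  if (length(n_values) != 1L) {
    stop("ragged rows in expression file: rows have differing field counts")
  }
  if (length(header) == n_values + 1L) {
    sample_ids <- header[-1L]
  } else if (length(header) == n_values) {
    sample_ids <- header
  } else {
    stop("header has ", length(header), " fields but data rows have ",
         n_values + 1L)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate row ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  values <- matrix(NA_real_, nrow = length(body), ncol = n_values,
                   dimnames = list(gene_ids, sample_ids))
  for (r in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[r]][-1L]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric or non-finite value '%s' at row %d (id '%s'), column %d (sample '%s')",
        body[[r]][bad[1L] + 1L], r, gene_ids[r], bad[1L], sample_ids[bad[1L]]))
    }
    values[r, ] <- v
  }
  values
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]: writes a header row
#' (`gene_id` corner label plus sample ids) followed by one row per gene.
#'
#' @param expr Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, delimiter = "\t") {
  expr <- .check_expression_matrix(expr)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = delimiter), con)
  body <- apply(expr, 1L, function(v) {
    paste(format(v, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = delimiter)
  })
  writeLines(paste(rownames(expr), body, sep = delimiter), con)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column delimited text (probe_id, gene_id); a header row is detected by
#' the literal column names `probe_id`/`gene_id` and skipped.  Many probes may
#' map to one gene; probe ids must be unique and gene ids non-empty.
#'
#' @param path Path to the two-column delimited file.
#' @param delimiter Field delimiter, default tab.
#' @return A data frame with columns `probe_id` and `gene_id`.
#' @export
read_probe_map <- function(path, delimiter = "\t") {
  tab <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(tab) != 2L) {
    stop("probe map must have exactly two columns (probe_id, gene_id)")
  }
  names(tab) <- c("probe_id", "gene_id")
  if (nrow(tab) && tolower(tab$probe_id[1L]) == "probe_id") {
    tab <- tab[-1L, , drop = FALSE]
  }
  .check_probe_map(tab)
  rownames(tab) <- NULL
  tab
}

.check_probe_map <- function(map) {
  if (!is.data.frame(map) || !all(c("probe_id", "gene_id") %in% names(map))) {
    stop("probe map must be a data frame with columns probe_id and gene_id")
  }
  if (anyDuplicated(map$probe_id)) {
    stop("duplicate probe ids in probe map: ",
         paste(unique(map$probe_id[duplicated(map$probe_id)]), collapse = ", "))
  }
  if (any(!nzchar(map$gene_id))) {
    stop("empty gene_id in probe map")
  }
  invisible(map)
}

.check_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must carry gene row names and sample column names")
  }
  if (any(!is.finite(expr))) {
    stop("expression matrix contains non-finite values")
  }
  expr
}

#' Per-row coefficient of variation
#'
#' CV = standard deviation / arithmetic mean, computed row-wise on the (log2)
#' values as supplied.  Rows with zero mean get `NA` (CV undefined).
#'
#' @param expr Numeric matrix (genes x samples).
#' @param denominator `"n-1"` (sample standard deviation, default) or `"n"`
#'   (population standard deviation); exposed for reproducibility of either
#'   convention.
#' @return Named numeric vector of CVs, one per row.
#' @export
row_cv <- function(expr, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  k <- ncol(expr)
  mu <- rowMeans(expr)
  ss <- rowSums((expr - mu)^2)
  sd_ <- sqrt(ss / if (denominator == "n-1") k - 1L else k)
  cv <- ifelse(mu == 0, NA_real_, sd_ / mu)
  names(cv) <- rownames(expr)
  cv
}

#' Collapse probe rows to one representative row per gene
#'
#' When several probes measure one gene, the probe with the largest
#' coefficient of variation across samples is kept as the representative and
#' relabelled with the gene id.  Ties in CV are broken by the
#' lexicographically smallest probe id so output is deterministic.  Genes
#' whose probes all have zero mean (CV undefined) raise an error.
#'
#' @param expr Numeric matrix with probe ids as row names.
#' @param map Probe map data frame (`probe_id`, `gene_id`); every row of
#'   `expr` must appear.
#' @param cv_denominator Passed to [row_cv()].
#' @return Expression matrix with one row per gene, ordered by first
#'   occurrence of each gene among the input rows.  The chosen probe for each
#'   gene is recorded in the `"probe"` attribute.
#' @export
collapse_probes_by_cv <- function(expr, map, cv_denominator = c("n-1", "n")) {
  expr <- .check_expression_matrix(expr)
  .check_probe_map(map)
  cv_denominator <- match.arg(cv_denominator)
  probes <- rownames(expr)
  missing <- setdiff(probes, map$probe_id)
  if (length(missing)) {
    stop("probes absent from probe map: ", paste(missing, collapse = ", "))
  }
  gene_of <- map$gene_id[match(probes, map$probe_id)]
  cv <- row_cv(expr, denominator = cv_denominator)
  first_seen <- unique(gene_of)
  keep <- vapply(first_seen, function(g) {
    rows <- which(gene_of == g)
    cvg <- cv[rows]
    if (all(is.na(cvg))) {
      stop("CV undefined (zero mean) for all probes of gene ", g)
    }
    rows <- rows[!is.na(cvg)]
    cvg <- cvg[!is.na(cvg)]
    best <- rows[cvg == max(cvg)]
    best[order(probes[best])][1L]
  }, integer(1L))
  out <- expr[keep, , drop = FALSE]
  rownames(out) <- first_seen
  attr(out, "probe") <- stats::setNames(probes[keep], first_seen)
  out
}

#' Filter out non-informative expression rows
#'
#' Removes rows whose coefficient of variation is below `cv_min` or whose mean
#' expression is below `mean_min` (both on the log2 scale); a row is retained
#' only when CV >= `cv_min` and mean >= `mean_min`, mirroring strict-`<`
#' removal.  Row order of survivors is preserved.
#'
#' @param expr Numeric matrix (genes x samples), log2 scale.
#' @param cv_min Minimum CV for retention (default 0.05, i.e. 5%).
#' @param mean_min Minimum row mean for retention (default 6 log2 units).
#' @param cv_denominator Passed to [row_cv()].
#' @return The surviving rows, with an attribute `"removed"`: a named integer
#'   vector counting rows failing the CV criterion and the mean criterion
#'   (a row may be counted under both).
#' @export
filter_noninformative <- function(expr, cv_min = 0.05, mean_min = 6,
                                  cv_denominator = c("n-1", "n")) {
  expr <- .check_expression_matrix(expr)
  cv <- row_cv(expr, denominator = match.arg(cv_denominator))
  mu <- rowMeans(expr)
  fail_cv <- is.na(cv) | cv < cv_min
  fail_mean <- mu < mean_min
  keep <- !fail_cv & !fail_mean
  if (!any(keep)) {
    warning("all rows removed by the CV/mean filters")
  }
  out <- expr[keep, , drop = FALSE]
  attr(out, "removed") <- c(cv = sum(fail_cv), mean = sum(fail_mean),
                            total = sum(!keep))
  out
}
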