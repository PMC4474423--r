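#' Estimated covariability profiles in a new cohort
#'
#' Applies discovery-cohort co-modulation patterns to a validation cohort:
#' the estimated covariability of pair p in patient k is
#' `intercept_p + sum_m beta_{p,m} * z_m^k`, where `z_m^k` is the z-score of
#' modulator m in patient k computed within the validation cohort (the
#' cohorts' scales differ, so z-scores are always cohort-local; the discovery
#' betas are applied unchanged).
#'
#' @param patterns A `"comre"` fit or pattern data frame carrying discovery
#'   betas.
#' @param modulator_expr Expression matrix of the validation cohort; must
#'   contain every modulator row.
#' @param pairs Optional subset of pairs (2-column specification or row
#'   indices); default all pairs in `patterns`.
#' @return Numeric matrix (pairs x patients) of estimated covariability.
#' @export
estimate_profile <- function(patterns, modulator_expr, pairs = NULL) {
  parts <- .pattern_parts(patterns)
  modulator_expr <- .check_expression_matrix(modulator_expr)
  missing <- setdiff(parts$modulators, rownames(modulator_expr))
  if (length(missing)) {
    stop("modulators absent from validation matrix: ",
         paste(missing, collapse = ", "))
  }
  idx <- .pair_subset_index(parts, pairs)
  z <- .zscore_rows(modulator_expr[parts$modulators, , drop = FALSE])
  b <- parts$betas[idx, , drop = FALSE]
  est <- b %*% z
  ic <- parts$intercepts[idx]
  ic[is.na(ic)] <- 0
  est <- est + ic
  rownames(est) <- paste(parts$pairs$gene_i[idx], parts$pairs$gene_j[idx], sep = "|")
  est
}

# Resolve a pair subset (NULL, indices, or 2-column ids) to row indices of
# the pattern table.
.pair_subset_index <- function(parts, pairs) {
  if (is.null(pairs)) return(seq_len(nrow(parts$pairs)))
  if (is.numeric(pairs)) return(as.integer(pairs))
  p <- .as_pair_matrix(pairs)
  have <- paste(parts$pairs$gene_i, parts$pairs$gene_j, sep = "|")
  want <- paste(p[, 1L], p[, 2L], sep = "|")
  idx <- match(want, have)
  if (anyNA(idx)) {
    stop("pairs not present in patterns: ",
         paste(want[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Validate co-modulation patterns in an independent cohort
#'
#' For each patient of the validation cohort, correlates the estimated
#' covariability profile (discovery betas applied to the patient's modulator
#' z-scores, [estimate_profile()]) with the real profile (covariability
#' computed from the validation cohort's own expression,
#' [covariability_profile()]) across the pair subset.  A patient is
#' "validated" when the Pearson correlation is positive with two-sided
#' p < `patient_alpha`.  The overall validated proportion is tested against
#' `null_proportion` with a one-sample z-test.
#'
#' @param patterns A `"comre"` fit or pattern data frame from the discovery
#'   cohort.
#' @param validation_expr Expression matrix of the validation cohort
#'   (must contain the pair genes and the modulators).
#' @param pairs Pair subset; default: all pairs with at least one significant
#'   modulator (p < `alpha`) in discovery.
#' @param patient_alpha Per-patient significance threshold (default 0.05).
#' @param null_proportion Null value for the z-test on the validated
#'   proportion (default 0.05, the chance rate of patient-level calls).
#' @param alpha Discovery threshold used to build the default pair subset.
#' @return An object of class `"comre_validation"`: list with `patients`
#'   (data frame: patient, r, pvalue, validated), `n_validated`,
#'   `n_patients`, `proportion`, `ci` (95% Wald), `z`, `z_pvalue`
#'   (one-sided, greater), `n_pairs`, `null_proportion`.
#' @export
validate_cohort <- function(patterns, validation_expr, pairs = NULL,
                            patient_alpha = 0.05, null_proportion = 0.05,
                            alpha = 0.05) {
  parts <- .pattern_parts(patterns)
  validation_expr <- .check_expression_matrix(validation_expr)
  if (is.null(pairs)) {
    idx <- which(rowSums(parts$pvalues < alpha) > 0L)
  } else {
    idx <- .pair_subset_index(parts, pairs)
  }
  if (length(idx) < 3L) {
    stop("fewer than 3 pairs in the validation subset; correlation undefined")
  }
  sub_pairs <- parts$pairs[idx, , drop = FALSE]
  genes <- unique(c(sub_pairs$gene_i, sub_pairs$gene_j))
  missing <- setdiff(genes, rownames(validation_expr))
  if (length(missing)) {
    stop("pair genes absent from validation matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  }
  est <- estimate_profile(patterns, validation_expr, pairs = idx)
  real <- covariability_profile(validation_expr, as.matrix(sub_pairs))
  n <- nrow(est)
  # vectorised per-patient Pearson r and its two-sided t-test
  ce <- sweep(est, 2L, colMeans(est))
  cr <- sweep(real, 2L, colMeans(real))
  se <- sqrt(colSums(ce^2))
  sr <- sqrt(colSums(cr^2))
  denom <- se * sr
  r <- ifelse(denom > 0, colSums(ce * cr) / denom, NA_real_)
  if (anyNA(r)) {
    warning(sum(is.na(r)), " patient(s) with a constant profile; ",
            "correlation undefined, counted as not validated")
  }
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tstat), df = n - 2)
  validated <- !is.na(r) & r > 0 & pv < patient_alpha
  n_patients <- length(r)
  n_validated <- sum(validated)
  prop <- n_validated / n_patients
  z <- (prop - null_proportion) /
    sqrt(null_proportion * (1 - null_proportion) / n_patients)
  structure(list(
    patients = data.frame(patient = colnames(validation_expr), r = r,
                          pvalue = pv, validated = validated,
                          stringsAsFactors = FALSE),
    n_validated = n_validated, n_patients = n_patients, proportion = prop,
    ci = proportion_ci(prop, n_patients),
    z = z, z_pvalue = stats::pnorm(z, lower.tail = FALSE),
    n_pairs = length(idx), patient_alpha = patient_alpha,
    null_proportion = null_proportion), class = "comre_validation")
}

#' @export
print.comre_validation <- function(x, ...) {
  cat("Cross-cohort validation of co-modulation patterns\n")
  cat(sprintf("  %d pair(s), %d patient(s)\n", x$n_pairs, x$n_patients))
  cat(sprintf("  validated (r > 0, p < %g): %d of %d (%.2f%%), 95%% CI [%.2f%%, %.2f%%]\n",
              x$patient_alpha, x$n_validated, x$n_patients, 100 * x$proportion,
              100 * x$ci[1L], 100 * x$ci[2L]))
  cat(sprintf("  one-sample z-test vs p0 = %g: z = %.2f, p = %.3g\n",
              x$null_proportion, x$z, x$z_pvalue))
  invisible(x)
}

#' Write a validation report
#'
#' One TSV row per patient plus a JSON summary block (requires the
#' `jsonlite` package for the JSON part).
#'
#' @param report A `"comre_validation"` object.
#' @param tsv_path Path for the per-patient table.
#' @param json_path Optional path for the JSON summary.
#' @return `report`, invisibly.
#' @export
write_validation_report <- function(report, tsv_path, json_path = NULL) {
  if (!inherits(report, "comre_validation")) {
    stop("report must be a comre_validation object")
  }
  utils::write.table(report$patients, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("the jsonlite package is required for JSON output")
    }
    jsonlite::write_json(list(
      n_validated = report$n_validated, n_patients = report$n_patients,
      proportion = report$proportion,
      ci_low = report$ci[1L], ci_high = report$ci[2L],
      z = report$z, z_pvalue = report$z_pvalue,
      n_pairs = report$n_pairs), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Predicted covariability profiles from a CoMRe fit
#'
#' With `newdata`, returns the estimated covariability profiles in that
#' cohort (see [estimate_profile()]); without, the fitted values.
#'
#' @param object A `"comre"` fit.
#' @param newdata Optional expression matrix containing the modulator rows.
#' @param pairs Optional pair subset.
#' @param ... Unused.
#' @return Numeric matrix (pairs x samples/patients).
#' @export
predict.comre <- function(object, newdata = NULL, pairs = NULL, ...) {
  if (is.null(newdata)) {
    f <- fitted.comre(object)
    parts <- .pattern_parts(object)
    return(f[.pair_subset_index(parts, pairs), , drop = FALSE])
  }
  estimate_profile(object, newdata, pairs = pairs)
}
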