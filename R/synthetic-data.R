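#' Generate a fully null expression matrix
#'
#' Independent Gaussian log2-like expression for every gene and sample (mean
#' 8, sd 1 by default, typical of RMA-processed microarray values), with no
#' dependence structure.  Used for calibration: co-modulation regression on
#' such data should reject each coefficient at roughly the nominal rate.
#'
#' @param n_genes Number of gene rows.
#' @param n_samples Number of sample columns (>= 10).
#' @param mean,sd Gaussian parameters of the log2 expression values.
#' @param seed Optional RNG seed; a fixed seed gives a bit-identical matrix.
#' @param prefix Row-name prefix (default `"g"`).
#' @return Expression matrix (genes x samples) with ids `g0001, ...` and
#'   `s0001, ...`.
#' @export
generate_null <- function(n_genes, n_samples, mean = 8, sd = 1, seed = NULL,
                          prefix = "g") {
  if (n_samples < 10L) stop("n_samples must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(n_genes * n_samples, mean = mean, sd = sd),
         nrow = n_genes,
         dimnames = list(sprintf("%s%04d", prefix, seq_len(n_genes)),
                         sprintf("s%04d", seq_len(n_samples))))
}

#' Describe a planted-modulation simulation scenario
#'
#' The generative model mirrors the assumption of the co-modulation
#' regression: for each planted gene pair, the per-sample correlation target
#' is a linear function of the modulator z-scores,
#' `rho_k = clip(baseline + sum_m beta_m * z_m^k)`, clipped to (-0.99, 0.99),
#' and the pair's two expression values in sample k are drawn from a
#' bivariate normal with that correlation.  Genes not involved in a planted
#' pair are independent noise.
#'
#' @param n_genes Number of non-modulator gene rows (must cover the planted
#'   pair genes; extra rows are independent filler genes).
#' @param n_modulators Number of modulator rows, named `M01, M02, ...`.
#' @param n_samples Number of samples.
#' @param planted Data frame with columns `gene_i`, `gene_j`, `modulator`,
#'   `beta`, and optionally `baseline` (per-pair override of
#'   `baseline_correlation`).  Several rows may share a pair (multi-modulator
#'   effects); a gene may not appear in two different planted pairs.
#' @param baseline_correlation Baseline correlation of planted pairs when no
#'   per-pair `baseline` is given (default 0).
#' @param noise_sd Expression standard deviation (default 1).
#' @param mean Expression mean (default 8, log2-like).
#' @param seed RNG seed driving every draw of the generator.
#' @return A list of class `"comre_scenario"`.
#' @export
simulation_scenario <- function(n_genes, n_modulators, n_samples,
                                planted = NULL, baseline_correlation = 0,
                                noise_sd = 1, mean = 8, seed = 1L) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (abs(baseline_correlation) >= 1) {
    stop("baseline_correlation must lie in (-1, 1)")
  }
  if (!is.null(planted)) {
    need <- c("gene_i", "gene_j", "modulator", "beta")
    if (!all(need %in% names(planted))) {
      stop("planted must have columns ", paste(need, collapse = ", "))
    }
    pid <- paste(planted$gene_i, planted$gene_j, sep = "|")
    per_gene <- unique(data.frame(gene = c(planted$gene_i, planted$gene_j),
                                  pair = c(pid, pid)))
    dup <- per_gene$gene[duplicated(per_gene$gene)]
    if (length(dup)) {
      stop("a gene may appear in only one planted pair: ",
           paste(unique(dup), collapse = ", "))
    }
    mods_ok <- planted$modulator %in% sprintf("M%02d", seq_len(n_modulators))
    if (!all(mods_ok)) {
      stop("planted modulators must be among M01..",
           sprintf("M%02d", n_modulators))
    }
  }
  structure(list(n_genes = n_genes, n_modulators = n_modulators,
                 n_samples = n_samples, planted = planted,
                 baseline_correlation = baseline_correlation,
                 noise_sd = noise_sd, mean = mean, seed = seed),
            class = "comre_scenario")
}

#' Generate expression data with planted modulation effects
#'
#' Draws modulator expression i.i.d. standard normal (rescaled to the
#' log2-like location/scale), computes each planted pair's per-sample
#' correlation target from the scenario's linear model, and samples the
#' pair's expression from the corresponding bivariate normal.  The emitted
#' ground-truth table records every planted (pair, modulator, beta) effect.
#'
#' @param scenario A `"comre_scenario"` from [simulation_scenario()].
#' @return List with `expr` (expression matrix containing modulator rows,
#'   planted-pair gene rows, and independent filler genes), `truth` (data
#'   frame `gene_i`, `gene_j`, `modulator`, `beta`, `baseline`), `modulators`
#'   (ids), `n_clipped` (count of per-sample correlation targets clipped to
#'   (-0.99, 0.99)), and `scenario`.
#' @export
generate_modulated <- function(scenario) {
  if (!inherits(scenario, "comre_scenario")) {
    stop("scenario must come from simulation_scenario()")
  }
  set.seed(scenario$seed)
  k <- scenario$n_samples
  m <- scenario$n_modulators
  mods <- sprintf("M%02d", seq_len(m))
  samples <- sprintf("s%04d", seq_len(k))
  zm <- matrix(stats::rnorm(m * k), nrow = m, dimnames = list(mods, samples))
  planted <- scenario$planted
  planted_genes <- if (is.null(planted)) character(0L) else
    unique(c(planted$gene_i, planted$gene_j))
  n_filler <- scenario$n_genes - length(planted_genes)
  if (n_filler < 0L) {
    stop("n_genes smaller than the number of distinct planted genes")
  }
  filler <- setdiff(sprintf("g%04d", seq_len(scenario$n_genes + length(planted_genes))),
                    planted_genes)[seq_len(n_filler)]
  genes <- c(planted_genes, filler)
  expr <- matrix(NA_real_, length(genes) + m, k,
                 dimnames = list(c(mods, genes), samples))
  expr[mods, ] <- scenario$mean + scenario$noise_sd * zm
  n_clipped <- 0L
  truth <- NULL
  if (!is.null(planted)) {
    pid <- paste(planted$gene_i, planted$gene_j, sep = "|")
    truth <- planted
    if (is.null(truth$baseline)) truth$baseline <- scenario$baseline_correlation
    truth$baseline[is.na(truth$baseline)] <- scenario$baseline_correlation
    for (id in unique(pid)) {
      rows <- which(pid == id)
      gi <- planted$gene_i[rows[1L]]
      gj <- planted$gene_j[rows[1L]]
      base <- truth$baseline[rows[1L]]
      rho <- base + colSums(zm[planted$modulator[rows], , drop = FALSE] *
                              planted$beta[rows])
      clipped <- abs(rho) > 0.99
      n_clipped <- n_clipped + sum(clipped)
      rho <- pmin(pmax(rho, -0.99), 0.99)
      x <- stats::rnorm(k)
      y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(k)
      expr[gi, ] <- scenario$mean + scenario$noise_sd * x
      expr[gj, ] <- scenario$mean + scenario$noise_sd * y
    }
  }
  if (length(filler)) {
    expr[filler, ] <- scenario$mean + scenario$noise_sd *
      matrix(stats::rnorm(length(filler) * k), nrow = length(filler))
  }
  if (n_clipped > 0L) {
    warning(n_clipped, " per-sample correlation target(s) clipped to (-0.99, 0.99)")
  }
  list(expr = expr, truth = truth, modulators = mods, n_clipped = n_clipped,
       scenario = scenario)
}

#' Planted replicate pairs sharing one modulation effect
#'
#' Convenience constructor for recovery experiments: `n_pairs` disjoint gene
#' pairs, each modulated by the same modulator(s) with the same beta(s).
#'
#' @param n_pairs Number of replicate pairs.
#' @param modulators Modulator id(s), e.g. `"M01"`.
#' @param betas Effect size(s), recycled against `modulators`.
#' @param baseline Optional per-pair baseline correlation(s), recycled.
#' @return Data frame suitable as the `planted` argument of
#'   [simulation_scenario()].
#' @export
planted_replicates <- function(n_pairs, modulators, betas, baseline = NULL) {
  eff <- data.frame(modulator = modulators, beta = betas,
                    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(n_pairs), function(p) {
    data.frame(gene_i = sprintf("gp%03d_a", p), gene_j = sprintf("gp%03d_b", p),
               modulator = eff$modulator, beta = eff$beta,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(baseline)) {
    out$baseline <- rep(rep_len(baseline, n_pairs), each = nrow(eff))
  }
  rownames(out) <- NULL
  out
}
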