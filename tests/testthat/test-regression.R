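test_that("design matrix z-transforms modulators and adds an intercept", {
  expr <- rbind(m1 = c(1, 2, 3), g1 = c(2, 1, 3), g2 = c(3, 1, 2),
                g3 = c(1, 3, 2), g4 = c(5, 1, 9))
  colnames(expr) <- c("s1", "s2", "s3")
  d <- build_design_matrix(expr, "m1")
  expect_identical(colnames(d$X), c("(Intercept)", "m1"))
  expect_equal(unname(d$X[, "m1"]), c(-1, 0, 1))
  expect_equal(unname(d$X[, 1]), c(1, 1, 1))

  expr2 <- random_expr(12, 40, seed = 2)
  d2 <- build_design_matrix(expr2, rownames(expr2)[1:10])
  expect_equal(unname(colMeans(d2$X[, -1])), rep(0, 10), tolerance = 1e-10)
  expect_equal(unname(apply(d2$X[, -1], 2, sd)), rep(1, 10), tolerance = 1e-10)

  expect_error(build_design_matrix(expr2, c("g001", "g001")), "duplicate")
  expect_error(build_design_matrix(expr2, "missing_mod"), "absent")
  exprc <- rbind(expr2, flat = rep(1, 40))
  expect_error(build_design_matrix(exprc, "flat"), "zero variance.*flat")
  expect_error(build_design_matrix(expr2[, 1:10], rownames(expr2)[1:10]),
               "more samples than modulators")
})

test_that("fit_pair recovers exact and degenerate responses", {
  expr <- random_expr(3, 30, seed = 4)
  d <- build_design_matrix(expr, "g001")
  zm <- zscore(expr["g001", ])
  # noiseless recovery
  fit <- fit_pair(2 * zm, d)
  expect_equal(unname(fit$betas), 2, tolerance = 1e-10)
  expect_lt(fit$pvalues[["g001"]], 1e-12)
  # constant response: zero betas, intercept equals the constant, p = 1
  flat <- fit_pair(rep(3.5, 30), d)
  expect_equal(unname(flat$betas), 0, tolerance = 1e-10)
  expect_equal(flat$intercept, 3.5, tolerance = 1e-10)
  expect_equal(unname(flat$pvalues), 1)
})

test_that("fit_pair matches the normal-equations and t-distribution oracle", {
  set.seed(10)
  expr <- random_expr(5, 30, seed = 10)
  d <- build_design_matrix(expr, rownames(expr)[1:3])
  for (i in 1:10) {
    C <- rnorm(30)
    fit <- fit_pair(C, d)
    X <- d$X
    xtxinv <- solve(t(X) %*% X)
    beta <- xtxinv %*% t(X) %*% C
    resid <- C - X %*% beta
    df <- 30 - ncol(X)
    sigma2 <- sum(resid^2) / df
    se <- sqrt(sigma2 * diag(xtxinv))
    p <- 2 * pt(-abs(beta / se), df)
    expect_equal(unname(c(fit$intercept, fit$betas)), unname(beta[, 1]),
                 tolerance = 1e-10)
    expect_equal(unname(fit$pvalues), unname(p[-1]), tolerance = 1e-10)
  }
})

test_that("fit_pair agrees with lm on a random instance", {
  expr <- random_expr(4, 25, seed = 20)
  d <- build_design_matrix(expr, rownames(expr)[1:2])
  set.seed(21)
  C <- rnorm(25)
  fit <- fit_pair(C, d)
  Zm <- apply(expr[1:2, ], 1, function(v) (v - mean(v)) / sd(v))
  ref <- summary(lm(C ~ Zm))$coefficients
  expect_equal(unname(fit$betas), unname(ref[-1, 1]), tolerance = 1e-12)
  expect_equal(unname(fit$pvalues), unname(ref[-1, 4]), tolerance = 1e-12)
  expect_equal(fit$intercept, unname(ref[1, 1]), tolerance = 1e-12)
})

test_that("batched fits equal per-pair fits and count_pairs is exact", {
  expr <- random_expr(13, 40, seed = 6)
  mods <- rownames(expr)[1:3]
  genes <- rownames(expr)[4:13]
  pat <- fit_all_pairs(expr, mods, pairs = all_pairs(genes), chunk_size = 8)
  expect_identical(nrow(pat), 45L)
  d <- build_design_matrix(expr, mods)
  for (p in c(1, 17, 45)) {
    C <- covariability(expr[pat$gene_i[p], ], expr[pat$gene_j[p], ])
    single <- fit_pair(C, d)
    expect_equal(unname(unlist(pat[p, paste0("beta_", mods)])),
                 unname(single$betas), tolerance = 1e-10)
    expect_equal(unname(unlist(pat[p, paste0("p_", mods)])),
                 unname(single$pvalues), tolerance = 1e-10)
  }
  expect_identical(nrow(fit_all_pairs(expr, mods,
                                      pairs = matrix(character(0), 0, 2))), 0L)
  expect_equal(count_pairs(2), 1)
  expect_equal(count_pairs(100), 4950)
  expect_error(count_pairs(1), ">= 2")
})

test_that("comre fits default to all non-modulator pairs and expose methods", {
  expr <- random_expr(8, 30, seed = 8)
  fit <- comre(expr, rownames(expr)[1:2])
  expect_s3_class(fit, "comre")
  expect_identical(nrow(fit$pairs), 15L) # choose(6, 2)
  expect_identical(dim(coef(fit)), c(15L, 3L))
  # residuals reconstruct the covariability exactly
  expect_equal(fitted(fit) + residuals(fit), fit$covariability,
               tolerance = 1e-12)
  # pattern table round-trips through disk
  tf <- tempfile(fileext = ".tsv")
  pat <- fit_all_pairs(expr, rownames(expr)[1:2],
                       pairs = as.matrix(fit$pairs), out_file = tf)
  back <- read_patterns(tf)
  expect_equal(back$beta_g001, pat$beta_g001, tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(dim(sims[[1]]), dim(fitted(fit)))
})

test_that("permuting samples consistently leaves betas and p-values unchanged", {
  expr <- random_expr(8, 30, seed = 12)
  mods <- rownames(expr)[1:2]
  fit <- comre(expr, mods)
  set.seed(13)
  perm <- sample(ncol(expr))
  fit2 <- comre(expr[, perm], mods)
  expect_equal(fit2$betas, fit$betas, tolerance = 1e-10)
  expect_equal(fit2$pvalues, fit$pvalues, tolerance = 1e-10)
})

test_that("rank-deficient and ill-conditioned designs are rejected by name", {
  expr <- random_expr(6, 30, seed = 14)
  expr <- rbind(expr, dup = 3 * expr["g001", ] - 1)
  expect_error(comre(expr, c("g001", "dup")),
               "collinear|ill-conditioned")
  expr2 <- rbind(expr[1:6, ], near = expr["g001", ] + rnorm(30, sd = 1e-8))
  expect_error(comre(expr2, c("g001", "near")), "ill-conditioned|collinear")
})

test_that("random-baseline mode is seeded and roughly calibrated", {
  expr <- random_expr(20, 60, seed = 15)
  fit1 <- fit_all_pairs(expr, paste0("r", 1:3), random_baseline = TRUE, seed = 99)
  fit2 <- fit_all_pairs(expr, paste0("r", 1:3), random_baseline = TRUE, seed = 99)
  expect_identical(fit1, fit2)
  expect_identical(nrow(fit1), 190L) # modulators are synthetic, all 20 genes pair up
  expect_error(comre(expr, paste0("r", 1:3), random_baseline = TRUE),
               "requires a seed")
})

test_that("null p-values are roughly uniform (rejection near alpha)", {
  expr <- generate_null(25, 100, seed = 16)
  fit <- comre(expr, rownames(expr)[1:5],
               pairs = all_pairs(rownames(expr)[6:25]),
               keep_covariability = FALSE)
  n_tests <- length(fit$pvalues)
  frac <- mean(fit$pvalues < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_tests) + 0.01)
})
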