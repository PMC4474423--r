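# Small deterministic fixtures built in code.

tiny_expr <- function() {
  matrix(c(1, 2, 3,
           4, 6, 8,
           9, 7, 5),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("gA", "gB", "gC"), c("s1", "s2", "s3")))
}

random_expr <- function(n_genes, n_samples, seed, mean = 8, sd = 1,
                        prefix = "g") {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, mean, sd), nrow = n_genes,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

# comre_calls object with given counts per modulator, for arithmetic checks
fake_calls <- function(per_modulator, total_pairs) {
  structure(list(per_modulator = per_modulator, total_pairs = total_pairs,
                 alpha = 0.05),
            class = "comre_calls")
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
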