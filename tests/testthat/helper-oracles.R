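# Independent oracles and small fixture builders shared across test files.

# Naive per-SNP loop for outgroup f3: deliberately scalar, no vectorization.
naive_f3 <- function(o, a, b) {
  tot <- 0; n <- 0L
  for (i in seq_along(o)) {
    if (!is.na(o[i]) && !is.na(a[i]) && !is.na(b[i])) {
      tot <- tot + (o[i] - a[i]) * (o[i] - b[i])
      n <- n + 1L
    }
  }
  tot / n
}

# Wald binomial 95% CI.
binom_ci <- function(phat, n) {
  hw <- 1.96 * sqrt(phat * (1 - phat) / n)
  c(phat - hw, phat + hw)
}

# Tiny panel with hand-picked alleles, chromosome 1, positions 100/200/...
tiny_panel <- function(n = 3L, ref = rep("A", n), alt = rep("G", n)) {
  snp_panel(sprintf("snp%d", seq_len(n)), rep("1", n), 100L * seq_len(n), ref, alt)
}

# Genotype table straight from a call matrix on a tiny panel.
tiny_table <- function(calls, samples = colnames(calls)) {
  calls <- as.matrix(calls)
  genotype_table(tiny_panel(nrow(calls)), calls,
                 samples %||% paste0("s", seq_len(ncol(calls))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fresh scratch directory per call (auto-cleaned with the session tempdir).
withr_tempdir <- function() {
  d <- tempfile("osteokin-test-")
  dir.create(d)
  d
}

with_seed_for_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}
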