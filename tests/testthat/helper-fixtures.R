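# Shared fixtures and independent oracles for the test suite.

# Small random panel without LD structure, optionally with missing
# entries; built directly so io/qc tests do not depend on the
# package's own simulator.
make_test_panel <- function(n, p, chromosomes = 2, seed = 1,
                            n_missing = 0) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  d <- matrix(rbinom(n * p, 2, runif(p, 0.2, 0.8)[rep(1:p, each = n)]),
              n, p)
  if (n_missing > 0) d[sample(length(d), n_missing)] <- NA
  per_chr <- diff(round(seq(0, p, length.out = chromosomes + 1)))
  map <- data.frame(
    marker_id = sprintf("t%03d", seq_len(p)),
    chromosome = rep(seq_len(chromosomes), times = per_chr),
    position = unlist(lapply(per_chr, function(k) seq_len(k) * 10L)))
  genotype_panel(d, map, samples = sprintf("s%03d", seq_len(n)))
}

# Independent OLS oracle: explicit normal equations + t distribution.
ols_oracle <- function(X, y) {
  D <- cbind(1, X)
  b <- solve(crossprod(D), crossprod(D, y))
  resid <- y - D %*% b
  df <- nrow(D) - ncol(D)
  s2 <- sum(resid^2) / df
  se <- sqrt(s2 * diag(solve(crossprod(D))))
  tt <- b / se
  p <- 2 * pt(-abs(tt), df)
  list(estimate = b[-1], t = tt[-1], p_value = p[-1])
}

# Independent HPD oracle: exhaustive search over every window of
# ceiling(prob * m) consecutive sorted draws.
hpd_oracle <- function(draws, prob) {
  s <- sort(draws)
  m <- length(s)
  k <- ceiling(prob * m)
  best <- c(-Inf, Inf)
  for (i in seq_len(m - k + 1)) {
    if (s[i + k - 1] - s[i] < best[2] - best[1])
      best <- c(s[i], s[i + k - 1])
  }
  best
}

# Evaluate expr under a local seed without disturbing the session RNG.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Cheap MCMC settings for tests that only need a functioning chain.
quick_mcmc <- function() mcmc_settings(300L, 100L, 2L)

# Write a minimal VCF 4.2 file; `records` is a character vector of
# data lines.
write_test_vcf <- function(path, records,
                           samples = c("sampleA", "sampleB")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}
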