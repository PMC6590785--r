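# Simulation framework: multi-chromosome genotype panels with local LD,
# planted QTL-effect scenarios, and phenotypes at chosen heritabilities.
#
# The additive model is y = 1*mu + X*beta + eps with eps ~ N(0, s2e) and
# heritability h2 = s2g / (s2g + s2e), where s2g is the empirical
# variance of the realized breeding values X*beta.  Solving for the
# residual variance gives s2e = s2g * (1 - h2) / h2; at h2 = 1 no
# residual is added at all.

#' Simulate a multi-chromosome genotype panel with local LD
#'
#' Markers are split as evenly as possible across chromosomes with
#' increasing integer positions.  For each sample, two haplotypes per
#' chromosome are generated by a first-order Markov chain over alleles:
#' each allele copies its left neighbour with probability `ld_rho` and
#' is otherwise drawn fresh as Bernoulli with the locus allele
#' frequency, itself drawn uniformly in `maf_range`.  Dosage is the
#' haplotype sum, so adjacent-marker dosage correlation within a
#' chromosome is approximately `ld_rho` while cross-chromosome
#' correlation is zero.  No dosages are missing.
#'
#' @param n number of samples.
#' @param p number of markers.
#' @param chromosomes number of chromosomes, default 10.
#' @param maf_range allele-frequency range (lo, hi) in (0, 1), default
#'   c(0.05, 0.5) — a post-QC chip-like frequency spectrum.
#' @param ld_rho adjacent-locus copy probability in \[0, 1), default 0.7
#'   (dense-chip local LD).
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @return a [genotype_panel] with marker IDs `chr<c>_m<j>`.
#' @export
simulate_panel <- function(n, p, chromosomes = 10,
                           maf_range = c(0.05, 0.5), ld_rho = 0.7,
                           seed = 1L) {
  if (n < 1L || p < 1L) stop_("n and p must be >= 1")
  if (chromosomes < 1L || chromosomes > p)
    stop_("chromosomes must be in [1, p]")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] >= 1 ||
      maf_range[1] > maf_range[2])
    stop_("maf_range must be (lo, hi) with 0 < lo <= hi < 1")
  if (ld_rho < 0 || ld_rho >= 1) stop_("ld_rho must be in [0, 1)")
  per_chr <- diff(round(seq(0, p, length.out = chromosomes + 1)))
  with_seed(derive_seed(seed, 1L), {
    dos <- matrix(0L, n, p)
    col0 <- 0L
    map_list <- vector("list", chromosomes)
    for (c_i in seq_len(chromosomes)) {
      pc <- per_chr[c_i]
      if (pc == 0L) next
      q <- stats::runif(pc, maf_range[1], maf_range[2])
      H <- matrix(0L, 2L * n, pc)
      H[, 1L] <- stats::rbinom(2L * n, 1L, q[1L])
      if (pc > 1L) for (l in 2L:pc) {
        fresh <- stats::rbinom(2L * n, 1L, q[l])
        copy <- stats::runif(2L * n) < ld_rho
        H[, l] <- ifelse(copy, H[, l - 1L], fresh)
      }
      dos[, (col0 + 1L):(col0 + pc)] <-
        H[seq_len(n), , drop = FALSE] +
        H[n + seq_len(n), , drop = FALSE]
      map_list[[c_i]] <- data.frame(
        marker_id = sprintf("chr%d_m%d", c_i, seq_len(pc)),
        chromosome = c_i,
        position = as.integer(seq_len(pc) * 1000L),
        stringsAsFactors = FALSE)
      col0 <- col0 + pc
    }
    map <- do.call(rbind, map_list)
    genotype_panel(dos, map,
                   samples = sprintf("id%0*d", nchar(n), seq_len(n)))
  })
}

#' Plant QTL effects on a panel under one of three scenarios
#'
#' Scenario 1: 48 non-zero effects in 4 tight clusters of 12 consecutive
#' markers on 4 distinct chromosomes, all positive (few large clustered
#' QTL).  Scenario 2: 48 effects on 8 chromosomes, 6 per chromosome
#' spaced at least 10 markers apart, all positive (large dispersed QTL).
#' Scenario 3: 250 effects spread uniformly over all chromosomes with
#' random signs and smaller magnitudes (many small QTL, the realistic
#' case).  Magnitudes are drawn uniformly in `[0.8, 1.2] * magnitude`
#' (scenarios 1-2) or `[0.1, 0.4] * magnitude` with random sign
#' (scenario 3).
#'
#' @param panel a [genotype_panel].
#' @param scenario 1, 2 or 3.
#' @param magnitude effect-size scale, default 1.
#' @param seed integer seed.
#' @return an object of class `effect_vector`: list with `beta` (length
#'   p, named by marker), `scenario`, `nonzero_index`, `seed`.
#' @export
plant_effects <- function(panel, scenario, magnitude = 1, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:3) stop_("scenario must be 1, 2 or 3")
  map <- panel$map
  p <- nrow(map)
  chrs <- unique(map$chromosome)
  need_chr <- c(4L, 8L, 1L)[scenario]
  if (length(chrs) < need_chr)
    stop_("scenario ", scenario, " needs >= ", need_chr,
          " chromosomes; panel has ", length(chrs))
  need_p <- c(48L, 48L, 250L)[scenario]
  if (p < need_p)
    stop_("scenario ", scenario, " plants ", need_p,
          " effects; panel has only ", p, " markers")
  beta <- stats::setNames(numeric(p), map$marker_id)
  with_seed(derive_seed(seed, 2L, scenario), {
    if (scenario == 1L) {
      chosen <- sample(chrs, 4L)
      idx <- integer(0)
      for (chr in chosen) {
        ci <- which(map$chromosome == chr)
        if (length(ci) < 12L)
          stop_("chromosome ", chr, " too small for a 12-marker cluster")
        start <- sample(length(ci) - 11L, 1L)
        idx <- c(idx, ci[start:(start + 11L)])
      }
      beta[idx] <- stats::runif(48L, 0.8, 1.2) * magnitude
    } else if (scenario == 2L) {
      chosen <- sample(chrs, 8L)
      idx <- integer(0)
      for (chr in chosen) {
        ci <- which(map$chromosome == chr)
        # 6 markers per chromosome, pairwise >= 10 map positions apart
        if (length(ci) < 5L * 10L + 6L)
          stop_("chromosome ", chr, " too small for 6 effects spaced >= 10")
        slots <- sort(sample(length(ci) - 50L, 6L))
        slots <- slots + (seq_len(6L) - 1L) * 10L
        idx <- c(idx, ci[slots])
      }
      beta[idx] <- stats::runif(48L, 0.8, 1.2) * magnitude
    } else {
      idx <- sort(sample(p, 250L))
      beta[idx] <- stats::runif(250L, 0.1, 0.4) * magnitude *
        sample(c(-1, 1), 250L, replace = TRUE)
    }
    structure(list(beta = beta, scenario = scenario,
                   nonzero_index = sort(unname(idx)), seed = seed),
              class = "effect_vector")
  })
}

#' @export
print.effect_vector <- function(x, ...) {
  cat("effect_vector: scenario ", x$scenario, ", ",
      length(x$nonzero_index), " non-zero effects of ",
      length(x$beta), " markers\n", sep = "")
  invisible(x)
}

#' Simulate phenotypes at a target heritability
#'
#' True breeding values are `gbv = X %*% beta`.  The additive genetic
#' variance is the empirical variance of the realized `gbv`; the
#' residual variance is solved from the heritability identity,
#' `sigma2_eps = sigma2_gbv * (1 - h2) / h2`.  Phenotypes are
#' `y = mu + gbv + eps` with i.i.d. normal residuals; at `h2 = 1` the
#' residual vector is identically zero.
#'
#' @param panel a [genotype_panel] with no missing dosages.
#' @param effects an `effect_vector` aligned to the panel (or a plain
#'   numeric vector of length p).
#' @param h2 heritability in (0, 1].
#' @param mu general mean, default 100.
#' @param seed integer seed for the residual draw.
#' @return an object of class `phenotype_set`: list with `y` (named by
#'   sample), `gbv_true`, `mu`, `h2`, `sigma2_gbv`, `sigma2_eps`,
#'   `seed`.
#' @export
simulate_phenotypes <- function(panel, effects, h2, mu = 100, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  beta <- if (inherits(effects, "effect_vector")) effects$beta else effects
  if (length(beta) != n_markers(panel))
    stop_("effects length != number of markers")
  if (h2 <= 0 || h2 > 1) stop_("h2 must be in (0, 1]")
  if (anyNA(panel$dosages)) stop_("panel has missing dosages")
  gbv <- drop(panel$dosages %*% beta)
  s2g <- stats::var(gbv)
  if (s2g == 0 && h2 < 1)
    stop_("zero genetic variance (all-zero effects?) with h2 < 1")
  s2e <- if (h2 == 1) 0 else s2g * (1 - h2) / h2
  eps <- if (h2 == 1) numeric(length(gbv)) else
    with_seed(derive_seed(seed, 3L), stats::rnorm(length(gbv), 0, sqrt(s2e)))
  y <- mu + gbv + eps
  names(y) <- names(gbv) <- rownames(panel$dosages)
  structure(list(y = y, gbv_true = gbv, mu = mu, h2 = h2,
                 sigma2_gbv = s2g, sigma2_eps = s2e, seed = seed),
            class = "phenotype_set")
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat("phenotype_set: n = ", length(x$y), ", h2 = ", x$h2,
      ", sigma2_gbv = ", signif(x$sigma2_gbv, 4),
      ", sigma2_eps = ", signif(x$sigma2_eps, 4), "\n", sep = "")
  invisible(x)
}

#' Write simulation truth tables
#'
#' Writes the per-marker effect table (`marker_id`, `beta`) and the
#' phenotype table (`sample_id`, `y`, `gbv_true`) as TSV.
#'
#' @param effects an `effect_vector`.
#' @param phen a `phenotype_set`.
#' @param effects_path,pheno_path output paths.
#' @export
write_truth <- function(effects, phen, effects_path, pheno_path) {
  utils::write.table(
    data.frame(marker_id = names(effects$beta), beta = effects$beta),
    effects_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(phen$y), y = phen$y,
               gbv_true = phen$gbv_true),
    pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
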