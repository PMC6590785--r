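# Predictive evaluation: GBV prediction, k-fold cross-validation over
# marker-count sweeps, replicated selection frequencies, correct-
# selection scoring against planted effects, and the HPD-frequency
# final-selection pipeline.

#' Predict genomic breeding values
#'
#' `GBV_hat = X_s %*% beta_hat` over the selected markers, on the raw
#' dosage scale (no intercept; any centering is the fitting step's
#' concern).
#'
#' @param panel a [genotype_panel] or dosage matrix.
#' @param selected_markers character vector of marker IDs.
#' @param beta_hat numeric effect estimates aligned to
#'   `selected_markers` (or named, in which case they are matched).
#' @return named numeric vector of predicted GBVs per sample.
#' @export
predict_gbv <- function(panel, selected_markers, beta_hat) {
  X <- if (inherits(panel, "genotype_panel")) panel$dosages else
    as.matrix(panel)
  miss <- setdiff(selected_markers, colnames(X))
  if (length(miss))
    stop_("marker(s) not in panel: ",
          paste(utils::head(miss, 5), collapse = ", "))
  if (!is.null(names(beta_hat))) beta_hat <- beta_hat[selected_markers]
  if (length(beta_hat) != length(selected_markers))
    stop_("beta_hat not aligned to selected_markers")
  drop(X[, selected_markers, drop = FALSE] %*% beta_hat)
}

#' Pearson correlation with input validation
#'
#' @param a,b numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return Pearson correlation coefficient.
#' @export
correlation <- function(a, b) {
  if (length(a) != length(b)) stop_("length mismatch")
  if (length(a) < 3L) stop_("need >= 3 observations")
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop_("zero-variance input")
  stats::cor(a, b)
}

#' Assign samples to cross-validation folds
#'
#' A seeded uniform permutation split into contiguous blocks; fold
#' sizes differ by at most one (384 samples in 8 folds gives folds of
#' exactly 48).
#'
#' @param n number of samples.
#' @param k number of folds, k <= n.
#' @param seed integer seed.
#' @return integer vector of fold indices (1..k) per sample.
#' @export
make_folds <- function(n, k = 8L, seed = 1L) {
  if (k > n) stop_("k must be <= n")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}

#' k-fold cross-validated GBV predictive ability
#'
#' For each marker count m and each fold: the fold is held out, marker
#' effects are estimated on the remaining folds with the Bayesian Lasso
#' on the top-m ranked markers, held-out GBVs are predicted, and the
#' train/test correlations of predicted GBV with phenotype (and with
#' the true GBV when available) are recorded.
#'
#' The ranking may be supplied fixed (`ranking`, computed once from all
#' data — mirrors published sweeps but lets the ranking see test
#' phenotypes) or as a selector function re-run on each training set
#' (`selector(panel, y)` returning a ranked marker vector), which is
#' leakage-free and is the recommended mode.
#'
#' @param panel a [genotype_panel].
#' @param y phenotype vector in panel sample order.
#' @param marker_counts integer vector of panel sizes m to sweep.
#' @param ranking fixed full-data marker ranking (character), best
#'   first; ignored when `selector` is given.
#' @param selector function(panel, y) -> ranked marker IDs, re-run per
#'   training set.
#' @param k number of folds, default 8.
#' @param settings [mcmc_settings()] for the per-fold effect fits.
#' @param seed integer seed (folds, fits and selector sub-seeds).
#' @param gbv_true optional true breeding values for r(GBV_hat, GBV).
#' @return object of class `cv_result`: data frame `folds` with one
#'   row per (marker_count, fold) and columns `r_train_y`, `r_test_y`,
#'   `r_train_gbv`, `r_test_gbv`, plus `means` aggregated over folds.
#' @export
kfold_cv <- function(panel, y, marker_counts, ranking = NULL,
                     selector = NULL, k = 8L,
                     settings = mcmc_settings(), seed = 1L,
                     gbv_true = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- n_samples(panel)
  if (length(y) != n) stop_("length(y) != n")
  if (is.null(ranking) && is.null(selector))
    stop_("supply a fixed ranking or a selector function")
  if (max(marker_counts) > n_markers(panel))
    stop_("marker count ", max(marker_counts), " exceeds panel size ",
          n_markers(panel))
  fold <- make_folds(n, k = k, seed = derive_seed(seed, 10L))
  rows <- vector("list", 0L)
  for (f in seq_len(k)) {
    test <- fold == f
    train_panel <- panel[!test, ]
    y_train <- y[!test]
    rank_f <- if (!is.null(selector)) selector(train_panel, y_train)
      else ranking
    for (m in marker_counts) {
      if (m > length(rank_f))
        stop_("marker count ", m, " exceeds ranking length")
      top <- rank_f[seq_len(m)]
      fit <- blasso(train_panel$dosages[, top, drop = FALSE], y_train,
                    settings = settings,
                    seed = derive_seed(seed, 20L, f, m))
      gbv_tr <- predict_gbv(train_panel, top, coef(fit))
      gbv_te <- predict_gbv(panel[test, ], top, coef(fit))
      rows[[length(rows) + 1L]] <- data.frame(
        marker_count = m, fold = f,
        r_train_y = correlation(gbv_tr, y[!test]),
        r_test_y = correlation(gbv_te, y[test]),
        r_train_gbv = if (is.null(gbv_true)) NA_real_ else
          correlation(gbv_tr, gbv_true[!test]),
        r_test_gbv = if (is.null(gbv_true)) NA_real_ else
          correlation(gbv_te, gbv_true[test]))
    }
  }
  folds <- do.call(rbind, rows)
  means <- stats::aggregate(
    folds[c("r_train_y", "r_test_y", "r_train_gbv", "r_test_gbv")],
    by = list(marker_count = folds$marker_count), FUN = mean)
  structure(list(folds = folds, means = means, k = k, seed = seed,
                 fold_assignment = fold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("k-fold CV of GBV predictive ability (k = ", x$k, "):\n", sep = "")
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Training-set correlation sweep without cross-validation
#'
#' Fits the Bayesian Lasso on the top-m ranked markers of the full data
#' for each m and reports the correlation of in-sample predicted GBVs
#' with the phenotype (and the true GBV when available).  This is the
#' no-validation sweep whose correlations grow with m as the model
#' overfits.
#'
#' @inheritParams kfold_cv
#' @return data frame with columns `marker_count`, `r_train_y`,
#'   `r_train_gbv`.
#' @export
marker_sweep <- function(panel, y, marker_counts, ranking,
                         settings = mcmc_settings(), seed = 1L,
                         gbv_true = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  rows <- lapply(marker_counts, function(m) {
    top <- ranking[seq_len(m)]
    fit <- blasso(panel$dosages[, top, drop = FALSE], y,
                  settings = settings, seed = derive_seed(seed, 30L, m))
    gbv <- predict_gbv(panel, top, coef(fit))
    data.frame(marker_count = m,
               r_train_y = correlation(gbv, y),
               r_train_gbv = if (is.null(gbv_true)) NA_real_ else
                 correlation(gbv, gbv_true))
  })
  do.call(rbind, rows)
}

#' Replicated marker-selection frequencies
#'
#' Repeats a full selection stage R times — with fresh phenotype noise
#' when an effect vector and heritability are supplied, and fresh
#' selector randomisation always — counting how often each marker is
#' selected.  Per-repetition seeds are derived from `seed` and stored.
#'
#' @param panel a [genotype_panel].
#' @param selector function(panel, y, seed) returning selected marker
#'   IDs.
#' @param R number of repetitions, default 100.
#' @param effects an `effect_vector` (with `h2`) to resimulate
#'   phenotypes each repetition; otherwise supply a fixed `y`.
#' @param h2 heritability for phenotype resimulation.
#' @param y fixed phenotype vector (used when `effects` is NULL).
#' @param mu general mean for resimulation, default 100.
#' @param seed integer master seed.
#' @return object of class `selection_frequency`: list with `counts`
#'   (named integer vector over all panel markers), `R`, `rep_seeds`.
#' @export
selection_frequency <- function(panel, selector, R = 100L,
                                effects = NULL, h2 = NULL, y = NULL,
                                mu = 100, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (R < 1L) stop_("R must be >= 1")
  if (is.null(effects) && is.null(y))
    stop_("supply effects + h2 or a fixed y")
  counts <- stats::setNames(integer(n_markers(panel)),
                            panel$map$marker_id)
  rep_seeds <- vapply(seq_len(R), function(r) derive_seed(seed, 40L, r),
                      integer(1))
  for (r in seq_len(R)) {
    y_r <- if (!is.null(effects)) {
      if (is.null(h2)) stop_("h2 required with effects")
      simulate_phenotypes(panel, effects, h2 = h2, mu = mu,
                          seed = rep_seeds[r])$y
    } else y
    sel <- selector(panel, y_r, rep_seeds[r])
    counts[sel] <- counts[sel] + 1L
  }
  structure(list(counts = counts, R = R, rep_seeds = rep_seeds,
                 seed = seed),
            class = "selection_frequency")
}

#' @export
print.selection_frequency <- function(x, ...) {
  cat("selection_frequency over R = ", x$R, " repetitions; ",
      sum(x$counts > 0L), " of ", length(x$counts),
      " markers ever selected\n", sep = "")
  invisible(x)
}

#' Score selected markers against planted effects
#'
#' A selected marker is a hit when it is itself a planted (non-zero
#' effect) marker or lies within `window` markers of one on the same
#' chromosome (marker-index distance; set `unit = "bp"` to use base
#' pairs).
#'
#' @param selected character vector of selected marker IDs.
#' @param truth an `effect_vector` (or numeric effect vector named /
#'   aligned to the map).
#' @param map marker map of the panel the selection came from.
#' @param window proximity window, default 5 (marker indices).
#' @param unit `"markers"` or `"bp"`.
#' @return list with `hits` (count), `hit_fraction`, and logical
#'   `is_hit` aligned to `selected`.
#' @export
score_correct_selection <- function(selected, truth, map, window = 5,
                                    unit = c("markers", "bp")) {
  unit <- match.arg(unit)
  if (window < 0) stop_("window must be >= 0")
  beta <- if (inherits(truth, "effect_vector")) truth$beta else truth
  if (length(beta) != nrow(map)) stop_("truth length != map rows")
  planted <- which(beta != 0)
  sel_idx <- match(selected, map$marker_id)
  if (anyNA(sel_idx)) stop_("selected marker(s) missing from map")
  chr <- map$chromosome
  # index within chromosome so marker distance respects chromosome ends
  within_idx <- stats::ave(seq_len(nrow(map)), chr, FUN = seq_along)
  pos <- if (unit == "bp") map$position else within_idx
  is_hit <- vapply(sel_idx, function(i) {
    same <- planted[chr[planted] == chr[i]]
    if (!length(same)) return(FALSE)
    any(abs(pos[same] - pos[i]) <= window)
  }, logical(1))
  list(hits = sum(is_hit),
       hit_fraction = mean(is_hit),
       is_hit = stats::setNames(is_hit, selected))
}

#' Tournament + HPD final-selection pipeline
#'
#' Replicated final selection: (1) screen to `target` markers by a
#' random-group tournament; (2) fit the Bayesian Lasso to the
#' survivors; (3) keep markers whose HPD interval excludes zero;
#' (4) repeat R times and tabulate selection frequencies; (5) markers
#' selected in at least `freq_min` repetitions form the final set.
#'
#' @param panel a [genotype_panel].
#' @param y phenotype vector.
#' @param R repetitions, default 100.
#' @param target tournament survivor count, default 100.
#' @param prob HPD probability, default 0.95.
#' @param freq_min minimum selection count for the final set; default
#'   18 (the worked real-data threshold for R = 100).
#' @param pg tournament group size, default 25.
#' @param settings [mcmc_settings()] for the per-repetition fits.
#' @param seed integer master seed.
#' @return list with `final` (marker IDs), `frequency` (named counts
#'   over markers ever selected), `R`, `freq_min`, `rep_seeds`.
#' @export
hpd_frequency_pipeline <- function(panel, y, R = 100L, target = 100L,
                                   prob = 0.95, freq_min = 18L, pg = 25L,
                                   settings = mcmc_settings(),
                                   seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  selector <- function(p, y_r, s) {
    tour <- tournament(p, y_r, target = target, pg = pg, mode = "random",
                       seed = s)
    fit <- blasso(p$dosages[, tour$survivors, drop = FALSE], y_r,
                  settings = settings, seed = derive_seed(s, 50L))
    select_by_hpd(fit, prob = prob)
  }
  freq <- selection_frequency(panel, selector, R = R, y = y, seed = seed)
  counts <- freq$counts[freq$counts > 0L]
  final <- names(counts)[counts >= freq_min]
  list(final = final, frequency = sort(counts, decreasing = TRUE),
       R = R, freq_min = freq_min, rep_seeds = freq$rep_seeds)
}
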