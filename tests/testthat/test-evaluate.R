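# GBV prediction, cross-validation, selection frequency, correctness
# scoring and the HPD-frequency pipeline.

test_that("predict_gbv is the plain dosage-effect product", {
  pan <- make_test_panel(10, 6, seed = 71)
  ids <- pan$map$marker_id
  expect_equal(unname(predict_gbv(pan, ids, rep(0, 6))), rep(0, 10))
  one <- predict_gbv(pan, ids[3], 1)
  expect_equal(unname(one), unname(pan$dosages[, 3]))
  expect_error(predict_gbv(pan, "nope", 1), "not in panel")
  # noiseless recovery: fitting the true markers reproduces the GBVs
  pan2 <- simulate_panel(150, 60, chromosomes = 2, seed = 71)
  beta <- numeric(60); beta[c(10, 30, 50)] <- c(1, -1, 0.5)
  ph <- simulate_phenotypes(pan2, beta, h2 = 1, seed = 71)
  true_ids <- pan2$map$marker_id[beta != 0]
  fit <- blasso(pan2$dosages[, true_ids], ph$y, quick_mcmc(), seed = 1)
  r <- correlation(predict_gbv(pan2, true_ids, coef(fit)), ph$gbv_true)
  expect_gt(r, 0.95)
})

test_that("correlation matches direct arithmetic and validates input", {
  a <- c(1, 3, 2, 5, 4); b <- c(2, 1, 4, 7, 6)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlation(a, b), num / den, tolerance = 1e-12)
  expect_equal(correlation(a, a), 1)
  expect_equal(correlation(a, -a), -1)
  expect_error(correlation(a, b[1:4]), "length")
  expect_error(correlation(rep(1, 5), b), "zero-variance")
})

test_that("folds partition samples with near-equal sizes", {
  f <- make_folds(384, 8, seed = 1)
  expect_equal(as.integer(table(f)), rep(48L, 8))
  f2 <- make_folds(103, 8, seed = 2)
  expect_equal(length(f2), 103L)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(make_folds(5, 8), "k must be <=")
  expect_false(identical(make_folds(103, 8, seed = 2),
                         make_folds(103, 8, seed = 3)))
})

test_that("cross-validation never lets test phenotypes touch training", {
  pan <- simulate_panel(60, 30, chromosomes = 2, seed = 72)
  beta <- numeric(30); beta[c(4, 22)] <- 1
  ph <- simulate_phenotypes(pan, beta, h2 = 0.5, seed = 72)
  rank_ids <- pan$map$marker_id
  cv1 <- kfold_cv(pan, ph$y, marker_counts = 8, ranking = rank_ids,
                  k = 2, settings = quick_mcmc(), seed = 9,
                  gbv_true = ph$gbv_true)
  # perturb phenotypes of fold-1 test samples only; fold 1's own
  # training rows (and its fitted effects) must be unchanged
  y2 <- ph$y
  y2[cv1$fold_assignment == 1L] <- y2[cv1$fold_assignment == 1L] + 50
  cv2 <- kfold_cv(pan, y2, marker_counts = 8, ranking = rank_ids,
                  k = 2, settings = quick_mcmc(), seed = 9,
                  gbv_true = ph$gbv_true)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  r1 <- cv1$folds[cv1$folds$fold == 1, ]
  r2 <- cv2$folds[cv2$folds$fold == 1, ]
  expect_identical(r1$r_train_y, r2$r_train_y)
  expect_identical(r1$r_train_gbv, r2$r_train_gbv)
  expect_false(identical(r1$r_test_y, r2$r_test_y))
})

test_that("shuffled phenotypes give near-zero test correlations", {
  pan <- simulate_panel(96, 40, chromosomes = 2, seed = 73)
  beta <- numeric(40); beta[c(7, 31)] <- 1
  ph <- simulate_phenotypes(pan, beta, h2 = 0.5, seed = 73)
  rank_ids <- pan$map$marker_id
  rs <- vapply(1:5, function(s) {
    y_shuf <- with_seed_test(s, sample(ph$y))
    cv <- kfold_cv(pan, y_shuf, marker_counts = 10, ranking = rank_ids,
                   k = 4, settings = quick_mcmc(), seed = s)
    mean(cv$folds$r_test_y)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("selector functions re-rank inside each training fold", {
  pan <- simulate_panel(40, 20, chromosomes = 2, seed = 74)
  beta <- numeric(20); beta[5] <- 2
  ph <- simulate_phenotypes(pan, beta, h2 = 0.5, seed = 74)
  seen_n <- integer(0)
  sel <- function(p, y_tr) {
    seen_n <<- c(seen_n, n_samples(p))
    ranking(tournament(p, y_tr, target = 5, pg = 5, seed = 1))
  }
  cv <- kfold_cv(pan, ph$y, marker_counts = 5, selector = sel, k = 2,
                 settings = quick_mcmc(), seed = 4)
  expect_equal(seen_n, c(20L, 20L))  # selector saw training halves only
  expect_equal(nrow(cv$folds), 2L)
})

test_that("selection frequency counts are reproducible and bounded", {
  pan <- simulate_panel(50, 30, chromosomes = 2, seed = 75)
  beta <- numeric(30); beta[c(3, 17)] <- 1.5
  eff <- structure(list(beta = setNames(beta, pan$map$marker_id),
                        scenario = 0L, nonzero_index = c(3L, 17L)),
                   class = "effect_vector")
  selector <- function(p, y, s)
    tournament(p, y, target = 6, pg = 6, seed = s)$survivors
  one <- selection_frequency(pan, selector, R = 1, effects = eff,
                             h2 = 0.5, seed = 5)
  expect_true(all(one$counts %in% 0:1))
  expect_equal(sum(one$counts), 6L)

  # deterministic selector on frozen phenotypes: counts all-or-nothing
  set.seed(75); y_fix <- rnorm(50)
  det <- function(p, y, s) p$map$marker_id[1:4]
  frozen <- selection_frequency(pan, det, R = 10, y = y_fix, seed = 5)
  expect_true(all(frozen$counts %in% c(0L, 10L)))
  expect_equal(sum(frozen$counts == 10L), 4L)

  # same master seed reproduces the counts
  again <- selection_frequency(pan, selector, R = 3, effects = eff,
                               h2 = 0.5, seed = 5)
  again2 <- selection_frequency(pan, selector, R = 3, effects = eff,
                                h2 = 0.5, seed = 5)
  expect_identical(again$counts, again2$counts)
  expect_equal(length(again$rep_seeds), 3L)
})

test_that("correct-selection scoring matches an all-pairs oracle", {
  pan <- make_test_panel(5, 40, chromosomes = 4, seed = 76)
  beta <- numeric(40); beta[c(8, 23, 36)] <- 1
  map <- pan$map
  sel_all <- map$marker_id
  for (w in c(0, 2, 5)) {
    got <- score_correct_selection(sel_all, beta, map, window = w)
    # oracle: brute-force all-pairs within-chromosome index distance
    wi <- ave(seq_len(40), map$chromosome, FUN = seq_along)
    oracle <- vapply(seq_len(40), function(i) {
      any(beta != 0 & map$chromosome == map$chromosome[i] &
            abs(wi - wi[i]) <= w)
    }, logical(1))
    expect_equal(unname(got$is_hit), oracle)
  }
  # exact planted selection scores 1.0
  exact <- score_correct_selection(map$marker_id[beta != 0], beta, map)
  expect_equal(exact$hit_fraction, 1.0)
  # window rule: 3 indices away hits at window 5, misses at window 2
  three_away <- map$marker_id[26]  # same chromosome as marker 23
  expect_equal(score_correct_selection(three_away, beta, map,
                                       window = 5)$hits, 1L)
  expect_equal(score_correct_selection(three_away, beta, map,
                                       window = 2)$hits, 0L)
  expect_error(score_correct_selection(sel_all, beta, map, window = -1),
               "window")
})

test_that("the HPD-frequency pipeline filters tournament survivors", {
  pan <- simulate_panel(60, 40, chromosomes = 2, seed = 77)
  beta <- numeric(40); beta[c(6, 28)] <- 2
  ph <- simulate_phenotypes(pan, beta, h2 = 0.5, seed = 77)
  one <- hpd_frequency_pipeline(pan, ph$y, R = 1, target = 10, pg = 8,
                                settings = quick_mcmc(), freq_min = 1,
                                seed = 3)
  tour <- tournament(pan, ph$y, target = 10, pg = 8, mode = "random",
                     seed = one$rep_seeds[1])
  expect_true(all(one$final %in% tour$survivors))

  # an impossible threshold empties the final set
  none <- hpd_frequency_pipeline(pan, ph$y, R = 2, target = 10, pg = 8,
                                 settings = quick_mcmc(), freq_min = 3,
                                 seed = 3)
  expect_equal(length(none$final), 0L)
  expect_true(all(none$frequency <= 2))
})

test_that("training-set sweep runs over marker counts", {
  pan <- simulate_panel(50, 30, chromosomes = 2, seed = 78)
  beta <- numeric(30); beta[c(3, 17)] <- 1
  ph <- simulate_phenotypes(pan, beta, h2 = 0.5, seed = 78)
  tour <- tournament(pan, ph$y, target = 5, pg = 6, seed = 1)
  sw <- marker_sweep(pan, ph$y, c(5, 15, 30), ranking(tour),
                     settings = quick_mcmc(), seed = 2,
                     gbv_true = ph$gbv_true)
  expect_equal(sw$marker_count, c(5, 15, 30))
  expect_true(all(sw$r_train_y > -1 & sw$r_train_y < 1))
})
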