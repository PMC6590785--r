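# Tournament screening: grouping, per-group regression, elimination,
# full runs, ranking.

test_that("random groups have near-equal sizes and partition the input", {
  ids <- sprintf("m%03d", 1:100)
  g <- make_groups(ids, pg = 25, mode = "random", seed = 1)
  expect_equal(length(g), 4L)
  expect_equal(unname(lengths(g)), rep(25L, 4))
  expect_setequal(unlist(g), ids)

  ids103 <- sprintf("m%03d", 1:103)
  g103 <- make_groups(ids103, pg = 25, mode = "random", seed = 2)
  expect_equal(sort(unname(lengths(g103)), decreasing = TRUE),
               c(26L, 26L, 26L, 25L))
  expect_setequal(unlist(g103), ids103)
  expect_error(make_groups(ids, pg = 1), "pg must be >= 2")
})

test_that("chromosome-conditioned groups follow proportional allocation", {
  map <- data.frame(
    marker_id = c(sprintf("a%02d", 1:75), sprintf("b%02d", 1:25)),
    chromosome = rep(c("A", "B"), c(75, 25)),
    position = c(1:75, 1:25) * 10L)
  g <- make_groups(map$marker_id, map = map, pg = 25,
                   mode = "chromosome_conditioned", seed = 3)
  expect_equal(length(g), 4L)
  expect_equal(unname(lengths(g)), rep(25L, 4))
  expect_setequal(unlist(g), map$marker_id)
  from_a <- vapply(g, function(x) sum(startsWith(x, "a")), integer(1))
  # largest-remainder oracle: 25 * 75/100 = 18.75 per group
  expect_true(all(from_a %in% 18:19))
  expect_equal(sum(from_a), 75L)
})

test_that("group regression separates signal from noise", {
  set.seed(41)
  X <- matrix(as.double(rbinom(50 * 2, 2, 0.5)), 50, 2,
              dimnames = list(NULL, c("x1", "x2")))
  y <- 2 * X[, "x1"] + rnorm(50, 0, 0.1)
  gr <- group_regression(X, y)
  expect_lt(gr$p_value[1], 1e-10)
  expect_gt(gr$p_value[2] / gr$p_value[1], 1e6)
  expect_error(group_regression(X, rep(1, 50)), "zero-variance")
})

test_that("a duplicated column is flagged non-estimable, once", {
  set.seed(42)
  X <- matrix(as.double(rbinom(60 * 5, 2, 0.4)), 60, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  X[, 4] <- X[, 2]
  y <- rnorm(60)
  gr <- group_regression(X, y)
  expect_equal(sum(!gr$estimable), 1L)
  expect_false(gr$estimable[4])   # the later column of the pair
  expect_true(gr$estimable[2])
  expect_true(is.na(gr$p_value[4]))
})

test_that("estimates and p-values match the brute-force OLS oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(as.double(rbinom(60 * 5, 2, runif(1, 0.2, 0.6))), 60, 5,
                dimnames = list(NULL, paste0("m", 1:5)))
    beta <- rnorm(5, 0, 0.5)
    y <- drop(X %*% beta) + rnorm(60)
    gr <- group_regression(X, y)
    or <- ols_oracle(X, y)
    expect_equal(gr$estimate, unname(or$estimate), tolerance = 1e-8)
    expect_equal(gr$p_value, unname(or$p_value), tolerance = 1e-8)
  }
})

test_that("eliminate_worst applies the max-p rule and tie-breaks", {
  res <- data.frame(marker_id = c("a", "b", "c"),
                    estimate = c(1, 2, 0.1), t = c(2.5, 2.1, 0.13),
                    p_value = c(0.01, 0.04, 0.90),
                    estimable = TRUE, stringsAsFactors = FALSE)
  expect_equal(eliminate_worst(res)$marker_id, "c")
  expect_equal(eliminate_worst(res)$reason, "worst_pvalue")

  # exact tie on p: smaller |t| loses; then lexicographic id
  tie <- data.frame(marker_id = c("b", "a"), estimate = 1,
                    t = c(1.0, -1.0), p_value = c(0.5, 0.5),
                    estimable = TRUE, stringsAsFactors = FALSE)
  expect_equal(eliminate_worst(tie)$marker_id, "a")

  # non-estimable markers take priority, seeded-random choice
  col <- data.frame(marker_id = c("a", "b", "c"), estimate = NA,
                    t = NA, p_value = c(0.2, NA, NA),
                    estimable = c(TRUE, FALSE, FALSE),
                    stringsAsFactors = FALSE)
  pick1 <- eliminate_worst(col, seed = 99)
  pick2 <- eliminate_worst(col, seed = 99)
  expect_equal(pick1$reason, "collinear_random")
  expect_true(pick1$marker_id %in% c("b", "c"))
  expect_identical(pick1$marker_id, pick2$marker_id)
})

test_that("eliminate_worst agrees with a brute-force re-fit oracle on
           100 random instances", {
  for (inst in 1:100) {
    set.seed(1000 + inst)
    g <- sample(3:8, 1)
    X <- matrix(as.double(rbinom(40 * g, 2, runif(1, 0.25, 0.6))), 40, g,
                dimnames = list(NULL, sprintf("m%02d", seq_len(g))))
    y <- drop(X %*% rnorm(g, 0, 0.4)) + rnorm(40)
    got <- eliminate_worst(group_regression(X, y))$marker_id
    # oracle: independent normal-equations fit, pick the max p-value
    or <- ols_oracle(X, y)
    expect_equal(got, colnames(X)[which.max(or$p_value)])
  }
})

test_that("smallest tournament runs one stage with one elimination", {
  pan <- make_test_panel(40, 26, chromosomes = 2, seed = 51)
  set.seed(51)
  y <- rnorm(40)
  tour <- tournament(pan, y, target = 25, pg = 25, seed = 1)
  expect_equal(length(tour$survivors), 25L)
  expect_equal(length(tour$elimination_order), 1L)
  expect_equal(nrow(tour$stage_log), 1L)
  expect_equal(tour$stage_log$K, 1L)
})

test_that("tournaments conserve markers and hit the target exactly", {
  pan <- make_test_panel(50, 83, chromosomes = 3, seed = 52)
  set.seed(52)
  y <- drop(pan$dosages %*% rnorm(83, 0, 0.2)) + rnorm(50)
  for (mode in c("random", "chromosome_conditioned")) {
    tour <- tournament(pan, y, target = 17, pg = 10, mode = mode,
                       seed = 7)
    expect_equal(length(tour$survivors), 17L)
    expect_setequal(c(tour$survivors, tour$elimination_order),
                    pan$map$marker_id)
    expect_equal(length(tour$survivors) + length(tour$elimination_order),
                 83L)
    # stage-boundary conservation from the log
    expect_equal(tour$stage_log$markers_in[1], 83L)
    expect_equal(tail(tour$stage_log$markers_out, 1), 17L)
    expect_true(all(diff(tour$stage_log$markers_in) < 0))
    expect_equal(tour$stage_log$markers_in[-1],
                 head(tour$stage_log$markers_out, -1))
  }
})

test_that("the final stage trims by worst p-value instead of overshooting", {
  pan <- make_test_panel(60, 100, chromosomes = 2, seed = 53)
  set.seed(53)
  y <- rnorm(60)
  # 100 markers, pg 10 -> 10 groups/stage; target 95 forces a 5-marker
  # trim in stage 1
  tour <- tournament(pan, y, target = 95, pg = 10, seed = 3)
  expect_equal(length(tour$survivors), 95L)
  expect_equal(nrow(tour$stage_log), 1L)
  expect_equal(tour$stage_log$n_overshoot_trim, 5L)
})

test_that("identical seeds give identical tournaments", {
  pan <- make_test_panel(45, 60, chromosomes = 3, seed = 54)
  set.seed(54)
  y <- rnorm(45)
  t1 <- tournament(pan, y, target = 12, pg = 9, seed = 101)
  t2 <- tournament(pan, y, target = 12, pg = 9, seed = 101)
  expect_identical(t1$survivors, t2$survivors)
  expect_identical(t1$elimination_order, t2$elimination_order)
  t3 <- tournament(pan, y, target = 12, pg = 9, seed = 102)
  expect_false(identical(t1$survivors, t3$survivors))
})

test_that("ranking lists survivors then reversed eliminations", {
  fake <- structure(list(survivors = c("A", "B"),
                         elimination_order = c("C", "D")),
                    class = "tournament")
  expect_equal(ranking(fake), c("A", "B", "D", "C"))

  pan <- make_test_panel(40, 30, chromosomes = 2, seed = 55)
  set.seed(55)
  y <- rnorm(40)
  tour <- tournament(pan, y, target = 29, pg = 29, seed = 1)
  expect_equal(ranking(tour),
               c(tour$survivors, tour$elimination_order))
  expect_setequal(ranking(tour), pan$map$marker_id)
})

test_that("top-m of a deeper ranking extends the survivor set", {
  pan <- make_test_panel(50, 80, chromosomes = 2, seed = 56)
  set.seed(56)
  y <- drop(pan$dosages %*% rnorm(80, 0, 0.3)) + rnorm(50)
  tour <- tournament(pan, y, target = 10, pg = 10, seed = 5)
  r <- ranking(tour)
  expect_equal(r[1:10], tour$survivors)
  # the top-30 extension contains every survivor plus the 20
  # last-eliminated markers, without re-running the tournament
  expect_setequal(r[11:30], rev(tour$elimination_order)[1:20])
})

test_that("screening beats random selection when signal is strong", {
  pan <- simulate_panel(120, 400, chromosomes = 4, seed = 57)
  beta <- numeric(400)
  set.seed(57)
  planted <- sample(400, 12)
  beta[planted] <- 1.5
  ph <- simulate_phenotypes(pan, beta, h2 = 1, seed = 57)
  tour <- tournament(pan, ph$y, target = 40, pg = 20, seed = 57)
  hits <- sum(tour$survivors %in% pan$map$marker_id[planted])
  # uniform selection of 40 of 400 would recover 12 * 40/400 = 1.2
  expect_gt(hits, 6)
})

test_that("tournament rejects invalid configurations", {
  pan <- make_test_panel(20, 30, seed = 58)
  set.seed(58)
  y <- rnorm(20)
  expect_error(tournament(pan, y, target = 30, pg = 5), "target")
  expect_error(tournament(pan, y, target = 5, pg = 25), "pg must be <")
  pan$dosages[1, 1] <- NA
  expect_error(tournament(pan, y, target = 5, pg = 5), "missing dosages")
})
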