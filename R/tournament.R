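# Tournament screening: the core marker-selection procedure.
#
# At every stage the current markers are partitioned into groups of
# approximately `pg` markers, each group is fitted by multiple linear
# regression of the phenotype on its dosage columns, and the worst
# marker of each group (largest coefficient p-value; under perfect
# collinearity a random non-estimable marker) is eliminated.  Survivors
# are pooled and regrouped until the target panel size remains.  The
# elimination sequence gives a genome-wide marker score: survivors
# first, then markers in reverse order of elimination.

#' Partition markers into tournament groups
#'
#' Groups have sizes as equal as possible (differing by at most one);
#' the group count is `K = max(1, round(length(marker_ids) / pg))`.
#' Random mode partitions markers uniformly.  Chromosome-conditioned
#' mode fills each group from the chromosomes proportionally to their
#' current marker counts (largest-remainder allocation, markers drawn
#' without replacement within chromosome), so every group sees almost
#' every chromosome.
#'
#' @param marker_ids character vector of marker IDs (>= 2).
#' @param map marker map (`marker_id`, `chromosome`, `position`);
#'   required for chromosome-conditioned mode.
#' @param pg nominal group size, >= 2.
#' @param mode `"random"` or `"chromosome_conditioned"`.
#' @param seed integer seed.
#' @return list of disjoint character vectors whose union is
#'   `marker_ids`.
#' @export
make_groups <- function(marker_ids, map = NULL, pg = 25L,
                        mode = c("random", "chromosome_conditioned"),
                        seed = 1L) {
  mode <- match.arg(mode)
  p <- length(marker_ids)
  if (p < 2L) stop_("need >= 2 markers to form groups")
  if (pg < 2L) stop_("pg must be >= 2")
  K <- max(1L, as.integer(round(p / pg)))
  sizes <- rep(p %/% K, K)
  extra <- p %% K
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  with_seed(seed, {
    if (mode == "random") {
      perm <- sample(marker_ids)
      split(perm, rep(seq_len(K), times = sizes))
    } else {
      if (is.null(map)) stop_("chromosome-conditioned grouping needs a map")
      chr <- map$chromosome[match(marker_ids, map$marker_id)]
      if (anyNA(chr)) stop_("marker(s) missing from map")
      pools <- split(marker_ids, chr)
      pools <- lapply(pools, function(x) sample(x))
      groups <- rep(list(character(0)), K)
      remaining_cap <- sizes
      for (ci in seq_along(pools)) {
        m_c <- length(pools[[ci]])
        tot <- sum(remaining_cap)
        quota <- remaining_cap * m_c / tot
        base <- pmin(floor(quota), remaining_cap)
        short <- m_c - sum(base)
        if (short > 0L) {
          frac <- quota - floor(quota)
          frac[remaining_cap - base <= 0L] <- -1
          ord <- order(-frac, seq_len(K))
          gi <- 0L
          while (short > 0L) {
            gi <- gi + 1L
            if (gi > K) { # capacity-capped; refill by index order
              gi <- which(remaining_cap - base > 0L)[1L]
              base[gi] <- base[gi] + 1L
              short <- short - 1L
              gi <- 0L
              next
            }
            g <- ord[gi]
            if (remaining_cap[g] - base[g] > 0L) {
              base[g] <- base[g] + 1L
              short <- short - 1L
            }
          }
        }
        offset <- 0L
        for (g in seq_len(K)) {
          if (base[g] > 0L) {
            groups[[g]] <- c(groups[[g]],
                             pools[[ci]][(offset + 1L):(offset + base[g])])
            offset <- offset + base[g]
          }
        }
        remaining_cap <- remaining_cap - base
      }
      groups
    }
  })
}

#' Per-group multiple linear regression
#'
#' Ordinary least squares of `y` on the group's dosage columns with an
#' intercept; returns each marker's estimate, t statistic and two-sided
#' p-value.  Columns lying in the span of the preceding columns (rank
#' deficiency at `collinearity_tol` relative to the design's largest
#' singular value) are flagged non-estimable and carry no p-value.
#'
#' @param X n x g dosage submatrix (columns named by marker).
#' @param y numeric response, length n, non-constant.
#' @param collinearity_tol relative rank tolerance, default 1e-10.
#' @return data frame with columns `marker_id`, `estimate`, `t`,
#'   `p_value`, `estimable`; attribute `"df"` holds the residual
#'   degrees of freedom.
#' @export
group_regression <- function(X, y, collinearity_tol = 1e-10) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_("nrow(X) != length(y)")
  if (stats::var(y) == 0) stop_("zero-variance response")
  if (anyNA(X) || anyNA(y)) stop_("missing values in regression inputs")
  fit <- .ols_group(X, y, collinearity_tol)
  out <- data.frame(
    marker_id = colnames(X) %||% paste0("m", seq_len(ncol(X))),
    estimate = fit$estimate, t = fit$t, p_value = fit$p_value,
    estimable = fit$estimable, stringsAsFactors = FALSE)
  attr(out, "df") <- fit$df
  out
}

#' Pick the marker a group eliminates
#'
#' If any marker in the group is non-estimable (perfectly collinear
#' with preceding columns), one of those is eliminated uniformly at
#' random under the supplied seed.  Otherwise the marker with the
#' largest p-value is eliminated; exact p-value ties break toward the
#' smaller |t|, then the lexicographically smaller marker ID.
#'
#' @param group_result data frame from [group_regression()].
#' @param seed integer seed for the random collinear choice.
#' @return list with `marker_id` (the eliminated marker) and `reason`
#'   (`"collinear_random"` or `"worst_pvalue"`).
#' @export
eliminate_worst <- function(group_result, seed = 1L) {
  stopifnot(nrow(group_result) >= 1L)
  worst_of_group(group_result$marker_id, group_result$p_value,
                 group_result$t, group_result$estimable, seed)
}

# vector-level core of eliminate_worst, shared with the tournament loop
worst_of_group <- function(ids, p, t, estimable, seed) {
  non_est <- which(!estimable)
  if (length(non_est)) {
    pick <- if (length(non_est) == 1L) non_est else
      with_seed(seed, sample(non_est, 1L))
    return(list(marker_id = ids[pick], reason = "collinear_random",
                p_value = NA_real_))
  }
  tt <- abs(t)
  tt[is.na(tt)] <- 0
  ord <- order(-p, tt, ids)
  list(marker_id = ids[ord[1L]], reason = "worst_pvalue",
       p_value = p[ord[1L]])
}

#' Tournament screening of a marker panel
#'
#' Runs elimination stages until exactly `target` markers survive.
#' Each stage forms fresh groups ([make_groups()]), fits each group
#' ([group_regression()]) and eliminates one marker per group
#' ([eliminate_worst()]).  When a full stage would overshoot the
#' target, the stage's would-be eliminations are ranked worst first
#' (non-estimable markers ahead of the largest p-values) and only the
#' markers in excess of the target are removed (reason
#' `overshoot_trim`), so the survivor count is exact.
#'
#' Group analyses within a stage are pure functions of the group data
#' and a seed derived from (master seed, stage, group index), and
#' results are combined in group-index order, so the outcome is
#' identical under any parallel execution schedule.
#'
#' @param panel a [genotype_panel] with no missing dosages (run QC
#'   first), or a plain dosage matrix.
#' @param y numeric phenotype vector, length n.
#' @param target number of surviving markers (< p), default 100.
#' @param pg nominal group size (>= 2, < n), default 25.
#' @param mode group formation: `"random"` (default) or
#'   `"chromosome_conditioned"`.
#' @param seed master integer seed.
#' @param collinearity_tol rank tolerance for [group_regression()].
#' @param max_stages stage guard against non-termination.
#' @return object of class `tournament`: list with `survivors`
#'   (marker IDs, best first by final-stage p-value),
#'   `elimination_order` (first eliminated first), `stage_log` (data
#'   frame: stage, K, markers_in, markers_out, n_worst_pvalue,
#'   n_collinear_random, n_overshoot_trim), `target`, `pg`, `mode`,
#'   `seed`.
#' @examples
#' pan <- simulate_panel(n = 60, p = 40, chromosomes = 2, seed = 2)
#' beta <- numeric(40); beta[c(5, 25)] <- 1
#' phe <- simulate_phenotypes(pan, beta, h2 = 0.5, seed = 2)
#' tour <- tournament(pan, phe$y, target = 10, pg = 8, seed = 3)
#' tour
#' head(ranking(tour))
#' @export
tournament <- function(panel, y, target = 100L, pg = 25L,
                       mode = c("random", "chromosome_conditioned"),
                       seed = 1L, collinearity_tol = 1e-10,
                       max_stages = 10000L) {
  mode <- match.arg(mode)
  if (inherits(panel, "genotype_panel")) {
    X <- panel$dosages
    map <- panel$map
  } else {
    X <- as.matrix(panel)
    if (is.null(colnames(X))) colnames(X) <- paste0("m", seq_len(ncol(X)))
    map <- data.frame(marker_id = colnames(X), chromosome = 1L,
                      position = seq_len(ncol(X)), stringsAsFactors = FALSE)
  }
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_("length(y) != number of samples")
  if (anyNA(X)) stop_("panel has missing dosages; run QC first")
  if (anyNA(y)) stop_("missing phenotypes")
  if (stats::var(y) == 0) stop_("zero-variance response")
  if (pg < 2L) stop_("pg must be >= 2")
  if (pg >= n) stop_("pg must be < n so each group is solvable")
  if (target < 1L || target >= p)
    stop_("target must be in [1, p); got ", target, " with p = ", p)

  cn <- colnames(X)
  alive_idx <- seq_len(p)
  elim_ids <- character(p - target)
  elim_reasons <- character(p - target)
  n_elim <- 0L
  last_p <- rep(NA_real_, p)
  log_rows <- vector("list", 0L)
  stage <- 0L
  while (length(alive_idx) > target) {
    stage <- stage + 1L
    if (stage > max_stages) stop_("max_stages exceeded")
    p_t <- length(alive_idx)
    groups <- make_groups(cn[alive_idx], map = map, pg = pg, mode = mode,
                          seed = derive_seed(seed, stage))
    K <- length(groups)
    idx_list <- split(match(unlist(groups), cn),
                      rep(seq_len(K), lengths(groups)))
    fits <- .ols_batch(X, y, idx_list, collinearity_tol)
    cand <- vector("list", K)
    for (k in seq_len(K)) {
      fit <- fits[[k]]
      pv <- fit$p_value
      est <- fit$estimable
      pv_store <- pv
      pv_store[!est] <- Inf
      last_p[idx_list[[k]]] <- pv_store
      cand[[k]] <- worst_of_group(groups[[k]], pv, fit$t, est,
                                  derive_seed(seed, stage, k))
    }
    cand_ids <- vapply(cand, `[[`, "", "marker_id")
    cand_reasons <- vapply(cand, `[[`, "", "reason")
    cand_p <- vapply(cand, function(x) x$p_value %||% NA_real_, 0)
    overshoot <- (p_t - K) < target
    if (overshoot) {
      n_drop <- p_t - target
      # worst first: non-estimable (no p-value) ahead of largest p
      key <- ifelse(cand_reasons == "collinear_random", 2, cand_p)
      ord <- order(-key, cand_ids)
      sel <- ord[seq_len(n_drop)]
      cand_ids <- cand_ids[sel]
      cand_reasons <- rep("overshoot_trim", n_drop)
    }
    m <- length(cand_ids)
    elim_ids[n_elim + seq_len(m)] <- cand_ids
    elim_reasons[n_elim + seq_len(m)] <- cand_reasons
    n_elim <- n_elim + m
    alive_idx <- setdiff(alive_idx, match(cand_ids, cn))
    log_rows[[stage]] <- data.frame(
      stage = stage, K = K, markers_in = p_t,
      markers_out = length(alive_idx),
      n_worst_pvalue = sum(cand_reasons == "worst_pvalue"),
      n_collinear_random = sum(cand_reasons == "collinear_random"),
      n_overshoot_trim = sum(cand_reasons == "overshoot_trim"))
  }
  alive <- cn[alive_idx]
  surv_p <- last_p[alive_idx]
  survivors <- alive[order(surv_p, alive)]
  structure(list(survivors = survivors,
                 elimination_order = elim_ids,
                 elimination_reasons = elim_reasons,
                 stage_log = do.call(rbind, log_rows),
                 target = as.integer(target), pg = as.integer(pg),
                 mode = mode, seed = seed),
            class = "tournament")
}

#' @export
print.tournament <- function(x, ...) {
  cat("tournament screening (", x$mode, " groups, pg = ", x$pg, "):\n",
      sep = "")
  cat("  ", length(x$survivors) + length(x$elimination_order),
      " markers -> ", length(x$survivors), " survivors in ",
      nrow(x$stage_log), " stages\n", sep = "")
  invisible(x)
}

#' @export
summary.tournament <- function(object, ...) {
  log <- object$stage_log
  cat("tournament screening summary\n")
  cat("  mode: ", object$mode, ", pg = ", object$pg,
      ", seed = ", object$seed, "\n", sep = "")
  cat("  stages: ", nrow(log), ", eliminations: ",
      length(object$elimination_order), " (",
      sum(log$n_collinear_random), " collinear, ",
      sum(log$n_overshoot_trim), " overshoot-trimmed)\n", sep = "")
  cat("  survivors: ", length(object$survivors), "\n", sep = "")
  invisible(object)
}

#' Marker ranking implied by a tournament
#'
#' Best markers first: the survivors (ordered by ascending final-stage
#' p-value), followed by the eliminated markers from last-eliminated to
#' first-eliminated.  Taking the top m of this ranking extends a
#' finished tournament to any marker count m >= target without
#' re-running it.
#'
#' @param result a `tournament` object.
#' @return character vector over all input markers, best first.
#' @export
ranking <- function(result) {
  stopifnot(inherits(result, "tournament"))
  c(result$survivors, rev(result$elimination_order))
}

#' Write tournament outputs
#'
#' Writes `survivors.txt` (one marker per line), `ranking.txt` and
#' `stage_log.tsv` into `dir`.
#'
#' @param result a `tournament` object.
#' @param dir output directory (created if needed).
#' @export
write_tournament <- function(result, dir) {
  stopifnot(inherits(result, "tournament"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(result$survivors, file.path(dir, "survivors.txt"))
  writeLines(ranking(result), file.path(dir, "ranking.txt"))
  utils::write.table(result$stage_log, file.path(dir, "stage_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(result)
}
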