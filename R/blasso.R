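# Bayesian Lasso (Park-Casella hierarchical Gibbs sampler).
#
# Used two ways: as the comparison selector (top-|posterior mean| from a
# model with all markers) and as the effect estimator / final selector
# (posterior means and 95% HPD intervals) on a screened marker subset.

#' MCMC settings for the Bayesian Lasso
#'
#' Defaults follow the standard genomic-prediction run: a chain of
#' 4,000 iterations, burn-in 2,000, thin 20 (100 retained draws).
#' `r` and `delta` are the shape and rate of the Gamma hyperprior on
#' the squared shrinkage parameter lambda^2.
#'
#' @param iterations total Gibbs iterations.
#' @param burn_in discarded initial iterations (< iterations).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param r,delta Gamma(r, delta) hyperprior on lambda^2.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(iterations = 4000L, burn_in = 2000L, thin = 20L,
                          r = 1, delta = 0.1) {
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= iterations) stop_("burn_in must be < iterations")
  if (thin < 1L) stop_("thin must be >= 1")
  retained <- (iterations - burn_in) %/% thin
  if (retained < 10L)
    stop_("settings retain only ", retained, " draws; need >= 10")
  structure(list(iterations = iterations, burn_in = burn_in, thin = thin,
                 r = r, delta = delta, retained = retained),
            class = "mcmc_settings")
}

rinvgauss_r <- function(n, mu, lambda) {
  nu <- stats::rnorm(n)
  y <- nu^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  x[x <= 0 | !is.finite(x)] <- (mu * 1e-10)[x <= 0 | !is.finite(x)]
  swap <- stats::runif(n) > mu / (mu + x)
  x[swap] <- (mu^2 / x)[swap]
  x
}

# Blockwise sampler: beta drawn jointly from its full conditional
# multivariate normal.  Direct Cholesky when g <= n; for g > n the draw
# uses the n-dimensional Woodbury-style solve (Bhattacharya et al.
# algorithm), which is mathematically equivalent to the g-dimensional
# multivariate normal draw.
blasso_joint_r <- function(Xc, y, settings) {
  n <- nrow(Xc); g <- ncol(Xc)
  mu <- mean(y)
  sigma2 <- stats::var(y); if (!(sigma2 > 0)) sigma2 <- 1
  lambda2 <- 1
  beta <- numeric(g)
  invtau2 <- rep(1, g)
  n_keep <- settings$retained
  beta_draws <- matrix(0, n_keep, g)
  mu_draws <- sigma2_draws <- lambda2_draws <- numeric(n_keep)
  XtX <- if (g <= n) crossprod(Xc) else NULL
  kept <- 0L
  for (iter in seq_len(settings$iterations)) {
    res_mu <- y - drop(Xc %*% beta)
    mu <- mean(res_mu) + stats::rnorm(1) * sqrt(sigma2 / n)
    yt <- y - mu
    if (g <= n) {
      A <- XtX + diag(invtau2, g)
      R <- chol(A)
      m <- backsolve(R, forwardsolve(t(R), crossprod(Xc, yt)))
      beta <- drop(m + sqrt(sigma2) * backsolve(R, stats::rnorm(g)))
    } else {
      tau2 <- 1 / invtau2
      u <- sqrt(tau2) * stats::rnorm(g)
      v <- drop(Xc %*% u) + stats::rnorm(n)
      M <- Xc %*% (tau2 * t(Xc)) + diag(n)
      w <- solve(M, yt / sqrt(sigma2) - v)
      beta <- sqrt(sigma2) * (u + tau2 * drop(crossprod(Xc, w)))
    }
    b2 <- pmax(beta^2, 1e-20)
    mu_ig <- pmin(sqrt(lambda2 * sigma2 / b2), 1e10)
    invtau2 <- rinvgauss_r(g, mu_ig, lambda2)
    e <- yt - drop(Xc %*% beta)
    rate_s <- 0.5 * sum(e^2) + 0.5 * sum(beta^2 * invtau2)
    sigma2 <- 1 / stats::rgamma(1, shape = 0.5 * (n - 1) + 0.5 * g,
                                rate = rate_s)
    lambda2 <- stats::rgamma(1, shape = settings$r + g,
                             rate = settings$delta + 0.5 * sum(1 / invtau2))
    if (iter > settings$burn_in &&
        (iter - settings$burn_in) %% settings$thin == 0 &&
        kept < n_keep) {
      kept <- kept + 1L
      beta_draws[kept, ] <- beta
      mu_draws[kept] <- mu
      sigma2_draws[kept] <- sigma2
      lambda2_draws[kept] <- lambda2
    }
  }
  list(beta = beta_draws, mu = mu_draws, sigma2 = sigma2_draws,
       lambda2 = lambda2_draws)
}

#' Fit the Bayesian Lasso by Gibbs sampling
#'
#' Hierarchical model: `beta_j | tau2_j, sigma2 ~ N(0, sigma2 tau2_j)`,
#' `tau2_j ~ Exp(lambda2 / 2)`, `lambda2 ~ Gamma(r, delta)`, flat prior
#' on the intercept and scale-invariant prior on `sigma2`.  Dosage
#' columns are centered internally; reported effects stay on the
#' original dosage scale.
#'
#' Two update schemes for the marker effects are available.  The
#' default `"scan"` updates each effect from its univariate full
#' conditional with residual updating (O(n g) per sweep), which is what
#' makes whole-panel fits with thousands of markers practical.
#' `"joint"` draws the full effect vector from its multivariate-normal
#' full conditional (Cholesky for g <= n, an n-dimensional
#' Woodbury-style solve for g > n).  Both are Gibbs samplers for the
#' same posterior; their agreement is part of the test suite.
#'
#' @param X n x g dosage matrix (or a [genotype_panel]), no missing
#'   values.
#' @param y numeric response of length n.
#' @param settings an [mcmc_settings()] object.
#' @param seed integer seed (draws are reproducible).
#' @param method `"scan"` (default) or `"joint"`.
#' @param hpd_prob probability for the stored HPD intervals.
#' @return object of class `blasso` with elements `beta_mean`
#'   (named), `beta_draws` (retained draws x g), `mu_mean`, `mu_draws`,
#'   `sigma2_draws`, `lambda_draws`, `hpd` (g x 2), `center`, `fitted`,
#'   `residuals`, `settings`, `method`.
#' @examples
#' set.seed(1)
#' X <- matrix(rbinom(200 * 5, 2, 0.4), 200, 5)
#' y <- X %*% c(2, -1, 0, 0, 0) + rnorm(200, 0, 0.5)
#' fit <- blasso(X, y, mcmc_settings(600, 100, 5), seed = 7)
#' coef(fit)
#' @export
blasso <- function(X, y, settings = mcmc_settings(), seed = 1L,
                   method = c("scan", "joint"), hpd_prob = 0.95) {
  method <- match.arg(method)
  if (inherits(X, "genotype_panel")) X <- X$dosages
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_("nrow(X) != length(y)")
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)) || any(!is.finite(y)))
    stop_("non-finite values in X or y")
  if (ncol(X) < 1L) stop_("need at least one marker")
  stopifnot(inherits(settings, "mcmc_settings"))
  ids <- colnames(X) %||% paste0("m", seq_len(ncol(X)))
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  draws <- with_seed(seed, {
    if (method == "scan")
      .blasso_scan(Xc, y, settings$iterations, settings$burn_in,
                   settings$thin, settings$r, settings$delta)
    else
      blasso_joint_r(Xc, y, settings)
  })
  colnames(draws$beta) <- ids
  beta_mean <- colMeans(draws$beta)
  hpd <- t(apply(draws$beta, 2L, hpd_interval, prob = hpd_prob))
  colnames(hpd) <- c("lower", "upper")
  mu_mean <- mean(draws$mu)
  fitted <- mu_mean + drop(Xc %*% beta_mean)
  structure(list(beta_mean = beta_mean, beta_draws = draws$beta,
                 mu_mean = mu_mean, mu_draws = draws$mu,
                 sigma2_draws = draws$sigma2,
                 lambda_draws = sqrt(draws$lambda2),
                 hpd = hpd, hpd_prob = hpd_prob, center = center,
                 fitted = fitted, residuals = y - fitted, y = y,
                 settings = settings, method = method, seed = seed),
            class = "blasso")
}

#' @export
print.blasso <- function(x, ...) {
  cat("Bayesian Lasso fit (", x$method, " sampler): ",
      length(x$beta_mean), " markers, ", nrow(x$beta_draws),
      " retained draws\n", sep = "")
  cat("  mu = ", signif(x$mu_mean, 5), ", sigma2 = ",
      signif(mean(x$sigma2_draws), 5), ", lambda = ",
      signif(mean(x$lambda_draws), 5), "\n", sep = "")
  invisible(x)
}

#' @export
coef.blasso <- function(object, ...) object$beta_mean

#' @export
residuals.blasso <- function(object, ...) object$residuals

#' @export
fitted.blasso <- function(object, ...) object$fitted

#' @export
summary.blasso <- function(object, ...) {
  tab <- data.frame(marker_id = names(object$beta_mean),
                    mean = unname(object$beta_mean),
                    sd = apply(object$beta_draws, 2L, stats::sd),
                    hpd_lower = object$hpd[, "lower"],
                    hpd_upper = object$hpd[, "upper"],
                    excludes_zero = object$hpd[, "lower"] > 0 |
                      object$hpd[, "upper"] < 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, hpd_prob = object$hpd_prob,
                 mu_mean = object$mu_mean, method = object$method),
            class = "summary.blasso")
}

#' @export
print.summary.blasso <- function(x, n = 10L, ...) {
  cat("Bayesian Lasso posterior summary (", 100 * x$hpd_prob,
      "% HPD):\n", sep = "")
  ord <- order(-abs(x$table$mean))
  print(utils::head(x$table[ord, ], n), row.names = FALSE)
  if (nrow(x$table) > n) cat("... ", nrow(x$table) - n, " more\n")
  invisible(x)
}

#' Predict from a Bayesian Lasso fit
#'
#' `type = "gbv"` (default) returns genomic breeding values
#' `X_s %*% beta_hat` on the raw dosage scale; `type = "response"`
#' returns trait-scale predictions `mu_hat + (X_s - center) %*%
#' beta_hat`, consistent with the internal centering.
#'
#' @param object a `blasso` fit.
#' @param newdata matrix or [genotype_panel] with the fit's markers
#'   (columns matched by name when available).
#' @param type `"gbv"` or `"response"`.
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
predict.blasso <- function(object, newdata = NULL,
                           type = c("gbv", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted)
    stop_("newdata required for GBV prediction")
  }
  if (inherits(newdata, "genotype_panel")) newdata <- newdata$dosages
  newdata <- as.matrix(newdata)
  ids <- names(object$beta_mean)
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(ids, colnames(newdata))
    if (length(miss))
      stop_("newdata lacks marker(s): ",
            paste(utils::head(miss, 5), collapse = ", "))
    newdata <- newdata[, ids, drop = FALSE]
  } else if (ncol(newdata) != length(ids)) {
    stop_("newdata has ", ncol(newdata), " columns; fit has ",
          length(ids), " markers")
  }
  if (type == "gbv") drop(newdata %*% object$beta_mean)
  else object$mu_mean +
    drop(sweep(newdata, 2L, object$center) %*% object$beta_mean)
}

#' @export
plot.blasso <- function(x, ...) {
  g <- length(x$beta_mean)
  graphics::plot(seq_len(g), x$beta_mean, pch = 16, cex = 0.6,
                 xlab = "marker index", ylab = "posterior mean effect",
                 main = "Bayesian Lasso marker effects", ...)
  graphics::segments(seq_len(g), x$hpd[, "lower"],
                     seq_len(g), x$hpd[, "upper"],
                     col = grDevices::grey(0.6))
  graphics::points(seq_len(g), x$beta_mean, pch = 16, cex = 0.6)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(prob * m)` of the
#' `m` sorted draws.  Among tied-width windows the first (lowest) is
#' returned.
#'
#' @param draws numeric vector of at least 10 posterior draws.
#' @param prob interval probability in (0, 1), default 0.95.
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  if (prob <= 0 || prob >= 1) stop_("prob must be in (0, 1)")
  m <- length(draws)
  if (m < 10L) stop_("need >= 10 draws for an HPD interval")
  s <- sort(draws)
  k <- ceiling(prob * m)
  n_win <- m - k + 1L
  widths <- s[k:m] - s[seq_len(n_win)]
  i <- which.min(widths)  # first minimum on ties
  c(lower = s[i], upper = s[i + k - 1L])
}

#' Select the markers with the largest posterior-mean effects
#'
#' The comparison selector: the k markers with the largest absolute
#' posterior mean effect, ties broken by marker ID.  The full
#' |estimate| ranking is attached as attribute `"ranking"` for
#' marker-count sweeps.
#'
#' @param fit a `blasso` fit.
#' @param k number of markers, k <= number fitted.
#' @return character vector of k marker IDs, best first, with the full
#'   ranking in `attr(, "ranking")`.
#' @export
select_top_by_estimate <- function(fit, k = 100L) {
  stopifnot(inherits(fit, "blasso"))
  g <- length(fit$beta_mean)
  if (k > g) stop_("k = ", k, " exceeds number of markers g = ", g)
  ids <- names(fit$beta_mean)
  ord <- order(-abs(fit$beta_mean), ids)
  ranking <- ids[ord]
  structure(ranking[seq_len(k)], ranking = ranking)
}

#' Select markers whose HPD interval excludes zero
#'
#' A marker is selected when its HPD interval lies strictly on one side
#' of zero; an interval touching zero counts as including it.
#'
#' @param fit a `blasso` fit.
#' @param prob HPD probability, default 0.95.
#' @return character vector of selected marker IDs.
#' @export
select_by_hpd <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "blasso"))
  hpd <- if (isTRUE(all.equal(prob, fit$hpd_prob))) fit$hpd else
    t(apply(fit$beta_draws, 2L, hpd_interval, prob = prob))
  sel <- hpd[, 1L] > 0 | hpd[, 2L] < 0
  names(fit$beta_mean)[sel]
}

#' Write a posterior effect summary as TSV
#'
#' Columns: `marker_id`, `mean`, `hpd_lower`, `hpd_upper`.
#'
#' @param fit a `blasso` fit.
#' @param path output path.
#' @export
write_beta_summary <- function(fit, path) {
  tab <- summary(fit)$table[, c("marker_id", "mean", "hpd_lower",
                                "hpd_upper")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fit)
}
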