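#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of V by lambda, leaving the
#' diagonal unchanged. lambda = 1 returns the Brownian-motion
#' covariance; lambda = 0 leaves a diagonal matrix, under which the
#' phylogenetic regression collapses to an ordinary (independent-error)
#' generalized least squares fit.
#'
#' @param V square symmetric covariance matrix (see
#'   [phylo_covariance()]).
#' @param lambda scalar in [0, 1].
#' @return the transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda > 1)
    stop("'lambda' must be a scalar in [0, 1]")
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  Vl
}

# Core GLS machinery: chol-whitened least squares.
# Returns coefficients, their covariance, whitened RSS, and the ML
# Gaussian log-likelihood with sigma^2 profiled out.
gls_core <- function(X, y, V) {
  n <- length(y)
  U <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix is not positive definite"))
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  qrx <- qr(Xw)
  if (qrx$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- qr.coef(qrx, yw)
  res <- yw - Xw %*% beta
  rss <- sum(res^2)
  p <- ncol(X)
  sigma2 <- rss / (n - p)                       # unbiased, for SEs
  XtX_inv <- chol2inv(qr.R(qrx))
  logdetV <- 2 * sum(log(diag(U)))
  # ML log-likelihood, sigma^2_ML = rss/n profiled in
  loglik <- -0.5 * (n * log(2 * pi) + n * log(rss / n) + logdetV + n)
  list(beta = as.numeric(beta), vcov = sigma2 * XtX_inv, rss = rss,
       sigma2 = sigma2, loglik = loglik, n = n, p = p)
}

#' Generalized least squares regression under a fixed covariance
#'
#' Fits y = a + b x with error covariance proportional to \code{V} by
#' the V-whitened normal equations. With \code{V} the identity this is
#' ordinary least squares; with \code{V} a lambda-transformed
#' phylogenetic covariance it is the PGLS of comparative biology.
#' R-squared is computed in the whitened space, against the
#' intercept-only GLS fit, so it is comparable across lambda values.
#'
#' @param data data.frame with columns \code{taxon}, \code{x}, \code{y}
#'   (species means; no missing values).
#' @param V covariance matrix with dimnames covering \code{data$taxon}.
#' @param lambda fixed Pagel's lambda applied to V before fitting
#'   (default 1, i.e. V as supplied).
#' @return object of class \code{gls_fit}: slope, intercept, se_slope,
#'   t_slope, p_slope (two-sided, n - 2 df), r2_multiple, r2_adjusted,
#'   lambda, loglik, n, and the coefficient covariance.
#' @export
gls_fit <- function(data, V, lambda = 1) {
  stopifnot(all(c("taxon", "x", "y") %in% names(data)))
  if (anyNA(data$x) || anyNA(data$y))
    stop("missing trait values: drop incomplete rows before fitting")
  n <- nrow(data)
  if (n < 3L) stop("need at least 3 species")
  idx <- match(data$taxon, rownames(V))
  if (anyNA(idx))
    stop("taxa absent from covariance matrix: ",
         paste(data$taxon[is.na(idx)], collapse = ", "))
  Vs <- lambda_transform(V[idx, idx, drop = FALSE], lambda)
  X <- cbind(intercept = 1, x = data$x)
  fit <- gls_core(X, data$y, Vs)
  null <- gls_core(X[, 1, drop = FALSE], data$y, Vs)
  se <- sqrt(diag(fit$vcov))
  tval <- fit$beta[2] / se[2]
  r2 <- 1 - fit$rss / null$rss
  structure(list(
    intercept = fit$beta[1], slope = fit$beta[2],
    se_intercept = se[1], se_slope = se[2],
    t_slope = tval,
    p_slope = 2 * stats::pt(-abs(tval), df = n - 2),
    r2_multiple = r2,
    r2_adjusted = 1 - (1 - r2) * (n - 1) / (n - 2),
    lambda = lambda, lambda_ci = c(NA_real_, NA_real_),
    loglik = fit$loglik, sigma2 = fit$sigma2, n = n,
    taxa = data$taxon), class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf(
    "GLS/PGLS fit (n = %d): lambda = %.3f [%s, %s]\n", x$n, x$lambda,
    ifelse(is.na(x$lambda_ci[1]), "NA", sprintf("%.3f", x$lambda_ci[1])),
    ifelse(is.na(x$lambda_ci[2]), "NA", sprintf("%.3f", x$lambda_ci[2]))))
  cat(sprintf("  slope = %.4f (SE %.4f, t = %.4f, p = %.4g)\n",
              x$slope, x$se_slope, x$t_slope, x$p_slope))
  cat(sprintf("  intercept = %.4f; R2 = %.4f (adj %.4f); logLik = %.3f\n",
              x$intercept, x$r2_multiple, x$r2_adjusted, x$loglik))
  invisible(x)
}

# 95% profile-likelihood CI for lambda: { lambda : logL >= logL_max - 1.92 }.
# Endpoints that sit at the search boundary are reported NA, matching the
# convention of comparative packages.
lambda_profile_ci <- function(ll_fun, lambda_hat, ll_max,
                              drop = stats::qchisq(0.95, 1) / 2) {
  f <- function(l) ll_fun(l) - (ll_max - drop)
  lower <- upper <- NA_real_
  if (lambda_hat > 0 && f(0) < 0)
    lower <- stats::uniroot(f, c(0, lambda_hat), tol = 1e-6)$root
  if (lambda_hat < 1 && f(1) < 0)
    upper <- stats::uniroot(f, c(lambda_hat, 1), tol = 1e-6)$root
  c(lower, upper)
}

#' Maximum-likelihood Pagel's lambda for a phylogenetic regression
#'
#' Profiles the ML Gaussian log-likelihood of the regression over
#' lambda in [0, 1]: a coarse grid locates the mode, a bracketed 1-D
#' search refines it to tolerance 1e-6, and the fit is refitted at the
#' optimum. The 95% confidence interval is the profile-likelihood set
#' \{lambda : logL(lambda) >= logL(lambda_hat) - 1.92\}; an endpoint
#' lying at the [0, 1] boundary is reported NA (no finite bound), the
#' convention used in published lambda tables. The maximized
#' log-likelihood is guaranteed >= the likelihood at both endpoints.
#'
#' @inheritParams gls_fit
#' @param grid_n number of coarse grid points (default 21).
#' @return a \code{gls_fit} with \code{lambda} at the ML estimate and
#'   \code{lambda_ci} filled in.
#' @export
profile_lambda <- function(data, V, grid_n = 21L) {
  ll <- function(l) gls_fit(data, V, lambda = l)$loglik
  grid <- seq(0, 1, length.out = grid_n)
  llg <- vapply(grid, ll, numeric(1))
  i <- which.max(llg)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(grid_n, i + 1L)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, grid[i], 0, 1)
  llc <- c(opt$objective, llg[i], llg[1], llg[grid_n])
  lambda_hat <- cand[which.max(llc)]
  fit <- gls_fit(data, V, lambda = lambda_hat)
  fit$lambda_ci <- lambda_profile_ci(ll, lambda_hat, max(llc))
  fit
}

#' Phylogenetic signal of a single trait (Pagel's lambda)
#'
#' ML lambda for an intercept-only model: how much of the trait's
#' variance across species is structured by the phylogeny. A constant
#' trait has no information about lambda and returns 0 with a warning.
#'
#' @param trait named numeric vector (names = taxa) or data.frame with
#'   columns \code{taxon} and a trait column.
#' @param tree a dated \code{phylo}, or a precomputed covariance matrix.
#' @return list with \code{lambda}, \code{ci} (length 2, NA at
#'   unbounded ends), \code{loglik}, \code{n}.
#' @export
lambda_signal <- function(trait, tree) {
  if (is.data.frame(trait)) {
    v <- trait[[setdiff(names(trait), "taxon")[1]]]
    names(v) <- trait$taxon
    trait <- v
  }
  if (is.null(names(trait))) stop("'trait' must be named by taxon")
  trait <- trait[!is.na(trait)]
  if (length(trait) < 3L) stop("need >= 3 taxa with trait values")
  V <- if (inherits(tree, "phylo")) phylo_covariance(tree) else tree
  keep <- names(trait)[names(trait) %in% rownames(V)]
  trait <- trait[keep]
  if (length(trait) < 3L) stop("fewer than 3 taxa match the tree")
  if (stats::var(trait) == 0) {
    warning("constant trait: lambda unidentifiable, returning 0")
    return(list(lambda = 0, ci = c(NA_real_, NA_real_),
                loglik = NA_real_, n = length(trait)))
  }
  ll <- function(l) {
    Vi <- lambda_transform(V[keep, keep, drop = FALSE], l)
    gls_core(matrix(1, length(trait), 1), as.numeric(trait), Vi)$loglik
  }
  grid <- seq(0, 1, length.out = 21L)
  llg <- vapply(grid, ll, numeric(1))
  i <- which.max(llg)
  opt <- stats::optimize(ll, c(grid[max(1L, i - 1L)], grid[min(21L, i + 1L)]),
                         maximum = TRUE, tol = 1e-6)
  cand <- c(opt$maximum, grid[i], 0, 1)
  llc <- c(opt$objective, llg[i], llg[1], llg[21])
  lambda_hat <- cand[which.max(llc)]
  list(lambda = lambda_hat,
       ci = lambda_profile_ci(ll, lambda_hat, max(llc)),
       loglik = max(llc), n = length(trait))
}

#' Welch two-sample t-test from group summary statistics
#'
#' The unequal-variance t-test computed from (n, mean, variance) per
#' group: t = (m1 - m2) / sqrt(v1/n1 + v2/n2) with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. Operating on summaries
#' lets published species tables be pooled and compared without the
#' raw specimen values.
#'
#' @param a,b lists (or one-row data.frames) with elements \code{n},
#'   \code{mean}, \code{var}; both n >= 2, var > 0.
#' @return list with \code{t}, \code{df}, \code{p}, \code{mean_a},
#'   \code{mean_b}.
#' @export
welch_t <- function(a, b) {
  for (g in list(a, b)) {
    if (g$n < 2) stop("each group needs n >= 2")
    if (!is.finite(g$var) || g$var <= 0) stop("degenerate group variance")
  }
  se2a <- a$var / a$n; se2b <- b$var / b$n
  t <- (a$mean - b$mean) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_a = a$mean, mean_b = b$mean)
}

#' Pool species summaries into specimen-level group statistics
#'
#' Exact variance decomposition: given per-species n, mean and sample
#' SD, the pooled n, mean and sample variance equal what would be
#' computed from the underlying specimens directly,
#' pooled var = (sum (n_i - 1) sd_i^2 + sum n_i (m_i - m)^2) / (N - 1).
#' Species with n = 1 contribute only through the between-species term
#' (their SD is NA by convention).
#'
#' @param summaries data.frame as from [summarize_species()].
#' @param tribe optional tribe label to filter on.
#' @param trait \code{"D"} (default) or \code{"area"}: which pair of
#'   n/mean/sd columns to pool.
#' @return list with \code{label}, \code{n}, \code{mean}, \code{var}.
#' @export
pooled_from_species <- function(summaries, tribe = NULL, trait = "D") {
  s <- summaries
  if (!is.null(tribe)) s <- s[s$tribe == tribe, , drop = FALSE]
  nc <- paste0("n_", trait); mc <- paste0("mean_", trait)
  sc <- paste0("sd_", trait)
  s <- s[s[[nc]] > 0 & !is.na(s[[mc]]), , drop = FALSE]
  if (nrow(s) == 0L) stop("no species in group", if (!is.null(tribe))
    paste0(" '", tribe, "'"))
  n <- s[[nc]]; m <- s[[mc]]; sd <- s[[sc]]
  N <- sum(n)
  mbar <- sum(n * m) / N
  within <- sum(ifelse(n > 1, (n - 1) * sd^2, 0))
  between <- sum(n * (m - mbar)^2)
  list(label = if (is.null(tribe)) "all" else tribe, n = N, mean = mbar,
       var = if (N > 1) (within + between) / (N - 1) else NA_real_)
}

#' Compare the slopes of two independent regressions
#'
#' Classical parallel-slopes t-test: t = (b1 - b2) / sqrt(se1^2 +
#' se2^2) on n1 + n2 - 4 degrees of freedom (two slopes and two
#' intercepts estimated), two-sided p. Used to ask whether two clades
#' share the same complexity-area relationship.
#'
#' @param fit1,fit2 \code{gls_fit} objects (or lists with \code{slope},
#'   \code{se_slope}, \code{n}).
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
compare_slopes <- function(fit1, fit2) {
  t <- (fit1$slope - fit2$slope) / sqrt(fit1$se_slope^2 + fit2$se_slope^2)
  df <- fit1$n + fit2$n - 4
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Normality and equal-variance checks by group
#'
#' Shapiro-Wilk W per group and Bartlett's test of homogeneity of
#' variances across groups: the standard pre-checks before comparing
#' group means with a t-test. Degenerate (constant) groups are flagged
#' rather than tested.
#'
#' @param values_by_group named list of numeric vectors, each n >= 3.
#' @return list with \code{shapiro} (data.frame: group, n, W, p,
#'   degenerate) and \code{bartlett} (list: statistic, df, p; NULL if
#'   fewer than 2 usable groups).
#' @export
distribution_checks <- function(values_by_group) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 1L)
  rows <- lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    if (length(v) < 3L) stop("group '", g, "' has n < 3")
    degenerate <- stats::var(v) == 0
    if (degenerate)
      data.frame(group = g, n = length(v), W = NA_real_, p = NA_real_,
                 degenerate = TRUE)
    else {
      sw <- stats::shapiro.test(v)
      data.frame(group = g, n = length(v), W = unname(sw$statistic),
                 p = sw$p.value, degenerate = FALSE)
    }
  })
  shapiro <- do.call(rbind, rows)
  usable <- values_by_group[!shapiro$degenerate]
  bartlett <- NULL
  if (length(usable) >= 2L) {
    bt <- stats::bartlett.test(usable)
    bartlett <- list(statistic = unname(bt$statistic),
                     df = unname(bt$parameter), p = bt$p.value)
  }
  list(shapiro = shapiro, bartlett = bartlett)
}
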