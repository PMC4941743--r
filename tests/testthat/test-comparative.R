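make_V <- function(n, seed = 1) {
  tr <- simulate_tree(n, birth = 1, seed = seed)
  phylo_covariance(tr)
}

test_that("lambda transform scales only the off-diagonal", {
  V <- make_V(8, seed = 2)
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0), diag(diag(V)),
               ignore_attr = TRUE)
  Vh <- lambda_transform(V, 0.5)
  for (i in 1:8) for (j in 1:8) {
    want <- if (i == j) V[i, j] else 0.5 * V[i, j]
    expect_equal(Vh[i, j], want)
  }
  expect_error(lambda_transform(V, 1.2), "lambda")
})

test_that("GLS with identity covariance reproduces OLS", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 20
    x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
    taxa <- paste0("t", 1:n)
    V <- diag(n); dimnames(V) <- list(taxa, taxa)
    fit <- gls_fit(data.frame(taxon = taxa, x = x, y = y), V)
    ols <- summary(lm(y ~ x))
    expect_equal(fit$slope, unname(coef(ols)[2, 1]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(coef(ols)[1, 1]), tolerance = 1e-10)
    expect_equal(fit$se_slope, unname(coef(ols)[2, 2]), tolerance = 1e-10)
    expect_equal(fit$p_slope, unname(coef(ols)[2, 4]), tolerance = 1e-10)
    expect_equal(fit$r2_multiple, ols$r.squared, tolerance = 1e-10)
    expect_equal(fit$r2_adjusted, ols$adj.r.squared, tolerance = 1e-10)
  }
})

test_that("GLS with diagonal covariance equals weighted regression", {
  d <- data.frame(taxon = c("a", "b", "c", "d"),
                  x = c(1, 2, 3, 4), y = c(1.1, 1.9, 3.2, 3.7))
  V <- diag(c(1, 1, 1, 4)); dimnames(V) <- list(d$taxon, d$taxon)
  fit <- gls_fit(d, V)
  w <- summary(lm(y ~ x, data = d, weights = 1 / c(1, 1, 1, 4)))
  expect_equal(fit$slope, unname(coef(w)[2, 1]), tolerance = 1e-10)
  expect_equal(fit$se_slope, unname(coef(w)[2, 2]), tolerance = 1e-10)
})

test_that("lambda profile peaks above both endpoints and bounds the CI", {
  set.seed(8)
  tr <- simulate_tree(32, birth = 1, seed = 8)
  V <- phylo_covariance(tr)
  for (lam in c(0, 0.6, 1)) {
    d <- simulate_traits(tr, lambda = lam, slope = 0.3, sigma2 = 0.5)
    fit <- profile_lambda(d, V)
    ll <- function(l) gls_fit(d, V, lambda = l)$loglik
    expect_gte(fit$loglik, ll(0) - 1e-8)
    expect_gte(fit$loglik, ll(1) - 1e-8)
    # CI endpoints away from the boundary satisfy the 1.92-drop equation
    for (end in fit$lambda_ci[!is.na(fit$lambda_ci)])
      expect_equal(ll(end), fit$loglik - qchisq(0.95, 1) / 2,
                   tolerance = 1e-4)
  }
})

test_that("lambda is recovered from Brownian and shuffled traits", {
  tr <- simulate_tree(48, birth = 1, seed = 10)
  V <- phylo_covariance(tr)
  set.seed(31)
  lam_bm <- replicate(15, {
    d <- simulate_traits(tr, lambda = 1, slope = 0.4, sigma2 = 1)
    profile_lambda(d, V)$lambda
  })
  expect_gte(median(lam_bm), 0.85)
  lam_perm <- replicate(15, {
    d <- simulate_traits(tr, lambda = 1, slope = 0, sigma2 = 1)
    d$y <- sample(d$y)
    profile_lambda(d, V)$lambda
  })
  expect_lte(median(lam_perm), 0.1)
})

test_that("single-trait signal matches an independent lambda implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(40, birth = 1, seed = 12)
  # interior optimum: the reference searches lambda past 1 (to the PD
  # bound), so only non-boundary optima are directly comparable
  x <- simulate_traits(tr, lambda = 0.5, slope = 0, intercept = 0,
                       sigma2 = 1, seed = 14)$y
  names(x) <- tr$tip.label
  ours <- lambda_signal(x, tr)
  ref <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(ours$lambda, ref$lambda, tolerance = 1e-3)
  expect_equal(ours$loglik, ref$logL, tolerance = 1e-6)
})

test_that("constant traits yield lambda 0 with a warning", {
  tr <- simulate_tree(8, birth = 1, seed = 3)
  x <- setNames(rep(1.4, 8), tr$tip.label)
  expect_warning(out <- lambda_signal(x, tr), "constant")
  expect_equal(out$lambda, 0)
})

test_that("Welch t from summaries matches formula and t.test", {
  g <- list(n = 10, mean = 2, var = 1.5)
  same <- welch_t(g, g)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  a <- list(n = 5, mean = 1, var = 1); b <- list(n = 7, mean = 2, var = 1)
  out <- welch_t(a, b)
  t_hand <- (1 - 2) / sqrt(1 / 5 + 1 / 7)
  df_hand <- (1 / 5 + 1 / 7)^2 / ((1 / 5)^2 / 4 + (1 / 7)^2 / 6)
  expect_equal(out$t, t_hand)
  expect_equal(out$df, df_hand)
  # antisymmetry under group exchange
  expect_equal(welch_t(b, a)$t, -out$t)

  set.seed(17)
  x <- rnorm(12, 1.4, 0.1); y <- rnorm(20, 1.35, 0.08)
  ours <- welch_t(list(n = 12, mean = mean(x), var = var(x)),
                  list(n = 20, mean = mean(y), var = var(y)))
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("pooling species summaries reconstructs specimen-level moments", {
  one <- data.frame(tribe = "Equini", taxon = "A", n_D = 4, mean_D = 1.4,
                    sd_D = 0.05)
  p1 <- pooled_from_species(one)
  expect_equal(p1$n, 4); expect_equal(p1$mean, 1.4)
  expect_equal(p1$var, 0.05^2)

  two <- data.frame(tribe = "E", taxon = c("A", "B"), n_D = c(2, 2),
                    mean_D = c(1, 3), sd_D = c(0, 0))
  p2 <- pooled_from_species(two)
  expect_equal(p2$mean, 2)
  expect_equal(p2$var, 4 / 3)

  set.seed(23)
  coh <- simulate_cohort(n_species = 12, seed = 23)
  summ <- summarize_species(coh$specimens)
  pooled <- pooled_from_species(summ, trait = "D")
  expect_equal(pooled$n, nrow(coh$specimens))
  expect_equal(pooled$mean, mean(coh$specimens$D), tolerance = 1e-12)
  expect_equal(pooled$var, var(coh$specimens$D), tolerance = 1e-12)
})

test_that("slope comparison follows the parallel-slopes t formula", {
  f <- list(slope = 1, se_slope = 0.5, n = 10)
  g <- list(slope = 0, se_slope = 0.5, n = 10)
  out <- compare_slopes(f, g)
  expect_equal(out$t, sqrt(2))
  expect_equal(out$df, 16)
  expect_equal(out$p, 2 * pt(-sqrt(2), 16))
  expect_equal(compare_slopes(f, f)$t, 0)
})

test_that("slope estimates are unbiased under independent residuals", {
  tr <- simulate_tree(32, birth = 1, seed = 20)
  V <- phylo_covariance(tr)
  set.seed(41)
  beta <- -0.016
  est <- replicate(60, {
    d <- simulate_traits(tr, lambda = 0, slope = beta, sigma2 = 1e-3)
    gls_fit(d, V, lambda = 0)$slope
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - beta), 2 * mc_se + 1e-12)
})

test_that("distribution checks run Shapiro-Wilk and Bartlett", {
  expect_error(distribution_checks(list(a = c(1, 2))), "n < 3")
  out <- distribution_checks(list(flat = rep(1, 10),
                                  ok = c(1.2, 1.4, 1.3, 1.5, 1.1)))
  expect_true(out$shapiro$degenerate[out$shapiro$group == "flat"])
  expect_false(out$shapiro$degenerate[out$shapiro$group == "ok"])
  expect_null(out$bartlett)   # only one usable group

  set.seed(29)
  g1 <- rnorm(30, 0, 1); g2 <- rnorm(30, 0, 3)
  out2 <- distribution_checks(list(a = g1, b = g2))
  ref <- bartlett.test(list(g1, g2))
  expect_equal(out2$bartlett$statistic, unname(ref$statistic))
  expect_equal(out2$bartlett$p, ref$p.value)
  expect_lt(out2$bartlett$p, 0.05)
  sw <- shapiro.test(g1)
  expect_equal(out2$shapiro$W[1], unname(sw$statistic))
})
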