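test_that("GLS with identity covariance reproduces OLS exactly", {
  set.seed(7)
  n <- 12
  x <- rnorm(n)
  y <- 1.5 + 0.8 * x + rnorm(n)
  fit <- gls_fixed(y, x, diag(n))
  ols <- stats::lm(y ~ x)
  sm <- summary(ols)
  expect_equal(fit$beta0, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(fit$beta1, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(fit$r2, sm$r.squared, tolerance = 1e-10)
  expect_equal(fit$f_stat, unname(sm$fstatistic[1]), tolerance = 1e-10)
  expect_equal(fit$p_value,
               unname(stats::pf(sm$fstatistic[1], 1, n - 2,
                                lower.tail = FALSE)), tolerance = 1e-10)
})

test_that("a perfect affine relationship gives r2 = 1 under any covariance", {
  tr <- sim_yule_tree(10, depth = 100, seed = 2)
  x <- sim_trait(tr, "BM", sigma2 = 1, seed = 3)
  y <- 2 * x + 1
  for (V in list(phylo_covariance(tr), ou_scale(tr, 0.05))) {
    fit <- gls_fixed(y, x, V)
    expect_equal(fit$beta1, 2, tolerance = 1e-8)
    expect_equal(fit$beta0, 1, tolerance = 1e-8)
    expect_equal(fit$r2, 1, tolerance = 1e-10)
  }
  ou_fit <- pgls_ou(y, x, tr, n_restarts = 3, seed = 4)
  expect_equal(ou_fit$r2, 1, tolerance = 1e-10)
})

test_that("GLS coefficients match the dense normal-equations oracle", {
  tr <- sim_yule_tree(10, depth = 150, seed = 12)
  V <- phylo_covariance(tr)
  x <- sim_trait(tr, "BM", sigma2 = 1, seed = 13)
  y <- 0.5 - 1.2 * x + sim_trait(tr, "BM", sigma2 = 0.5, seed = 14)
  fit <- gls_fixed(y, x, V)
  beta <- bf_gls_beta(y, x, V)
  expect_equal(c(fit$beta0, fit$beta1), beta, tolerance = 1e-9)
  expect_equal(fit$f_stat, (fit$n - 2) * fit$r2 / (1 - fit$r2),
               tolerance = 1e-8)
})

test_that("GLS input validation catches degenerate designs", {
  tr <- sim_yule_tree(8, depth = 10, seed = 15)
  V <- phylo_covariance(tr)
  y <- sim_trait(tr, "BM", seed = 16)
  expect_error(gls_fixed(y, rep(1, 8), V), "constant")
  expect_error(gls_fixed(y[1:3], rnorm(3), V[1:3, 1:3]), "at least 4")
})

test_that("R2 is invariant to affine rescaling of either variable", {
  tr <- sim_yule_tree(14, depth = 100, seed = 22)
  pair <- sim_regression_pair(tr, beta0 = 1, beta1 = 0.5,
                              resid_lambda = 0.7, sigma2 = 0.5, seed = 23)
  base <- pgls_ml_lambda(pair$y, pair$x, tr)
  resc <- pgls_ml_lambda(3 * pair$y - 10, -0.2 * pair$x + 4, tr)
  expect_equal(base$r2, resc$r2, tolerance = 1e-6)
  expect_equal(base$shape, resc$shape, tolerance = 1e-4)
})

test_that("profile lambda dominates both endpoints", {
  for (seed in c(31, 32, 33)) {
    tr <- sim_yule_tree(16, depth = 150, seed = seed)
    pair <- sim_regression_pair(tr, beta0 = 0, beta1 = 0.3,
                                resid_lambda = 0.5, sigma2 = 1,
                                seed = seed + 100)
    fit <- pgls_ml_lambda(pair$y, pair$x, tr)
    V <- phylo_covariance(tr)
    ll_at <- function(l) gls_fixed(pair$y, pair$x,
                                   lambda_scale(V, l))$loglik
    expect_gte(fit$loglik, ll_at(0) - 1e-8)
    expect_gte(fit$loglik, ll_at(1) - 1e-8)
  }
})

test_that("star-phylogeny residuals make ML-lambda PGLS collapse to OLS", {
  tr <- sim_yule_tree(40, depth = 150, seed = 41)
  x <- sim_trait(tr, "BM", sigma2 = 1, seed = 42)
  set.seed(43)
  y <- 0.5 * x + rnorm(40)          # iid residuals: lambda = 0
  names(y) <- names(x)
  fit <- pgls_ml_lambda(y, x, tr)
  expect_lt(fit$shape, 0.15)
  ols <- summary(stats::lm(y ~ x))
  expect_equal(fit$r2, ols$r.squared, tolerance = 0.05)
})

test_that("ML-lambda PGLS agrees with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  # a draw whose ML lambda is interior to [0, 1]: the reference optimizer
  # searches lambda unconstrained, so boundary cases would differ by design
  tr <- sim_yule_tree(30, depth = 150, seed = 55)
  pair <- sim_regression_pair(tr, beta0 = 2, beta1 = 0.6,
                              resid_lambda = 0.6, sigma2 = 1, seed = 56)
  fit <- pgls_ml_lambda(pair$y, pair$x, tr)
  dat <- data.frame(y = pair$y, x = pair$x, sp = names(pair$y))
  ref <- nlme::gls(y ~ x, data = dat,
                   correlation = ape::corPagel(0.5, tr, form = ~sp),
                   method = "ML")
  expect_gt(fit$shape, 0.05)   # interior, so the comparison is meaningful
  expect_lt(fit$shape, 0.99)
  expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 1e-3)
  expect_equal(fit$shape,
               unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-2)
})

test_that("OU-transformed PGLS approaches the BM fit as alpha vanishes", {
  tr <- sim_yule_tree(20, depth = 150, seed = 61)
  pair <- sim_regression_pair(tr, beta0 = 1, beta1 = 0.4,
                              resid_lambda = 1, sigma2 = 1, seed = 62)
  bm_fit <- gls_fixed(pair$y, pair$x, phylo_covariance(tr))
  small_alpha <- gls_fixed(pair$y, pair$x, ou_scale(tr, 1e-7))
  expect_equal(small_alpha$beta1, bm_fit$beta1, tolerance = 1e-4)
  expect_equal(small_alpha$r2, bm_fit$r2, tolerance = 1e-4)
})

test_that("the pair battery reports the default pairings and flags", {
  fx <- make_study_fixture(seed = 5)
  tab <- run_pair_battery(fx$traits, fx$tree)
  expect_equal(nrow(tab), 17)
  expect_equal(nrow(default_pgls_pairs()), 17)
  expect_setequal(tab$n[grepl("genome_size", tab$pair)], 8)

  # exact affine pair: flagged significant with r2 = 1
  traits2 <- fx$traits
  traits2$double_larval <- 2 * traits2$minimum_larval_period + 1
  tab2 <- run_pair_battery(traits2, fx$tree,
                           pairs = data.frame(
                             response = "double_larval",
                             predictor = "minimum_larval_period"))
  expect_equal(tab2$r2, 1, tolerance = 1e-8)
  expect_true(tab2$significant)

  expect_error(run_pair_battery(fx$traits, fx$tree,
                                pairs = data.frame(response = "nope",
                                                   predictor = "logQ")),
               "available")
})

test_that("complete-case filtering prunes tree and reports n per pair", {
  fx <- make_study_fixture(seed = 6)
  y <- stats::setNames(fx$traits$genome_size, fx$traits$species)
  x <- stats::setNames(fx$traits$minimum_larval_period, fx$traits$species)
  fit <- pgls_ml_lambda(y, x, fx$tree)
  expect_equal(fit$n, sum(!is.na(y)))
})
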