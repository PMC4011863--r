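# Phylogenetic generalized least squares (PGLS) for simple regressions
# y ~ x with phylogenetically structured errors.
#
# The GLS core whitens both sides with the Cholesky factor of the error
# covariance and runs ordinary least squares in the whitened space. R^2 is
# variance explained in that space relative to the phylogenetic-mean-only
# model, and the slope is tested with an F statistic on (1, n - 2) df.

new_pgls_fit <- function(beta0, beta1, shape_kind, shape, sigma2, r2, fstat,
                         p, n, loglik) {
  structure(list(beta0 = beta0, beta1 = beta1, shape_kind = shape_kind,
                 shape = shape, sigma2_hat = sigma2, r2 = r2,
                 f_stat = fstat, p_value = p, n = n, loglik = loglik),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit (n = %d): y = %.4g + %.4g * x\n", x$n, x$beta0,
              x$beta1))
  if (!is.null(x$shape))
    cat(sprintf("  %s = %.4g\n", x$shape_kind, x$shape))
  cat(sprintf("  R2 = %.4f  F(1,%d) = %.4f  p = %.4g\n",
              x$r2, x$n - 2L, x$f_stat, x$p_value))
  invisible(x)
}

#' Generalized least squares with a fixed error covariance
#'
#' Regresses `y` on `x` under errors with covariance proportional to `V`.
#' With `V` the identity this reduces exactly to ordinary least squares.
#'
#' @param y,x Numeric vectors aligned to the rows of `V`.
#' @param V Error covariance structure (positive definite up to scale).
#' @param shape_kind,shape Optional annotation of the transform that
#'   produced `V` (recorded in the result, not used in fitting).
#' @return A `"pgls_fit"` with coefficients, `r2`, `f_stat`, `p_value`,
#'   the ML error scale `sigma2_hat` and the Gaussian log-likelihood.
#' @export
gls_fixed <- function(y, x, V, shape_kind = NULL, shape = NULL) {
  n <- length(y)
  if (length(x) != n) stop("y and x differ in length")
  if (nrow(V) != n) stop("V does not match data length")
  if (n < 4) stop("need at least 4 observations, got ", n)
  if (stats::sd(x) == 0) stop("predictor is constant; slope unidentifiable")
  ch <- chol_safe(V)
  z <- backsolve(ch, y, transpose = TRUE)
  W <- backsolve(ch, cbind(`(Intercept)` = 1, x = x), transpose = TRUE)
  qr_W <- qr(W)
  beta <- qr.coef(qr_W, z)
  rss <- sum(qr.resid(qr_W, z)^2)
  # intercept-only GLS (the phylogenetic mean) defines the total SS
  ones <- W[, 1]
  mu_gls <- sum(ones * z) / sum(ones^2)
  tss <- sum((z - mu_gls * ones)^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 0
  fstat <- if (r2 < 1) (n - 2) * r2 / (1 - r2) else Inf
  p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(ch)))
  loglik <- if (sigma2 > 0)
    -n / 2 * (log(2 * pi) + log(sigma2) + 1) - logdetV / 2 else Inf
  new_pgls_fit(unname(beta[1]), unname(beta[2]), shape_kind, shape, sigma2,
               r2, fstat, p, n, loglik)
}

align_pair <- function(y, x, tree) {
  if (is.null(names(y)) || is.null(names(x))) {
    if (length(y) != length(tree$tip.label) ||
        length(x) != length(tree$tip.label))
      stop("unnamed y/x must have one value per tip")
    names(y) <- names(x) <- tree$tip.label
  }
  keep <- tree$tip.label[tree$tip.label %in% names(y) &
                         tree$tip.label %in% names(x)]
  keep <- keep[!is.na(y[keep]) & !is.na(x[keep])]
  if (length(keep) < 4)
    stop("fewer than 4 complete cases shared between y, x and the tree")
  tr <- if (length(keep) < length(tree$tip.label))
    ape::keep.tip(tree, keep) else tree
  list(y = y[tr$tip.label], x = x[tr$tip.label], tree = tr)
}

#' PGLS with jointly estimated Pagel's lambda
#'
#' For each candidate lambda the residual covariance is
#' `lambda_scale(V, lambda)` and the error scale is concentrated out by ML;
#' lambda maximizing the profile log-likelihood (bounded search on
#' \[0, 1\], tolerance 1e-8, endpoints checked) is retained and the
#' regression statistics are reported at that lambda. Lambda is
#' re-estimated for every regression rather than reused from single-trait
#' fits.
#'
#' @param y,x Named trait vectors; species missing either value are dropped
#'   (complete-case) and the tree pruned accordingly.
#' @param tree Ultrametric `"phylo"`.
#' @return A `"pgls_fit"` with `shape_kind = "lambda"`.
#' @export
pgls_ml_lambda <- function(y, x, tree) {
  al <- align_pair(y, x, tree)
  V <- phylo_covariance(al$tree)
  prof <- function(lam) {
    gls_fixed(al$y, al$x, lambda_scale(V, lam))$loglik
  }
  opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, prof(0)), c(1, prof(1)))
  lam_hat <- cand[which.max(cand[, 2]), 1]
  gls_fixed(al$y, al$x, lambda_scale(V, lam_hat),
            shape_kind = "lambda", shape = lam_hat)
}

#' PGLS on an OU-transformed tree
#'
#' The restraining force alpha is estimated from the response variable by
#' [fit_ou()] (multi-restart, minimum deviance) and the regression is then
#' run under the fixed OU covariance [ou_scale()].
#'
#' @inheritParams pgls_ml_lambda
#' @inheritParams fit_ou
#' @return A `"pgls_fit"` with `shape_kind = "alpha"`.
#' @export
pgls_ou <- function(y, x, tree, n_restarts = 10, seed = 20140506) {
  al <- align_pair(y, x, tree)
  alpha_hat <- fit_ou(al$y, al$tree, n_restarts = n_restarts,
                      seed = seed)$shape
  gls_fixed(al$y, al$x, ou_scale(al$tree, alpha_hat),
            shape_kind = "alpha", shape = alpha_hat)
}

#' Default regression pairings for the developmental-climate analysis
#'
#' The seventeen response/predictor pairings of the case study: midpoint
#' developmental traits against mean climate and aridity, minima against
#' minimum precipitation, the matched-locality variant, hatching time
#' against larval period, and developmental traits against genome size.
#'
#' @return Data frame with columns `response`, `predictor`.
#' @export
default_pgls_pairs <- function() {
  data.frame(
    response = c(
      "midpoint_larval_period", "midpoint_larval_period",
      "midpoint_larval_period", "midpoint_larval_period",
      "midpoint_hatching_time", "midpoint_hatching_time",
      "midpoint_hatching_time", "midpoint_hatching_time",
      "minimum_larval_period", "minimum_hatching_time",
      "matched_larval_period",
      "midpoint_hatching_time", "minimum_hatching_time",
      "midpoint_larval_period", "minimum_larval_period",
      "midpoint_hatching_time", "minimum_hatching_time"),
    predictor = c(
      "mean_annual_precip", "mean_precip_wettest_quarter",
      "mean_precip_seasonality", "logQ",
      "mean_annual_precip", "mean_precip_wettest_quarter",
      "mean_precip_seasonality", "logQ",
      "min_annual_precip", "min_annual_precip",
      "matched_annual_precip",
      "midpoint_larval_period", "minimum_larval_period",
      "genome_size", "genome_size",
      "genome_size", "genome_size"),
    stringsAsFactors = FALSE)
}

#' Run a battery of PGLS regressions over a trait table
#'
#' @param traits Data frame with a `species` column matching the tree's tip
#'   labels (case-sensitive) and one column per variable; missing values as
#'   `NA`, dropped per pair (complete-case) with the per-pair n reported.
#' @param tree Ultrametric `"phylo"`.
#' @param pairs Data frame of `response`, `predictor` (and optionally
#'   `method`) columns; defaults to [default_pgls_pairs()].
#' @param method `"lambda"` (ML-lambda PGLS) or `"ou"`; a `method` column
#'   in `pairs` overrides this per row.
#' @param alpha_level Significance threshold for the `significant` flag.
#' @inheritParams fit_ou
#' @return Data frame with one row per pair: `pair`, `n`, `beta0`, `beta1`,
#'   `shape_param`, `r2`, `f_stat`, `p_value`, `significant`.
#' @export
run_pair_battery <- function(traits, tree, pairs = default_pgls_pairs(),
                             method = c("lambda", "ou"), alpha_level = 0.05,
                             n_restarts = 10, seed = 20140506) {
  method <- match.arg(method)
  if (!"species" %in% names(traits))
    stop("`traits` must contain a `species` column")
  vars <- unique(c(pairs$response, pairs$predictor))
  unknown <- setdiff(vars, names(traits))
  if (length(unknown) > 0)
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         "; available: ",
         paste(setdiff(names(traits), "species"), collapse = ", "))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    yv <- stats::setNames(traits[[pairs$response[i]]], traits$species)
    xv <- stats::setNames(traits[[pairs$predictor[i]]], traits$species)
    m <- if ("method" %in% names(pairs)) pairs$method[i] else method
    fit <- if (m == "ou")
      pgls_ou(yv, xv, tree, n_restarts = n_restarts, seed = seed)
    else pgls_ml_lambda(yv, xv, tree)
    data.frame(pair = paste(pairs$response[i], "~", pairs$predictor[i]),
               n = fit$n, beta0 = fit$beta0, beta1 = fit$beta1,
               shape_param = fit$shape, r2 = fit$r2, f_stat = fit$f_stat,
               p_value = fit$p_value,
               significant = fit$p_value < alpha_level,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
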