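# Single-trait evolutionary model fitting: Brownian motion (BM),
# Ornstein-Uhlenbeck (OU) and Pagel's-lambda, compared by AIC.
#
# All fits are maximum likelihood (ML, n divisor for sigma2) so that AIC is
# comparable across models. mu and sigma2 have closed forms given the
# covariance structure; only the shape parameter (lambda or alpha) is
# profiled numerically.

#' Multivariate-normal log-likelihood on a phylogenetic covariance
#'
#' Density of `y ~ N(mu * 1, sigma2 * V)` evaluated through a Cholesky
#' factorization (never an explicit inverse or determinant of the scaled
#' matrix).
#'
#' @param y Numeric trait vector aligned to the rows of `V`.
#' @param V Phylogenetic covariance matrix.
#' @param mu Root (ancestral) mean.
#' @param sigma2 Evolutionary rate (> 0), trait units squared per Myr.
#' @return Log-likelihood (scalar).
#' @export
mvn_loglik <- function(y, V, mu, sigma2) {
  n <- length(y)
  if (nrow(V) != n || ncol(V) != n)
    stop("length(y) = ", n, " does not match dim(V) = ", nrow(V))
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  ch <- chol_safe(V)
  r <- backsolve(ch, y - mu, transpose = TRUE)
  logdetV <- 2 * sum(log(diag(ch)))
  -n / 2 * log(2 * pi) - n / 2 * log(sigma2) - logdetV / 2 -
    sum(r^2) / (2 * sigma2)
}

# Closed-form ML of (mu, sigma2) for y ~ N(mu 1, sigma2 V), via one
# Cholesky. Returns estimates plus the maximized log-likelihood.
profile_normal_fit <- function(y, V) {
  n <- length(y)
  ch <- chol_safe(V)
  yt <- backsolve(ch, y, transpose = TRUE)
  ot <- backsolve(ch, rep(1, n), transpose = TRUE)
  mu <- sum(ot * yt) / sum(ot * ot)
  rss <- sum((yt - mu * ot)^2)
  sigma2 <- rss / n
  logdetV <- 2 * sum(log(diag(ch)))
  if (sigma2 <= .Machine$double.eps * max(1, stats::var(y))) {
    return(list(mu = mu, sigma2 = 0, loglik = Inf, degenerate = TRUE,
                logdetV = logdetV))
  }
  ll <- -n / 2 * (log(2 * pi) + log(sigma2) + 1) - logdetV / 2
  list(mu = mu, sigma2 = sigma2, loglik = ll, degenerate = FALSE,
       logdetV = logdetV)
}

new_evo_fit <- function(model, mu, sigma2, shape, loglik, n_params, n,
                        degenerate = FALSE, extra = NULL) {
  structure(
    c(list(model = model, mu = mu, sigma2 = sigma2, shape = shape,
           loglik = loglik, n_params = n_params,
           aic = -2 * loglik + 2 * n_params, n = n,
           degenerate = degenerate), extra),
    class = "evo_model_fit")
}

#' @export
print.evo_model_fit <- function(x, ...) {
  shp <- if (is.null(x$shape)) "" else
    sprintf("  %s = %.4g", if (x$model == "OU") "alpha" else "lambda", x$shape)
  cat(sprintf("%s fit (n = %d): mu = %.4g  sigma2 = %.4g%s\n",
              x$model, x$n, x$mu, x$sigma2, shp))
  cat(sprintf("  logLik = %.4f  AIC = %.4f%s\n", x$loglik, x$aic,
              if (x$degenerate) "  [degenerate: constant trait]" else ""))
  invisible(x)
}

check_trait <- function(y, tree) {
  if (is.null(names(y))) {
    if (length(y) != length(tree$tip.label))
      stop("unnamed `y` must have one value per tip")
    names(y) <- tree$tip.label
  }
  missing_tips <- setdiff(tree$tip.label, names(y))
  if (length(missing_tips) > 0)
    stop("trait values missing for tips: ",
         paste(missing_tips, collapse = ", "))
  y <- y[tree$tip.label]
  if (anyNA(y)) stop("`y` contains NA; drop missing species and prune the ",
                     "tree before fitting")
  if (length(y) < 3) stop("need at least 3 tips, got ", length(y))
  y
}

#' Fit Brownian motion to a trait
#'
#' Closed-form ML: `mu = (1'V^-1 y)/(1'V^-1 1)`, `sigma2` the GLS residual
#' quadratic form divided by n. Two parameters.
#'
#' @param y Named trait vector (names matching `tree$tip.label`), or an
#'   unnamed vector in tip order.
#' @param tree Ultrametric `"phylo"`.
#' @return An `"evo_model_fit"`.
#' @export
fit_bm <- function(y, tree) {
  y <- check_trait(y, tree)
  V <- phylo_covariance(tree)
  f <- profile_normal_fit(y, V)
  new_evo_fit("BM", f$mu, f$sigma2, NULL, f$loglik, 2L, length(y),
              degenerate = f$degenerate)
}

#' Fit Pagel's lambda model to a trait
#'
#' Profiles lambda on \[0, 1\]: for each lambda the mean and rate have the
#' BM closed form on the lambda-scaled covariance, and the profile
#' log-likelihood is maximized by bounded one-dimensional optimization
#' (tolerance 1e-8) with both endpoints checked explicitly, since the
#' maximum frequently sits on the boundary. Three parameters.
#'
#' @inheritParams fit_bm
#' @return An `"evo_model_fit"` with `shape` = lambda-hat.
#' @export
fit_lambda <- function(y, tree) {
  y <- check_trait(y, tree)
  V <- phylo_covariance(tree)
  if (profile_normal_fit(y, V)$degenerate)
    stop("trait is constant; lambda is unidentifiable")
  prof <- function(lam) profile_normal_fit(y, lambda_scale(V, lam))$loglik
  opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, prof(0)), c(1, prof(1)))
  best <- cand[which.max(cand[, 2]), ]
  f <- profile_normal_fit(y, lambda_scale(V, best[1]))
  new_evo_fit("LAMBDA", f$mu, f$sigma2, best[1], best[2], 3L, length(y))
}

# Deterministic fan-out of one master seed into per-stage sub-seeds,
# kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + stream) %% 2147483647)
}

#' Fit a single-optimum Ornstein-Uhlenbeck model to a trait
#'
#' Profiles alpha over the OU-transformed covariance [ou_scale()]. The
#' profile surface can be flat or multimodal in alpha, so `n_restarts`
#' local optimizations (on log alpha, box-bounded to
#' `[1e-4/T, 100/T]` with T the tree depth) are launched from random
#' log-uniform starts and the fit with minimum deviance (-2 logLik) is
#' kept. Three parameters.
#'
#' @inheritParams fit_bm
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed from which restart starting points are derived
#'   deterministically.
#' @return An `"evo_model_fit"` with `shape` = alpha-hat and a `restarts`
#'   data frame of per-restart diagnostics.
#' @export
fit_ou <- function(y, tree, n_restarts = 10, seed = 20140506) {
  y <- check_trait(y, tree)
  stopifnot(n_restarts >= 1)
  if (profile_normal_fit(y, phylo_covariance(tree))$degenerate)
    stop("trait is constant; alpha is unidentifiable")
  T_depth <- tree_depth(tree)
  lo <- 1e-4 / T_depth
  hi <- 100 / T_depth
  negprof <- function(la) {
    -profile_normal_fit(y, ou_scale(tree, exp(la)))$loglik
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, 1L))
  starts <- stats::runif(n_restarts, log(lo), log(hi))
  runs <- lapply(starts, function(s) {
    res <- tryCatch(
      stats::nlminb(s, negprof, lower = log(lo), upper = log(hi)),
      error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(start = exp(s), alpha = NA_real_,
                        deviance = NA_real_, converged = FALSE))
    }
    data.frame(start = exp(s), alpha = exp(res$par),
               deviance = 2 * res$objective,
               converged = res$convergence == 0)
  })
  diag_tbl <- do.call(rbind, runs)
  ok <- which(is.finite(diag_tbl$deviance))
  if (length(ok) == 0)
    stop("all OU restarts failed to converge; diagnostics:\n",
         paste(utils::capture.output(print(diag_tbl)), collapse = "\n"))
  best <- ok[which.min(diag_tbl$deviance[ok])]
  alpha_hat <- diag_tbl$alpha[best]
  f <- profile_normal_fit(y, ou_scale(tree, alpha_hat))
  new_evo_fit("OU", f$mu, f$sigma2, alpha_hat, f$loglik, 3L, length(y),
              extra = list(restarts = diag_tbl))
}

# Save/restore .Random.seed so fitting functions do not perturb the
# caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Compare BM, OU and lambda fits for one trait by AIC
#'
#' Fits all three models and applies the delta-AIC >= 4 decision rule:
#' models within `delta_threshold` AIC units of the best are treated as
#' comparably supported.
#'
#' @inheritParams fit_ou
#' @param delta_threshold AIC-difference threshold (default 4).
#' @return An object of class `"evo_model_comparison"`: list with `fits`,
#'   `aic`, `delta_aic` and `preferred`.
#' @export
model_table <- function(y, tree, n_restarts = 10, seed = 20140506,
                        delta_threshold = 4) {
  fits <- list(BM = fit_bm(y, tree),
               OU = fit_ou(y, tree, n_restarts = n_restarts, seed = seed),
               LAMBDA = fit_lambda(y, tree))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  delta <- aic - min(aic)
  structure(list(fits = fits, aic = aic, delta_aic = delta,
                 preferred = names(delta)[delta < delta_threshold],
                 delta_threshold = delta_threshold),
            class = "evo_model_comparison")
}

#' @export
print.evo_model_comparison <- function(x, ...) {
  tab <- data.frame(
    model = names(x$fits),
    loglik = vapply(x$fits, `[[`, numeric(1), "loglik"),
    n_params = vapply(x$fits, `[[`, numeric(1), "n_params"),
    AIC = x$aic, dAIC = x$delta_aic,
    preferred = names(x$fits) %in% x$preferred)
  print(tab, row.names = FALSE, digits = 6)
  invisible(x)
}
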