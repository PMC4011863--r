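# Pagel's-lambda phylogenetic signal, per trait and in batteries.

#' Estimate phylogenetic signal (Pagel's lambda) for one trait
#'
#' Lambda-hat comes from the ML lambda-model fit; likelihood-ratio tests
#' against the no-signal (lambda = 0) and Brownian (lambda = 1) boundaries
#' use the 50:50 chi-square mixture convention (halved chi-square(1)
#' p-value), appropriate when the estimate can sit on the boundary of the
#' parameter space.
#'
#' @param y Named trait vector; `NA` species are dropped and the tree
#'   pruned (at least 3 values required).
#' @param tree Ultrametric `"phylo"`.
#' @param trait_name Label carried into the result.
#' @return A `"signal_result"`: `trait_name`, `lambda_hat`, the three
#'   log-likelihoods and the two boundary p-values. The p-value convention
#'   is recorded in attribute `"p_convention"`.
#' @export
pagels_lambda <- function(y, tree, trait_name = deparse(substitute(y))) {
  if (is.null(names(y))) {
    if (length(y) != length(tree$tip.label))
      stop("unnamed `y` must have one value per tip")
    names(y) <- tree$tip.label
  }
  keep <- tree$tip.label[tree$tip.label %in% names(y)]
  keep <- keep[!is.na(y[keep])]
  if (length(keep) < 3)
    stop("need at least 3 non-missing values, got ", length(keep))
  tr <- if (length(keep) < length(tree$tip.label))
    ape::keep.tip(tree, keep) else tree
  yv <- y[tr$tip.label]
  if (stats::sd(yv) == 0)
    stop("trait `", trait_name, "` is constant; signal is unidentifiable")
  fit <- fit_lambda(yv, tr)
  V <- phylo_covariance(tr)
  ll0 <- profile_normal_fit(yv, lambda_scale(V, 0))$loglik
  ll1 <- profile_normal_fit(yv, lambda_scale(V, 1))$loglik
  boundary_p <- function(ll_constrained) {
    lr <- 2 * (fit$loglik - ll_constrained)
    if (lr <= 0) 1 else 0.5 * stats::pchisq(lr, 1, lower.tail = FALSE)
  }
  structure(list(trait_name = trait_name, lambda_hat = fit$shape,
                 loglik_at_hat = fit$loglik, loglik_at_0 = ll0,
                 loglik_at_1 = ll1, p_vs_0 = boundary_p(ll0),
                 p_vs_1 = boundary_p(ll1), n = fit$n),
            class = "signal_result",
            p_convention = "halved chi-square(1) (50:50 boundary mixture)")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Pagel's lambda for %s (n = %d): lambda = %.4g\n",
              x$trait_name, x$n, x$lambda_hat))
  cat(sprintf("  logLik %.4f (at hat), %.4f (lambda=0), %.4f (lambda=1)\n",
              x$loglik_at_hat, x$loglik_at_0, x$loglik_at_1))
  cat(sprintf("  p vs lambda=0: %.4g   p vs lambda=1: %.4g\n",
              x$p_vs_0, x$p_vs_1))
  invisible(x)
}

#' Default variables tested for phylogenetic signal
#'
#' The eight variables of the case study's signal table.
#'
#' @return Character vector of column names.
#' @export
default_signal_variables <- function() {
  c("mean_annual_precip", "mean_precip_wettest_quarter",
    "mean_precip_seasonality", "logQ", "min_annual_precip",
    "midpoint_larval_period", "midpoint_hatching_time", "genome_size")
}

#' Phylogenetic signal for a battery of traits
#'
#' @param traits Data frame with a `species` column and the named trait
#'   columns.
#' @param tree Ultrametric `"phylo"`.
#' @param variables Column names to test, in output order; defaults to
#'   [default_signal_variables()].
#' @return Data frame with one row per variable: `variable`, `n`,
#'   `lambda`, `loglik`, `p_vs_0`, `p_vs_1`.
#' @export
signal_battery <- function(traits, tree,
                           variables = default_signal_variables()) {
  if (!"species" %in% names(traits))
    stop("`traits` must contain a `species` column")
  unknown <- setdiff(variables, names(traits))
  if (length(unknown) > 0)
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         "; available: ",
         paste(setdiff(names(traits), "species"), collapse = ", "))
  rows <- lapply(variables, function(v) {
    yv <- stats::setNames(traits[[v]], traits$species)
    s <- pagels_lambda(yv, tree, trait_name = v)
    data.frame(variable = v, n = s$n, lambda = s$lambda_hat,
               loglik = s$loglik_at_hat, p_vs_0 = s$p_vs_0,
               p_vs_1 = s$p_vs_1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
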