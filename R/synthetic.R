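# Synthetic trees, traits and locality tables with the statistical
# structure the analysis assumes: a 16-species clade of depth ~150 Myr,
# developmental traits in days evolving with phylogenetic signal, genome
# sizes (picograms) with near-Brownian signal and patchy coverage, and
# museum-style locality tables with within-species climate dispersion.
#
# Seed scheme: every generator takes one integer master seed and derives
# per-stage sub-seeds as (seed * 7919 + stream) mod (2^31 - 1)
# (child_seed()), so stages are independently regeneratable and the whole
# fixture is bit-reproducible for a fixed seed.

#' Simulate a pure-birth (Yule) ultrametric tree
#'
#' Pure-birth simulation conditioned on the number of tips (via
#' [ape::rphylo()]), then rescaled so the root-to-tip depth equals `depth`
#' exactly. Deterministic given `seed`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param depth Root-to-tip depth, Myr.
#' @param seed Integer seed.
#' @return Ultrametric `"phylo"` with tips `sp01`, `sp02`, ...
#' @export
sim_yule_tree <- function(n_tips, depth = 150, seed = 1) {
  stopifnot(n_tips >= 3, depth > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, 11L))
  tr <- ape::rphylo(n_tips, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length * (depth / tree_depth(tr))
  tr$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tr
}

#' Simulate one trait on a tree under BM, OU or the lambda model
#'
#' One draw from `N(mu * 1, sigma2 * V)` where `V` is the Brownian,
#' lambda-scaled or OU-transformed covariance, sampled through a Cholesky
#' factor of the covariance.
#'
#' @param tree Ultrametric `"phylo"`.
#' @param model `"BM"`, `"LAMBDA"` or `"OU"`.
#' @param sigma2 Evolutionary rate (> 0).
#' @param shape Lambda in \[0, 1\] (LAMBDA) or alpha > 0 (OU); ignored for
#'   BM.
#' @param mu Root mean.
#' @param seed Integer seed.
#' @return Named numeric vector in tip order.
#' @export
sim_trait <- function(tree, model = c("BM", "LAMBDA", "OU"), sigma2 = 1,
                      shape = NULL, mu = 0, seed = 1) {
  model <- match.arg(model)
  stopifnot(sigma2 >= 0)
  V <- switch(model,
              BM = phylo_covariance(tree),
              LAMBDA = lambda_scale(phylo_covariance(tree), shape),
              OU = ou_scale(tree, shape))
  n <- nrow(V)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, 13L))
  z <- stats::rnorm(n)
  y <- if (sigma2 == 0) rep(mu, n) else
    as.numeric(mu + sqrt(sigma2) * crossprod(chol_safe(V), z))
  stats::setNames(y, rownames(V))
}

#' Simulate a regression pair with phylogenetically structured residuals
#'
#' `x` evolves under BM; `y = beta0 + beta1 * x + e` with residuals drawn
#' under the lambda-scaled covariance. `beta1 = 0` gives the phylogenetic
#' null for type-I-error studies.
#'
#' @param tree Ultrametric `"phylo"`.
#' @param beta0,beta1 Regression coefficients.
#' @param resid_lambda Pagel's lambda of the residuals, \[0, 1\].
#' @param sigma2 Residual rate (> 0).
#' @param sigma2_x BM rate of the predictor.
#' @param seed Integer seed.
#' @return List with named vectors `x` and `y`.
#' @export
sim_regression_pair <- function(tree, beta0 = 0, beta1 = 0,
                                resid_lambda = 1, sigma2 = 1,
                                sigma2_x = 1, seed = 1) {
  x <- sim_trait(tree, "BM", sigma2 = sigma2_x, seed = child_seed(seed, 17L))
  eps <- sim_trait(tree, "LAMBDA", sigma2 = sigma2, shape = resid_lambda,
                   seed = child_seed(seed, 19L))
  list(x = x, y = beta0 + beta1 * x + eps)
}

# Log-uniform integers in [lo, hi]; matches the right-skewed per-species
# record counts typical of museum databases.
rint_loguniform <- function(n, lo, hi) {
  pmin(hi, pmax(lo, round(exp(stats::runif(n, log(lo), log(hi))))))
}

#' Generate a complete synthetic study fixture
#'
#' Emulates the compiled data of the case study: a 16-species ultrametric
#' tree of depth 150 Myr; minimum larval periods (days) under BM; minimum
#' hatching times regressed on larval period with lambda-structured
#' residuals; midpoints at or above the minima; genome sizes (pg) with
#' strong signal and only `n_genome` species covered; and a locality table
#' with 3-322 records per species whose bioclim values scatter around
#' species-level centres that themselves carry phylogenetic signal
#' (precipitation seasonality deliberately carries none). All knobs default
#' to the study conditions; `beta1`/`resid_lambda`/`resid_sigma2` control
#' the planted hatching-vs-larval effect for power studies.
#'
#' @param seed Integer master seed.
#' @param dir Optional directory; when given, writes `tree.nwk`,
#'   `traits.csv`, `localities.csv` and `manifest.json` there.
#' @param n_species,depth Tree size and depth (Myr).
#' @param beta0,beta1,resid_lambda,resid_sigma2 Planted regression of
#'   minimum hatching time on minimum larval period.
#' @param sigma2_larval BM rate of minimum larval period (days^2/Myr).
#' @param n_genome Species with non-missing genome size.
#' @param min_localities,max_localities Range of per-species record counts.
#' @return List: `tree`, `traits` (species x variable table including the
#'   climate summary columns), `localities`, `params`.
#' @export
make_study_fixture <- function(seed = 1, dir = NULL, n_species = 16,
                               depth = 150, beta0 = 1, beta1 = 0.15,
                               resid_lambda = 0.6, resid_sigma2 = 0.02,
                               sigma2_larval = 2, n_genome = 8,
                               min_localities = 3, max_localities = 322) {
  tree <- sim_yule_tree(n_species, depth, seed = child_seed(seed, 1L))
  sp <- tree$tip.label

  pair <- sim_regression_pair(tree, beta0 = beta0, beta1 = beta1,
                              resid_lambda = resid_lambda,
                              sigma2 = resid_sigma2,
                              sigma2_x = sigma2_larval,
                              seed = child_seed(seed, 2L))
  min_larval <- pmax(3, pair$x + 40)        # days; floor at 3
  min_hatch <- pmax(0.5, pair$y + beta1 * 40)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(child_seed(seed, 3L))
  mid_larval <- min_larval * stats::runif(n_species, 1.2, 2.0)
  mid_hatch <- min_hatch * stats::runif(n_species, 1.1, 1.8)
  genome <- pmax(0.8, sim_trait(tree, "LAMBDA", sigma2 = 0.05, shape = 0.98,
                                mu = 4, seed = child_seed(seed, 4L)))
  genome[sample.int(n_species, n_species - n_genome)] <- NA

  # species-level climate centres (bio15 is iid: no signal, as observed)
  c_bio12 <- pmax(80, sim_trait(tree, "LAMBDA", sigma2 = 400, shape = 0.7,
                                mu = 650, seed = child_seed(seed, 5L)))
  c_bio5 <- sim_trait(tree, "LAMBDA", sigma2 = 0.08, shape = 0.7, mu = 31,
                      seed = child_seed(seed, 6L))
  c_gap <- pmax(8, sim_trait(tree, "BM", sigma2 = 0.15, mu = 26,
                             seed = child_seed(seed, 7L)))
  c_bio6 <- c_bio5 - c_gap
  c_bio15 <- pmax(5, stats::rnorm(n_species, 55, 20))
  c_bio16 <- pmax(20, 0.45 * c_bio12 + stats::rnorm(n_species, 0, 25))
  names(c_bio15) <- names(c_bio16) <- sp

  n_loc <- rint_loguniform(n_species, min_localities, max_localities)
  names(n_loc) <- sp
  lon0 <- stats::runif(n_species, -118, -70)
  lat0 <- stats::runif(n_species, 26, 46)
  elev0 <- stats::runif(n_species, 100, 1800)
  loc <- do.call(rbind, lapply(seq_along(sp), function(i) {
    k <- n_loc[i]
    bio5 <- c_bio5[i] + stats::rnorm(k, 0, 1.5)
    gap <- pmax(0.5, c_gap[i] + stats::rnorm(k, 0, 2))
    data.frame(
      species = sp[i],
      lon = pmin(180, pmax(-180, lon0[i] + stats::rnorm(k, 0, 1.5))),
      lat = pmin(90, pmax(-90, lat0[i] + stats::rnorm(k, 0, 1.2))),
      elevation = pmax(0, elev0[i] + stats::rnorm(k, 0, 150)),
      in_range = TRUE,
      bio5 = bio5,
      bio6 = bio5 - gap,
      bio10 = bio5 - 4 + stats::rnorm(k, 0, 0.8),
      bio11 = bio5 - gap + 5 + stats::rnorm(k, 0, 0.8),
      bio12 = pmax(5, c_bio12[i] + stats::rnorm(k, 0, 80)),
      bio15 = pmax(1, c_bio15[i] + stats::rnorm(k, 0, 5)),
      bio16 = pmax(2, c_bio16[i] + stats::rnorm(k, 0, 30)),
      stringsAsFactors = FALSE)
  }))

  summ <- summarize_species(loc)
  matched_idx <- vapply(sp, function(s) {
    rows <- which(loc$species == s)
    rows[sample.int(length(rows), 1)]
  }, integer(1))

  traits <- data.frame(
    species = sp,
    minimum_larval_period = as.numeric(min_larval),
    midpoint_larval_period = as.numeric(mid_larval),
    minimum_hatching_time = as.numeric(min_hatch),
    midpoint_hatching_time = as.numeric(mid_hatch),
    genome_size = as.numeric(genome),
    matched_larval_period =
      as.numeric(min_larval) * stats::runif(n_species, 1.0, 1.15),
    matched_annual_precip = loc$bio12[matched_idx],
    stringsAsFactors = FALSE)
  traits <- merge(traits, climate_summary_variables(summ), by = "species",
                  sort = FALSE)

  params <- list(seed = seed, n_species = n_species, depth = depth,
                 beta0 = beta0, beta1 = beta1, resid_lambda = resid_lambda,
                 resid_sigma2 = resid_sigma2, sigma2_larval = sigma2_larval,
                 n_genome = n_genome, min_localities = min_localities,
                 max_localities = max_localities,
                 temperature_units = "celsius")
  out <- list(tree = tree, traits = traits, localities = loc,
              params = params)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_newick(tree, file.path(dir, "tree.nwk"))
    utils::write.csv(traits, file.path(dir, "traits.csv"),
                     row.names = FALSE)
    utils::write.csv(loc, file.path(dir, "localities.csv"),
                     row.names = FALSE)
    jsonlite::write_json(params, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

# Map a summarize_species() table onto the analysis variable names.
climate_summary_variables <- function(summ) {
  data.frame(species = summ$species,
             mean_annual_precip = summ$bio12_mean,
             mean_precip_wettest_quarter = summ$bio16_mean,
             mean_precip_seasonality = summ$bio15_mean,
             min_annual_precip = summ$bio12_min,
             logQ = summ$logQ,
             logQ2 = summ$logQ2,
             stringsAsFactors = FALSE)
}
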