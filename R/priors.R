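# Fossil calibration priors for divergence-time dating: the offset
# lognormal (fossil minimum age as hard offset, "mean" given in real
# space as in BEAUti, spread as the log-space sd) and the normal.

#' Offset-lognormal calibration prior
#'
#' Age = offset + L with L lognormal; `mean_real` is the real-space mean of
#' the unshifted lognormal (so the log-space mean is
#' `log(mean_real) - sdlog^2/2`) and `sdlog` its log-space standard
#' deviation. The offset is the minimum age of the oldest assignable
#' fossil.
#'
#' @param offset Hard minimum age, Myr (>= 0).
#' @param mean_real Real-space mean of the unshifted lognormal, Myr (> 0).
#' @param sdlog Log-space standard deviation (> 0).
#' @return A `"calibration_prior"`.
#' @examples
#' p <- prior_offset_lognormal(50.3, 5, 1)
#' prior_interval(p) # c(50.9, 66.0) after rounding to 0.1 Myr
#' @export
prior_offset_lognormal <- function(offset, mean_real, sdlog) {
  stopifnot(offset >= 0, mean_real > 0, sdlog > 0)
  structure(list(kind = "offset_lognormal", offset = offset,
                 mean_real = mean_real, sdlog = sdlog,
                 meanlog = log(mean_real) - sdlog^2 / 2),
            class = "calibration_prior")
}

#' Normal calibration prior
#'
#' @param mean Mean age, Myr.
#' @param sd Standard deviation, Myr (> 0).
#' @return A `"calibration_prior"`.
#' @export
prior_normal <- function(mean, sd) {
  stopifnot(sd > 0)
  structure(list(kind = "normal", mean = mean, sd = sd),
            class = "calibration_prior")
}

#' @export
print.calibration_prior <- function(x, ...) {
  if (x$kind == "offset_lognormal")
    cat(sprintf(
      "offset-lognormal prior: offset %.4g + lognormal(mean %.4g Myr, sdlog %.4g)\n",
      x$offset, x$mean_real, x$sdlog))
  else
    cat(sprintf("normal prior: mean %.4g Myr, sd %.4g Myr\n", x$mean, x$sd))
  iv <- prior_interval(x)
  cat(sprintf("  5%%-95%% interval: %.1f-%.1f Myr\n", iv[1], iv[2]))
  invisible(x)
}

#' Quantile of a calibration prior
#'
#' @param prior A `"calibration_prior"`.
#' @param q Probability in (0, 1) (vectorized).
#' @return Age(s) in Myr.
#' @export
prior_quantile <- function(prior, q) {
  stopifnot(inherits(prior, "calibration_prior"))
  if (any(q <= 0 | q >= 1)) stop("`q` must lie strictly in (0, 1)")
  switch(prior$kind,
         offset_lognormal =
           prior$offset + stats::qlnorm(q, prior$meanlog, prior$sdlog),
         normal = stats::qnorm(q, prior$mean, prior$sd))
}

#' CDF of a calibration prior
#'
#' @param prior A `"calibration_prior"`.
#' @param age Age(s) in Myr.
#' @return Probability of an age at most `age`.
#' @export
prior_cdf <- function(prior, age) {
  stopifnot(inherits(prior, "calibration_prior"))
  switch(prior$kind,
         offset_lognormal =
           stats::plnorm(age - prior$offset, prior$meanlog, prior$sdlog),
         normal = stats::pnorm(age, prior$mean, prior$sd))
}

#' Density of a calibration prior
#'
#' @param prior A `"calibration_prior"`.
#' @param age Age(s) in Myr.
#' @return Density value(s); zero below the offset for the lognormal kind.
#' @export
prior_density <- function(prior, age) {
  stopifnot(inherits(prior, "calibration_prior"))
  switch(prior$kind,
         offset_lognormal =
           stats::dlnorm(age - prior$offset, prior$meanlog, prior$sdlog),
         normal = stats::dnorm(age, prior$mean, prior$sd))
}

#' Central quantile interval of a calibration prior
#'
#' Defaults to the 5th-95th percentile span, the convention under which the
#' dating literature's printed "95%" calibration intervals reproduce.
#' Rounding is left to the caller (presentation convention: 0.1 Myr).
#'
#' @param prior A `"calibration_prior"`.
#' @param lower_q,upper_q Quantile bounds, `0 < lower_q < upper_q < 1`.
#' @return Numeric length-2 vector (lower, upper), Myr.
#' @export
prior_interval <- function(prior, lower_q = 0.05, upper_q = 0.95) {
  if (!(lower_q > 0 && lower_q < upper_q && upper_q < 1))
    stop("need 0 < lower_q < upper_q < 1")
  prior_quantile(prior, c(lower_q, upper_q))
}
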