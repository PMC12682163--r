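#' Distribution specification for a model parameter
#'
#' The atom of the model's parameter table: a parameter is carried as its
#' natural-scale mean and uncertainty SD together with the sampling family
#' used in probabilistic sensitivity analysis. An SD of zero always denotes
#' a structural constant and is stored with family \code{"fixed"}.
#'
#' @param family one of \code{"beta"}, \code{"lognormal"}, \code{"fixed"}.
#' @param mean parameter mean on the natural scale. Beta parameters must lie
#'   in \[0,1\] (0 or 1 only with \code{sd = 0}); lognormal means must be
#'   positive unless the value is a structural zero with \code{sd = 0}.
#' @param sd uncertainty standard deviation on the natural scale; \code{0}
#'   collapses the spec to the fixed family.
#' @return an object of class \code{"dist_spec"}.
#' @examples
#' dist_spec("beta", 0.910, 0.082)
#' dist_spec("lognormal", 1176.55, 1587.10)
#' @export
dist_spec <- function(family = c("beta", "lognormal", "fixed"), mean, sd = 0) {
  family <- match.arg(family)
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd), sd >= 0)
  if (sd == 0) family <- "fixed"
  if (family == "beta") {
    if (mean <= 0 || mean >= 1)
      stop("beta family requires mean in (0,1); use sd = 0 for boundary values")
    if (sd^2 >= mean * (1 - mean))
      stop(sprintf("infeasible beta moments: sd^2 = %.6g >= mean(1-mean) = %.6g",
                   sd^2, mean * (1 - mean)))
  }
  if (family == "lognormal" && mean <= 0)
    stop("lognormal family requires mean > 0")
  structure(list(family = family, mean = mean, sd = sd), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec %s mean=%g sd=%g>\n", x$family, x$mean, x$sd))
  invisible(x)
}

#' Beta shape parameters from a mean and standard deviation
#'
#' Method-of-moments parameterisation: with
#' \eqn{\nu = m(1-m)/s^2 - 1}, \eqn{\alpha = m\nu} and
#' \eqn{\beta = (1-m)\nu}. The implied Beta distribution has exactly the
#' requested mean and SD.
#'
#' @param mean mean in (0,1).
#' @param sd standard deviation; must satisfy \code{sd^2 < mean*(1-mean)}
#'   and be strictly positive (structural constants use the fixed family).
#' @return named numeric vector \code{c(alpha=, beta=)}.
#' @examples
#' beta_from_moments(0.5, sqrt(1/12)) # the uniform distribution
#' @export
beta_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd))
  if (any(sd <= 0)) stop("sd must be > 0; an sd of 0 is a fixed value, not a Beta")
  if (any(mean <= 0 | mean >= 1)) stop("mean must lie in (0,1)")
  if (any(sd^2 >= mean * (1 - mean)))
    stop("infeasible moments: sd^2 must be < mean*(1-mean)")
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Lognormal parameters from a mean and standard deviation
#'
#' Moment matching on the natural scale:
#' \eqn{\sigma^2 = \log(1 + s^2/m^2)}, \eqn{\mu = \log m - \sigma^2/2},
#' so that \eqn{\exp(\mu + \sigma^2/2) = m} exactly.
#'
#' @param mean natural-scale mean, > 0.
#' @param sd natural-scale standard deviation, > 0 (an sd of 0 is a fixed
#'   value and is refused).
#' @return named numeric vector \code{c(meanlog=, sdlog=)}.
#' @export
lognormal_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd))
  if (any(mean <= 0)) stop("mean must be > 0 for a lognormal")
  if (any(sd <= 0)) stop("sd must be > 0; an sd of 0 is a fixed value, not a lognormal")
  sigma2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Draw samples from a distribution specification
#'
#' @param spec a \code{\link{dist_spec}}.
#' @param n number of draws.
#' @return numeric vector of length \code{n}; fixed specs return the mean
#'   replicated.
#' @export
sample_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"), n >= 0)
  switch(spec$family,
    fixed = rep(spec$mean, n),
    beta = {
      ab <- beta_from_moments(spec$mean, spec$sd)
      stats::rbeta(n, ab[["alpha"]], ab[["beta"]])
    },
    lognormal = {
      ms <- lognormal_from_moments(spec$mean, spec$sd)
      stats::rlnorm(n, ms[["meanlog"]], ms[["sdlog"]])
    })
}
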