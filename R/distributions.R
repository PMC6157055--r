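#' Sensitivity-analysis distributions
#'
#' Constructors for the four distribution kinds used to express parameter
#' uncertainty in the probabilistic sensitivity analysis (PSA): Beta for
#' probabilities (shape parameters are the counts of patients with and
#' without the event of interest), Poisson for resource-use means, Gamma for
#' costs (scale = variance / mean, shape = mean / scale), and a degenerate
#' `fixed` kind for quantities without variance data.
#'
#' @param a First Beta shape (events observed).
#' @param b Second Beta shape (non-events observed).
#' @param lambda Poisson mean.
#' @param shape Gamma shape.
#' @param scale Gamma scale.
#' @param value Degenerate point mass.
#' @param currency Currency the distribution is parameterised in, `"USD"`
#'   or `"COP"`. Gamma cost distributions are typically on the Colombian
#'   peso scale and are converted after sampling.
#' @return An object of class `bia_dist`.
#' @examples
#' dist_mean(dist_beta(45, 55)) # 0.45
#' @name bia_dist
NULL

#' @rdname bia_dist
#' @export
dist_beta <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), a > 0, b > 0)
  structure(list(kind = "beta", a = a, b = b, currency = "USD"),
            class = "bia_dist")
}

#' @rdname bia_dist
#' @export
dist_poisson <- function(lambda) {
  stopifnot(is.numeric(lambda), lambda > 0)
  structure(list(kind = "poisson", lam = lambda, currency = "USD"),
            class = "bia_dist")
}

#' @rdname bia_dist
#' @export
dist_gamma <- function(shape, scale, currency = c("USD", "COP")) {
  stopifnot(is.numeric(shape), is.numeric(scale), shape > 0, scale > 0)
  currency <- match.arg(currency)
  structure(list(kind = "gamma", a = shape, b = scale, currency = currency),
            class = "bia_dist")
}

#' @rdname bia_dist
#' @export
dist_fixed <- function(value) {
  stopifnot(is.numeric(value))
  structure(list(kind = "fixed", value = value, currency = "USD"),
            class = "bia_dist")
}

#' @export
print.bia_dist <- function(x, ...) {
  desc <- switch(x$kind,
    beta    = sprintf("Beta(a = %g, b = %g)", x$a, x$b),
    poisson = sprintf("Poisson(lambda = %g)", x$lam),
    gamma   = sprintf("Gamma(shape = %g, scale = %g) [%s]", x$a, x$b,
                      x$currency),
    fixed   = sprintf("Fixed(%g)", x$value))
  cat(desc, "\n")
  invisible(x)
}

#' Analytic mean of a PSA distribution
#'
#' @param d A [bia_dist] object.
#' @return The analytic expectation: `a/(a+b)` for Beta, `lambda` for
#'   Poisson, `shape * scale` for Gamma (on the scale the distribution is
#'   parameterised in), the point mass for `fixed`.
#' @export
dist_mean <- function(d) {
  stopifnot(inherits(d, "bia_dist"))
  switch(d$kind,
    beta    = d$a / (d$a + d$b),
    poisson = d$lam,
    gamma   = d$a * d$b,
    fixed   = d$value)
}

#' Draw from a PSA distribution
#'
#' Uses the current R random stream, so draws are reproducible under
#' `set.seed()`. The `fixed` kind returns its value exactly.
#'
#' @param d A [bia_dist] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`, on the distribution's own scale
#'   (COP-scale Gamma draws are not currency-converted here).
#' @export
dist_sample <- function(d, n = 1) {
  stopifnot(inherits(d, "bia_dist"), n >= 1)
  switch(d$kind,
    beta    = stats::rbeta(n, d$a, d$b),
    poisson = stats::rpois(n, d$lam),
    gamma   = stats::rgamma(n, shape = d$a, scale = d$b),
    fixed   = rep(d$value, n))
}

#' Reconcile a parameter's point estimate with its PSA distribution
#'
#' Several published parameter rows carry a distribution whose analytic mean
#' disagrees with the printed point estimate (e.g. a prescription
#' probability of 0.52 alongside Beta(29, 31), mean 0.483). The three
#' policies resolve this:
#' \describe{
#'   \item{point_estimate}{Keep both as printed: deterministic runs use the
#'     point estimate, the PSA samples the printed distribution.}
#'   \item{distribution_mean}{Replace the point estimate by the
#'     distribution's analytic mean (currency-converted for COP-scale
#'     Gamma).}
#'   \item{rescaled_distribution}{Rescale the distribution so its mean
#'     equals the printed point estimate: Gamma adjusts scale only, Poisson
#'     sets lambda, Beta holds a+b fixed and moves a.}
#' }
#'
#' @param p A `bia_parameter` (see [load_parameters()]).
#' @param policy One of `"point_estimate"`, `"distribution_mean"`,
#'   `"rescaled_distribution"`.
#' @param fx_cop_per_usd Exchange rate used to move between a USD point
#'   estimate and a COP-scale Gamma distribution.
#' @return The reconciled parameter.
#' @export
reconcile <- function(p, policy = c("point_estimate", "distribution_mean",
                                    "rescaled_distribution"),
                      fx_cop_per_usd = 2877) {
  policy <- match.arg(policy)
  stopifnot(inherits(p, "bia_parameter"))
  if (policy == "point_estimate") return(p)
  if (is.null(p$dist)) {
    stop("parameter '", p$name, "' has no distribution to reconcile")
  }
  d <- p$dist
  fx <- if (identical(d$currency, "COP")) fx_cop_per_usd else 1
  if (policy == "distribution_mean") {
    if (d$kind == "fixed") return(p)
    p$estimate <- dist_mean(d) / fx
    return(p)
  }
  # rescaled_distribution: distribution mean moved onto the point estimate
  target <- p$estimate * fx
  p$dist <- switch(d$kind,
    fixed = dist_fixed(p$estimate),
    poisson = dist_poisson(target),
    gamma = dist_gamma(d$a, target / d$a,
                       currency = if (fx == 1) "USD" else "COP"),
    beta = {
      if (target <= 0 || target >= 1) {
        stop("cannot rescale beta distribution of '", p$name,
             "' to mean ", target, " outside (0, 1)")
      }
      n <- d$a + d$b
      dist_beta(target * n, (1 - target) * n)
    })
  p
}
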