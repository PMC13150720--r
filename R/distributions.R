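#' Specify an uncertain model parameter
#'
#' A `dist_spec` couples a point value (used in deterministic analyses) with a
#' sampling distribution (used in probabilistic sensitivity analysis). The
#' supported families follow standard practice for decision models: beta for
#' probabilities and utilities, Dirichlet for competing transition rows, gamma
#' for costs, lognormal for hazard/risk ratios, normal for unbounded
#' quantities, and `fixed` for parameters held constant.
#'
#' The point value of a spec is its distribution mean (the value itself for
#' `fixed`); see [spec_mean()].
#'
#' @param kind One of `"fixed"`, `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"normal"`, `"dirichlet"`.
#' @param parameters Numeric vector of family parameters: `fixed` takes one
#'   value; `beta` takes `(shape1, shape2)`, both > 0; `gamma` takes
#'   `(shape, scale)`, both > 0; `lognormal` takes `(meanlog, sdlog)`;
#'   `normal` takes `(mean, sd)`; `dirichlet` takes a vector of
#'   concentrations, all > 0 (named by destination when used for a
#'   transition row).
#' @return An object of class `dist_spec`.
#' @export
#' @examples
#' dist_spec("beta", c(8, 2))          # a utility around 0.8
#' dist_spec("fixed", 0.03)            # a constant
#' spec_mean(dist_spec("gamma", c(4, 25000)))
dist_spec <- function(kind = c("fixed", "beta", "gamma", "lognormal",
                               "normal", "dirichlet"),
                      parameters) {
  kind <- match.arg(kind)
  parameters <- unlist(parameters)
  if (!is.numeric(parameters) || anyNA(parameters)) {
    stop("dist_spec parameters must be numeric and non-missing", call. = FALSE)
  }
  np <- length(parameters)
  switch(kind,
    fixed = if (np != 1L)
      stop("a fixed spec has exactly one value", call. = FALSE),
    beta = if (np != 2L || any(parameters <= 0))
      stop("beta spec needs two positive shape parameters", call. = FALSE),
    gamma = if (np != 2L || any(parameters <= 0))
      stop("gamma spec needs positive shape and scale", call. = FALSE),
    lognormal = if (np != 2L || parameters[2L] < 0)
      stop("lognormal spec needs (meanlog, sdlog >= 0)", call. = FALSE),
    normal = if (np != 2L || parameters[2L] < 0)
      stop("normal spec needs (mean, sd >= 0)", call. = FALSE),
    dirichlet = if (np < 2L || any(parameters <= 0))
      stop("dirichlet spec needs >= 2 positive concentrations", call. = FALSE)
  )
  structure(list(kind = kind, parameters = parameters), class = "dist_spec")
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' @export
print.dist_spec <- function(x, ...) {
  p <- x$parameters
  lbl <- if (is.null(names(p))) paste(signif(p, 6), collapse = ", ")
         else paste(names(p), signif(p, 6), sep = "=", collapse = ", ")
  cat(sprintf("<dist_spec %s(%s)>\n", x$kind, lbl))
  invisible(x)
}

#' Point value (mean) of a distribution spec
#'
#' @param spec A [dist_spec()].
#' @return The distribution mean; for `dirichlet`, the normalized
#'   concentration vector.
#' @export
spec_mean <- function(spec) {
  stopifnot(is_dist_spec(spec))
  p <- spec$parameters
  switch(spec$kind,
    fixed     = unname(p),
    beta      = unname(p[1L] / (p[1L] + p[2L])),
    gamma     = unname(p[1L] * p[2L]),
    lognormal = unname(exp(p[1L] + p[2L]^2 / 2)),
    normal    = unname(p[1L]),
    dirichlet = p / sum(p)
  )
}

#' Draw from a distribution spec
#'
#' Sampling uses R's active RNG stream; callers control reproducibility with
#' `set.seed()`. A `fixed` spec always returns its value.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`, or for `dirichlet` an
#'   `n x k` matrix whose rows sum to 1.
#' @export
spec_sample <- function(spec, n = 1L) {
  stopifnot(is_dist_spec(spec), n >= 1L)
  p <- spec$parameters
  switch(spec$kind,
    fixed     = rep(unname(p), n),
    beta      = stats::rbeta(n, p[1L], p[2L]),
    gamma     = stats::rgamma(n, shape = p[1L], scale = p[2L]),
    lognormal = stats::rlnorm(n, meanlog = p[1L], sdlog = p[2L]),
    normal    = stats::rnorm(n, mean = p[1L], sd = p[2L]),
    dirichlet = {
      k <- length(p)
      g <- matrix(stats::rgamma(n * k, shape = rep(p, each = n)), n, k)
      out <- g / rowSums(g)
      colnames(out) <- names(p)
      out
    }
  )
}

#' Beta spec from a mean and standard error
#'
#' Method-of-moments construction used when a probability or utility is
#' reported as mean (SE); standard practice for PSA inputs.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error, with `se^2 < mean (1 - mean)`.
#' @return A beta [dist_spec()].
#' @export
beta_spec_from_moments <- function(mean, se) {
  if (mean <= 0 || mean >= 1) stop("mean must be in (0, 1)", call. = FALSE)
  v <- se^2
  if (v >= mean * (1 - mean)) stop("se too large for a beta", call. = FALSE)
  nu <- mean * (1 - mean) / v - 1
  dist_spec("beta", c(mean * nu, (1 - mean) * nu))
}

#' Gamma spec from a mean and standard error
#'
#' @param mean Positive mean.
#' @param se Positive standard error.
#' @return A gamma [dist_spec()].
#' @export
gamma_spec_from_moments <- function(mean, se) {
  if (mean <= 0 || se <= 0) stop("mean and se must be positive", call. = FALSE)
  shape <- (mean / se)^2
  dist_spec("gamma", c(shape, mean / shape))
}

#' Lognormal spec from a median and 95% interval
#'
#' Useful for risk or hazard ratios reported as `median (lo, hi)`; the sdlog
#' is `(log(hi) - log(lo)) / (2 * 1.96)`.
#'
#' @param median Positive central value.
#' @param lo,hi Positive 95% interval bounds, `lo < hi`.
#' @return A lognormal [dist_spec()].
#' @export
lognormal_spec_from_ci <- function(median, lo, hi) {
  if (any(c(median, lo, hi) <= 0) || lo >= hi)
    stop("need 0 < lo < hi and median > 0", call. = FALSE)
  dist_spec("lognormal", c(log(median), (log(hi) - log(lo)) / (2 * stats::qnorm(0.975))))
}
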