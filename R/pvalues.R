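# Gumbel (type-I extreme value, right-tail / maximum convention)
# CDF F(x) = exp(-exp(-(x - mu) / beta))

dgumbel <- function(x, location = 0, scale = 1, log = FALSE) {
  z <- (x - location) / scale
  ld <- -z - exp(-z) - log(scale)
  if (log) ld else exp(ld)
}

pgumbel <- function(q, location = 0, scale = 1, lower.tail = TRUE) {
  z <- (q - location) / scale
  if (lower.tail) exp(-exp(-z)) else -expm1(-exp(-z))
}

qgumbel <- function(p, location = 0, scale = 1) {
  location - scale * log(-log(p))
}

rgumbel <- function(n, location = 0, scale = 1) {
  qgumbel(stats::runif(n), location, scale)
}

#' Fit a Gumbel (extreme value) distribution
#'
#' Maximum-likelihood fit of the right-tail Gumbel distribution
#' `F(x) = exp(-exp(-(x - mu)/beta))`, used to model the permutation null of
#' max-type Gene Set Z-scores. The scale is found by profile likelihood
#' (one-dimensional root solve), the location in closed form given the
#' scale. If the root solve fails, a method-of-moments fit
#' (`beta = sd * sqrt(6)/pi`, `mu = mean - gamma * beta`, `gamma` the
#' Euler-Mascheroni constant) is returned instead, with `fit_method`
#' recording the fallback.
#'
#' @param null_scores Numeric vector of >= 50 finite values with positive
#'   spread.
#' @param method `"mle"` (default, with moments fallback) or `"moments"`.
#' @return Object of class `gumbel_fit`: list with `location`, `scale`,
#'   `n_null`, `fit_method`.
#' @export
fit_gumbel <- function(null_scores, method = c("mle", "moments")) {
  method <- match.arg(method)
  x <- as.numeric(null_scores)
  if (any(!is.finite(x))) stop("null scores must be finite")
  n <- length(x)
  if (n < 50L) stop("need at least 50 null values to fit (got ", n, ")")
  sdx <- stats::sd(x)
  if (sdx <= 0) stop("degenerate null scores: zero spread")
  gamma_em <- 0.5772156649015329
  beta_mom <- sdx * sqrt(6) / pi
  mu_mom <- mean(x) - gamma_em * beta_mom

  make <- function(mu, beta, how)
    structure(list(location = mu, scale = beta, n_null = n, fit_method = how),
              class = "gumbel_fit")
  if (method == "moments") return(make(mu_mom, beta_mom, "moments"))

  xc <- x - max(x)  # center for a stable log-sum-exp
  profile <- function(beta) {
    w <- exp(-xc / beta)
    beta - mean(x) + sum(x * w) / sum(w)
  }
  fit <- tryCatch({
    lo <- beta_mom / 20; hi <- beta_mom * 20
    root <- stats::uniroot(profile, lower = lo, upper = hi, tol = 1e-10)
    beta <- root$root
    mu <- max(x) - beta * log(mean(exp(-xc / beta)))
    if (!is.finite(mu) || !is.finite(beta) || beta <= 0) stop("bad fit")
    make(mu, beta, "maximum_likelihood")
  }, error = function(e) make(mu_mom, beta_mom, "moments"))
  fit
}

#' @export
print.gumbel_fit <- function(x, ...) {
  cat(sprintf("gumbel_fit (%s): location %.4f, scale %.4f (n = %d)\n",
              x$fit_method, x$location, x$scale, x$n_null))
  invisible(x)
}

#' Asymptotic p-value from a fitted Gumbel null
#'
#' Upper-tail probability of the observed score under the fitted Gumbel,
#' `p = 1 - F(observed)`, clamped to `[1e-300, 1 - 1e-16]`; strictly
#' decreasing in the observed score. At `observed = location` the value is
#' `1 - exp(-1) ~ 0.6321`.
#'
#' @param observed Numeric vector of observed scores (finite).
#' @param fit A [fit_gumbel()] object.
#' @return Vector of p-values in `(0, 1)`.
#' @export
asymptotic_pvalue <- function(observed, fit) {
  stopifnot(inherits(fit, "gumbel_fit"))
  if (any(!is.finite(observed))) stop("observed score must be finite")
  p <- pgumbel(observed, fit$location, fit$scale, lower.tail = FALSE)
  pmin(pmax(p, 1e-300), 1 - 1e-16)
}

#' Empirical permutation p-value
#'
#' Add-one-corrected empirical upper-tail probability,
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)`. Provided for
#' cross-checking the asymptotic path.
#'
#' @param observed Numeric vector of observed scores.
#' @param null_scores Numeric vector of null scores (>= 1).
#' @return Vector of p-values.
#' @export
empirical_pvalue <- function(observed, null_scores) {
  stopifnot(length(null_scores) >= 1)
  vapply(observed, function(o)
    (1 + sum(null_scores >= o)) / (1 + length(null_scores)), 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (wraps `stats::p.adjust(method = "BH")`): monotone
#' non-decreasing in ranked p, capped at 1, and never below the raw p-value.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Vector of adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1 | !is.finite(p_values)))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
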