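#' Build a dispersion ladder
#'
#' A dispersion ladder is an ordered set of instances of one distribution
#' family whose theoretical variances form a geometric sequence: the relative
#' change in variance between consecutive levels is fixed, so a metric that
#' tracks dispersion perfectly has a constant relative change along the
#' ladder.
#'
#' The varying parameter per family, and how the fixed variance ratio is
#' achieved:
#'
#' * `poisson`: `lambda` geometric from `param_low` to `param_high`
#'   (variance = lambda, so the variance is geometric too).
#' * `negbinom`: size `r` geometric; `p` fixed (default 0.5). Variance
#'   `r(1-p)/p^2` is linear in `r`, hence geometric.
#' * `poisson_lognormal`: `sigma` varies; levels are solved numerically so
#'   the theoretical variance is exactly geometric between the variances at
#'   `sigma = param_low` and `sigma = param_high`. `mu` fixed (default 0).
#' * `hurdle_nb`: size `r` varies; solved numerically as above so the hurdle
#'   mixture variance is geometric between its values at the `r` endpoints.
#'   `pi` (default 0.1) and `p` (default 0.5) fixed.
#' * `uniform`: upper limit `b` solved from the geometric variance sequence
#'   and rounded to an integer (counts are integral); the realized ratio is
#'   exact only up to rounding. `a` fixed (default 0).
#' * `betapoisson`: the scale factor `c` on the Beta `beta` parameter is
#'   geometric from `param_low` to `param_high`; the hyperparameters
#'   `alpha ~ U(0,1)`, `lambda1 ~ U(0,1000)`, `lambda2 ~ U(0,1)` and the base
#'   `beta_base ~ U(0,1)` are drawn once per ladder (supply `seed`, or pass
#'   them in `fixed_params`) and shared by every level, so only dispersion
#'   changes along the ladder. No closed-form variance; `variance_ratio` is
#'   `NA`.
#'
#' @param family distribution family (see [dist_spec()]).
#' @param n_levels number of levels (>= 2).
#' @param param_low,param_high range of the varying parameter
#'   (`param_high > param_low > 0`).
#' @param fixed_params named list of parameters held fixed across levels.
#' @param seed integer; required for `betapoisson` unless all hyperparameters
#'   are given in `fixed_params`.
#' @return an object of class `dispersion_ladder` with fields `family`,
#'   `levels` (list of [dist_spec()]), `variance_ratio`, `n_levels`, and
#'   `varying` (name of the varying parameter).
#' @examples
#' lad <- make_ladder("negbinom", 10, 0.6, 10, fixed_params = list(p = 0.5))
#' sapply(lad$levels, function(s) theoretical_moments(s)[["variance"]])
#' @export
make_ladder <- function(family, n_levels, param_low, param_high,
                        fixed_params = list(), seed = NULL) {
  family <- match.arg(family, dist_families())
  if (n_levels < 2) stop("n_levels must be >= 2", call. = FALSE)
  if (!(param_high > param_low))
    stop("param_high must exceed param_low", call. = FALSE)
  if (param_low <= 0) stop("parameter bounds must be positive", call. = FALSE)

  geom_seq <- function(lo, hi, n) lo * (hi / lo)^((seq_len(n) - 1) / (n - 1))

  levels <- switch(family,
    poisson = lapply(geom_seq(param_low, param_high, n_levels),
                     function(l) dist_spec("poisson", lambda = l)),
    negbinom = {
      p <- fixed_params$p %||% 0.5
      lapply(geom_seq(param_low, param_high, n_levels),
             function(r) dist_spec("negbinom", r = r, p = p))
    },
    poisson_lognormal = {
      mu <- fixed_params$mu %||% 0
      mk <- function(s) dist_spec("poisson_lognormal", mu = mu, sigma = s)
      solve_variance_ladder(mk, "sigma", param_low, param_high, n_levels)
    },
    hurdle_nb = {
      pi <- fixed_params$pi %||% 0.1
      p <- fixed_params$p %||% 0.5
      mk <- function(r) dist_spec("hurdle_nb", pi = pi, r = r, p = p)
      solve_variance_ladder(mk, "r", param_low, param_high, n_levels)
    },
    uniform = {
      a <- fixed_params$a %||% 0
      vfun <- function(b) (((b - a + 1)^2 - 1) / 12)
      b_lo <- round(param_low); b_hi <- round(param_high)
      if (b_lo <= a) stop("param_low must exceed the lower limit a",
                          call. = FALSE)
      v <- geom_seq(vfun(b_lo), vfun(b_hi), n_levels)
      b <- round(a - 1 + sqrt(12 * v + 1))
      b <- as.numeric(cummax_strict(b))   # integer rounding: keep b increasing
      lapply(b, function(bb) dist_spec("uniform", a = a, b = bb))
    },
    betapoisson = {
      hp <- betapoisson_hyperparams(fixed_params, seed)
      lapply(geom_seq(param_low, param_high, n_levels), function(cc)
        dist_spec("betapoisson", alpha = hp$alpha, beta = cc * hp$beta_base,
                  lambda1 = hp$lambda1, lambda2 = hp$lambda2))
    })

  vr <- NA_real_
  if (family != "betapoisson") {
    v <- vapply(levels, function(s) theoretical_moments(s)[["variance"]],
                numeric(1))
    if (any(diff(v) <= 0))
      stop("internal error: theoretical variance not strictly increasing")
    vr <- (v[n_levels] / v[1])^(1 / (n_levels - 1))
  }
  structure(list(family = family, levels = levels, variance_ratio = vr,
                 n_levels = as.integer(n_levels),
                 varying = switch(family, poisson = "lambda", negbinom = "r",
                                  poisson_lognormal = "sigma",
                                  hurdle_nb = "r", uniform = "b",
                                  betapoisson = "c")),
            class = "dispersion_ladder")
}

# Invert a monotone variance function so the theoretical variance sequence is
# exactly geometric between its values at the parameter endpoints.
solve_variance_ladder <- function(mk, par_name, lo, hi, n) {
  vfun <- function(x) theoretical_moments(mk(x))[["variance"]]
  v <- vfun(lo) * (vfun(hi) / vfun(lo))^((seq_len(n) - 1) / (n - 1))
  pars <- vapply(v, function(target) {
    if (target <= vfun(lo) * (1 + 1e-14)) return(lo)
    if (target >= vfun(hi) * (1 - 1e-14)) return(hi)
    stats::uniroot(function(x) log(vfun(x)) - log(target),
                   interval = c(lo, hi), tol = .Machine$double.eps^0.75)$root
  }, numeric(1))
  lapply(pars, mk)
}

betapoisson_hyperparams <- function(fixed_params, seed) {
  need <- c("alpha", "beta_base", "lambda1", "lambda2")
  if (all(need %in% names(fixed_params))) return(fixed_params[need])
  if (is.null(seed))
    stop("betapoisson ladders need either a seed or explicit hyperparameters ",
         "(alpha, beta_base, lambda1, lambda2) in fixed_params", call. = FALSE)
  with_seed(derive_seed(seed, 97L), list(
    alpha = stats::runif(1), beta_base = stats::runif(1),
    lambda1 = stats::runif(1, 0, 1000), lambda2 = stats::runif(1)))
}

cummax_strict <- function(x) {
  for (i in seq_along(x)[-1]) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + 1
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.dispersion_ladder <- function(x, ...) {
  cat(sprintf("<dispersion_ladder> %s, %d levels, varying '%s'",
              x$family, x$n_levels, x$varying))
  if (is.finite(x$variance_ratio))
    cat(sprintf(", variance ratio %.6g", x$variance_ratio))
  cat("\n")
  invisible(x)
}

#' Theoretical variances along a ladder
#'
#' @param ladder a [make_ladder()] object.
#' @return numeric vector of per-level theoretical variances (errors for
#'   beta-Poisson ladders, which have no closed form).
#' @export
ladder_variances <- function(ladder) {
  stopifnot(inherits(ladder, "dispersion_ladder"))
  vapply(ladder$levels, function(s) theoretical_moments(s)[["variance"]],
         numeric(1))
}
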