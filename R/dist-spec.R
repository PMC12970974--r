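#' Distribution specification for count simulation
#'
#' A `dist_spec` names one parameterized sampling distribution used to
#' simulate UMI counts. Supported families and their parameters:
#'
#' * `poisson`: `lambda` (rate).
#' * `negbinom`: `r` (size, the gamma shape), `p` (success probability);
#'   mean `r(1-p)/p`, variance `r(1-p)/p^2`, Fano factor `1/p`.
#' * `betapoisson`: `alpha`, `beta` (Beta shapes), `lambda1` (Poisson rate
#'   scale), `lambda2` (output scale). Each gene draws `B ~ Beta(alpha, beta)`,
#'   counts are `round(lambda2 * Poisson(lambda1 * B))`.
#' * `poisson_lognormal`: `mu`, `sigma` (log-scale location and spread of the
#'   latent rate).
#' * `hurdle_nb`: `pi` (probability of a non-zero count), `r`, `p`; a point
#'   mass at zero mixed with a zero-truncated negative binomial.
#' * `uniform`: integers on `{a, ..., b}` (`a <= b`; `b == a` gives the
#'   degenerate constant distribution).
#'
#' @param family one of `"poisson"`, `"negbinom"`, `"betapoisson"`,
#'   `"poisson_lognormal"`, `"hurdle_nb"`, `"uniform"`.
#' @param ... named parameters for the family (see above).
#' @return an object of class `dist_spec`.
#' @examples
#' dist_spec("negbinom", r = 10, p = 0.5)
#' dist_spec("poisson", lambda = 0.2)
#' @export
dist_spec <- function(family, ...) {
  family <- match.arg(family, dist_families())
  params <- list(...)
  if (length(params) == 1L && is.null(names(params)) && is.list(params[[1]]))
    params <- params[[1]]
  validate_params(family, params)
  structure(list(family = family, params = params), class = "dist_spec")
}

dist_families <- function() {
  c("poisson", "negbinom", "betapoisson", "poisson_lognormal",
    "hurdle_nb", "uniform")
}

# Guard against parameter values that would overflow integer counts.
.max_rate <- 1e8

validate_params <- function(family, params) {
  need <- switch(family,
    poisson = "lambda",
    negbinom = c("r", "p"),
    betapoisson = c("alpha", "beta", "lambda1", "lambda2"),
    poisson_lognormal = c("mu", "sigma"),
    hurdle_nb = c("pi", "r", "p"),
    uniform = c("a", "b"))
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop(sprintf("family '%s' requires parameter(s): %s",
                 family, paste(missing, collapse = ", ")), call. = FALSE)
  for (nm in need) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
  }
  p <- params
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  switch(family,
    poisson = {
      chk(p$lambda > 0, "lambda must be > 0")
      chk(p$lambda <= .max_rate, "lambda rejected: overflow-scale rate")
    },
    negbinom = {
      chk(p$r > 0, "r must be > 0")
      chk(p$p > 0 && p$p < 1, "p must be in (0, 1)")
    },
    betapoisson = {
      chk(p$alpha > 0 && p$beta > 0, "alpha and beta must be > 0")
      chk(p$lambda1 > 0 && p$lambda2 > 0, "lambda1 and lambda2 must be > 0")
      chk(p$lambda1 * p$lambda2 <= .max_rate,
          "lambda1 * lambda2 rejected: overflow-scale rate")
    },
    poisson_lognormal = {
      chk(p$sigma > 0, "sigma must be > 0")
      chk(exp(p$mu + p$sigma^2 / 2) <= .max_rate,
          "mu/sigma rejected: overflow-scale rate")
    },
    hurdle_nb = {
      chk(p$pi > 0 && p$pi < 1, "pi must be in (0, 1)")
      chk(p$r > 0, "r must be > 0")
      chk(p$p > 0 && p$p < 1, "p must be in (0, 1)")
    },
    uniform = {
      chk(p$a >= 0, "a must be >= 0")
      chk(p$b >= p$a, "b must be >= a")
      chk(p$a == round(p$a) && p$b == round(p$b),
          "a and b must be integers")
      chk(p$b <= 1e9, "b rejected: overflow-scale upper limit")
    })
  invisible(TRUE)
}

#' @exportS3Method base::print
print.dist_spec <- function(x, ...) {
  pv <- vapply(x$params, function(v) format(v, digits = 6), "")
  cat(sprintf("<dist_spec> %s(%s)\n", x$family,
              paste(names(pv), pv, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Does a distribution family have closed-form moments?
#'
#' @param spec a [dist_spec()].
#' @return `TRUE` except for the beta-Poisson (whose output rounding and
#'   scaling leave no usable closed form).
#' @export
has_closed_form <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  spec$family != "betapoisson"
}

#' Theoretical mean and variance of a sampling distribution
#'
#' Exact analytic moments. For the hurdle negative binomial these are the
#' moments of the mixture of a point mass at 0 (probability `1 - pi`) and a
#' zero-truncated negative binomial (probability `pi`). The uniform family is
#' the discrete uniform on `{a, ..., b}` (variance `((b-a+1)^2 - 1)/12`),
#' matching the integer-valued sampler.
#'
#' @param spec a [dist_spec()].
#' @return named numeric vector `c(mean = , variance = )`.
#' @examples
#' theoretical_moments(dist_spec("negbinom", r = 10, p = 0.5))  # mean 10, var 20
#' @export
theoretical_moments <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  if (!has_closed_form(spec))
    stop("no closed form: beta-Poisson moments depend on the rounded, ",
         "scaled composition; use empirical moments instead",
         call. = FALSE)
  p <- spec$params
  out <- switch(spec$family,
    poisson = c(p$lambda, p$lambda),
    negbinom = {
      m <- p$r * (1 - p$p) / p$p
      c(m, m / p$p)
    },
    poisson_lognormal = {
      m <- exp(p$mu + p$sigma^2 / 2)
      c(m, m + m^2 * (exp(p$sigma^2) - 1))
    },
    hurdle_nb = {
      q0 <- p$p^p$r                      # P(NB = 0)
      mnb <- p$r * (1 - p$p) / p$p
      vnb <- mnb / p$p
      ez <- mnb / (1 - q0)               # zero-truncated mean
      ez2 <- (vnb + mnb^2) / (1 - q0)    # zero-truncated second moment
      m <- p$pi * ez
      c(m, p$pi * ez2 - m^2)
    },
    uniform = {
      w <- p$b - p$a + 1
      c((p$a + p$b) / 2, (w^2 - 1) / 12)
    })
  c(mean = out[[1]], variance = out[[2]])
}
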