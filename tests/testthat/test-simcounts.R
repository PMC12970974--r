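test_that("closed-form moments are exact for each family", {
  expect_equal(theoretical_moments(dist_spec("negbinom", r = 10, p = 0.5)),
               c(mean = 10, variance = 20))
  expect_equal(theoretical_moments(dist_spec("poisson", lambda = 0.2)),
               c(mean = 0.2, variance = 0.2))
  # discrete uniform on {0..9}
  expect_equal(theoretical_moments(dist_spec("uniform", a = 0, b = 9)),
               c(mean = 4.5, variance = (100 - 1) / 12))
  expect_error(theoretical_moments(
    dist_spec("betapoisson", alpha = 1, beta = 1, lambda1 = 10, lambda2 = 1)),
    "no closed form")
})

test_that("NB and hurdle moments agree with direct pmf summation", {
  nb <- dist_spec("negbinom", r = 3.7, p = 0.35)
  expect_equal(theoretical_moments(nb),
               pmf_moments(function(k) dnbinom(k, size = 3.7, prob = 0.35),
                           3000), tolerance = 1e-9)
  # hurdle: point mass at 0 with prob 1 - pi, zero-truncated NB otherwise
  hz <- function(pi, r, p) function(k) {
    q0 <- dnbinom(0, size = r, prob = p)
    ifelse(k == 0, 1 - pi, pi * dnbinom(k, size = r, prob = p) / (1 - q0))
  }
  expect_equal(theoretical_moments(dist_spec("hurdle_nb", pi = 0.5, r = 1,
                                             p = 0.5)),
               pmf_moments(hz(0.5, 1, 0.5), 5000), tolerance = 1e-9)
  # mean = 0.5 * E[zero-truncated Geom(0.5)] = 0.5 * 2 = 1
  expect_equal(theoretical_moments(dist_spec("hurdle_nb", pi = 0.5, r = 1,
                                             p = 0.5))[["mean"]], 1)
  expect_equal(theoretical_moments(dist_spec("hurdle_nb", pi = 0.1, r = 0.06,
                                             p = 0.5)),
               pmf_moments(hz(0.1, 0.06, 0.5), 5000), tolerance = 1e-9)
})

test_that("Poisson-lognormal moments agree with Monte Carlo", {
  set.seed(5)
  lam <- rlnorm(4e5, meanlog = 0, sdlog = 0.8)
  x <- rpois(4e5, lam)
  tm <- theoretical_moments(dist_spec("poisson_lognormal", mu = 0,
                                      sigma = 0.8))
  expect_equal(mean(x), tm[["mean"]], tolerance = 0.02)
  expect_equal(var(x), tm[["variance"]], tolerance = 0.05)
})

test_that("spec validation rejects bad parameters", {
  expect_error(dist_spec("poisson", lambda = -1), "lambda")
  expect_error(dist_spec("negbinom", r = 1, p = 1.2), "p must")
  expect_error(dist_spec("negbinom", r = 1), "requires parameter")
  expect_error(dist_spec("hurdle_nb", pi = 0, r = 1, p = 0.5), "pi")
  expect_error(dist_spec("uniform", a = 5, b = 2), "b must be >= a")
  expect_error(dist_spec("uniform", a = 0, b = 2.5), "integers")
  expect_error(dist_spec("poisson", lambda = 1e12), "overflow")
})

test_that("ladders have the documented geometric structure", {
  lad <- make_ladder("negbinom", 100, 0.6, 10, fixed_params = list(p = 0.5))
  r <- sapply(lad$levels, function(s) s$params$r)
  expect_equal(r[1], 0.6)
  expect_equal(r[100], 10)
  expect_equal(unique(round(r[-1] / r[-100], 6)),
               round((10 / 0.6)^(1 / 99), 6))  # ~1.0289
  # var(level k) = r_k (1-p)/p^2 = 2 r_k at p = 0.5
  expect_equal(ladder_variances(lad), 2 * r, tolerance = 1e-12)

  lp <- make_ladder("poisson", 100, 0.2, 2278)
  expect_equal(lp$variance_ratio, (2278 / 0.2)^(1 / 99), tolerance = 1e-12)

  expect_error(make_ladder("poisson", 2, 1, 1), "must exceed")
  expect_error(make_ladder("poisson", 1, 1, 2), "n_levels")
  expect_error(make_ladder("nosuch", 5, 1, 2))
})

test_that("theoretical variance ratio is constant along closed-form ladders", {
  lads <- list(
    make_ladder("poisson", 30, 0.2, 2278),
    make_ladder("negbinom", 30, 0.6, 10),
    make_ladder("poisson_lognormal", 30, 0.2, 2),
    make_ladder("hurdle_nb", 30, 0.06, 10, fixed_params = list(pi = 0.1)),
    make_ladder("hurdle_nb", 30, 0.06, 10, fixed_params = list(pi = 0.9)))
  for (lad in lads) {
    v <- ladder_variances(lad)
    expect_true(all(diff(v) > 0))
    ratios <- v[-1] / v[-length(v)]
    expect_lt(max(abs(ratios - lad$variance_ratio)) / lad$variance_ratio,
              1e-9)
  }
})

test_that("uniform ladders follow the geometric variance law up to rounding", {
  lad <- make_ladder("uniform", 20, 100, 1e7)
  v <- ladder_variances(lad)
  expect_true(all(diff(v) > 0))
  ratios <- v[-1] / v[-length(v)]
  # integer b: exact at the top of the ladder, rounding-limited at the bottom
  expect_equal(ratios, rep(lad$variance_ratio, 19), tolerance = 0.02)
})

test_that("beta-Poisson ladders share hyperparameters and scale beta by c", {
  lad <- make_ladder("betapoisson", 10, 0.67, 100, seed = 4)
  a <- sapply(lad$levels, function(s) s$params$alpha)
  b <- sapply(lad$levels, function(s) s$params$beta)
  expect_equal(length(unique(a)), 1L)
  expect_equal(unique(round(b[-1] / b[-10], 8)),
               round((100 / 0.67)^(1 / 9), 8))
  expect_true(is.na(lad$variance_ratio))
  expect_error(make_ladder("betapoisson", 10, 0.67, 100), "seed")
})

test_that("samplers are deterministic and match theoretical moments", {
  sp <- dist_spec("poisson", lambda = 5)
  m1 <- sample_counts(sp, 1000, 1000, seed = 7)
  expect_identical(m1, sample_counts(sp, 1000, 1000, seed = 7))
  # CLT three-sigma bound: 3 * sqrt(5 / 1e6) ~ 0.0067
  expect_equal(mean(m1), 5, tolerance = 0.01 / 5)

  nb <- sample_counts(dist_spec("negbinom", r = 10, p = 0.5), 2000, 500,
                      seed = 1)
  expect_equal(var(as.vector(nb)) / mean(nb), 2, tolerance = 0.1 / 2)

  u0 <- sample_counts(dist_spec("uniform", a = 0, b = 0), 5, 8, seed = 2)
  expect_true(all(u0 == 0))
  u <- sample_counts(dist_spec("uniform", a = 2, b = 6), 100, 100, seed = 3)
  expect_true(all(u >= 2 & u <= 6))
  expect_true(all(sort(unique(as.vector(u))) == 2:6))

  bp <- sample_counts(dist_spec("betapoisson", alpha = 0.5, beta = 1,
                                lambda1 = 100, lambda2 = 0.5), 50, 50,
                      seed = 9)
  expect_true(all(bp >= 0) && all(bp == round(bp)))
})

test_that("empirical moments converge per CLT for solved ladders", {
  sp <- make_ladder("poisson_lognormal", 3, 0.3, 1.2)$levels[[2]]
  tm <- theoretical_moments(sp)
  x <- as.vector(sample_counts(sp, 500, 200, seed = 5))
  se <- sqrt(tm[["variance"]] / length(x))
  expect_lt(abs(mean(x) - tm[["mean"]]), 4 * se)
})

test_that("hurdle sampler hits the configured zero fraction", {
  x <- as.vector(sample_counts(dist_spec("hurdle_nb", pi = 0.1, r = 1,
                                         p = 0.5), 500, 200, seed = 8))
  expect_gte(mean(x == 0), 0.88)
  expect_lte(mean(x == 0), 0.92)
  expect_true(all(x[x != 0] >= 1))
})

test_that("correlated sampler hits the target correlation and limits", {
  sp <- dist_spec("negbinom", r = 2, p = 0.5)
  for (seed in 1:3) {
    m <- sample_correlated(sp, 0.4, 100, 1500, seed = seed)
    cc <- cor(t(unclass(m)))
    expect_equal(mean(cc[upper.tri(cc)]), 0.4, tolerance = 0.05 / 0.4)
  }
  # independence limit: marginals indistinguishable from sample_counts
  m0 <- sample_correlated(sp, 0, 50, 400, seed = 4)
  mi <- sample_counts(sp, 50, 400, seed = 5)
  ks <- suppressWarnings(ks.test(as.vector(m0), as.vector(mi)))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_correlated(sp, 1.0, 10, 10, seed = 1), "rho_target")
  expect_error(sample_correlated(dist_spec("uniform", a = 0, b = 5), 0.2,
                                 10, 10, seed = 1), "marginals")
})
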