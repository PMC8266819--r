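test_that("ILR transform is the expected bijection", {
  # uniform composition maps to the origin
  expect_equal(ilr_transform(rep(1 / 5, 5)), rep(0, 4), tolerance = 1e-12)
  # K = 2 closed form: ln(p1/p2)/sqrt(2)
  expect_equal(
    ilr_transform(c(0.731, 0.269)),
    log(0.731 / 0.269) / sqrt(2),
    tolerance = 1e-12
  )
  # round trips on random simplex points
  set.seed(2)
  for (K in c(2, 3, 7)) {
    for (i in 1:20) {
      p <- as.numeric(rexp(K))
      p <- p / sum(p)
      expect_equal(ilr_inverse(ilr_transform(p)), p, tolerance = 1e-10)
    }
  }
  expect_error(ilr_transform(c(0, 1)), "positive")
  # basis is orthonormal and orthogonal to the ones vector
  V <- ilr_basis(6)
  expect_equal(t(V) %*% V, diag(5), tolerance = 1e-12)
  expect_equal(as.numeric(colSums(V)), rep(0, 5), tolerance = 1e-12)
})

test_that("EDEC priors scale to the uninformative information weight", {
  expect_equal(unname(prior_from_edec(rep(25, 4))), rep(1, 4))
  expect_equal(unname(prior_from_edec(c(50, 25, 25))), c(1.5, 0.75, 0.75))
  expect_equal(unname(prior_from_edec(c(60, 40, 0))[3]), 0.01)
  expect_error(prior_from_edec(c(-1, 2)), "non-negative")
  expect_error(prior_from_edec(c(0, 0)), "positive")
})

test_that("the section log-likelihood matches independent density evaluation", {
  # sources with zero spread and unit residual SD: observation at the
  # mixture mean scores the normal mode for each isotope
  sp <- two_source_space(sd13 = 0, sd15 = 0)
  p <- c(0.4, 0.6)
  m13 <- mixture_mean(p, sp, "d13C")
  m15 <- mixture_mean(p, sp, "d15N")
  expect_equal(
    simm_loglik(m13, m15, p, sp, sigma_res = 1),
    2 * (-0.5 * log(2 * pi)),
    tolerance = 1e-12
  )
  # single-source space: the plain normal log-density at the source mean
  one <- build_mixing_space(
    tibble::tibble(
      category = "A", trophic_class = "vegetable", n = 3,
      mean_d13C = -25, sd_d13C = 0.8, mean_d15N = 4, sd_d15N = 0.5,
      digest_c = 45, digest_n = 3
    ),
    tefs = tef_zero()
  )
  expect_equal(
    simm_loglik(-24, NA, 1, one, sigma_res = 0.3),
    dnorm(-24, -25, sqrt(0.8^2 + 0.3^2), log = TRUE)
  )
  # worked two-source case against an independently coded density
  sp2 <- two_source_space()
  pp <- c(0.5, 0.5)
  q <- c(40, 50)
  w <- pp * q
  mm <- sum(w * c(-30, -20)) / sum(w)
  vv <- sum(w^2 * 1) / sum(w)^2 + 0.25
  expect_equal(
    simm_loglik(-26, NA, pp, sp2, sigma_res = c(0.5, 0.5)),
    -0.5 * log(2 * pi * vv) - 0.5 * (-26 - mm)^2 / vv,
    tolerance = 1e-12
  )
  expect_error(simm_loglik(NA, NA, p, sp), "isotope observation")
})

test_that("Gelman-Rubin separates mixed from unmixed chains", {
  set.seed(31)
  same <- cbind(rnorm(5000), rnorm(5000))
  expect_gt(gelman_rubin(same), 0.99)
  expect_lt(gelman_rubin(same), 1.01)
  apart <- cbind(rnorm(1000), rnorm(1000, 10))
  expect_gt(gelman_rubin(apart), 5)
  expect_warning(r <- gelman_rubin(cbind(rep(1, 50), rep(1, 50))), "Degenerate")
  expect_equal(r, 1)
  expect_error(gelman_rubin(matrix(rnorm(10), ncol = 1)), "2 chains")
})

test_that("Geweke z is calibrated on stationary chains", {
  set.seed(41)
  zs <- replicate(200, geweke_z(rnorm(2000)))
  expect_gte(mean(abs(zs) < 3), 0.99)
  # a strong mean drift is detected
  expect_gt(abs(geweke_z(c(rnorm(300), rnorm(300, 5)))), 5)
  expect_error(geweke_z(rnorm(10)), ">= 20")
})

test_that("posterior summaries follow the draws", {
  sp <- two_source_space()
  dat <- tibble::tibble(d13C = c(-26, -25.5, -26.2), d15N = c(2.4, 2.6, 2.2))
  f <- fit_simm(dat, sp,
    settings = mcmc_settings(chains = 2, iter = 3000, burn = 1000, thin = 4),
    seed = 2
  )
  td <- tidy(f)
  expect_equal(td$source, rownames(sp$mu))
  expect_true(all(td$conf.low <= td$mean & td$mean <= td$conf.high))
  # every draw and the summary means live on the simplex
  pd <- composition_draws(f)
  expect_equal(rowSums(pd), rep(1, nrow(pd)), tolerance = 1e-12)
  expect_equal(sum(td$mean), 1, tolerance = 1e-9)
  # summaries are invariant to draw order
  perm <- sample(nrow(pd))
  q1 <- apply(pd, 2, quantile, probs = c(0.025, 0.5, 0.975))
  q2 <- apply(pd[perm, ], 2, quantile, probs = c(0.025, 0.5, 0.975))
  expect_equal(q1, q2)
  g <- glance(f)
  expect_equal(g$n_draws, 2 * 500)
  expect_true(is.finite(g$looic))
})

test_that("a single-source model collapses to p = 1 with zero variance", {
  one <- build_mixing_space(
    tibble::tibble(
      category = "A", trophic_class = "vegetable", n = 3,
      mean_d13C = -25, sd_d13C = 0.8, mean_d15N = 4, sd_d15N = 0.5,
      digest_c = 45, digest_n = 3
    ),
    tefs = tef_zero()
  )
  dat <- tibble::tibble(d13C = c(-24.8, -25.1), d15N = c(4.1, 3.9))
  f <- fit_simm(dat, one, settings = mcmc_settings(
    chains = 2, iter = 2000, burn = 1000, thin = 5
  ), seed = 1)
  td <- tidy(f)
  expect_equal(td$mean, 1)
  expect_equal(td$conf.low, 1)
  expect_equal(td$conf.high, 1)
  expect_equal(td$sd, 0)
})

test_that("with a flooded likelihood the posterior returns the uniform prior", {
  # residual SD fixed at 1e6 makes the data uninformative, so the
  # Dirichlet(1) prior should dominate: mean ~ 1/K per source
  sp <- triangle_space(sd = 1)
  dat <- tibble::tibble(d13C = rep(-25, 5), d15N = rep(3, 5))
  f <- fit_simm(dat, sp,
    settings = mcmc_settings(
      chains = 3, iter = 24000, burn = 4000, thin = 4,
      fix_sigma_res = c(1e6, 1e6)
    ),
    seed = 9
  )
  td <- tidy(f)
  expect_equal(td$mean, rep(1 / 3, 3), tolerance = 0.05)
})

test_that("MCMC matches a dense-grid posterior on the 2-source 1-isotope model", {
  sp <- two_source_space()
  set.seed(2)
  ptrue <- 0.6
  m <- mixture_mean(c(ptrue, 1 - ptrue), sp, "d13C")
  v <- mixture_process_var(c(ptrue, 1 - ptrue), sp, "d13C") + 0.25
  y <- rnorm(15, m, sqrt(v))
  f <- fit_simm(
    tibble::tibble(d13C = y, d15N = NA_real_), sp,
    settings = mcmc_settings(
      chains = 3, iter = 40000, burn = 8000, thin = 2,
      fix_sigma_res = c(0.5, 0.5)
    ),
    seed = 4
  )
  pd <- composition_draws(f)[, 1]
  grid <- seq(1e-6, 1 - 1e-6, length.out = 2001)
  logpost <- vapply(grid, function(p) {
    w <- c(p, 1 - p) * c(40, 50)
    mm <- sum(w * c(-30, -20)) / sum(w)
    vv <- sum(w^2) / sum(w)^2 + 0.25
    sum(dnorm(y, mm, sqrt(vv), log = TRUE))
  }, numeric(1))
  dens <- exp(logpost - max(logpost))
  cdf <- cumsum(dens) / sum(dens)
  gap <- max(abs(stats::ecdf(pd)(grid) - cdf))
  expect_lt(gap, 0.02)
})

test_that("credible intervals tighten as residual noise shrinks and data grow", {
  sp <- two_source_space(sd13 = 0.3, sd15 = 0.3)
  ptrue <- c(0.6, 0.4)
  gen <- function(n, sig) {
    withr::with_seed(77, tibble::tibble(
      d13C = rnorm(
        n, mixture_mean(ptrue, sp, "d13C"),
        sqrt(mixture_process_var(ptrue, sp, "d13C") + sig^2)
      ),
      d15N = rnorm(
        n, mixture_mean(ptrue, sp, "d15N"),
        sqrt(mixture_process_var(ptrue, sp, "d15N") + sig^2)
      )
    ))
  }
  st <- function(sig) {
    mcmc_settings(
      chains = 2, iter = 8000, burn = 2000, thin = 2,
      fix_sigma_res = c(sig, sig)
    )
  }
  wide <- tidy(fit_simm(gen(8, 2), sp, settings = st(2), seed = 5))
  narrow <- tidy(fit_simm(gen(60, 0.1), sp, settings = st(0.1), seed = 5))
  expect_lt(
    mean(narrow$conf.high - narrow$conf.low),
    mean(wide$conf.high - wide$conf.low)
  )
})
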