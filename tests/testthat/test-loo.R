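conjugate_loglik <- function(y, S = 4000, s2 = 1, tau2 = 100, seed = 7) {
  # normal-mean model with known variance: posterior and LOO are analytic
  v <- 1 / (length(y) / s2 + 1 / tau2)
  m <- v * sum(y) / s2
  withr::with_seed(seed, {
    mu_s <- rnorm(S, m, sqrt(v))
  })
  sapply(y, function(yi) dnorm(yi, mu_s, sqrt(s2), log = TRUE))
}

exact_refit_loo <- function(y, s2 = 1, tau2 = 100) {
  elpd <- vapply(seq_along(y), function(i) {
    v <- 1 / ((length(y) - 1) / s2 + 1 / tau2)
    m <- v * sum(y[-i]) / s2
    dnorm(y[i], m, sqrt(v + s2), log = TRUE)
  }, numeric(1))
  -2 * sum(elpd)
}

test_that("degenerate posteriors make PSIS-LOO exact", {
  y <- c(-0.3, 0.4, 1.2, 0.1, -0.8)
  ll <- matrix(rep(dnorm(y, 0, 1, log = TRUE), each = 200), nrow = 200)
  res <- psis_loo(ll)
  expect_equal(res$pointwise, dnorm(y, 0, 1, log = TRUE))
  expect_equal(res$looic, -2 * sum(dnorm(y, 0, 1, log = TRUE)))
})

test_that("PSIS-LOO matches exact refit LOO on the conjugate model", {
  set.seed(7)
  y <- rnorm(5, 1, 1)
  ll <- conjugate_loglik(y)
  res <- psis_loo(ll)
  expect_lt(abs(res$looic - exact_refit_loo(y)), 0.5)
  expect_true(all(res$pareto_k < 0.7))
  # invariant to draw order
  res2 <- psis_loo(ll[sample(nrow(ll)), ])
  expect_equal(res2$looic, res$looic)
})

test_that("duplicating every observation doubles LOOic within MC tolerance", {
  set.seed(19)
  y <- rnorm(8, 0.5, 1)
  ll <- conjugate_loglik(y, seed = 19)
  single <- psis_loo(ll)$looic
  doubled <- psis_loo(cbind(ll, ll))$looic
  expect_equal(doubled, 2 * single, tolerance = 0.02)
  expect_error(psis_loo(ll[1:50, ]), "100")
  expect_error(psis_loo(ll[, 1, drop = FALSE]), "2 observations")
  llbad <- ll
  llbad[1, 1] <- Inf
  expect_error(psis_loo(llbad), "non-finite")
})

test_that("Akaike weights reproduce the published per-season top weights", {
  ref <- tibble::as_tibble(read.csv(
    system.file("extdata", "model_selection_reference.csv",
      package = "isodiet"
    ),
    stringsAsFactors = FALSE
  ))
  top <- function(sn) {
    d <- ref[ref$season == sn, ]
    max(akaike_weights(d$delta_looic))
  }
  # printed to three decimals
  expect_lt(abs(top("spring") - 0.548), 5e-4)
  expect_lt(abs(top("early_summer") - 0.698), 5e-4)
  expect_lt(abs(top("late_summer") - 0.558), 5e-4)
})

test_that("Akaike weights have the closed-form and invariance properties", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  expect_equal(akaike_weights(c(0, 2)), c(
    exp(0) / (exp(0) + exp(-1)),
    exp(-1) / (exp(0) + exp(-1))
  ))
  w1 <- akaike_weights(c(170.2, 171.3, 173))
  w2 <- akaike_weights(c(170.2, 171.3, 173) + 5000)
  expect_equal(w1, w2)
  expect_equal(sum(w1), 1, tolerance = 1e-12)
  expect_error(akaike_weights(c(1, Inf)), "finite")
})

test_that("model comparison ranks, differences and flags models", {
  set.seed(23)
  y <- rnorm(10, 0.8, 1)
  ll_a <- conjugate_loglik(y, seed = 2)
  # a clearly worse model: wrong fixed mean
  v <- 1
  ll_b <- sapply(y, function(yi) {
    dnorm(yi, rnorm(4000, 5, 0.05), sqrt(v), log = TRUE)
  })
  out <- compare_models(list(good = ll_a, bad = ll_b))
  expect_equal(out$model, c("good", "bad"))
  expect_equal(out$delta_looic[1], 0)
  expect_equal(out$se_delta[1], 0)
  expect_gt(out$delta_looic[2], 0)
  expect_true(out$selected[1])
  expect_false(out$selected[2])
  # paired SE equals the hand-computed formula
  pa <- psis_loo(ll_a)$pointwise
  pb <- psis_loo(ll_b)$pointwise
  expect_equal(
    out$se_delta[2], 2 * sqrt(length(y) * var(pb - pa)),
    tolerance = 1e-8
  )
  # identical models split the weight and tie at delta 0
  out2 <- compare_models(list(m2 = ll_a, m1 = ll_a))
  expect_equal(out2$weight, c(0.5, 0.5))
  expect_equal(out2$delta_looic, c(0, 0))
  expect_equal(out2$model, c("m1", "m2")) # lexicographic tie-break
  # input permutation does not change the ranking
  out3 <- compare_models(list(bad = ll_b, good = ll_a))
  expect_equal(out3$model, out$model)
  expect_equal(out3$looic, out$looic)
  expect_error(
    compare_models(list(a = ll_a, b = ll_b[, 1:5])),
    "identical observation set"
  )
})
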