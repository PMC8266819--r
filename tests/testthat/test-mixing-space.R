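test_that("TEF correction shifts means and propagates variances", {
  cats <- pool_category_stats(key_food_species())
  corr <- apply_tef(cats)
  herbs <- corr[corr$category == "Herbs", ]
  ung <- corr[corr$category == "Ungulates", ]
  expect_equal(herbs$corr_mean_d13C, -30.1 + 3.4, tolerance = 0.05)
  expect_equal(ung$corr_mean_d15N, 4.3 + 3.9, tolerance = 0.05)
  # corrected variances never fall below raw variances
  expect_true(all(corr$corr_sd_d13C >= cats$sd_d13C))
  expect_true(all(corr$corr_sd_d15N >= cats$sd_d15N))
  # zero TEF SD leaves the source SD untouched
  z <- apply_tef(cats, tefs = tef_zero())
  expect_equal(z$corr_sd_d13C, cats$sd_d13C)
  expect_error(
    apply_tef(dplyr::mutate(cats, trophic_class = "mineral")),
    "mineral"
  )
})

test_that("the model mixing space drops C4 and fixes source order", {
  cats <- pool_category_stats(key_food_species())
  sp <- build_mixing_space(cats)
  expect_false("C4" %in% rownames(sp$mu))
  expect_equal(nrow(sp$mu), 7)
  expect_equal(rownames(sp$mu), sort(rownames(sp$mu)))
})

test_that("mixture mean is the concentration-weighted source average", {
  sp <- two_source_space()
  # vertex composition returns that source's corrected mean exactly
  expect_equal(mixture_mean(c(1, 0), sp, "d13C"), -30)
  expect_equal(mixture_mean(c(0, 1), sp, "d15N"), 5)
  # worked example: p = (.5, .5), q = (2, 1), means (0, 3) -> 1.0
  cats <- tibble::tibble(
    category = c("A", "B"), trophic_class = "vegetable", n = 5,
    mean_d13C = c(0, 3), sd_d13C = 0, mean_d15N = 0, sd_d15N = 0,
    digest_c = c(2, 1), digest_n = 1
  )
  sp2 <- build_mixing_space(cats, tefs = tef_zero())
  expect_equal(mixture_mean(c(0.5, 0.5), sp2, "d13C"), 1.0)
  # equal concentrations reduce to the plain proportion-weighted mean
  spq <- two_source_space(q_c = c(40, 40))
  p <- c(0.3, 0.7)
  expect_equal(mixture_mean(p, spq, "d13C"), sum(p * c(-30, -20)))
  expect_error(mixture_mean(c(0.5, 0.6), sp, "d13C"), "sum to 1")
})

test_that("mixture mean and variance are invariant to rescaling q", {
  sp1 <- two_source_space(q_c = c(40, 50))
  sp2 <- two_source_space(q_c = 10 * c(40, 50))
  set.seed(4)
  for (i in 1:10) {
    p <- as.numeric(ilr_inverse(rnorm(1), K = 2))
    expect_equal(
      mixture_mean(p, sp1, "d13C"), mixture_mean(p, sp2, "d13C"),
      tolerance = 1e-12
    )
    expect_equal(
      mixture_process_var(p, sp1, "d13C"),
      mixture_process_var(p, sp2, "d13C"),
      tolerance = 1e-12
    )
  }
})

test_that("polygon probabilities behave at the geometric extremes", {
  sp <- triangle_space(sd = 0.3)
  centroid <- c(mean(sp$mu[, 1]), mean(sp$mu[, 2]))
  cons <- tibble::tibble(
    consumer_id = c("centroid", "far"),
    d13C = c(centroid[1], 0), d15N = c(centroid[2], 50)
  )
  out <- simulate_mixing_polygons(sp, cons, n_iter = 1000, seed = 8)
  expect_gte(out$inside_probability[out$consumer_id == "centroid"], 0.99)
  expect_equal(out$inside_probability[out$consumer_id == "far"], 0)
  expect_true(out$excluded[out$consumer_id == "far"])
  # seeded reproducibility
  out2 <- simulate_mixing_polygons(sp, cons, n_iter = 1000, seed = 8)
  expect_identical(out, out2)
  expect_error(
    simulate_mixing_polygons(two_source_space(), cons, n_iter = 10, seed = 1),
    "at least 3 sources"
  )
})

test_that("zero-variance polygons match an independent point-in-polygon oracle", {
  sp <- triangle_space(sd = 0)
  set.seed(12)
  cons <- tibble::tibble(
    consumer_id = sprintf("c%02d", 1:40),
    d13C = runif(40, -33, -17),
    d15N = runif(40, -3, 13)
  )
  out <- simulate_mixing_polygons(sp, cons, n_iter = 25, seed = 5)
  expect_true(all(out$inside_probability %in% c(0, 1)))
  hull <- grDevices::chull(sp$mu[, 1], sp$mu[, 2])
  oracle <- ray_cast_inside(
    cons$d13C, cons$d15N, sp$mu[hull, 1], sp$mu[hull, 2]
  )
  expect_equal(out$inside_probability == 1, oracle)
})
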