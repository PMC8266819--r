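test_that("delta notation conversion follows the reference equation", {
  # identity and linearity
  expect_equal(delta_from_ratio(0.0112, 0.0112), 0)
  expect_equal(delta_from_ratio(1.001 * 0.0112, 0.0112), 1.0)
  # direct evaluation of the formula
  expect_equal(delta_from_ratio(0.011238, 0.011180), 5.187835, tolerance = 1e-6)
  expect_error(delta_from_ratio(0.01, 0), "positive")
  expect_error(delta_from_ratio(-0.01, 0.0112), "non-negative")
})

test_that("ratio -> delta -> ratio round-trips to 1e-12 relative error", {
  set.seed(1)
  r_std <- 0.0112
  r <- runif(50, 0.005, 0.02)
  back <- ratio_from_delta(delta_from_ratio(r, r_std), r_std)
  expect_lt(max(abs(back - r) / r), 1e-12)
})

test_that("read_sources validates schema, vocabulary and cell contents", {
  samples <- generate_table1_fixture(seed = 3)
  path <- write_sources_csv(samples)
  got <- read_sources(path)
  expect_equal(nrow(got), 191)
  counts <- table(got$category)
  expect_equal(unname(counts[["Herbs"]]), 63)
  expect_equal(unname(counts[["Hard mast"]]), 18)
  expect_equal(unname(counts[["Wild fleshy fruits"]]), 46)
  expect_equal(unname(counts[["Cultivated fleshy fruits"]]), 16)
  expect_equal(unname(counts[["Cultivated vegetables"]]), 12)
  expect_equal(unname(counts[["Ungulates"]]), 7)
  expect_equal(unname(counts[["Formicidae"]]), 26)
  expect_equal(unname(counts[["C4"]]), 3)

  # empty file with header -> empty tibble
  empty <- samples[0, ]
  expect_equal(nrow(read_sources(write_sources_csv(empty))), 0)

  # unknown category label -> error naming row and label
  bad <- samples
  bad$category[5] <- "Fish"
  expect_error(read_sources(write_sources_csv(bad)), "Fish.*row 5|row 5.*Fish")

  # missing column -> schema error naming the column
  noiso <- samples[setdiff(names(samples), "d15N")]
  expect_error(read_sources(write_sources_csv(noiso)), "d15N")

  # non-numeric isotope cell -> row-level parse error
  txt <- samples
  txt$d13C <- as.character(txt$d13C)
  txt$d13C[7] <- "oops"
  expect_error(read_sources(write_sources_csv(txt)), "d13C.*row 7")
})

test_that("category pooling uses weighted means and within+between variance", {
  # two species, n = 2 each, means 0 and 2, SDs 0:
  # grand mean 1, total SS = 4, pooled SD = sqrt(4/3)
  stats <- tibble::tibble(
    category = "X", species = c("a", "b"), trophic_class = "vegetable",
    n = c(2, 2),
    d13C_mean = c(0, 2), d13C_sd = 0,
    d15N_mean = 0, d15N_sd = 0,
    C_mean = 45, C_sd = 0, N_mean = 3, N_sd = 0
  )
  out <- pool_category_stats(stats)
  expect_equal(out$mean_d13C, 1.0)
  expect_equal(out$sd_d13C, sqrt(4 / 3), tolerance = 1e-12)

  # a single-species category: pooled stats equal the species stats
  one <- stats[1, ]
  one$d13C_sd <- 0.7
  out1 <- pool_category_stats(one)
  expect_equal(out1$mean_d13C, 0)
  expect_equal(out1$sd_d13C, 0.7)

  # identical subgroups: pooled SD equals the SD of the concatenated raw
  # sample (the N - 1 total-variance convention), approaching the common
  # subgroup SD as n grows
  raw_a <- c(0.5, 1.5) # mean 1, sd 1/sqrt(2)
  raw_b <- c(0.5, 1.5)
  same <- stats
  same$d13C_mean <- 1
  same$d13C_sd <- sd(raw_a)
  expect_equal(
    pool_category_stats(same)$sd_d13C, sd(c(raw_a, raw_b)),
    tolerance = 1e-12
  )
  # pooled SD never falls below the within-only component
  expect_gte(
    pool_category_stats(stats)$sd_d13C,
    sqrt(sum((stats$n - 1) * stats$d13C_sd^2) / (sum(stats$n) - 1))
  )
})

test_that("pooling the published species rows reproduces the category cells", {
  cats <- pool_category_stats(key_food_species())
  cell <- function(cat, col) cats[[col]][cats$category == cat]
  expect_equal(cell("Herbs", "mean_d13C"), -30.1, tolerance = 0.05)
  expect_equal(cell("Herbs", "sd_d13C"), 1.6, tolerance = 0.05)
  expect_equal(cell("Herbs", "mean_d15N"), -2.2, tolerance = 0.05)
  expect_equal(cell("Wild fleshy fruits", "mean_d13C"), -27.8, tolerance = 0.05)
  expect_equal(cell("Cultivated fleshy fruits", "mean_d13C"), -27.2,
    tolerance = 0.05
  )
  expect_equal(cell("Cultivated vegetables", "mean_d15N"), 9.0,
    tolerance = 0.05
  )
  expect_equal(cell("Ungulates", "mean_d15N"), 4.3, tolerance = 0.05)
})

test_that("aggregating raw samples equals pooling their species summaries", {
  samples <- generate_table1_fixture(seed = 11)
  agg <- aggregate_sources(samples)
  pooled <- pool_category_stats(key_food_species())
  expect_equal(agg$mean_d13C, pooled$mean_d13C, tolerance = 1e-8)
  expect_equal(agg$sd_d13C, pooled$sd_d13C, tolerance = 1e-8)
  expect_equal(agg$mean_d15N, pooled$mean_d15N, tolerance = 1e-8)
  expect_equal(agg$n, pooled$n)
  expect_error(aggregate_sources(samples[0, ]), "empty")
})
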