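test_that("collection dates classify around the annual moult", {
  expect_equal(classify_sampling_period(as.Date("2014-06-15")), "pre_moult")
  expect_equal(classify_sampling_period(as.Date("2014-09-10")), "post_moult")
  expect_equal(classify_sampling_period(as.Date("2014-07-20")), "excluded_moult")
  expect_equal(classify_sampling_period(as.Date("2014-08-01")), "excluded_moult")
  expect_equal(
    classify_sampling_period(as.Date("2014-11-05")),
    "excluded_out_of_design"
  )
  expect_error(classify_sampling_period("not-a-date"), "unparseable|format")
})

test_that("hairs split into full 15-mm sections with remainder discarded", {
  out <- section_hair(c(45, 50, 10))
  expect_equal(out$n_sections, c(3L, 3L, 0L))
  expect_equal(out$remainder_mm, c(0, 5, 10))
  expect_equal(out$usable, c(TRUE, TRUE, FALSE))
  expect_error(section_hair(0), "positive")
})

test_that("months map onto the four dietary seasons", {
  expect_equal(month_to_season(3:5), rep("spring", 3))
  expect_equal(month_to_season(6:7), rep("early_summer", 2))
  expect_equal(month_to_season(8:9), rep("late_summer", 2))
  expect_equal(month_to_season(10:11), rep("autumn", 2))
  expect_true(all(is.na(month_to_season(c(12, 1, 2)))))
  expect_error(month_to_season(13), "between 1 and 12")
})

test_that("section months step backwards from the growth-model root", {
  # pre-moult: root -> November of the previous year
  pre <- assign_months(as.Date("2014-06-15"), "pre_moult", 3)
  expect_equal(pre$month, c(11L, 10L, 9L))
  expect_equal(pre$year, rep(2013L, 3))
  expect_equal(pre$season, c("autumn", "autumn", "late_summer"))

  # post-moult: root -> month preceding collection
  post <- assign_months(as.Date("2014-09-15"), "post_moult", 2)
  expect_equal(post$month, c(8L, 7L))
  expect_equal(post$year, rep(2014L, 2))

  # stepping past the activity start flags sections, never drops them
  long <- assign_months(as.Date("2014-09-15"), "post_moult", 8)
  expect_equal(long$month, c(8L, 7L, 6L, 5L, 4L, 3L, 2L, 1L))
  expect_equal(long$out_of_activity, c(rep(FALSE, 6), TRUE, TRUE))

  expect_error(assign_months(as.Date("2014-07-15"), "excluded_moult", 2),
    "pre- or post-moult"
  )
})

test_that("chronology is pure: strictly decreasing months, reproducible", {
  for (case in list(
    list(date = "2014-06-15", period = "pre_moult", n = 9),
    list(date = "2014-09-15", period = "post_moult", n = 6)
  )) {
    a <- assign_months(as.Date(case$date), case$period, case$n)
    b <- assign_months(as.Date(case$date), case$period, case$n)
    expect_identical(a, b)
    serial <- a$year * 12 + a$month
    expect_true(all(diff(serial) == -1))
    expect_true(all(serial <
      as.integer(format(as.Date(case$date), "%Y")) * 12 +
        as.integer(format(as.Date(case$date), "%m"))))
  }
})

test_that("build_chronology joins hairs and sections with exclusion reasons", {
  hairs <- tibble::tibble(
    sample_id = c("H1", "H2", "H3"),
    bear_id = c("B1", "B1", "B2"),
    collection_date = c("2014-06-15", "2014-07-20", "2014-09-15"),
    length_mm = c(45, 30, 90)
  )
  sections <- tidyr::expand_grid(
    sample_id = c("H1", "H2", "H3"), section_index = 0:5
  ) |>
    dplyr::mutate(d13C = -22, d15N = 3)
  out <- build_chronology(hairs, sections)
  # moult-period hair is retained but excluded
  expect_true(all(
    out$exclusion_reason[out$sample_id == "H2"] == "collected_during_moult"
  ))
  # sections beyond the measured hair length are flagged
  h1 <- out[out$sample_id == "H1", ]
  expect_equal(sum(is.na(h1$exclusion_reason)), 3)
  expect_true(all(
    h1$exclusion_reason[h1$section_index >= 3] == "beyond_measured_length"
  ))
  # post-moult 90 mm hair: Aug..Mar, all in activity
  h3 <- out[out$sample_id == "H3", ]
  expect_equal(h3$month[1:6], c(8L, 7L, 6L, 5L, 4L, 3L))
  expect_true(all(is.na(h3$exclusion_reason)))
  expect_error(
    build_chronology(hairs, dplyr::bind_rows(sections, sections[1, ])),
    "Duplicate"
  )
})

test_that("synthetic scenarios reproduce configured per-season counts exactly", {
  scn <- generate_scenario(scenario_config(seed = 21))
  chron <- build_chronology(scn$hairs, scn$sections) |>
    dplyr::left_join(scn$bears, by = "bear_id")
  got <- chron |>
    dplyr::filter(is.na(exclusion_reason)) |>
    dplyr::count(season, sex)
  want <- default_section_counts()
  merged <- dplyr::left_join(want, got, by = c("season", "sex"))
  expect_equal(merged$n, merged$n_sections)
})
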