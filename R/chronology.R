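#' Classify a hair collection date relative to the annual moult
#'
#' Bears moult once a year between late spring and summer; hairs collected in
#' June are fully grown hairs from the previous activity period (pre-moult),
#' hairs collected in September grew during the current activity period
#' (post-moult). Hairs collected during the moult itself (July, August) are
#' excluded because their growth period is ambiguous, and collections in any
#' other month fall outside the sampling design.
#'
#' @param collection_date `Date` vector (or string coercible via
#'   `as.Date()`).
#' @return Character vector: `"pre_moult"`, `"post_moult"`,
#'   `"excluded_moult"` (July/August) or `"excluded_out_of_design"`.
#' @export
classify_sampling_period <- function(collection_date) {
  d <- as.Date(collection_date)
  if (any(is.na(d))) {
    abort("`collection_date` contains unparseable dates.")
  }
  m <- as.integer(format(d, "%m"))
  dplyr::case_when(
    m == 6 ~ "pre_moult",
    m == 9 ~ "post_moult",
    m %in% c(7, 8) ~ "excluded_moult",
    TRUE ~ "excluded_out_of_design"
  )
}

#' Number of full 15-mm sections in a hair
#'
#' Guard hairs grow at roughly 15 mm per month, so each full 15-mm section
#' archives about one month of diet. The terminal remainder shorter than one
#' section is discarded: tip material is the oldest and most uncertain.
#'
#' @param length_mm Hair length(s) in millimetres (> 0).
#' @param section_length_mm Section length in millimetres (default 15).
#' @return Tibble with `length_mm`, `n_sections`, `remainder_mm` and a
#'   `usable` flag (`FALSE` when no full section fits).
#' @export
section_hair <- function(length_mm, section_length_mm = 15) {
  if (any(!is.finite(length_mm)) || any(length_mm <= 0)) {
    abort("`length_mm` must be finite and strictly positive.")
  }
  if (section_length_mm <= 0) {
    abort("`section_length_mm` must be strictly positive.")
  }
  n <- floor(length_mm / section_length_mm)
  tibble::tibble(
    length_mm = length_mm,
    n_sections = as.integer(n),
    remainder_mm = length_mm - n * section_length_mm,
    usable = n >= 1
  )
}

#' Map a calendar month to a dietary season
#'
#' Seasons follow the phenology of the key bear foods: spring
#' (March-May), early summer (June-July), late summer (August-September),
#' autumn (October-November). December-February fall in dormancy and belong
#' to no dietary season (`NA`).
#'
#' @param month Integer month(s), 1-12.
#' @return Character vector of `"spring"`, `"early_summer"`,
#'   `"late_summer"`, `"autumn"` or `NA` for dormancy months.
#' @export
month_to_season <- function(month) {
  if (any(!is.finite(month)) || any(month < 1 | month > 12) ||
    any(month != floor(month))) {
    abort("`month` must be an integer between 1 and 12.")
  }
  dplyr::case_when(
    month %in% 3:5 ~ "spring",
    month %in% 6:7 ~ "early_summer",
    month %in% 8:9 ~ "late_summer",
    month %in% 10:11 ~ "autumn",
    TRUE ~ NA_character_
  )
}

#' Season level order used throughout the package
#' @return Character vector of the four dietary seasons in calendar order.
#' @export
season_levels <- function() {
  c("spring", "early_summer", "late_summer", "autumn")
}

#' Assign calendar months to the sections of one hair
#'
#' Sections are counted from the root (index 0). For pre-moult hairs
#' (collected in June of year Y, fully grown the previous activity period)
#' the basal section is assigned to the last month of growth before dormancy
#' (November of Y - 1), and each successive section steps one calendar month
#' backwards. For post-moult hairs the basal section is assigned to the
#' calendar month preceding the collection month, stepping backwards likewise.
#' Sections reaching months before the start of the activity period
#' (March by default) are flagged `out_of_activity`.
#'
#' @param collection_date Collection `Date` of the hair.
#' @param period `"pre_moult"` or `"post_moult"` (see
#'   [classify_sampling_period()]).
#' @param n_sections Number of full 15-mm sections.
#' @param activity_start First month of the activity period (default 3,
#'   March).
#' @return Tibble with `section_index` (0-based from the root), `month`,
#'   `year`, `season`, `out_of_activity`.
#' @export
assign_months <- function(collection_date, period, n_sections,
                          activity_start = 3) {
  if (!period %in% c("pre_moult", "post_moult")) {
    abort(paste0(
      "Months can only be assigned for pre- or post-moult hairs, got \"",
      period, "\"."
    ))
  }
  if (n_sections < 1) {
    abort("`n_sections` must be at least 1.")
  }
  d <- as.Date(collection_date)
  cy <- as.integer(format(d, "%Y"))
  cm <- as.integer(format(d, "%m"))
  if (period == "pre_moult") {
    root_month <- 11L
    root_year <- cy - 1L
  } else {
    root_month <- cm - 1L
    root_year <- cy
    if (root_month == 0L) {
      root_month <- 12L
      root_year <- cy - 1L
    }
  }
  # step backwards one calendar month per section, root -> tip
  idx <- seq_len(n_sections) - 1L
  serial <- (root_year * 12L + (root_month - 1L)) - idx
  month <- serial %% 12L + 1L
  year <- serial %/% 12L
  tibble::tibble(
    section_index = idx,
    month = as.integer(month),
    year = as.integer(year),
    season = month_to_season(month),
    out_of_activity = month < activity_start | month == 12L
  )
}

#' Build a section-level chronology for a set of hairs
#'
#' Joins a hair table with its section-level isotope measurements and assigns
#' each section a calendar month, year and dietary season under the 15-mm /
#' month growth model. Hairs collected during or outside the June/September
#' windows are retained with an `exclusion_reason`; so are sections falling
#' outside the activity period or in dormancy months.
#'
#' @param hairs Tibble with columns `sample_id`, `bear_id`,
#'   `collection_date`, `length_mm` (and optionally `method`).
#' @param sections Tibble with columns `sample_id`, `section_index` (0-based
#'   from the root), `d13C`, `d15N`.
#' @param activity_start First month of the activity period (default March).
#' @return Tibble with one row per measured section: identifiers, isotopes,
#'   `month`, `year`, `season`, `sampling_period` and `exclusion_reason`
#'   (`NA` when the section enters the models).
#' @export
build_chronology <- function(hairs, sections, activity_start = 3) {
  required_h <- c("sample_id", "bear_id", "collection_date", "length_mm")
  missing_h <- setdiff(required_h, names(hairs))
  if (length(missing_h) > 0) {
    abort(paste0("`hairs` lacks column(s): ", paste(missing_h, collapse = ", ")))
  }
  required_s <- c("sample_id", "section_index", "d13C", "d15N")
  missing_s <- setdiff(required_s, names(sections))
  if (length(missing_s) > 0) {
    abort(paste0(
      "`sections` lacks column(s): ", paste(missing_s, collapse = ", ")
    ))
  }
  if (anyDuplicated(sections[c("sample_id", "section_index")]) > 0) {
    abort("Duplicate (sample_id, section_index) in `sections`.")
  }
  hairs <- hairs |>
    dplyr::mutate(
      collection_date = as.Date(.data$collection_date),
      sampling_period = classify_sampling_period(.data$collection_date),
      n_sections = section_hair(.data$length_mm)$n_sections
    )
  assignments <- hairs |>
    dplyr::filter(
      .data$sampling_period %in% c("pre_moult", "post_moult"),
      .data$n_sections >= 1
    ) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      sample_id = .data$sample_id,
      assign_months(
        .data$collection_date, .data$sampling_period, .data$n_sections,
        activity_start = activity_start
      )
    )
  out <- sections |>
    dplyr::inner_join(
      hairs |>
        dplyr::select(
          "sample_id", "bear_id", "collection_date", "sampling_period",
          "n_sections"
        ),
      by = "sample_id"
    ) |>
    dplyr::left_join(assignments, by = c("sample_id", "section_index")) |>
    dplyr::mutate(
      exclusion_reason = dplyr::case_when(
        .data$sampling_period == "excluded_moult" ~ "collected_during_moult",
        .data$sampling_period == "excluded_out_of_design" ~
          "collected_outside_design",
        .data$section_index >= .data$n_sections ~ "beyond_measured_length",
        .data$out_of_activity | is.na(.data$season) ~ "out_of_activity",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select(
      "sample_id", "bear_id", "section_index", "d13C", "d15N",
      "month", "year", "season", "sampling_period", "exclusion_reason"
    ) |>
    dplyr::arrange(.data$sample_id, .data$section_index)
  out
}
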