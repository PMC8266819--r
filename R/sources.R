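#' Key-food source category vocabulary
#'
#' The diet sources recognised by the pipeline: seven key-food categories plus
#' C4 plants (corn). C4 is retained in diagnostics but excluded from the
#' mixing space used by the models because its carbon signature falls far
#' outside the consumer mixing region.
#'
#' @param include_c4 Keep the "C4" label (default `TRUE`).
#' @return Character vector of category labels, alphabetical.
#' @export
source_categories <- function(include_c4 = TRUE) {
  cats <- c(
    "C4", "Cultivated fleshy fruits", "Cultivated vegetables",
    "Formicidae", "Hard mast", "Herbs", "Ungulates", "Wild fleshy fruits"
  )
  if (!include_c4) cats <- setdiff(cats, "C4")
  cats
}

#' Read key-food source samples from CSV
#'
#' Expects one row per analysed food sample with columns `species`,
#' `category`, `trophic_class`, `d13C`, `d15N`, `C_pct`, `N_pct`,
#' `digest_C_pct`, `digest_N_pct`. Category labels must belong to the closed
#' vocabulary of [source_categories()] (extensible via `categories`).
#'
#' @param path Path to a UTF-8 CSV file with a dot decimal separator.
#' @param categories Permitted category labels.
#' @return A tibble of source samples, one row per sample.
#' @export
read_sources <- function(path, categories = source_categories()) {
  if (!file.exists(path)) {
    abort(paste0("Source file not found: ", path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c(
    "species", "category", "trophic_class", "d13C", "d15N",
    "C_pct", "N_pct", "digest_C_pct", "digest_N_pct"
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "Source file is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  df <- tibble::as_tibble(df[required])
  if (nrow(df) == 0) {
    return(df)
  }
  num_cols <- c("d13C", "d15N", "C_pct", "N_pct", "digest_C_pct", "digest_N_pct")
  for (col in num_cols) {
    vals <- df[[col]]
    if (!is.numeric(vals)) {
      parsed <- suppressWarnings(as.numeric(vals))
      bad <- which(is.na(parsed) & !is.na(vals) & trimws(vals) != "")
      if (length(bad) > 0) {
        abort(paste0(
          "Non-numeric value in column `", col, "` at row ", bad[1],
          ": \"", vals[bad[1]], "\""
        ))
      }
      df[[col]] <- parsed
    }
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      abort(paste0("Missing or non-finite `", col, "` at row ", bad[1]))
    }
  }
  unknown <- which(!df$category %in% categories)
  if (length(unknown) > 0) {
    abort(paste0(
      "Unknown source category \"", df$category[unknown[1]],
      "\" at row ", unknown[1],
      " (permitted: ", paste(categories, collapse = ", "), ")"
    ))
  }
  bad_tc <- which(!df$trophic_class %in% c("vegetable", "animal"))
  if (length(bad_tc) > 0) {
    abort(paste0(
      "Invalid trophic_class \"", df$trophic_class[bad_tc[1]],
      "\" at row ", bad_tc[1], " (must be \"vegetable\" or \"animal\")"
    ))
  }
  for (col in c("C_pct", "N_pct", "digest_C_pct", "digest_N_pct")) {
    bad <- which(df[[col]] <= 0 | df[[col]] > 100)
    if (length(bad) > 0) {
      abort(paste0("`", col, "` outside (0, 100] at row ", bad[1]))
    }
  }
  df
}

#' Aggregate source samples into category-level distributions
#'
#' Collapses per-sample key-food measurements into one distribution per
#' category: the grand mean and total (N - 1 denominator) standard deviation
#' of each isotope, plus mean elemental and digestible elemental
#' concentrations. These are the source distributions the mixing model uses.
#'
#' @param samples Tibble from [read_sources()].
#' @return A tibble with one row per category: `category`, `trophic_class`,
#'   `n`, `mean_d13C`, `sd_d13C`, `mean_d15N`, `sd_d15N`, `digest_c`,
#'   `digest_n` (concentrations as % dry weight).
#' @export
aggregate_sources <- function(samples) {
  if (nrow(samples) == 0) {
    abort("Cannot aggregate an empty sample table.")
  }
  samples |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      trophic_class = unique(.data$trophic_class)[1],
      n = dplyr::n(),
      mean_d13C = mean(.data$d13C),
      sd_d13C = if (dplyr::n() > 1) sd(.data$d13C) else 0,
      mean_d15N = mean(.data$d15N),
      sd_d15N = if (dplyr::n() > 1) sd(.data$d15N) else 0,
      digest_c = mean(.data$digest_C_pct),
      digest_n = mean(.data$digest_N_pct),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$category)
}

#' Pool species-level summary statistics into category statistics
#'
#' Given per-species summary rows (mean, SD, n) this computes, per category,
#' the sample-size-weighted mean of species means and the pooled total SD
#' combining within-species and between-species sums of squares with an
#' N - 1 denominator. For raw data whose species moments match the summaries
#' exactly this equals the grand mean / SD over all samples, which is how the
#' published category rows are reproduced from published species rows.
#'
#' @param species_stats Tibble with columns `category`, `species`,
#'   `trophic_class`, `n`, and `<var>_mean` / `<var>_sd` pairs for variables
#'   `d13C`, `d15N`, `C`, `N`.
#' @param digestibility Named numeric of length 2 (`c`, `n`): digestibility
#'   multipliers applied to mean elemental concentrations to obtain digestible
#'   concentrations. Defaults to 1 for both (digestible = elemental).
#' @return A tibble with one row per category (same shape as
#'   [aggregate_sources()], plus pooled `mean_c`, `sd_c`, `mean_n`, `sd_n`).
#' @export
pool_category_stats <- function(species_stats,
                                digestibility = c(c = 1, n = 1)) {
  if (nrow(species_stats) == 0) {
    abort("Cannot pool an empty species table.")
  }
  if (any(species_stats$n < 1)) {
    abort("Species sample sizes must be >= 1.")
  }
  pool_var <- function(n, m, s) {
    # within + between sums of squares, denominator N - 1
    N <- sum(n)
    if (N <= 1) {
      return(0)
    }
    gm <- sum(n * m) / N
    ss_within <- sum((n - 1) * s^2)
    ss_between <- sum(n * (m - gm)^2)
    (ss_within + ss_between) / (N - 1)
  }
  species_stats |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      trophic_class = unique(.data$trophic_class)[1],
      mean_d13C = sum(.data$n * .data$d13C_mean) / sum(.data$n),
      sd_d13C = sqrt(pool_var(.data$n, .data$d13C_mean, .data$d13C_sd)),
      mean_d15N = sum(.data$n * .data$d15N_mean) / sum(.data$n),
      sd_d15N = sqrt(pool_var(.data$n, .data$d15N_mean, .data$d15N_sd)),
      mean_c = sum(.data$n * .data$C_mean) / sum(.data$n),
      sd_c = sqrt(pool_var(.data$n, .data$C_mean, .data$C_sd)),
      mean_n = sum(.data$n * .data$N_mean) / sum(.data$n),
      sd_n = sqrt(pool_var(.data$n, .data$N_mean, .data$N_sd)),
      n = sum(.data$n), # must come last: summarise masks columns sequentially
      .groups = "drop"
    ) |>
    dplyr::mutate(
      digest_c = .data$mean_c * digestibility[["c"]],
      digest_n = .data$mean_n * digestibility[["n"]]
    ) |>
    dplyr::arrange(.data$category)
}

#' Packaged species-level key-food reference table
#'
#' Summary statistics (mean, SD, n for both isotopes and elemental
#' concentrations) of the key bear foods sampled in the central Apennines,
#' by species within the eight source categories.
#'
#' @return Tibble of species-level summaries.
#' @export
key_food_species <- function() {
  path <- system.file("extdata", "key_food_species.csv", package = "isodiet")
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
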