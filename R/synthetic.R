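#' Moment-matched sample-level key-food fixture
#'
#' Expands the species-level reference table ([key_food_species()]) into
#' per-sample rows: for each species, `n` values are drawn per variable and
#' then affinely adjusted so the sample mean and SD match the published
#' species-level statistics exactly. Aggregating the result therefore
#' reproduces the published category rows. Digestible concentrations default
#' to the elemental concentrations (digestibility multiplier 1).
#'
#' @param seed Integer seed.
#' @param species_stats Species-level summary tibble (defaults to the
#'   packaged reference table).
#' @param digestibility Named multipliers (`c`, `n`) mapping elemental to
#'   digestible concentrations.
#' @return Tibble in the [read_sources()] schema, one row per sample.
#' @export
generate_table1_fixture <- function(seed = 1,
                                    species_stats = key_food_species(),
                                    digestibility = c(c = 1, n = 1)) {
  moment_match <- function(n, mean, s) {
    if (n == 1 || s == 0) {
      return(rep(mean, n))
    }
    for (attempt in 1:20) {
      x <- rnorm(n)
      if (sd(x) > 0) break
    }
    x <- (x - mean(x)) / sd(x) * s + mean
    x
  }
  withr::with_seed(seed, {
    rows <- purrr::pmap(species_stats, function(category, species,
                                                trophic_class, n, d13C_mean,
                                                d13C_sd, d15N_mean, d15N_sd,
                                                C_mean, C_sd, N_mean, N_sd) {
      # redraw (bounded) if concentrations stray outside (0, 100]
      for (attempt in 1:50) {
        C_pct <- moment_match(n, C_mean, C_sd)
        N_pct <- moment_match(n, N_mean, N_sd)
        if (all(C_pct > 0 & C_pct <= 100) && all(N_pct > 0 & N_pct <= 100)) {
          break
        }
      }
      tibble::tibble(
        species = species, category = category,
        trophic_class = trophic_class,
        d13C = moment_match(n, d13C_mean, d13C_sd),
        d15N = moment_match(n, d15N_mean, d15N_sd),
        C_pct = C_pct, N_pct = N_pct
      )
    })
    dplyr::bind_rows(rows) |>
      dplyr::mutate(
        digest_C_pct = .data$C_pct * digestibility[["c"]],
        digest_N_pct = .data$N_pct * digestibility[["n"]]
      )
  })
}

#' Default synthetic bear roster
#'
#' 27 bears (16 females, 11 males) with a fixed, synthetic management-status
#' assignment (3 management, 4 unknown, the rest non-management).
#'
#' @return Tibble with `bear_id`, `sex`, `status`.
#' @export
default_bear_roster <- function() {
  ids <- c(sprintf("F%02d", 1:16), sprintf("M%02d", 1:11))
  sex <- c(rep("F", 16), rep("M", 11))
  status <- rep("non-management", 27)
  status[c(1, 2, 17)] <- "management"
  status[c(15, 16, 26, 27)] <- "unknown"
  tibble::tibble(bear_id = ids, sex = sex, status = status)
}

#' Default per-season section counts
#'
#' The study design the generator emulates: hair-section counts per dietary
#' season and sex (45/9 in spring, 40/21 in early summer, 33/22 in late
#' summer, 14/12 in autumn for females/males).
#'
#' @return Tibble with `season`, `sex`, `n_sections`.
#' @export
default_section_counts <- function() {
  tibble::tibble(
    season = rep(season_levels(), each = 2),
    sex = rep(c("F", "M"), 4),
    n_sections = c(45L, 9L, 40L, 21L, 33L, 22L, 14L, 12L)
  )
}

#' Default true seasonal diet compositions
#'
#' Synthetic ground-truth diet proportions per season (identical for both
#' sexes by default), chosen to echo the qualitative seasonal pattern of a
#' temperate omnivore: herbs dominant in spring, ants in early summer, wild
#' fleshy fruits in late summer and hard mast in autumn.
#'
#' @return Tibble with `season`, `sex`, `source`, `prop`; proportions sum to
#'   1 within each season and sex.
#' @export
default_true_diets <- function() {
  src <- source_categories(include_c4 = FALSE)
  comp <- list(
    spring = c(0.07, 0.03, 0.08, 0.25, 0.35, 0.10, 0.12),
    early_summer = c(0.08, 0.05, 0.33, 0.08, 0.22, 0.06, 0.18),
    late_summer = c(0.15, 0.05, 0.10, 0.12, 0.08, 0.05, 0.45),
    autumn = c(0.15, 0.05, 0.06, 0.50, 0.08, 0.04, 0.12)
  )
  purrr::imap(comp, function(p, season) {
    tidyr::expand_grid(sex = c("F", "M"), source = src) |>
      dplyr::mutate(season = season, prop = rep(p, 2))
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("season", "sex", "source", "prop")
}

#' Scenario configuration for the synthetic-data generator
#'
#' Bundles everything the generator needs: source distributions (the
#' species-level reference table), TEFs, the bear roster, per-season section
#' counts, true seasonal diets per sex, error magnitudes and a master seed.
#' The defaults reproduce the study design the analysis assumes (27 bears,
#' the default section counts, the packaged source table, the default TEFs).
#'
#' @param species_stats Species-level source summary table.
#' @param tefs TEF tibble ([default_tefs()]).
#' @param bears Bear roster tibble (`bear_id`, `sex`, `status`).
#' @param section_counts Per-season/sex section counts.
#' @param diets True diet compositions (`season`, `sex`, `source`, `prop`).
#' @param sigma_res Residual SD per isotope (per mil).
#' @param sigma_bear SD of individual random effects in ILR space.
#' @param digestibility Digestibility multipliers (`c`, `n`).
#' @param year Collection year.
#' @param seed Master seed; all stream seeds derive from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(species_stats = key_food_species(),
                            tefs = default_tefs(),
                            bears = default_bear_roster(),
                            section_counts = default_section_counts(),
                            diets = default_true_diets(),
                            sigma_res = c(0.5, 0.5),
                            sigma_bear = 0.3,
                            digestibility = c(c = 1, n = 1),
                            year = 2014,
                            seed = 1) {
  sums <- diets |>
    dplyr::group_by(.data$season, .data$sex) |>
    dplyr::summarise(s = sum(.data$prop), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-8) || any(diets$prop < 0)) {
    abort("True diets must be non-negative and sum to 1 per season and sex.")
  }
  if (any(section_counts$n_sections < 0)) {
    abort("Section counts must be non-negative.")
  }
  if (any(sigma_res < 0) || sigma_bear < 0) {
    abort("Error magnitudes must be non-negative.")
  }
  structure(
    list(
      species_stats = species_stats, tefs = tefs, bears = bears,
      section_counts = section_counts, diets = diets,
      sigma_res = rep(sigma_res, length.out = 2), sigma_bear = sigma_bear,
      digestibility = digestibility, year = year, seed = seed
    ),
    class = "scenario_config"
  )
}

# Allocate hairs (collection period + section count) reproducing exact
# per-season section totals under the contiguous backwards-growth model.
# Pre-moult hairs grow root = November backwards; post-moult (September)
# root = August backwards.
allocate_hairs <- function(counts) {
  need <- setNames(rep(0L, 4), season_levels())
  need[counts$season] <- as.integer(counts$n_sections)
  s <- need[["spring"]]
  e <- need[["early_summer"]]
  l <- need[["late_summer"]]
  a <- need[["autumn"]]
  hairs <- list()
  add <- function(period, n) {
    hairs[[length(hairs) + 1]] <<- list(period = period, n_sections = n)
  }
  while (a > 0) {
    at <- min(2L, a)
    lt <- et <- st <- 0L
    if (at == 2L) lt <- min(2L, l)
    if (lt == 2L) et <- min(2L, e)
    if (et == 2L) st <- min(3L, s)
    add("pre_moult", at + lt + et + st)
    a <- a - at
    l <- l - lt
    e <- e - et
    s <- s - st
  }
  while (s > 0) {
    if (l < 1 || e < 2) {
      abort("Infeasible section counts: spring sections need contiguous late-summer and early-summer growth.")
    }
    st <- min(3L, s)
    add("post_moult", 3L + st)
    s <- s - st
    e <- e - 2L
    l <- l - 1L
  }
  while (e > 0) {
    if (l < 1) {
      abort("Infeasible section counts: early-summer sections need a contiguous late-summer section.")
    }
    et <- min(2L, e)
    add("post_moult", 1L + et)
    e <- e - et
    l <- l - 1L
  }
  while (l > 0) {
    add("post_moult", 1L)
    l <- l - 1L
  }
  hairs
}

#' Generate a fully specified synthetic study
#'
#' Produces sample-level sources, a hair table whose chronology reproduces
#' the configured per-season section counts exactly, section-level isotope
#' values drawn from the same mixing equations the model assumes
#' (concentration-weighted mixture mean; process + residual variance), and a
#' `truth` record of every latent quantity. Per bear and season the true
#' composition is the inverse-ILR of the group (season x sex) ILR mean plus
#' the bear's random effect.
#'
#' @param config A [scenario_config()].
#' @return List of class `scenario` with elements `sources`, `hairs`,
#'   `sections`, `truth`, `space` (the mixing space used to simulate).
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  sources <- generate_table1_fixture(
    seed = config$seed,
    species_stats = config$species_stats,
    digestibility = config$digestibility
  )
  categories <- aggregate_sources(sources)
  space <- build_mixing_space(categories, tefs = config$tefs)
  src_names <- rownames(space$mu)
  K <- length(src_names)

  withr::with_seed(config$seed + 1L, {
    # bear random effects in ILR space, one draw per bear, fixed across seasons
    bears <- config$bears
    b_eff <- matrix(
      rnorm(nrow(bears) * (K - 1), 0, config$sigma_bear),
      nrow = nrow(bears)
    )
    rownames(b_eff) <- bears$bear_id

    # group ILR means per season x sex (empty coordinates when K = 1)
    diets <- config$diets |>
      dplyr::arrange(.data$season, .data$sex, .data$source)
    stopifnot(all(sort(unique(diets$source)) == src_names))
    group_z <- diets |>
      dplyr::group_by(.data$season, .data$sex) |>
      dplyr::summarise(
        z = list(if (K == 1) numeric(0) else {
          ilr_transform(pmax(.data$prop[order(.data$source)], 1e-8) /
            sum(pmax(.data$prop[order(.data$source)], 1e-8)))
        }),
        .groups = "drop"
      )

    # hairs per sex, reproducing section counts exactly
    hair_rows <- list()
    for (sx in unique(config$section_counts$sex)) {
      counts <- config$section_counts |> dplyr::filter(.data$sex == sx)
      alloc <- allocate_hairs(counts)
      roster <- bears$bear_id[bears$sex == sx]
      if (length(roster) == 0) {
        abort(paste0("No bears of sex ", sx, " in the roster."))
      }
      for (i in seq_along(alloc)) {
        hair_rows[[length(hair_rows) + 1]] <- tibble::tibble(
          bear_id = roster[(i - 1) %% length(roster) + 1],
          sex = sx,
          collection_date = if (alloc[[i]]$period == "pre_moult") {
            as.Date(sprintf("%d-06-15", config$year))
          } else {
            as.Date(sprintf("%d-09-15", config$year))
          },
          n_sections = alloc[[i]]$n_sections,
          length_mm = alloc[[i]]$n_sections * 15
        )
      }
    }
    hairs <- dplyr::bind_rows(hair_rows) |>
      dplyr::mutate(
        sample_id = sprintf("H%03d", dplyr::row_number()),
        method = rep_len(c("HS", "RT", "RAM", "Acc"), dplyr::n()),
        .before = 1
      )

    # section-level chronology and isotope values
    sec_rows <- purrr::pmap(hairs, function(sample_id, method, bear_id, sex,
                                            collection_date, n_sections,
                                            length_mm) {
      period <- classify_sampling_period(collection_date)
      asg <- assign_months(collection_date, period, n_sections)
      asg$sample_id <- sample_id
      asg$bear_id <- bear_id
      asg$sex <- sex
      asg
    })
    sections <- dplyr::bind_rows(sec_rows)

    # true composition per bear x season, then draw the isotope values
    truth_bear <- list()
    sections$d13C <- NA_real_
    sections$d15N <- NA_real_
    for (i in seq_len(nrow(sections))) {
      sn <- sections$season[i]
      sx <- sections$sex[i]
      bid <- sections$bear_id[i]
      z <- group_z$z[group_z$season == sn & group_z$sex == sx][[1]]
      p <- if (K == 1) 1 else ilr_inverse(z + b_eff[bid, ], K = K)
      key <- paste(bid, sn, sep = "|")
      if (is.null(truth_bear[[key]])) {
        truth_bear[[key]] <- tibble::tibble(
          bear_id = bid, season = sn, source = src_names, prop = p
        )
      }
      for (e in c(1L, 2L)) {
        iso <- c("d13C", "d15N")[e]
        m <- mixture_mean(p, space, iso)
        v <- mixture_process_var(p, space, iso) + config$sigma_res[e]^2
        sections[[iso]][i] <- rnorm(1, m, sqrt(v))
      }
    }

    truth <- list(
      seed = config$seed,
      sigma_res = config$sigma_res,
      sigma_bear = config$sigma_bear,
      source_order = src_names,
      group_diets = diets,
      bear_effects = if (K == 1) {
        tibble::tibble(bear_id = bears$bear_id)
      } else {
        tibble::as_tibble(b_eff, .name_repair = ~ paste0(
          "ilr", seq_len(K - 1)
        )) |>
          dplyr::mutate(bear_id = bears$bear_id, .before = 1)
      },
      bear_diets = dplyr::bind_rows(truth_bear)
    )

    structure(
      list(
        sources = sources,
        hairs = hairs |>
          dplyr::select(
            "sample_id", "bear_id", "collection_date", "length_mm", "method"
          ),
        bears = bears,
        sections = sections |>
          dplyr::select(
            "sample_id", "section_index", "d13C", "d15N"
          ),
        truth = truth,
        space = space,
        config = config
      ),
      class = "scenario"
    )
  })
}

#' Write a synthetic scenario to disk
#'
#' Emits `sources.csv`, `hairs.csv`, `bears.csv`, `sections.csv` and
#' `truth.json` (all latent quantities plus the master seed) into `dir`.
#'
#' @param scenario From [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(scenario$sources, file.path(dir, "sources.csv"),
    row.names = FALSE
  )
  utils::write.csv(scenario$hairs, file.path(dir, "hairs.csv"),
    row.names = FALSE
  )
  utils::write.csv(scenario$bears, file.path(dir, "bears.csv"),
    row.names = FALSE
  )
  utils::write.csv(scenario$sections, file.path(dir, "sections.csv"),
    row.names = FALSE
  )
  truth <- scenario$truth
  jsonlite::write_json(
    list(
      seed = truth$seed,
      sigma_res = truth$sigma_res,
      sigma_bear = truth$sigma_bear,
      source_order = truth$source_order,
      group_diets = truth$group_diets,
      bear_effects = truth$bear_effects,
      bear_diets = truth$bear_diets
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
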