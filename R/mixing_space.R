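#' Default trophic enrichment factors
#'
#' Diet-to-hair trophic enrichment factors (TEFs) by trophic class, from
#' controlled feeding experiments on omnivorous mammals: vegetable foods
#' \eqn{\Delta^{13}C = 3.4 \pm 0.5}‰, \eqn{\Delta^{15}N = 2.4 \pm 0.2}‰;
#' animal foods \eqn{\Delta^{13}C = 2.1 \pm 0.2}‰,
#' \eqn{\Delta^{15}N = 3.9 \pm 0.3}‰.
#'
#' @return Tibble with one row per trophic class and columns
#'   `trophic_class`, `d13C_mean`, `d13C_sd`, `d15N_mean`, `d15N_sd`.
#' @export
default_tefs <- function() {
  tibble::tibble(
    trophic_class = c("vegetable", "animal"),
    d13C_mean = c(3.4, 2.1),
    d13C_sd = c(0.5, 0.2),
    d15N_mean = c(2.4, 3.9),
    d15N_sd = c(0.2, 0.3)
  )
}

#' Apply trophic enrichment factors to source categories
#'
#' Shifts each source category into consumer (hair) isotope space: corrected
#' mean = source mean + TEF mean, corrected SD = sqrt(source SD^2 + TEF SD^2),
#' per isotope, using the TEF of the category's trophic class.
#'
#' @param categories Tibble from [aggregate_sources()] or
#'   [pool_category_stats()].
#' @param tefs TEF table as from [default_tefs()].
#' @return `categories` with added columns `corr_mean_d13C`, `corr_sd_d13C`,
#'   `corr_mean_d15N`, `corr_sd_d15N`.
#' @export
apply_tef <- function(categories, tefs = default_tefs()) {
  missing_tc <- setdiff(unique(categories$trophic_class), tefs$trophic_class)
  if (length(missing_tc) > 0) {
    abort(paste0(
      "No TEF provided for trophic class(es): ",
      paste(missing_tc, collapse = ", ")
    ))
  }
  if (any(tefs$d13C_sd < 0) || any(tefs$d15N_sd < 0)) {
    abort("TEF standard deviations must be non-negative.")
  }
  categories |>
    dplyr::left_join(tefs, by = "trophic_class") |>
    dplyr::mutate(
      corr_mean_d13C = .data$mean_d13C + .data$d13C_mean,
      corr_sd_d13C = sqrt(.data$sd_d13C^2 + .data$d13C_sd^2),
      corr_mean_d15N = .data$mean_d15N + .data$d15N_mean,
      corr_sd_d15N = sqrt(.data$sd_d15N^2 + .data$d15N_sd^2)
    ) |>
    dplyr::select(-"d13C_mean", -"d13C_sd", -"d15N_mean", -"d15N_sd")
}

#' Build a TEF-corrected, concentration-weighted mixing space
#'
#' Combines aggregated source categories with TEFs and digestible elemental
#' concentrations into the mixing space used by the models. C4 plants are
#' dropped by default because their carbon signature does not match the
#' consumer mixing region. Source order is fixed (alphabetical) and recorded.
#'
#' @param categories Category table with per-isotope means/SDs and
#'   `digest_c`, `digest_n` columns.
#' @param tefs TEF table as from [default_tefs()].
#' @param exclude Categories to exclude from the model sources (default
#'   `"C4"`).
#' @return Object of class `mixing_space`: a list with `sources` (the
#'   corrected tibble, alphabetical by category), `mu` (K x 2 corrected
#'   means), `var` (K x 2 corrected variances), `q` (K x 2 digestible
#'   concentration weights), `isotopes = c("d13C", "d15N")`.
#' @export
build_mixing_space <- function(categories, tefs = default_tefs(),
                               exclude = "C4") {
  src <- categories |>
    dplyr::filter(!.data$category %in% exclude) |>
    dplyr::arrange(.data$category)
  if (nrow(src) < 1) {
    abort("Mixing space needs at least one source category.")
  }
  if (any(src$digest_c <= 0) || any(src$digest_n <= 0)) {
    abort("Digestible concentrations must be strictly positive.")
  }
  src <- apply_tef(src, tefs)
  mu <- cbind(d13C = src$corr_mean_d13C, d15N = src$corr_mean_d15N)
  vv <- cbind(d13C = src$corr_sd_d13C^2, d15N = src$corr_sd_d15N^2)
  # concentrations held as % internally; the mixing equation normalises them
  q <- cbind(d13C = src$digest_c, d15N = src$digest_n)
  rownames(mu) <- rownames(vv) <- rownames(q) <- src$category
  structure(
    list(
      sources = src, mu = mu, var = vv, q = q,
      isotopes = c("d13C", "d15N")
    ),
    class = "mixing_space"
  )
}

#' @export
print.mixing_space <- function(x, ...) {
  cat(
    "<mixing_space> ", nrow(x$mu), " sources: ",
    paste(rownames(x$mu), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Concentration-weighted mixture mean
#'
#' Expected consumer isotope value for a diet composition `p`:
#' \deqn{\mu_{mix} = \frac{\sum_k p_k q_k (\delta_k + \Delta_k)}
#'   {\sum_k p_k q_k},}
#' where \eqn{q_k} is the digestible concentration of the isotope's element
#' in source \eqn{k} and \eqn{\delta_k + \Delta_k} the TEF-corrected source
#' mean. Weighting by digestible concentration makes the estimated
#' proportions reflect assimilated element fluxes rather than ingested bulk.
#' The result is invariant to rescaling all \eqn{q_k} by a common constant.
#'
#' @param p Diet proportions: vector of length K (sums to 1) or an
#'   n x K matrix of compositions.
#' @param space A [build_mixing_space()] object.
#' @param isotope `"d13C"` or `"d15N"`.
#' @return Mixture mean(s) in per mil.
#' @export
mixture_mean <- function(p, space, isotope = c("d13C", "d15N")) {
  isotope <- match.arg(isotope)
  p <- as_composition_matrix(p, nrow(space$mu))
  q <- space$q[, isotope]
  mu <- space$mu[, isotope]
  w <- p %*% diag(q, nrow = length(q))
  denom <- rowSums(w)
  if (any(denom <= 0)) {
    abort("Concentration-weighted denominator is zero.")
  }
  out <- as.numeric((w %*% mu) / denom)
  out
}

#' Concentration-weighted process variance of the mixture
#'
#' Variance of the mixture value induced by source (and TEF) variability,
#' with the same concentration weights as [mixture_mean()]:
#' \eqn{\sum_k p_k^2 q_k^2 \sigma_k^2 / (\sum_k p_k q_k)^2}.
#'
#' @inheritParams mixture_mean
#' @return Process variance(s) in per-mil squared.
#' @export
mixture_process_var <- function(p, space, isotope = c("d13C", "d15N")) {
  isotope <- match.arg(isotope)
  p <- as_composition_matrix(p, nrow(space$mu))
  q <- space$q[, isotope]
  vv <- space$var[, isotope]
  w <- p %*% diag(q, nrow = length(q))
  denom <- rowSums(w)
  if (any(denom <= 0)) {
    abort("Concentration-weighted denominator is zero.")
  }
  as.numeric((w^2 %*% vv) / denom^2)
}

as_composition_matrix <- function(p, K) {
  if (is.null(dim(p))) {
    if (length(p) != K) {
      abort(paste0("`p` must have length ", K, " (one per source)."))
    }
    p <- matrix(p, nrow = 1)
  }
  if (ncol(p) != K) {
    abort(paste0("`p` must have ", K, " columns (one per source)."))
  }
  if (any(p < -1e-12)) {
    abort("Diet proportions must be non-negative.")
  }
  sums <- rowSums(p)
  if (any(abs(sums - 1) > 1e-6)) {
    abort("Diet proportions must sum to 1.")
  }
  p
}
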