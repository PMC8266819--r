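#' Posterior draws of diet compositions
#'
#' Reconstructs composition draws on the simplex from the sampled ILR
#' coordinates, for the baseline (population) composition, a covariate
#' level, or an individual bear (baseline + its covariate shifts + its
#' random effect).
#'
#' @param fit A [fit_simm()] object.
#' @param what `"population"`, a covariate level such as `"Sex:M"` /
#'   `"Status:management"`, or `"bear:<id>"`.
#' @return Matrix (draws x K sources) with source names as columns; every
#'   row sums to 1.
#' @export
composition_draws <- function(fit, what = "population") {
  if (isTRUE(fit$degenerate)) {
    n <- nrow(fit$loglik)
    out <- matrix(1, n, 1)
    colnames(out) <- rownames(fit$space$mu)
    return(out)
  }
  K <- nrow(fit$space$mu)
  draws <- do.call(rbind, fit$chains)
  znames <- function(col) paste0("z[", col, ",", seq_len(K - 1), "]")
  z <- draws[, znames("(Intercept)"), drop = FALSE]
  if (!identical(what, "population")) {
    if (startsWith(what, "bear:")) {
      id <- sub("^bear:", "", what)
      if (!id %in% fit$design$bears) {
        abort(paste0("Unknown bear id: ", id))
      }
      # the bear's own covariate levels
      row <- fit$sections[match(id, fit$sections$bear_id), , drop = FALSE]
      for (col in setdiff(colnames(fit$design$X), "(Intercept)")) {
        xv <- design_value(col, row)
        if (xv != 0) {
          z <- z + xv * draws[, znames(col), drop = FALSE]
        }
      }
      bn <- paste0("b[", id, ",", seq_len(K - 1), "]")
      z <- z + draws[, bn, drop = FALSE]
    } else {
      if (!what %in% colnames(fit$design$X)) {
        abort(paste0(
          "Unknown level \"", what, "\"; available: ",
          paste(setdiff(colnames(fit$design$X), "(Intercept)"),
            collapse = ", "
          )
        ))
      }
      z <- z + draws[, znames(what), drop = FALSE]
    }
  }
  p <- ilr_inverse(z, K = K)
  colnames(p) <- rownames(fit$space$mu)
  p
}

design_value <- function(col, row) {
  if (startsWith(col, "Sex:")) {
    as.numeric(row$sex == sub("^Sex:", "", col))
  } else if (startsWith(col, "Status:")) {
    as.numeric(row$status == sub("^Status:", "", col))
  } else {
    0
  }
}

summarise_composition <- function(p, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  tibble::tibble(
    source = colnames(p),
    mean = unname(colMeans(p)),
    sd = unname(apply(p, 2, sd)),
    conf.low = unname(apply(p, 2, quantile, probs = a)),
    conf.high = unname(apply(p, 2, quantile, probs = 1 - a))
  )
}

#' Summarise posterior diet proportions
#'
#' Posterior mean, SD and central credible interval of the diet proportion
#' of every source, at the population level and (when the model includes
#' them) per covariate level and per individual bear. This is the
#' `tidy()` method for `simm_fit` objects.
#'
#' @param x A [fit_simm()] object.
#' @param level Which summaries to return: `"population"`, `"group"`
#'   (population plus every covariate level), or `"bear"` (per individual).
#' @param conf_level Credible-interval mass (default 0.95).
#' @param ... Unused.
#' @return Tibble with columns `level`, `source`, `mean`, `sd`, `conf.low`,
#'   `conf.high`; sources in the fixed (alphabetical) mixing-space order.
#' @export
tidy.simm_fit <- function(x, level = c("population", "group", "bear"),
                          conf_level = 0.95, ...) {
  level <- match.arg(level)
  if (nrow(x$loglik) < 100 && !isTRUE(x$degenerate)) {
    warn("Fewer than 100 posterior draws; summaries will be noisy.")
  }
  targets <- "population"
  if (level == "group" && !isTRUE(x$degenerate)) {
    targets <- c(
      "population",
      setdiff(colnames(x$design$X), "(Intercept)")
    )
  } else if (level == "bear" && !isTRUE(x$degenerate)) {
    if (x$design$n_bears == 0) {
      abort("Model has no bear random effect; no per-bear summaries.")
    }
    targets <- paste0("bear:", x$design$bears)
  }
  purrr::map(targets, function(tg) {
    summarise_composition(composition_draws(x, tg), conf_level) |>
      dplyr::mutate(level = tg, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' One-row summary of a fitted mixing model
#'
#' Model label, data size, draw count, convergence pass rate and the
#' PSIS-LOO information criterion.
#'
#' @param x A [fit_simm()] object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.simm_fit <- function(x, ...) {
  loo <- psis_loo(x$loglik)
  conv <- x$convergence
  tibble::tibble(
    model = x$model,
    n_sections = nrow(x$sections),
    n_sources = nrow(x$space$mu),
    n_draws = nrow(x$loglik),
    looic = loo$looic,
    se_looic = loo$se,
    converged = fit_converged(x),
    max_rhat = if (nrow(conv) == 0) NA_real_ else
      suppressWarnings(max(conv$rhat, na.rm = TRUE))
  )
}

#' Posterior diet plot for a fitted mixing model
#'
#' Points at posterior means with credible-interval bars per source, for the
#' population or every covariate level.
#'
#' @param object A [fit_simm()] object.
#' @param level Passed to [tidy.simm_fit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.simm_fit <- function(object, level = "group", ...) {
  td <- tidy(object, level = level)
  ggplot2::ggplot(
    td,
    ggplot2::aes(
      x = .data$mean, y = .data$source, colour = .data$level
    )
  ) +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::labs(
      x = "Posterior diet proportion", y = NULL, colour = NULL,
      title = paste("Model:", object$model)
    ) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}
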