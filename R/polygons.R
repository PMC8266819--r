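#' Simulated mixing-polygon validation of consumers
#'
#' A consumer can only be expressed as a mixture of the sources if it lies
#' inside the convex hull of the TEF-corrected source signatures. Because the
#' source signatures are uncertain, the hull itself is uncertain: each
#' iteration draws every corrected source mean from a normal distribution
#' with its corrected mean and SD, forms the convex hull in
#' (\eqn{\delta^{13}C}, \eqn{\delta^{15}N}) space, and tests each consumer
#' for membership. The per-consumer fraction of iterations inside is its
#' mixing-region probability; consumers below `threshold` (the 95% mixing
#' region at the default 0.05) are flagged for exclusion from the models.
#'
#' @param space A [build_mixing_space()] object with at least 3 sources.
#' @param consumers Tibble with columns `consumer_id`, `d13C`, `d15N`.
#' @param n_iter Number of simulated hulls (default 1500).
#' @param threshold Exclusion threshold on the inside probability
#'   (default 0.05).
#' @param seed Integer seed for reproducibility.
#' @param spread `"sd"` draws source means with the corrected SD (population
#'   spread of plausible source signatures, the default); `"se"` scales by
#'   `1/sqrt(n)`.
#' @return Tibble with `consumer_id`, `inside_probability`, `excluded`,
#'   `n_iter`, `seed`.
#' @export
simulate_mixing_polygons <- function(space, consumers, n_iter = 1500,
                                     threshold = 0.05, seed = 1,
                                     spread = c("sd", "se")) {
  spread <- match.arg(spread)
  K <- nrow(space$mu)
  if (K < 3) {
    abort("Mixing polygons need at least 3 sources (degenerate geometry).")
  }
  if (n_iter < 1) {
    abort("`n_iter` must be at least 1.")
  }
  required <- c("consumer_id", "d13C", "d15N")
  missing <- setdiff(required, names(consumers))
  if (length(missing) > 0) {
    abort(paste0(
      "`consumers` lacks column(s): ", paste(missing, collapse = ", ")
    ))
  }
  sdx <- sqrt(space$var[, "d13C"])
  sdy <- sqrt(space$var[, "d15N"])
  if (spread == "se") {
    sdx <- sdx / sqrt(space$sources$n)
    sdy <- sdy / sqrt(space$sources$n)
  }
  px <- consumers$d13C
  py <- consumers$d15N
  inside <- integer(length(px))
  withr::with_seed(seed, {
    for (it in seq_len(n_iter)) {
      sx <- rnorm(K, space$mu[, "d13C"], sdx)
      sy <- rnorm(K, space$mu[, "d15N"], sdy)
      hull <- grDevices::chull(sx, sy)
      inside <- inside +
        in_convex_polygon(px, py, sx[hull], sy[hull])
    }
  })
  prob <- inside / n_iter
  tibble::tibble(
    consumer_id = consumers$consumer_id,
    inside_probability = prob,
    excluded = prob < threshold,
    n_iter = n_iter,
    seed = seed
  )
}

# Membership test for a convex polygon given in hull order (either
# orientation). Closed boundary: points within `tol` of an edge count as
# inside.
in_convex_polygon <- function(px, py, hx, hy, tol = 1e-9) {
  nh <- length(hx)
  if (nh < 3) {
    # degenerate hull (collinear draws): nothing is strictly inside
    return(integer(length(px)))
  }
  # orient counter-clockwise via the shoelace sum
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (area2 < 0) {
    hx <- rev(hx)
    hy <- rev(hy)
  }
  ok <- rep(TRUE, length(px))
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    ok <- ok & (cross >= -tol)
  }
  as.integer(ok)
}

#' Plot consumers over the corrected mixing space
#'
#' Scatterplot of consumer signatures over the TEF-corrected source means
#' with +/- 1 SD error bars and the source convex hull, the standard visual
#' companion to [simulate_mixing_polygons()].
#'
#' @param space A [build_mixing_space()] object.
#' @param consumers Optional tibble with `d13C`, `d15N` (and optionally a
#'   column to map to colour via `colour`).
#' @param colour Optional column name in `consumers` mapped to point colour.
#' @return A ggplot object.
#' @export
plot_mixing_space <- function(space, consumers = NULL, colour = NULL) {
  src <- space$sources
  hull <- grDevices::chull(src$corr_mean_d13C, src$corr_mean_d15N)
  hull_df <- src[c(hull, hull[1]), ]
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(
      data = hull_df,
      ggplot2::aes(x = .data$corr_mean_d13C, y = .data$corr_mean_d15N),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::geom_errorbar(
      data = src,
      ggplot2::aes(
        x = .data$corr_mean_d13C,
        ymin = .data$corr_mean_d15N - .data$corr_sd_d15N,
        ymax = .data$corr_mean_d15N + .data$corr_sd_d15N
      ),
      width = 0
    ) +
    ggplot2::geom_errorbarh(
      data = src,
      ggplot2::aes(
        y = .data$corr_mean_d15N,
        xmin = .data$corr_mean_d13C - .data$corr_sd_d13C,
        xmax = .data$corr_mean_d13C + .data$corr_sd_d13C
      ),
      height = 0
    ) +
    ggplot2::geom_point(
      data = src,
      ggplot2::aes(x = .data$corr_mean_d13C, y = .data$corr_mean_d15N),
      shape = 15, size = 2.5
    ) +
    ggplot2::geom_text(
      data = src,
      ggplot2::aes(
        x = .data$corr_mean_d13C, y = .data$corr_mean_d15N,
        label = .data$category
      ),
      vjust = -1, size = 3
    ) +
    ggplot2::labs(
      x = expression(delta^13 * C ~ "(‰)"),
      y = expression(delta^15 * N ~ "(‰)")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(consumers)) {
    if (!is.null(colour)) {
      p <- p + ggplot2::geom_point(
        data = consumers,
        ggplot2::aes(
          x = .data$d13C, y = .data$d15N,
          colour = .data[[colour]]
        ),
        alpha = 0.6
      )
    } else {
      p <- p + ggplot2::geom_point(
        data = consumers,
        ggplot2::aes(x = .data$d13C, y = .data$d15N),
        alpha = 0.6
      )
    }
  }
  p
}
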