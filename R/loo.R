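#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density under
#' leave-one-out cross-validation from posterior draws, without refitting:
#' for each observation the importance ratios \eqn{1/p(y_i|\theta^s)} are
#' stabilised by replacing their largest 20% with quantiles of a generalized
#' Pareto distribution fitted by the Zhang-Stephens method. Observations
#' whose Pareto shape \eqn{\hat{k} > 0.7} are flagged as unreliable. When
#' the Pareto fit fails (e.g. effectively constant weights) the observation
#' falls back to truncated importance sampling with a warning.
#'
#' @param loglik Matrix of pointwise log-likelihoods, draws x observations.
#' @return List with `looic` (\eqn{-2\sum \widehat{elpd}_i}), `se`
#'   (\eqn{2\sqrt{n \, \mathrm{Var}(\widehat{elpd}_i)}}), `pointwise`
#'   (per-observation elpd), `pareto_k`, and `n_bad_k` (count with
#'   \eqn{\hat k > 0.7}).
#' @export
psis_loo <- function(loglik) {
  if (!is.matrix(loglik)) {
    abort("`loglik` must be a draws x observations matrix.")
  }
  S <- nrow(loglik)
  n <- ncol(loglik)
  if (S < 100) {
    abort("PSIS-LOO needs at least 100 posterior draws.")
  }
  if (n < 2) {
    abort("PSIS-LOO needs at least 2 observations.")
  }
  if (any(!is.finite(loglik))) {
    abort("`loglik` contains non-finite values.")
  }
  elpd <- numeric(n)
  khat <- numeric(n)
  fell_back <- FALSE
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    lw <- -ll
    lw <- lw - max(lw)
    sm <- psis_smooth(lw)
    khat[i] <- sm$k
    if (!sm$ok) fell_back <- TRUE
    lw_s <- sm$lw
    elpd[i] <- logsumexp(ll + lw_s) - logsumexp(lw_s)
  }
  if (fell_back) {
    warn("Pareto fit failed for some observations; used truncated importance sampling there.")
  }
  looic <- -2 * sum(elpd)
  se <- 2 * sqrt(n * var(elpd))
  list(
    looic = looic, se = se, pointwise = elpd, pareto_k = khat,
    n_bad_k = sum(khat > 0.7, na.rm = TRUE)
  )
}

# smooth the weight tail (standard recipe: min(20%, 3*sqrt(S)) largest
# weights) with a fitted generalized Pareto
psis_smooth <- function(lw) {
  S <- length(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  ord <- order(lw)
  top <- ord[seq(S - M + 1, S)]
  cut <- if (S - M >= 1) exp(lw[ord[S - M]]) else 0
  x <- exp(lw[top]) - cut
  if (max(x) <= 0 || sd(x) == 0) {
    # degenerate weights: nothing to smooth
    return(list(lw = lw, k = NA_real_, ok = TRUE))
  }
  fit <- gpd_fit(x)
  if (is.null(fit) || !is.finite(fit$k) || !is.finite(fit$sigma) ||
    fit$sigma <= 0) {
    # truncated importance sampling fallback
    cap <- log(mean(exp(lw))) + 0.75 * log(S)
    return(list(lw = pmin(lw, cap), k = NA_real_, ok = FALSE))
  }
  jj <- seq_len(M)
  qq <- gpd_quantile((jj - 0.5) / M, fit$k, fit$sigma)
  smoothed <- log(pmin(cut + qq, exp(max(lw))))
  lw[top[order(lw[top])]] <- smoothed
  list(lw = lw, k = fit$k, ok = TRUE)
}

# Zhang-Stephens (2009) quasi-Bayesian generalized Pareto fit to exceedances
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5) {
    return(NULL)
  }
  prior_b <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  if (xstar <= 0) {
    return(NULL)
  }
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_b * xstar)
  kappa_of <- function(t) mean(log1p(-t * x)) # GPD shape at rate t
  kk <- vapply(theta, kappa_of, numeric(1))
  ll <- n * (log(-theta / kk) - kk - 1)
  ok <- is.finite(ll)
  if (!any(ok)) {
    return(NULL)
  }
  w <- exp(ll - max(ll[ok]))
  w[!ok] <- 0
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  kappa <- kappa_of(theta_hat)
  sigma <- -kappa / theta_hat
  # weakly informative shrinkage of the shape towards 0.5 (10 pseudo-obs)
  k <- (n * kappa + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) {
    -sigma * log1p(-p)
  } else {
    sigma * expm1(-k * log1p(-p)) / k
  }
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Akaike weights from information-criterion values
#'
#' Relative support of each model in a set:
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)} with
#' \eqn{\Delta_i} the difference from the smallest value, computed with
#' max-subtraction for numerical stability. Weights are invariant to adding
#' a constant to all values.
#'
#' @param looic Finite numeric vector of information-criterion values.
#' @return Numeric weights summing to 1.
#' @export
akaike_weights <- function(looic) {
  if (length(looic) < 1 || any(!is.finite(looic))) {
    abort("`looic` must be a non-empty vector of finite values.")
  }
  delta <- looic - min(looic)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Compare fitted mixing models by PSIS-LOO
#'
#' Builds the per-season model-comparison table: LOOic with its standard
#' error, the difference from the best (lowest-LOOic) model with a paired
#' standard error computed from pointwise elpd differences, and Akaike
#' weights. Models with the lowest LOOic and weight > 0.2 are flagged as
#' the selected set. Ties in the minimum are broken by model label
#' (lexicographic).
#'
#' @param fits Named list of [fit_simm()] objects (names are model labels),
#'   or a named list of pointwise log-likelihood matrices, all fitted to
#'   the identical observation set.
#' @param weight_rule Selection threshold on the Akaike weight
#'   (default 0.2).
#' @return Tibble sorted by ascending LOOic with columns `model`, `looic`,
#'   `se_looic`, `delta_looic`, `se_delta`, `weight`, `selected`.
#' @export
compare_models <- function(fits, weight_rule = 0.2) {
  if (length(fits) < 2) {
    abort("Model comparison needs at least 2 models.")
  }
  if (is.null(names(fits)) || any(names(fits) == "")) {
    abort("`fits` must be a fully named list.")
  }
  mats <- purrr::map(fits, function(f) {
    if (inherits(f, "simm_fit")) f$loglik else f
  })
  ns <- vapply(mats, ncol, integer(1))
  if (length(unique(ns)) != 1) {
    abort("All models must be fitted to the identical observation set.")
  }
  loos <- purrr::map(mats, psis_loo)
  looic <- vapply(loos, `[[`, numeric(1), "looic")
  se <- vapply(loos, `[[`, numeric(1), "se")
  # lexicographic tie-break for the reference model
  ord_labels <- names(looic)[order(looic, names(looic))]
  best <- ord_labels[1]
  pw_best <- loos[[best]]$pointwise
  n <- ns[[1]]
  rows <- purrr::map(names(loos), function(lbl) {
    d <- looic[[lbl]] - looic[[best]]
    se_d <- if (lbl == best) {
      0
    } else {
      2 * sqrt(n * var(loos[[lbl]]$pointwise - pw_best))
    }
    tibble::tibble(
      model = lbl, looic = looic[[lbl]], se_looic = se[[lbl]],
      delta_looic = d, se_delta = se_d
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(weight = akaike_weights(.data$looic)) |>
    dplyr::arrange(.data$looic, .data$model) |>
    dplyr::mutate(
      selected = .data$weight > weight_rule
    )
  out
}
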