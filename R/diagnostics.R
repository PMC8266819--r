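#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) \eqn{\hat{R}} for one scalar parameter traced by
#' \eqn{m \ge 2} chains of equal length \eqn{n}:
#' \deqn{\hat{R} = \sqrt{\frac{(n-1)/n \; W + B/n}{W}},}
#' with \eqn{W} the mean within-chain variance and \eqn{B/n} the
#' between-chain variance of chain means. Values near 1 indicate that the
#' chains have mixed.
#'
#' @param chains Numeric matrix (iterations x chains) or list of equal-length
#'   numeric vectors.
#' @return \eqn{\hat{R}} (1 with a warning when all chains are constant).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    lens <- lengths(chains)
    if (length(unique(lens)) != 1) {
      abort("All chains must have equal length.")
    }
    chains <- do.call(cbind, chains)
  }
  if (ncol(chains) < 2) {
    abort("Gelman-Rubin needs at least 2 chains.")
  }
  n <- nrow(chains)
  W <- mean(apply(chains, 2, var))
  B <- n * var(colMeans(chains))
  if (W == 0) {
    warn("Degenerate (constant) chains; R-hat reported as 1.")
    return(1)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `first` fraction of a chain with the mean
#' of the last `last` fraction via a z score whose variance terms are
#' spectral density estimates at frequency zero (so autocorrelation within
#' each window is accounted for). |z| below ~2 is consistent with
#' stationarity.
#'
#' @param chain Numeric vector (length >= 20).
#' @param first,last Window fractions (defaults 0.1 and 0.5).
#' @return The z score (0 with a warning for constant chains).
#' @export
geweke_z <- function(chain, first = 0.1, last = 0.5) {
  n <- length(chain)
  if (n < 20) {
    abort("Geweke diagnostic needs a chain of length >= 20.")
  }
  if (first + last > 1) {
    abort("`first` + `last` must not exceed 1.")
  }
  a <- chain[seq_len(floor(first * n))]
  b <- chain[seq(n - floor(last * n) + 1, n)]
  if (sd(chain) == 0) {
    warn("Degenerate (constant) chain; Geweke z reported as 0.")
    return(0)
  }
  s0 <- function(x) {
    # spectral density at frequency 0 via an AIC-selected AR fit
    if (sd(x) == 0) {
      return(0)
    }
    fit <- tryCatch(
      ar(x, aic = TRUE, order.max = min(20, length(x) - 1)),
      error = function(e) NULL
    )
    if (is.null(fit) || length(fit$ar) == 0) {
      return(var(x))
    }
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  va <- s0(a) / length(a)
  vb <- s0(b) / length(b)
  if (va + vb == 0) {
    return(0)
  }
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Overall convergence verdict for a fitted mixing model
#'
#' A fit is declared converged when every parameter passes the R-hat
#' criterion and fewer than `geweke_frac` of parameters fail the Geweke
#' criterion. The tolerance on Geweke failures reflects its ~5% false-alarm
#' rate at |z| < 2: in models with hundreds of parameters a few flagged
#' parameters are expected for perfectly stationary chains.
#'
#' @param fit A [fit_simm()] object.
#' @param geweke_frac Tolerated fraction of Geweke failures (default 0.1).
#' @return Logical.
#' @export
fit_converged <- function(fit, geweke_frac = 0.1) {
  conv <- fit$convergence
  if (is.null(conv) || nrow(conv) == 0) {
    return(TRUE)
  }
  all(conv$rhat_pass) && mean(!conv$geweke_pass) < geweke_frac
}

#' Convergence report for a fitted mixing model
#'
#' R-hat across chains and per-chain Geweke z for every sampled parameter,
#' with pass flags at the configured thresholds.
#'
#' @param fit A [fit_simm()] object.
#' @param rhat_max R-hat pass threshold (default 1.05).
#' @param geweke_max |z| pass threshold (default 2; applied to the worst
#'   chain).
#' @return Tibble with `parameter`, `rhat`, `geweke_z` (worst across
#'   chains), `rhat_pass`, `geweke_pass`, `pass`.
#' @export
convergence_report <- function(fit, rhat_max = 1.05, geweke_max = 2) {
  pars <- colnames(fit$chains[[1]])
  if (length(pars) == 0) {
    return(tibble::tibble(
      parameter = character(0), rhat = numeric(0), geweke_z = numeric(0),
      rhat_pass = logical(0), geweke_pass = logical(0), pass = logical(0)
    ))
  }
  multi <- length(fit$chains) >= 2
  rows <- purrr::map(pars, function(pn) {
    traces <- lapply(fit$chains, function(m) m[, pn])
    const <- all(vapply(traces, sd, numeric(1)) == 0)
    rhat <- if (const) {
      1
    } else if (multi) {
      gelman_rubin(traces)
    } else {
      NA_real_
    }
    gz <- if (const) {
      0
    } else {
      max(abs(vapply(traces, geweke_z, numeric(1))))
    }
    tibble::tibble(parameter = pn, rhat = rhat, geweke_z = gz)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      rhat_pass = is.na(.data$rhat) | .data$rhat < rhat_max,
      geweke_pass = abs(.data$geweke_z) < geweke_max,
      pass = .data$rhat_pass & .data$geweke_pass
    )
}
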