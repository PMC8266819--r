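#' Log-likelihood of a hair section under the mixing model
#'
#' The observed section value for each isotope is modelled as normal around
#' the concentration-weighted mixture mean, with variance equal to the
#' propagated source + TEF process variance ([mixture_process_var()]) plus a
#' residual variance \eqn{\sigma_{res}^2}. Isotopes are treated as
#' conditionally independent; an `NA` observation for one isotope simply
#' drops that isotope's term, which allows single-tracer models.
#'
#' @param d13C,d15N Observed section values in per mil (either may be `NA`).
#' @param p Diet proportions (length-K vector on the simplex).
#' @param space A [build_mixing_space()] object.
#' @param sigma_res Residual SD per isotope: length-2 numeric
#'   `c(d13C, d15N)` (recycled if length 1), each \eqn{\ge 0}.
#' @return The log-likelihood (a single finite number).
#' @export
simm_loglik <- function(d13C, d15N, p, space, sigma_res = c(0, 0)) {
  if (length(sigma_res) == 1) sigma_res <- rep(sigma_res, 2)
  if (any(sigma_res < 0) || any(!is.finite(sigma_res))) {
    abort("`sigma_res` must be finite and non-negative.")
  }
  obs <- c(d13C = d13C, d15N = d15N)
  if (all(is.na(obs))) {
    abort("At least one isotope observation is required.")
  }
  if (any(!is.finite(obs[!is.na(obs)]))) {
    abort("Isotope observations must be finite or NA.")
  }
  ll <- 0
  for (i in c(1L, 2L)) {
    iso <- c("d13C", "d15N")[i]
    if (is.na(obs[[iso]])) next
    m <- mixture_mean(p, space, iso)
    v <- mixture_process_var(p, space, iso) + sigma_res[i]^2
    if (v <= 0) {
      abort("Total observation variance must be positive.")
    }
    ll <- ll + dnorm(obs[[iso]], mean = m, sd = sqrt(v), log = TRUE)
  }
  ll
}
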