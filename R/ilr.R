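#' Fixed Helmert-type ILR basis
#'
#' Orthonormal basis of the hyperplane orthogonal to the ones vector,
#' built from (sign-flipped) Helmert contrasts so that for K = 2 the single
#' coordinate is \eqn{\ln(p_1/p_2)/\sqrt{2}}. The basis is a deterministic
#' function of K, which makes ILR coordinates comparable across runs.
#'
#' @param K Number of parts (>= 2).
#' @return K x (K-1) matrix with orthonormal columns.
#' @export
ilr_basis <- function(K) {
  if (K < 2) {
    abort("ILR needs at least 2 parts.")
  }
  V <- -stats::contr.helmert(K)
  V <- apply(V, 2, function(col) col / sqrt(sum(col^2)))
  matrix(V, nrow = K)
}

#' Isometric log-ratio transform and its inverse
#'
#' Bijection between the open K-part probability simplex and
#' \eqn{R^{K-1}}, used to place regression structure (covariates, random
#' effects) on diet compositions. `ilr_inverse(ilr_transform(p))` recovers
#' `p` exactly up to floating point.
#'
#' @param p Composition: positive vector of length K summing to 1, or an
#'   n x K matrix of such rows.
#' @param z Real coordinates: vector of length K-1 or an n x (K-1) matrix.
#' @param K Number of parts (inferred from `z` for the inverse).
#' @return `ilr_transform`: vector/matrix of K-1 coordinates;
#'   `ilr_inverse`: composition vector/matrix on the simplex.
#' @examples
#' ilr_transform(c(0.731, 0.269)) # ln(p1/p2)/sqrt(2)
#' @export
ilr_transform <- function(p) {
  vec <- is.null(dim(p))
  if (vec) p <- matrix(p, nrow = 1)
  K <- ncol(p)
  if (any(p <= 0)) {
    abort("ILR requires strictly positive compositions (floor zeros first).")
  }
  if (any(abs(rowSums(p) - 1) > 1e-8)) {
    abort("Compositions must sum to 1.")
  }
  z <- log(p) %*% ilr_basis(K)
  if (vec) as.numeric(z) else z
}

#' @rdname ilr_transform
#' @export
ilr_inverse <- function(z, K = NULL) {
  vec <- is.null(dim(z))
  if (vec) z <- matrix(z, nrow = 1)
  K <- K %||% (ncol(z) + 1L)
  u <- z %*% t(ilr_basis(K))
  u <- u - apply(u, 1, max)
  p <- exp(u)
  p <- p / rowSums(p)
  if (vec) as.numeric(p) else p
}

#' Dirichlet concentration vector from prior diet knowledge
#'
#' Converts prior dietary proportions (for instance estimated digestible
#' energy content, EDEC%, from scat analysis) into an informative Dirichlet
#' prior whose total concentration matches the uninformative
#' \eqn{\alpha = (1, \ldots, 1)} prior:
#' \eqn{\alpha_k = \max(\epsilon,\ \mathrm{edec}_k / \sum \mathrm{edec})
#' \times \mathrm{total}} with `total = K` by default, so the prior carries
#' the same overall information weight but redistributes it across sources.
#'
#' @param edec Non-negative vector of prior proportions (percent or
#'   fractions; only relative magnitude matters). Optionally named by source.
#' @param total Total concentration (default `length(edec)`).
#' @param eps Floor applied after scaling so every \eqn{\alpha_k > 0}
#'   (default 0.01).
#' @return Named numeric vector of Dirichlet concentrations.
#' @export
prior_from_edec <- function(edec, total = length(edec), eps = 0.01) {
  if (any(!is.finite(edec)) || any(edec < 0)) {
    abort("`edec` entries must be finite and non-negative.")
  }
  if (sum(edec) <= 0) {
    abort("`edec` must have at least one positive entry.")
  }
  alpha <- pmax(eps, edec / sum(edec) * total)
  names(alpha) <- names(edec)
  alpha
}

# log Dirichlet density at p (p strictly positive, sums to 1)
ddirichlet_log <- function(p, alpha) {
  sum((alpha - 1) * log(p)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}
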