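#' Covariate structures recognised by the mixing model
#'
#' The seven structures compared per season: the null model, sex and/or
#' management status as fixed effects, and individual bear identity as a
#' random effect.
#'
#' @return Character vector of model labels.
#' @export
model_structures <- function() {
  c("Null", "Sex", "Status", "BearID", "Sex+Status", "Sex+BearID",
    "Status+BearID")
}

parse_model_structure <- function(model) {
  model <- match.arg(model, model_structures())
  terms <- if (model == "Null") character(0) else strsplit(model, "+", fixed = TRUE)[[1]]
  list(
    label = model,
    fixed = intersect(terms, c("Sex", "Status")),
    ranef = "BearID" %in% terms
  )
}

#' Default MCMC settings
#'
#' Three chains of 300,000 iterations each with a burn-in of 200,000 and a
#' thinning rate of 100, i.e. 1,000 kept draws per chain. Smaller runs are
#' appropriate for simulation studies; convergence is always checked.
#'
#' @param chains,iter,burn,thin MCMC run lengths.
#' @param fix_sigma_res Optional length-2 numeric: fix the residual SDs
#'   (per mil, order d13C, d15N) instead of sampling them.
#' @param beta_sd Prior SD of fixed-effect coefficients in ILR space.
#' @param sigma_b_scale Half-normal prior scale of the random-effect SD.
#' @param sigma_res_scale Half-normal prior scale of the residual SDs.
#' @return A list of settings for [fit_simm()].
#' @export
mcmc_settings <- function(chains = 3, iter = 300000, burn = 200000,
                          thin = 100, fix_sigma_res = NULL, beta_sd = 10,
                          sigma_b_scale = 2, sigma_res_scale = 5) {
  if (chains < 1 || iter <= burn || thin < 1) {
    abort("Invalid MCMC settings: need chains >= 1, iter > burn, thin >= 1.")
  }
  list(
    chains = chains, iter = iter, burn = burn, thin = thin,
    fix_sigma_res = fix_sigma_res, beta_sd = beta_sd,
    sigma_b_scale = sigma_b_scale, sigma_res_scale = sigma_res_scale
  )
}

#' Fit the Bayesian mixing model to hair sections
#'
#' Estimates diet proportions from section-level isotope values by an
#' adaptive random-walk Metropolis-within-Gibbs sampler on ILR coordinates.
#' The intercept composition carries the informative Dirichlet prior
#' (`alpha`); sex and management status enter as fixed-effect shifts in ILR
#' space and bear identity as an individual random effect, depending on
#' `model`. Residual SDs per isotope are sampled on the log scale unless
#' fixed. Chains are run sequentially with per-chain seeds derived from
#' `seed`.
#'
#' @param sections Tibble with columns `d13C`, `d15N` (either may be `NA`,
#'   not both), and — as required by `model` — `bear_id`, `sex`
#'   (`"F"`/`"M"`/`"unknown"`), `status`
#'   (`"management"`/`"non-management"`/`"unknown"`).
#' @param space A [build_mixing_space()] object.
#' @param model One of [model_structures()].
#' @param alpha Dirichlet prior concentrations for the baseline composition,
#'   ordered as `rownames(space$mu)`; default uninformative (all 1). See
#'   [prior_from_edec()].
#' @param settings From [mcmc_settings()].
#' @param seed Master integer seed.
#' @return An object of class `simm_fit`.
#' @export
fit_simm <- function(sections, space, model = "Null",
                     alpha = rep(1, nrow(space$mu)),
                     settings = mcmc_settings(), seed = 1) {
  spec <- parse_model_structure(model)
  K <- nrow(space$mu)
  if (nrow(sections) == 0) {
    abort("`sections` is empty.")
  }
  if (!all(c("d13C", "d15N") %in% names(sections))) {
    abort("`sections` needs `d13C` and `d15N` columns.")
  }
  if (any(is.na(sections$d13C) & is.na(sections$d15N))) {
    abort("Every section needs at least one isotope value.")
  }
  if (length(alpha) != K || any(alpha <= 0)) {
    abort(paste0("`alpha` must have ", K, " strictly positive entries."))
  }

  # drop unknown-sex bears from Sex models (unknown is not a sex level)
  if ("Sex" %in% spec$fixed) {
    drop <- sections$sex == "unknown" | is.na(sections$sex)
    if (any(drop)) {
      inform(paste0(
        sum(drop), " section(s) of unknown-sex bears excluded from the Sex model."
      ))
      sections <- sections[!drop, , drop = FALSE]
    }
    if (nrow(sections) == 0) abort("No sections left after sex filtering.")
  }

  dm <- simm_design(sections, spec)

  if (K == 1) {
    return(degenerate_single_source_fit(sections, space, spec, settings, seed))
  }

  y <- cbind(sections$d13C, sections$d15N)
  V <- ilr_basis(K)
  fix <- settings$fix_sigma_res
  fix_sigma <- !is.null(fix)
  sigma_fixed <- if (fix_sigma) rep(fix, length.out = 2) else c(1, 1)

  n_keep <- (settings$iter - settings$burn) %/% settings$thin
  npar <- ncol(dm$X) * (K - 1) +
    (if (dm$n_bears > 0) dm$n_bears * (K - 1) + 1 else 0) + 2
  init <- c(
    as.numeric(matrix(0, ncol(dm$X), K - 1)),
    log(0.5), log(0.5), log(0.5)
  )
  # start the intercept at the prior mean composition
  z0 <- ilr_transform(pmax(alpha / sum(alpha), 1e-6) /
    sum(pmax(alpha / sum(alpha), 1e-6)))
  Z0 <- matrix(0, ncol(dm$X), K - 1)
  Z0[1, ] <- z0
  init[seq_len(ncol(dm$X) * (K - 1))] <- as.numeric(Z0)

  chains <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) {
    chains[[ch]] <- withr::with_seed(seed + ch - 1L, {
      simm_mcmc_cpp(
        y = y, X = dm$X, bear = dm$bear_index, n_bears = dm$n_bears,
        mu = space$mu, vr = space$var, q = space$q, V = V, alpha = alpha,
        beta_sd = settings$beta_sd, sb_scale = settings$sigma_b_scale,
        sres_scale = settings$sigma_res_scale,
        fix_sigma = rep(fix_sigma, 2), sigma_fixed = sigma_fixed,
        n_iter = settings$iter, n_burn = settings$burn,
        thin = settings$thin, init = init, init_scale = 0.2
      )
    })
  }

  par_names <- simm_par_names(dm, K)
  for (ch in seq_along(chains)) {
    colnames(chains[[ch]]$draws) <- par_names
  }

  fit <- structure(
    list(
      model = spec$label,
      sections = sections,
      space = space,
      alpha = alpha,
      design = dm,
      chains = lapply(chains, `[[`, "draws"),
      loglik = do.call(rbind, lapply(chains, `[[`, "loglik")),
      accept = lapply(chains, `[[`, "accept_rate"),
      settings = settings,
      seed = seed,
      n_keep = n_keep
    ),
    class = "simm_fit"
  )
  fit$convergence <- convergence_report(fit)
  fit
}

# design matrix + bear indexing for a covariate structure
simm_design <- function(sections, spec) {
  X <- matrix(1, nrow(sections), 1)
  colnames(X) <- "(Intercept)"
  for (term in spec$fixed) {
    col <- if (term == "Sex") "sex" else "status"
    if (!col %in% names(sections)) {
      abort(paste0("Model ", spec$label, " needs a `", col, "` column."))
    }
    levs <- if (term == "Sex") {
      c("F", "M")
    } else {
      c("non-management", "management", "unknown")
    }
    vals <- factor(sections[[col]], levels = levs)
    if (any(is.na(vals))) {
      abort(paste0("Invalid ", col, " level in `sections`."))
    }
    mm <- stats::model.matrix(~vals)[, -1, drop = FALSE]
    present <- levs[-1][levs[-1] %in% unique(as.character(vals))]
    keep <- paste0("vals", present)
    mm <- mm[, colnames(mm) %in% keep, drop = FALSE]
    if (ncol(mm) > 0) {
      colnames(mm) <- paste0(term, sub("^vals", ":", colnames(mm)))
      X <- cbind(X, mm)
    }
  }
  if (spec$ranef) {
    if (!"bear_id" %in% names(sections)) {
      abort(paste0("Model ", spec$label, " needs a `bear_id` column."))
    }
    bears <- sort(unique(sections$bear_id))
    bear_index <- match(sections$bear_id, bears) - 1L
    list(X = X, bear_index = bear_index, bears = bears,
         n_bears = length(bears))
  } else {
    list(X = X, bear_index = rep(-1L, nrow(sections)),
         bears = character(0), n_bears = 0L)
  }
}

simm_par_names <- function(dm, K) {
  coord <- seq_len(K - 1)
  nm <- c()
  for (c in coord) {
    nm <- c(nm, paste0("z[", colnames(dm$X), ",", c, "]"))
  }
  if (dm$n_bears > 0) {
    for (c in coord) {
      nm <- c(nm, paste0("b[", dm$bears, ",", c, "]"))
    }
    nm <- c(nm, "log_sigma_bear")
  }
  c(nm, "log_sigma_d13C", "log_sigma_d15N")
}

degenerate_single_source_fit <- function(sections, space, spec, settings,
                                         seed) {
  # one source: the simplex collapses to p = 1 with zero variance
  n_keep <- max(1L, (settings$iter - settings$burn) %/% settings$thin)
  sig <- settings$fix_sigma_res %||% 0
  ll <- vapply(seq_len(nrow(sections)), function(i) {
    simm_loglik(
      sections$d13C[i], sections$d15N[i], 1, space,
      sigma_res = rep(sig, length.out = 2)
    )
  }, numeric(1))
  structure(
    list(
      model = spec$label, sections = sections, space = space,
      alpha = 1, design = NULL,
      chains = replicate(
        settings$chains,
        matrix(numeric(0), nrow = n_keep, ncol = 0),
        simplify = FALSE
      ),
      loglik = matrix(rep(ll, each = n_keep * settings$chains),
        nrow = n_keep * settings$chains
      ),
      accept = NULL, settings = settings, seed = seed, n_keep = n_keep,
      convergence = tibble::tibble(
        parameter = character(0), rhat = numeric(0), geweke_z = numeric(0),
        pass = logical(0)
      ),
      degenerate = TRUE
    ),
    class = "simm_fit"
  )
}

#' @export
print.simm_fit <- function(x, ...) {
  cat(
    "<simm_fit> model ", x$model, ": ", nrow(x$sections), " sections, ",
    nrow(x$space$mu), " sources, ", length(x$chains), " chain(s) x ",
    x$n_keep, " kept draws\n",
    sep = ""
  )
  if (!is.null(x$convergence) && nrow(x$convergence) > 0) {
    ok <- fit_converged(x)
    cat("convergence: ", if (ok) "passed" else "CHECK FAILED",
      "\n",
      sep = ""
    )
  }
  invisible(x)
}
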