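# Heteroscedastic Gaussian mixture EM for per-k-mer emission training.
#
# Events are shift/scale-transformed per read (e' = (e - a)/b) before
# pooling, so a single mixture is fit per k-mer (or k-bar class) with a
# per-event variance factor v_i = d_i / b_i carried from each event's
# read: component j contributes omega_j * Normal(mu_j, (v_i * sigma_j)^2)
# to event i, and the sigma update standardises residuals by 1 / v_i.

#' Training configuration
#'
#' Houses the EM initialisation grid and iteration controls used for
#' emission training: candidate component means at the reference mean and
#' +-5 / +-10 pA offsets, candidate standard deviations at the reference
#' value and +1 pA, component weights by count (0.95/0.05 for two
#' components, 0.5/0.3/0.2 for three, 0.25 x 4 for four), an EM cap of
#' 1000 iterations, and 5 outer alignment/training rounds.
#'
#' @param mean_offsets Candidate offsets (pA) for non-reference component
#'   means.
#' @param sd_offsets Candidate additive offsets (pA) for initial sds.
#' @param max_em_iterations EM iteration cap per initialisation.
#' @param outer_rounds Outer Viterbi-realignment rounds.
#' @param convergence_tol Convergence tolerance on max |delta mu| (pA).
#' @param consistency_tol Agreement tolerance (pA) between grid
#'   initialisations and for matching a component to the reference mean.
#' @param collapse_sd,collapse_weight A component with fitted sd below
#'   `collapse_sd` (pA) or weight below `collapse_weight` is dropped and
#'   the remaining weights renormalised.
#' @param min_events_per_component Minimum pooled events required per
#'   mixture component before a fit is attempted.
#' @param max_components Cap on the component count for k-bar classes.
#' @return A list of class `nj_training_config`.
#' @export
training_config <- function(mean_offsets = c(-10, -5, 5, 10),
                            sd_offsets = c(0, 1),
                            max_em_iterations = 1000L,
                            outer_rounds = 5L,
                            convergence_tol = 1e-3,
                            consistency_tol = 1.0,
                            collapse_sd = 0.05,
                            collapse_weight = 0.01,
                            min_events_per_component = 10L,
                            max_components = 4L) {
  stopifnot(max_em_iterations >= 1, outer_rounds >= 1, convergence_tol > 0,
            consistency_tol > 0, max_components >= 2)
  structure(list(mean_offsets = mean_offsets, sd_offsets = sd_offsets,
                 max_em_iterations = as.integer(max_em_iterations),
                 outer_rounds = as.integer(outer_rounds),
                 convergence_tol = convergence_tol,
                 consistency_tol = consistency_tol,
                 collapse_sd = collapse_sd,
                 collapse_weight = collapse_weight,
                 min_events_per_component = as.integer(min_events_per_component),
                 max_components = as.integer(max_components)),
            class = "nj_training_config")
}

component_weight_init <- function(n) {
  switch(as.character(n),
         "1" = 1,
         "2" = c(0.95, 0.05),
         "3" = c(0.5, 0.3, 0.2),
         "4" = rep(0.25, 4),
         stop("unsupported component count: ", n, call. = FALSE))
}

#' Fit a Gaussian mixture to transformed events by EM
#'
#' Expectation-maximisation with per-event variance factors: the E step
#' computes responsibilities from weighted Gaussian densities with sd
#' `v * sigma_j`; the M step updates weights as mean responsibility,
#' means as responsibility-weighted averages of the transformed events,
#' and variances as responsibility-weighted averages of squared residuals
#' rescaled by `1 / v`. Iterates until the largest mean change falls
#' below `tol` or `max_iter` is reached. Components that collapse (sd or
#' weight below the configured floors) are dropped and the weights
#' renormalised.
#'
#' @param x Numeric vector of transformed event levels (pA).
#' @param v Per-event variance factors d_i / b_i (recycled; default 1).
#' @param mu,sigma,omega Initial component means, sds and weights (equal
#'   lengths; `omega` defaults to the count-specific grid value).
#' @param max_iter Iteration cap (default 1000).
#' @param tol Convergence tolerance on max |delta mu| (default 1e-3 pA).
#' @param collapse_sd,collapse_weight Component collapse floors.
#' @return An object of class `nj_gmm`: list with `components` (tibble of
#'   `weight`, `mean`, `sd`), `responsibilities`, `loglik` (trace, one
#'   entry per iteration), `converged`, `n_iter`, `n`.
#' @export
fit_gmm <- function(x, v = 1, mu, sigma,
                    omega = component_weight_init(length(mu)),
                    max_iter = 1000L, tol = 1e-3,
                    collapse_sd = 0.05, collapse_weight = 0.01) {
  stopifnot(length(mu) == length(sigma), length(mu) == length(omega),
            all(sigma > 0), all(omega > 0))
  J <- length(mu)
  n <- length(x)
  if (n < 10L * J) stop("insufficient events for a ", J, "-component fit (",
                        n, " < ", 10L * J, ")", call. = FALSE)
  v <- rep_len(v, n)
  omega <- omega / sum(omega)

  loglik <- numeric(max_iter)
  n_ll <- 0L
  converged <- FALSE
  gamma <- NULL
  inv_v2 <- 1 / v^2
  log_const <- -0.5 * log(2 * pi) - log(v)
  for (it in seq_len(max_iter)) {
    dens <- matrix(0, n, J)
    for (j in seq_len(J)) {
      dens[, j] <- omega[j] / sigma[j] *
        exp(log_const - 0.5 * inv_v2 * ((x - mu[j]) / sigma[j])^2)
    }
    tot <- .rowSums(dens, n, J)
    tot[tot == 0] <- .Machine$double.xmin
    n_ll <- n_ll + 1L
    loglik[n_ll] <- sum(log(tot))
    gamma <- dens / tot

    nk <- .colSums(gamma, n, J)
    nk[nk == 0] <- .Machine$double.xmin
    mu_new <- .colSums(gamma * x, n, J) / nk
    res2 <- (x - rep(mu_new, each = n))^2 * inv_v2
    sigma_new <- sqrt(.colSums(gamma * res2, n, J) / nk)
    omega <- nk / n

    delta <- max(abs(mu_new - mu))
    mu <- mu_new
    sigma <- pmax(sigma_new, 1e-12)

    keep <- sigma >= collapse_sd & omega >= collapse_weight
    if (!all(keep)) {
      if (!any(keep)) keep[which.max(omega)] <- TRUE
      mu <- mu[keep]; sigma <- sigma[keep]; omega <- omega[keep]
      omega <- omega / sum(omega)
      J <- length(mu)
      next
    }
    if (delta < tol) { converged <- TRUE; break }
    # a flat observed-data log-likelihood means the fit has effectively
    # converged even if the means still drift along a ridge
    if (n_ll >= 2L && loglik[n_ll] - loglik[n_ll - 1L] < 1e-6) {
      converged <- TRUE
      break
    }
  }
  loglik <- loglik[seq_len(n_ll)]

  structure(list(
    components = tibble::tibble(weight = omega, mean = mu, sd = sigma),
    responsibilities = gamma,
    loglik = loglik,
    converged = converged,
    n_iter = length(loglik),
    n = n
  ), class = "nj_gmm")
}

# closed-form single-Gaussian weighted fit (the J = 1 EM fixed point)
fit_single_gaussian <- function(x, v = 1) {
  v <- rep_len(v, length(x))
  mu <- mean(x)
  sigma <- sqrt(mean(((x - mu) / v)^2))
  tibble::tibble(weight = 1, mean = mu, sd = max(sigma, 1e-12))
}

# Initialisation grid for a methylated k-mer / k-bar class: one component
# anchored at the reference mean, the remaining component means drawn from
# the +-5 / +-10 pA offsets (all subsets of the required size), both sd
# choices applied to every component.
init_grid <- function(ref_mean, ref_sd, n_components, cfg) {
  offs <- cfg$mean_offsets
  extra <- n_components - 1L
  if (extra < 1L || extra > length(offs)) {
    stop("component count out of range for the initialisation grid",
         call. = FALSE)
  }
  combos <- utils::combn(offs, extra, simplify = FALSE)
  grid <- list()
  for (cmb in combos) {
    for (soff in cfg$sd_offsets) {
      grid[[length(grid) + 1L]] <- list(
        mu = c(ref_mean, ref_mean + cmb),
        sigma = rep(ref_sd + soff, n_components),
        omega = component_weight_init(n_components)
      )
    }
  }
  grid
}

#' Fit a mixture over the full initialisation grid
#'
#' Runs [fit_gmm()] from every grid initialisation for the requested
#' component count and returns the list of fits (used by
#' [assign_parameters()]).
#'
#' @param x,v Transformed events and variance factors, as in [fit_gmm()].
#' @param ref_mean,ref_sd Reference (unmodified) model mean and sd.
#' @param n_components Number of mixture components.
#' @param cfg A [training_config()].
#' @return List of `nj_gmm` fits.
#' @export
fit_gmm_grid <- function(x, v, ref_mean, ref_sd, n_components,
                         cfg = training_config()) {
  grid <- init_grid(ref_mean, ref_sd, n_components, cfg)
  lapply(grid, function(g)
    fit_gmm(x, v, mu = g$mu, sigma = g$sigma, omega = g$omega,
            max_iter = cfg$max_em_iterations, tol = cfg$convergence_tol,
            collapse_sd = cfg$collapse_sd,
            collapse_weight = cfg$collapse_weight))
}

#' Assign trained parameters from grid fits to a methylated entry
#'
#' Consistency-based selection across grid initialisations: fits whose
#' sorted component means agree elementwise within `consistency_tol` form
#' a consensus group; if the largest group covers at least half of the
#' initialisations, its highest-likelihood member is the representative.
#' For a two-component (single-modification) entry the component whose
#' mean differs most from the reference mean is assigned with weight 1
#' (if only one component survived collapse, it is assigned). For a
#' multi-component (k-bar or doubly modified) entry, components matching
#' the reference mean within tolerance are dropped and the remainder
#' assigned with renormalised weights. Without a consensus (or when every
#' component matches the reference), the entry is flagged untrained and
#' keeps its initialisation values.
#'
#' @param fits List of `nj_gmm` fits from [fit_gmm_grid()].
#' @param ref_mean,ref_sd Reference model mean and sd.
#' @param kind `"two_component"` or `"multi_component"`.
#' @param consistency_tol Agreement tolerance in pA (default 1).
#' @param min_weight Components below this mixture weight are ignored
#'   during assignment (default 0.1): a training condition deposits its
#'   modification on most molecules, so a trace-weight component is an
#'   alignment artifact, not the methylated population.
#' @return List with `components` (tibble or `NULL`) and `trained`
#'   (logical).
#' @export
assign_parameters <- function(fits, ref_mean, ref_sd,
                              kind = c("two_component", "multi_component"),
                              consistency_tol = 1.0, min_weight = 0.1) {
  kind <- match.arg(kind)
  stopifnot(length(fits) >= 1L)

  sigs <- lapply(fits, function(f) sort(f$components$mean))
  lls <- vapply(fits, function(f) f$loglik[length(f$loglik)], numeric(1))

  agree <- function(a, b) {
    length(a) == length(b) && all(abs(a - b) <= consistency_tol)
  }
  n_agree <- vapply(seq_along(fits), function(i)
    sum(vapply(sigs, agree, logical(1), b = sigs[[i]])), integer(1))
  lead <- which.max(n_agree)
  if (n_agree[lead] < length(fits) / 2) {
    return(list(components = NULL, trained = FALSE))
  }
  group <- which(vapply(sigs, agree, logical(1), b = sigs[[lead]]))
  rep_fit <- fits[[group[which.max(lls[group])]]]
  comp <- rep_fit$components
  comp <- comp[order(comp$mean), ]
  if (any(comp$weight >= min_weight)) {
    comp <- comp[comp$weight >= min_weight, ]
  }

  if (kind == "two_component") {
    pick <- which.max(abs(comp$mean - ref_mean))
    out <- tibble::tibble(weight = 1, mean = comp$mean[pick],
                          sd = comp$sd[pick])
    return(list(components = out, trained = TRUE))
  }

  keep <- abs(comp$mean - ref_mean) > consistency_tol
  if (!any(keep)) return(list(components = NULL, trained = FALSE))
  out <- comp[keep, ]
  out$weight <- out$weight / sum(out$weight)
  list(components = out[, c("weight", "mean", "sd")], trained = TRUE)
}

#' @export
print.nj_gmm <- function(x, ...) {
  cat("Gaussian mixture fit (", nrow(x$components), " components, n = ",
      x$n, ", ", if (x$converged) "converged" else "not converged",
      " in ", x$n_iter, " iterations)\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Tidy a Gaussian mixture fit
#'
#' @param x An `nj_gmm` object.
#' @param ... Unused.
#' @return A tibble with one row per component: `component`, `weight`,
#'   `mean`, `sd`.
#' @export
tidy.nj_gmm <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(),
                .before = 1L)
}

#' Glance at a Gaussian mixture fit
#'
#' @param x An `nj_gmm` object.
#' @param ... Unused.
#' @return A one-row tibble with `n`, `n_components`, `logLik`, `n_iter`,
#'   `converged`.
#' @export
glance.nj_gmm <- function(x, ...) {
  tibble::tibble(n = x$n, n_components = nrow(x$components),
                 logLik = x$loglik[length(x$loglik)],
                 n_iter = x$n_iter, converged = x$converged)
}
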