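#' Group-level prior hyperparameters
#'
#' Diagonal Gaussian prior over the unconstrained parameters of a model
#' variant, shared by all subject-session units in the hierarchical
#' (empirical-Bayes) fit.
#'
#' @param mean Numeric vector of prior means (unconstrained scale).
#' @param var Numeric vector of prior variances (> 0); ignored when `cov`
#'   is supplied.
#' @param cov Optional full covariance matrix; `NULL` means diagonal.
#' @return Object of class `prior_hyper` with elements `mean`, `var`
#'   (diagonal) and `cov` (full matrix or `NULL`).
#' @export
prior_hyper <- function(mean, var, cov = NULL) {
    if (!is.null(cov)) {
        cov <- as.matrix(cov)
        if (!all(dim(cov) == length(mean))) stopf("cov dimension mismatch")
        var <- diag(cov)
    }
    if (length(mean) != length(var)) stopf("mean and var must match in length")
    if (any(var <= 0)) stopf("prior variances must be positive")
    structure(list(mean = as.numeric(mean), var = as.numeric(var), cov = cov),
              class = "prior_hyper")
}

# Cholesky-based draws from the (possibly full-covariance) prior
draw_prior <- function(n, prior) {
    d <- length(prior$mean)
    z <- matrix(rnorm(n * d), n, d)
    if (is.null(prior$cov)) {
        sweep(z, 2, sqrt(prior$var), `*`) +
            matrix(prior$mean, n, d, byrow = TRUE)
    } else {
        z %*% chol(prior$cov) + matrix(prior$mean, n, d, byrow = TRUE)
    }
}

default_prior <- function(variant) {
    variant <- model_variant(variant)
    # weakly informative on the unconstrained scale: covers rates in roughly
    # (0.01, 0.99) and weights over ~2 orders of magnitude
    prior_hyper(rep(0, variant$n_params), rep(6.25, variant$n_params))
}

#' Reference synthetic group prior
#'
#' The package's reference population for synthetic cohorts, on the
#' unconstrained scale of the full two-beta variant. The means correspond to
#' natural-scale values of roughly `bMB = bMF = 2`, `beta2 = 3`,
#' `alpha1 = 0.55`, `alpha2 = 0.45`, `lambda = 0.6` and `p = 0.1`, in the
#' range reported by published hierarchical fits of this task, with moderate
#' between-subject spread.
#'
#' @return A [prior_hyper()] for the 7-parameter two-beta variant.
#' @export
reference_prior <- function() {
    prior_hyper(c(log(2), log(2), log(3), qlogis(0.55), qlogis(0.45),
                  qlogis(0.6), 0.1),
                c(0.4, 0.4, 0.3, 0.4, 0.4, 0.4, 0.1))
}

neg_log_posterior_fn <- function(loglik_fn, prior) {
    pm <- prior$mean
    if (is.null(prior$cov)) {
        pv <- prior$var
        const <- 0.5 * sum(log(2 * pi * pv))
        function(u) -loglik_fn(u) + 0.5 * sum((u - pm)^2 / pv) + const
    } else {
        ch <- chol(prior$cov)
        sinv <- chol2inv(ch)
        const <- 0.5 * (length(pm) * log(2 * pi)) + sum(log(diag(ch)))
        function(u) {
            dlt <- u - pm
            -loglik_fn(u) + 0.5 * drop(dlt %*% sinv %*% dlt) + const
        }
    }
}

#' Maximum a posteriori fit of one unit
#'
#' Maximizes the session log-likelihood plus the log Gaussian prior over the
#' unconstrained parameters by multi-start quasi-Newton (BFGS) optimization,
#' and returns the best optimum together with the numerical Hessian of the
#' negative log posterior there.
#'
#' @param trials Trial table of one subject-session unit.
#' @param variant [model_variant()] or name.
#' @param prior [prior_hyper()].
#' @param n_restarts Number of additional starts drawn from the prior
#'   (default 4).
#' @param seed Optional seed governing the restart draws.
#' @param p_common Common-transition probability of the task.
#' @param start Optional extra starting point (e.g. a previous MAP).
#' @return List with `map` (unconstrained MAP vector), `hessian`, `logpost`
#'   (log posterior at the MAP, up to the prior normalizing constant),
#'   `loglik` and `converged`.
#' @export
map_fit_unit <- function(trials, variant = "ll2bmfbmb2alr",
                         prior = default_prior(variant), n_restarts = 4,
                         seed = NULL, p_common = 0.7, start = NULL) {
    variant <- model_variant(variant)
    set_seed_if(seed)
    d <- variant$n_params
    starts <- list(prior$mean)
    if (!is.null(start)) starts <- c(starts, list(start))
    if (n_restarts > 0) {
        for (k in seq_len(n_restarts))
            starts <- c(starts, list(rnorm(d, prior$mean, sqrt(prior$var) / 2)))
    }
    loglik_fn <- make_unit_loglik(trials, variant, p_common)
    obj <- neg_log_posterior_fn(loglik_fn, prior)
    best <- NULL
    any_conv <- FALSE
    for (s in starts) {
        fit <- tryCatch(
            optim(s, obj, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-10)),
            error = function(e) NULL)
        if (is.null(fit)) next
        any_conv <- any_conv || fit$convergence == 0
        if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best))
        stopf("map_fit_unit: all %d starts failed for variant '%s'",
              length(starts), variant$name)
    H <- tryCatch(optimHess(best$par, obj), error = function(e) NULL)
    if (is.null(H)) H <- diag(1 / prior$var, d)
    list(map = best$par, hessian = H, logpost = -best$value,
         loglik = loglik_fn(best$par), converged = any_conv)
}

# Posterior covariance from the Laplace approximation (inverse Hessian of
# the negative log posterior), with eigenvalues clipped into a sane range so
# flat or slightly indefinite directions cannot derail the M step.
laplace_covariance <- function(H, prior) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V)) V <- diag(1 / pmax(diag(H), 1 / (4 * prior$var)))
    V <- (V + t(V)) / 2
    e <- eigen(V, symmetric = TRUE)
    e$values <- pmin(pmax(e$values, 1e-8), 4 * max(prior$var))
    e$vectors %*% (e$values * t(e$vectors))
}

#' Hierarchical empirical-Bayes (EM) fit
#'
#' Alternates per-unit MAP estimation under the current group prior (E step,
#' with Laplace-approximated posterior moments) and moment updates of the
#' prior (M step: mean of posterior means; mean of posterior covariances
#' plus outer products of the deviations) until the hyperparameters
#' stabilize. All units are treated as draws from one Gaussian prior on the
#' unconstrained scale.
#'
#' @param trials Cohort trial table (multiple subject-session units).
#' @param variant [model_variant()] or name.
#' @param max_iter Maximum EM iterations (default 30).
#' @param tol Convergence tolerance on the maximal absolute hyperparameter
#'   change (default 1e-3).
#' @param seed Integer seed for the optimizer restart schedule.
#' @param n_restarts Optimizer restarts per unit in the first EM iteration;
#'   later iterations warm-start from the previous MAP.
#' @param prior0 Optional starting [prior_hyper()].
#' @param covariance `"full"` (default) estimates the complete group-level
#'   covariance of the unconstrained parameters, which respects the
#'   correlated trade-offs between them (e.g. stage-1 weight versus learning
#'   rate); `"diagonal"` restricts the prior to independent parameters.
#' @param p_common Common-transition probability.
#' @param verbose Print per-iteration progress.
#' @return Object of class `group_fit`: `prior`, `unit_map` (matrix, units x
#'   parameters, unconstrained), `unit_natural`, `unit_hessians`,
#'   `unit_loglik`, `unit_ids`, `ibic` (`NA` until [compute_ibic()] is
#'   called), `unit_bic`, `n_em_iterations`, `converged`, `trace`.
#' @export
em_fit <- function(trials, variant = "ll2bmfbmb2alr", max_iter = 30,
                   tol = 1e-3, seed = 1L, n_restarts = 4, prior0 = NULL,
                   covariance = c("full", "diagonal"), p_common = 0.7,
                   verbose = FALSE) {
    variant <- model_variant(variant)
    covariance <- match.arg(covariance)
    units <- split_units(trials)
    if (length(units) < 2) stopf("em_fit needs at least 2 units")
    d <- variant$n_params
    prior <- if (is.null(prior0)) default_prior(variant) else prior0
    maps <- matrix(0, length(units), d)
    hess <- vector("list", length(units))
    logliks <- numeric(length(units))
    trace <- data.frame()
    converged <- FALSE
    warm <- NULL
    for (it in seq_len(max_iter)) {
        covs <- vector("list", length(units))
        lap_ml <- 0
        for (i in seq_along(units)) {
            f <- map_fit_unit(units[[i]], variant, prior,
                              n_restarts = if (it == 1) n_restarts else 1,
                              seed = unit_seed(seed + it, names(units)[i], 0),
                              p_common = p_common,
                              start = if (is.null(warm)) NULL else warm[i, ])
            maps[i, ] <- f$map
            hess[[i]] <- f$hessian
            logliks[i] <- f$loglik
            covs[[i]] <- laplace_covariance(f$hessian, prior)
            ldet <- determinant(f$hessian, logarithm = TRUE)
            ld <- if (ldet$sign > 0) as.numeric(ldet$modulus) else sum(log(diag(f$hessian)))
            lap_ml <- lap_ml + f$logpost + d / 2 * log(2 * pi) - ld / 2
        }
        warm <- maps
        new_mean <- colMeans(maps)
        S <- Reduce(`+`, lapply(seq_along(units), function(i)
            covs[[i]] + tcrossprod(maps[i, ] - new_mean))) / length(units)
        S <- S + diag(1e-4, d)
        delta <- max(abs(new_mean - prior$mean), abs(diag(S) - prior$var))
        trace <- rbind(trace, data.frame(iter = it, laplace_ml = lap_ml,
                                         delta = delta))
        if (verbose)
            message(sprintf("EM iter %d: Laplace ML %.2f, delta %.4g",
                            it, lap_ml, delta))
        prior <- if (covariance == "full") prior_hyper(new_mean, cov = S)
                 else prior_hyper(new_mean, pmax(diag(S), 1e-4))
        if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged)
        warnf("em_fit did not converge within %d iterations (last delta %.3g)",
              max_iter, trace$delta[nrow(trace)])
    nat <- t(apply(maps, 1, function(u) {
        transform_params(u, variant)$natural
    }))
    colnames(nat) <- variant$par_names
    colnames(maps) <- variant$par_names
    ub <- vapply(seq_along(units), function(i) {
        unit_bic(maps[i, ], units[[i]], variant, p_common)
    }, numeric(1))
    structure(list(prior = prior, unit_map = maps, unit_natural = nat,
                   unit_hessians = hess, unit_loglik = logliks,
                   unit_ids = names(units), variant = variant,
                   p_common = p_common, ibic = NA_real_, unit_bic = ub,
                   n_em_iterations = nrow(trace), converged = converged,
                   trace = trace),
              class = "group_fit")
}

#' @export
print.group_fit <- function(x, ...) {
    cat(sprintf("Hierarchical fit of variant '%s': %d units, %d EM iterations%s\n",
                x$variant$name, nrow(x$unit_map), x$n_em_iterations,
                if (x$converged) "" else " (NOT converged)"))
    tab <- rbind(`prior mean` = x$prior$mean, `prior var` = x$prior$var)
    colnames(tab) <- x$variant$par_names
    print(round(tab, 3))
    if (is.finite(x$ibic)) cat(sprintf("iBIC: %.1f\n", x$ibic))
    invisible(x)
}

#' Integrated BIC of a hierarchical fit
#'
#' Approximates, for every unit, the marginal likelihood of its choices
#' integrated over the fitted group prior by Monte-Carlo sampling
#' (log-sum-exp accumulation), and penalizes with `h * log(N)` where `h` is
#' the number of prior hyperparameters (two per free parameter) and `N` the
#' total number of choices (two per valid trial). Lower is better.
#'
#' @param fit A [em_fit()] result.
#' @param trials The cohort trial table the fit was computed on.
#' @param n_samples Prior samples per unit (default 2000).
#' @param seed Seed for the sampled parameters.
#' @return The iBIC value; also stored in the returned copy of `fit` by
#'   [model_comparison()].
#' @export
compute_ibic <- function(fit, trials, n_samples = 2000, seed = 1L) {
    stopifnot(inherits(fit, "group_fit"))
    if (n_samples < 100) warnf("n_samples < 100 gives a noisy iBIC estimate")
    units <- split_units(trials)
    if (!identical(names(units), fit$unit_ids))
        stopf("trial table does not match the fitted units")
    set_seed_if(seed)
    d <- fit$variant$n_params
    total_choices <- 0
    sum_log_m <- 0
    for (i in seq_along(units)) {
        theta <- draw_prior(n_samples, fit$prior)
        llf <- make_unit_loglik(units[[i]], fit$variant, fit$p_common)
        lls <- vapply(seq_len(n_samples), function(k) llf(theta[k, ]),
                      numeric(1))
        sum_log_m <- sum_log_m + (log_sum_exp(lls) - log(n_samples))
        total_choices <- total_choices + 2 * sum(!units[[i]]$missed)
    }
    h <- 2 * d
    -2 * sum_log_m + h * log(total_choices)
}

#' Subject-specific BIC at the MAP estimate
#'
#' `BIC = -2 * loglik(MAP) + d * log(n_choices)` with `d` the number of free
#' parameters of the variant and `n_choices` counting both stage decisions of
#' every valid trial.
#'
#' @param map_vector Unconstrained MAP parameter vector.
#' @param trials Trial table of the unit.
#' @param variant [model_variant()] or name.
#' @param p_common Common-transition probability.
#' @return Scalar BIC.
#' @export
unit_bic <- function(map_vector, trials, variant = "ll2bmfbmb2alr",
                     p_common = 0.7) {
    variant <- model_variant(variant)
    n_choices <- 2 * sum(!trials$missed)
    -2 * session_loglik(map_vector, trials, variant, p_common) +
        variant$n_params * log(n_choices)
}

#' Compare model variants by iBIC
#'
#' Fits each requested variant hierarchically with a shared seed schedule,
#' computes its iBIC and ranks the variants (lower iBIC wins; ties broken
#' toward fewer parameters). Variants that fail to fit are excluded from the
#' ranking and flagged.
#'
#' @param trials Cohort trial table.
#' @param variants Character vector of variant names (default: both anchor
#'   variants).
#' @param seed Shared seed.
#' @param n_samples iBIC Monte-Carlo samples per unit.
#' @param ... Passed to [em_fit()].
#' @return List with `table` (data.frame: variant, n_params, ibic, rank,
#'   failed), `winner` (variant name) and `fits` (named list of `group_fit`).
#' @export
model_comparison <- function(trials,
                             variants = c("ll2bmfbmb2alr", "llm2b2alr"),
                             seed = 1L, n_samples = 2000, ...) {
    if (length(variants) < 1) stopf("no variants supplied")
    fits <- list()
    rows <- list()
    for (v in variants) {
        fit <- tryCatch(em_fit(trials, v, seed = seed, ...),
                        error = function(e) e)
        if (inherits(fit, "error")) {
            warnf("variant '%s' failed to fit: %s", v, conditionMessage(fit))
            rows[[v]] <- data.frame(variant = v,
                                    n_params = model_variant(v)$n_params,
                                    ibic = NA_real_, failed = TRUE)
            next
        }
        fit$ibic <- compute_ibic(fit, trials, n_samples = n_samples,
                                 seed = seed)
        fits[[v]] <- fit
        rows[[v]] <- data.frame(variant = v, n_params = fit$variant$n_params,
                                ibic = fit$ibic, failed = FALSE)
    }
    tab <- do.call(rbind, rows)
    ok <- !tab$failed
    ord <- order(tab$ibic, tab$n_params)
    tab <- tab[ord, ]
    tab$rank <- NA_integer_
    tab$rank[!tab$failed] <- seq_len(sum(!tab$failed))
    rownames(tab) <- NULL
    winner <- tab$variant[which(tab$rank == 1)]
    list(table = tab, winner = winner, fits = fits)
}

#' Parameter-recovery study
#'
#' Simulates a cohort of units from a known group prior, refits it with
#' [em_fit()], and reports per-parameter recovery: bias and RMSE of the
#' group prior mean, and the Spearman correlation between true and MAP
#' estimates across units (on the unconstrained scale).
#'
#' @param true_prior [prior_hyper()] on the unconstrained scale of
#'   `variant`.
#' @param n_units Number of subject-session units (default 100).
#' @param n_trials Trials per unit (default 201).
#' @param variant [model_variant()] or name.
#' @param seed Integer seed.
#' @param config Optional [task_config()] override (its `n_trials` is
#'   replaced).
#' @param ... Passed to [em_fit()].
#' @return List with `report` (data.frame per parameter: true_mean,
#'   recovered_mean, se, bias, rmse, spearman), `fit`, `true_unconstrained`
#'   (matrix) and `cohort`.
#' @export
recovery_study <- function(true_prior, n_units = 100, n_trials = 201,
                           variant = "ll2bmfbmb2alr", seed = 1L,
                           config = task_config(), ...) {
    variant <- model_variant(variant)
    d <- variant$n_params
    stopifnot(length(true_prior$mean) == d)
    set_seed_if(seed)
    true_u <- sapply(seq_len(d), function(j)
        rnorm(n_units, true_prior$mean[j], sqrt(true_prior$var[j])))
    colnames(true_u) <- variant$par_names
    nat <- t(apply(true_u, 1, function(u) transform_params(u, variant)$canonical))
    pt <- data.frame(subject = seq_len(n_units), session = 1L,
                     bMB = nat[, 1], bMF = nat[, 2], beta2 = nat[, 3],
                     alpha1 = nat[, 4], alpha2 = nat[, 5], lambda = nat[, 6],
                     p = nat[, 7])
    cfg <- config
    cfg$n_trials <- as.integer(n_trials)
    cohort <- simulate_cohort(pt, cfg, seed = seed)
    fit <- em_fit(cohort$trials, variant, seed = seed, ...)
    # units come back ordered by the subject:session key; align truth to it
    key <- paste0(pt$subject, ":", pt$session)
    idx <- match(fit$unit_ids, key)
    true_aligned <- true_u[idx, , drop = FALSE]
    report <- data.frame(
        parameter = variant$par_names,
        true_mean = true_prior$mean,
        recovered_mean = fit$prior$mean,
        se = sqrt(true_prior$var / n_units),
        bias = fit$prior$mean - true_prior$mean,
        rmse = sqrt(colMeans((fit$unit_map - true_aligned)^2)),
        spearman = vapply(seq_len(d), function(j)
            cor(true_aligned[, j], fit$unit_map[, j], method = "spearman"),
            numeric(1)))
    list(report = report, fit = fit, true_unconstrained = true_aligned,
         cohort = cohort)
}
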