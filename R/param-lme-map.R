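#' Specification of a one-parameter percentile sweep
#'
#' Defines the grid over which a single hybrid-model parameter is varied
#' while the other six are clamped at reference medians, mirroring a
#' percentile sweep (5th/25th/50th/75th/95th) of a reference distribution on
#' the natural scale.
#'
#' @param parameter One of `bMB, bMF, beta2, alpha1, alpha2, lambda, p`.
#' @param grid Strictly monotone numeric vector of natural-scale values
#'   (default: the packaged reference grid, see [reference_grid()]).
#' @param medians Named vector of the clamped values for the remaining
#'   parameters (default: centers of the reference grids).
#' @param n_subjects Total simulated subjects for the sweep, divisible by
#'   `length(grid)` (default 1000).
#' @param n_trials Trials per subject (default 201).
#' @param seed Integer seed.
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(parameter, grid = reference_grid()[[parameter]],
                       medians = reference_medians(), n_subjects = 1000,
                       n_trials = 201, seed = 1L) {
    pars <- c("bMB", "bMF", "beta2", "alpha1", "alpha2", "lambda", "p")
    if (!parameter %in% pars)
        stopf("unknown parameter '%s'", parameter)
    if (length(grid) < 2 || any(diff(grid) <= 0))
        stopf("grid must be strictly increasing with >= 2 values")
    if (n_subjects %% length(grid) != 0)
        stopf("n_subjects (%d) must be divisible by the grid length (%d)",
              n_subjects, length(grid))
    structure(list(parameter = parameter, grid = grid, medians = medians,
                   n_subjects = as.integer(n_subjects),
                   n_trials = as.integer(n_trials), seed = as.integer(seed)),
              class = "sweep_spec")
}

#' Reference sweep grids and medians
#'
#' Packaged percentile-style grids on the natural scale: weights and inverse
#' temperatures span two orders of magnitude around 1, rates and the
#' eligibility cover (0.1, 0.9), and perseveration is centered on zero. The
#' clamped medians are the grid centers. Both are fully configurable through
#' [sweep_spec()].
#'
#' @return `reference_grid()`: named list of length-5 numeric grids;
#'   `reference_medians()`: named numeric vector of the 7 medians.
#' @export
reference_grid <- function() {
    list(bMB = c(0.25, 0.5, 1, 2, 4), bMF = c(0.25, 0.5, 1, 2, 4),
         beta2 = c(0.25, 0.5, 1, 2, 4),
         alpha1 = c(0.1, 0.3, 0.5, 0.7, 0.9),
         alpha2 = c(0.1, 0.3, 0.5, 0.7, 0.9),
         lambda = c(0.1, 0.3, 0.5, 0.7, 0.9),
         p = c(-0.5, -0.15, 0, 0.15, 0.5))
}

#' @rdname reference_grid
#' @export
reference_medians <- function() {
    c(bMB = 1, bMF = 1, beta2 = 1, alpha1 = 0.5, alpha2 = 0.5, lambda = 0.5,
      p = 0)
}

#' Run a one-parameter sweep
#'
#' For every grid value, simulates `n_subjects / length(grid)` single-session
#' agents with the swept parameter set to that value and all others clamped
#' at the medians, builds the stay/switch design, fits the logistic stay
#' regression (no session terms; one session per agent) and records the
#' `reward`, `transition`, `reward x transition` and intercept coefficients.
#'
#' @param spec A [sweep_spec()].
#' @param config A [task_config()] (its `n_trials` is overridden by the
#'   spec).
#' @param method Passed to [fit_mixed_logistic()]; `"pooled"` (default) fits
#'   a plain logistic regression, which is equivalent here because all agents
#'   at a grid point share identical parameters, and keeps large sweeps fast.
#'   `"glmer"` uses the full hierarchical fit.
#' @return Data.frame of class `sweep_result`: one row per grid value with
#'   columns `parameter`, `value`, `intercept`, `reward`, `transition`,
#'   `reward_x_transition` and their standard errors.
#' @export
run_sweep <- function(spec, config = task_config(),
                      method = c("pooled", "glmer")) {
    stopifnot(inherits(spec, "sweep_spec"))
    method <- match.arg(method)
    per_point <- spec$n_subjects %/% length(spec$grid)
    cfg <- config
    cfg$n_trials <- spec$n_trials
    rows <- lapply(seq_along(spec$grid), function(g) {
        pars <- spec$medians
        pars[spec$parameter] <- spec$grid[g]
        pt <- data.frame(subject = seq_len(per_point), session = 1L,
                         bMB = pars[["bMB"]], bMF = pars[["bMF"]],
                         beta2 = pars[["beta2"]], alpha1 = pars[["alpha1"]],
                         alpha2 = pars[["alpha2"]], lambda = pars[["lambda"]],
                         p = pars[["p"]])
        coh <- simulate_cohort(pt, cfg,
                               seed = spec$seed + 1000003L * g)
        design <- build_stay_design(coh)
        fit <- fit_mixed_logistic(design, include_correct = FALSE,
                                  method = method)
        cf <- setNames(fit$coefficients$estimate, fit$coefficients$term)
        se <- setNames(fit$coefficients$se, fit$coefficients$term)
        data.frame(parameter = spec$parameter, value = spec$grid[g],
                   intercept = cf[["(Intercept)"]],
                   reward = cf[["reward_prev"]],
                   transition = cf[["transition_prev"]],
                   reward_x_transition = cf[["reward_prev:transition_prev"]],
                   se_reward = se[["reward_prev"]],
                   se_transition = se[["transition_prev"]],
                   se_reward_x_transition = se[["reward_prev:transition_prev"]])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("sweep_result", class(out))
    out
}

#' Parameter-specific correlation indices
#'
#' For each swept parameter, the Pearson correlation between the grid values
#' and the induced `reward` coefficients (the model-free index, `MF_CI`) and
#' between the grid values and the `reward x transition` coefficients (the
#' model-based index, `MB_CI`).
#'
#' @param sweeps A list of [run_sweep()] results (or a single one).
#' @return Data.frame with columns `parameter`, `MF_CI`, `MB_CI`. A
#'   coefficient series with zero variance yields `NA` (undefined), not 0.
#' @export
correlation_indices <- function(sweeps) {
    if (inherits(sweeps, "sweep_result")) sweeps <- list(sweeps)
    out <- do.call(rbind, lapply(sweeps, function(sw) {
        if (nrow(sw) < 3) stopf("need >= 3 grid points per parameter")
        safe_cor <- function(y) {
            if (sd(y) == 0) {
                warnf("zero variance in coefficients for '%s'; index undefined",
                      sw$parameter[1])
                return(NA_real_)
            }
            cor(sw$value, y)
        }
        data.frame(parameter = sw$parameter[1],
                   MF_CI = safe_cor(sw$reward),
                   MB_CI = safe_cor(sw$reward_x_transition))
    }))
    rownames(out) <- NULL
    out
}

#' Reconstruct session-wise regression coefficients from model parameters
#'
#' Approximates the model-free and model-based regression coefficients per
#' session by summing, over the parameters that primarily drive each index,
#' the product of the correlation index and the session mean of that
#' parameter: `bMF`, `alpha1` and `lambda` for the model-free coefficient;
#' `bMB`, `beta2` and `alpha2` for the model-based one. Values are reported
#' relative to the first session. The mapping is a descriptive projection and
#' is not invertible.
#'
#' @param param_means Matrix of natural-scale session means: rows named by
#'   parameter (at least the six above), columns are sessions.
#' @param indices A [correlation_indices()] data.frame covering those
#'   parameters.
#' @return Data.frame with columns `session`, `MF_recon`, `MB_recon`
#'   (first-session-relative).
#' @export
reconstruct_lme <- function(param_means, indices) {
    mf_pars <- c("bMF", "alpha1", "lambda")
    mb_pars <- c("bMB", "beta2", "alpha2")
    need <- union(mf_pars, mb_pars)
    if (!all(need %in% rownames(param_means)))
        stopf("param_means must have rows: %s", paste(need, collapse = ", "))
    if (!all(need %in% indices$parameter))
        stopf("indices must cover: %s", paste(need, collapse = ", "))
    if (any(is.na(param_means[need, ]))) stopf("missing session means")
    idx <- setNames(seq_len(nrow(indices)), indices$parameter)
    mf <- colSums(param_means[mf_pars, , drop = FALSE] *
                      indices$MF_CI[idx[mf_pars]])
    mb <- colSums(param_means[mb_pars, , drop = FALSE] *
                      indices$MB_CI[idx[mb_pars]])
    sessions <- colnames(param_means)
    if (is.null(sessions)) sessions <- paste0("S", seq_along(mf))
    data.frame(session = sessions, MF_recon = mf - mf[1],
               MB_recon = mb - mb[1], row.names = NULL)
}
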