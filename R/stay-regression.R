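#' Build the stay/switch regression design
#'
#' One row per analyzable trial: the outcome `stay` is 1 when the current
#' stage-1 choice repeats the previous one, and the predictors code the
#' previous trial's reward (+1 rewarded / -1 unrewarded), transition (+1
#' common / -1 uncommon) and correctness (+1 when the previous stage-1 choice
#' was the objectively better action). The first valid trial of every
#' session and any row whose current or previous trial was missed are
#' excluded.
#'
#' With the generative reward walks available (synthetic data), "correct"
#' means the action whose common transition leads to the stage-2 state with
#' the higher attainable reward probability at that trial. Without walks it
#' falls back to a running, exponentially decayed (rate 0.9) empirical reward
#' estimate per stage-2 state.
#'
#' @param cohort A `twostep_cohort` (from [simulate_cohort()]) or a trial
#'   data.frame.
#' @param walks Optional named list of reward walks keyed `"subject:session"`
#'   (taken from `cohort$walks` automatically when a cohort is supplied).
#' @return Data.frame of class `stay_design` with columns `subject`,
#'   `session`, `stay`, `reward_prev`, `transition_prev`, `correct_prev`.
#' @export
#' @examples
#' coh <- simulate_cohort(data.frame(subject = 1:2, session = 1L, bMB = 1,
#'                                   bMF = 1, beta2 = 1, alpha1 = 0.5,
#'                                   alpha2 = 0.5, lambda = 0.5, p = 0),
#'                        task_config(n_trials = 30), seed = 1)
#' head(build_stay_design(coh))
build_stay_design <- function(cohort, walks = NULL) {
    if (inherits(cohort, "twostep_cohort")) {
        if (is.null(walks)) walks <- cohort$walks
        trials <- cohort$trials
    } else if (inherits(cohort, "twostep_session")) {
        walks <- setNames(list(cohort$walk),
                          paste0(cohort$trials$subject[1], ":",
                                 cohort$trials$session[1]))
        trials <- cohort$trials
    } else trials <- cohort
    if (all(trials$missed)) stopf("no valid trials in cohort")
    units <- split_units(trials)
    rows <- lapply(names(units), function(key) {
        tr <- units[[key]]
        tr <- tr[order(tr$trial), ]
        walk <- if (!is.null(walks)) walks[[key]] else NULL
        n <- nrow(tr)
        if (n < 2) return(NULL)
        correct <- correct_choice(tr, walk)
        prev <- seq_len(n - 1)
        cur <- prev + 1
        ok <- !tr$missed[prev] & !tr$missed[cur]
        if (!any(ok)) return(NULL)
        data.frame(
            subject = tr$subject[cur][ok], session = tr$session[cur][ok],
            stay = as.integer(tr$choice1[cur][ok] == tr$choice1[prev][ok]),
            reward_prev = ifelse(tr$reward[prev][ok] == 1, 1, -1),
            transition_prev = ifelse(tr$transition[prev][ok] == "common", 1, -1),
            correct_prev = correct[prev][ok],
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out) || nrow(out) == 0)
        stopf("no analyzable consecutive trial pairs")
    class(out) <- c("stay_design", class(out))
    out
}

# +1 / -1 per trial: was the chosen stage-1 action the objectively better
# one? With the true walk, state value = max attainable reward probability;
# otherwise a decayed running mean of observed rewards per stage-2 state.
correct_choice <- function(tr, walk) {
    n <- nrow(tr)
    out <- rep(NA_real_, n)
    if (!is.null(walk)) {
        for (i in seq_len(n)) {
            if (tr$missed[i]) next
            v0 <- max(walk[tr$trial[i] + 1, 1, ])
            v1 <- max(walk[tr$trial[i] + 1, 2, ])
            best <- if (v0 >= v1) 0 else 1  # common mapping: action k -> state k
            out[i] <- ifelse(tr$choice1[i] == best, 1, -1)
        }
    } else {
        est <- c(0.5, 0.5)
        decay <- 0.9
        for (i in seq_len(n)) {
            if (tr$missed[i]) next
            best <- if (est[1] >= est[2]) 0 else 1
            out[i] <- ifelse(tr$choice1[i] == best, 1, -1)
            s <- tr$state2[i] + 1
            est[s] <- decay * est[s] + (1 - decay) * tr$reward[i]
        }
    }
    out
}

stay_formula <- function(design, include_correct, random) {
    multi_session <- length(unique(design$session)) > 1
    fixed <- if (multi_session)
        "reward_prev * transition_prev * session" else
        "reward_prev * transition_prev"
    if (include_correct) fixed <- paste(fixed, "+ correct_prev")
    as.formula(paste("stay ~", fixed, "+", random))
}

#' Mixed-effects logistic regression of stay behavior
#'
#' Fits `stay ~ reward * transition (* session) [+ correct]` with by-subject
#' random intercept and slopes via `lme4::glmer` (Laplace approximation).
#' Session enters as treatment-coded dummies against the first session. On
#' singular or non-converged fits the random structure falls back from
#' correlated slopes to uncorrelated slopes to a random intercept, with a
#' warning.
#'
#' @param design A [build_stay_design()] data.frame.
#' @param include_correct Include the `correct_prev` regressor (default
#'   `TRUE` when present).
#' @param random Random-effects specification; default
#'   `"(1 + reward_prev * transition_prev | subject)"`.
#' @param method `"glmer"` (default) or `"pooled"` for a plain logistic
#'   regression ignoring subject structure (useful for large homogeneous
#'   simulation sweeps).
#' @param nAGQ Integrationa setting passed to `glmer` (0 uses the faster
#'   PIRLS-only approximation).
#' @return Object of class `mixed_fit`: `coefficients` (data.frame with
#'   estimate, se, z, p per fixed term), `anova` (Wald chi-square/F table per
#'   term group), `ranef_variance`, `model`, `n_rows`, `converged`,
#'   `singular`, `family`.
#' @export
fit_mixed_logistic <- function(design,
                               include_correct = "correct_prev" %in% names(design),
                               random = "(1 + reward_prev * transition_prev | subject)",
                               method = c("glmer", "pooled"), nAGQ = 1) {
    method <- match.arg(method)
    if (length(unique(design$subject)) < 2 && method == "glmer")
        stopf("mixed-effects fit needs >= 2 subjects")
    design <- prepare_design(design)
    if (method == "pooled") {
        f <- stay_formula(design, include_correct, "0")
        f <- as.formula(sub("\\+ 0$", "", deparse1(f)))
        m <- stats::glm(f, family = stats::binomial(), data = design)
        return(mixed_fit_result(m, design, family = "binomial"))
    }
    ladder <- c(random,
                gsub("\\|", "||", random, fixed = FALSE),
                "(1 | subject)")
    ladder <- unique(ladder)
    fit <- NULL
    used <- NA_character_
    for (r in ladder) {
        f <- stay_formula(design, include_correct, r)
        m <- tryCatch(suppressWarnings(
            lme4::glmer(f, data = design, family = stats::binomial(),
                        nAGQ = nAGQ,
                        control = lme4::glmerControl(calc.derivs = FALSE))),
            error = function(e) NULL)
        if (is.null(m)) next
        fit <- m; used <- r
        if (!lme4::isSingular(m, tol = 1e-4)) break
        warnf("singular random-effects fit for '%s'; falling back", r)
    }
    if (is.null(fit)) stopf("all random-effects structures failed to fit")
    mixed_fit_result(fit, design, family = "binomial", random_used = used)
}

#' Mixed-effects linear regression for continuous trial responses
#'
#' The linear analogue of [fit_mixed_logistic()] for continuous per-trial
#' responses such as scaled hemodynamic amplitudes, fitted by REML via
#' `lmerTest::lmer` (Satterthwaite degrees of freedom for the per-term F
#' tests). Responses are z-scored per subject before fitting.
#'
#' @param design A [build_stay_design()] data.frame with an added `response`
#'   column.
#' @param scale_within_subject z-score the response per subject (default
#'   TRUE).
#' @inheritParams fit_mixed_logistic
#' @return A `mixed_fit` object (see [fit_mixed_logistic()]).
#' @export
fit_mixed_linear <- function(design,
                             include_correct = "correct_prev" %in% names(design),
                             random = "(1 + reward_prev * transition_prev | subject)",
                             scale_within_subject = TRUE) {
    if (!"response" %in% names(design)) stopf("design lacks a 'response' column")
    if (var(design$response, na.rm = TRUE) == 0)
        stopf("response has zero variance")
    design <- prepare_design(design)
    if (scale_within_subject) {
        design$response <- stats::ave(design$response, design$subject,
                                      FUN = function(x) as.numeric(scale(x)))
    }
    ladder <- unique(c(random, gsub("\\|", "||", random), "(1 | subject)"))
    fit <- NULL; used <- NA_character_
    for (r in ladder) {
        f <- stay_formula(design, include_correct, r)
        f <- as.formula(sub("^stay", "response", deparse1(f)))
        m <- tryCatch(suppressWarnings(
            lmerTest::lmer(f, data = design, REML = TRUE)),
            error = function(e) NULL)
        if (is.null(m)) next
        fit <- m; used <- r
        if (!lme4::isSingular(m, tol = 1e-4)) break
        warnf("singular random-effects fit for '%s'; falling back", r)
    }
    if (is.null(fit)) stopf("all random-effects structures failed to fit")
    mixed_fit_result(fit, design, family = "gaussian", random_used = used)
}

prepare_design <- function(design) {
    design <- as.data.frame(design)
    design$subject <- factor(design$subject)
    if ("session" %in% names(design))
        design$session <- factor(design$session)
    design
}

mixed_fit_result <- function(model, design, family, random_used = NULL) {
    is_mer <- inherits(model, "merMod")
    if (is_mer) {
        sm <- summary(model)$coefficients
        conv <- length(model@optinfo$conv$lme4$messages) == 0
        singular <- lme4::isSingular(model, tol = 1e-4)
        rv <- as.data.frame(lme4::VarCorr(model))
    } else {
        sm <- summary(model)$coefficients
        conv <- TRUE; singular <- FALSE; rv <- NULL
    }
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        z = sm[, 1] / sm[, 2],
                        p = 2 * pnorm(-abs(sm[, 1] / sm[, 2])),
                        row.names = NULL)
    an <- tryCatch({
        if (family == "gaussian" && inherits(model, "lmerModLmerTest")) {
            a <- anova(model, type = 3)
            data.frame(term = rownames(a), statistic = a$`F value`,
                       df = a$NumDF, df_denom = a$DenDF,
                       p = a$`Pr(>F)`, test = "F", row.names = NULL)
        } else {
            a <- car::Anova(model, type = 3)
            data.frame(term = rownames(a), statistic = a$Chisq / a$Df,
                       df = a$Df, df_denom = NA_real_,
                       p = a$`Pr(>Chisq)`, test = "Wald chisq/df",
                       row.names = NULL)
        }
    }, error = function(e) NULL)
    structure(list(coefficients = coefs, anova = an, ranef_variance = rv,
                   model = model, n_rows = nrow(design), converged = conv,
                   singular = singular, family = family,
                   random_used = random_used),
              class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
    cat(sprintf("%s mixed fit on %d rows%s%s\n",
                if (x$family == "binomial") "Logistic" else "Linear",
                x$n_rows,
                if (x$converged) "" else " (convergence warning)",
                if (isTRUE(x$singular)) " (singular random effects)" else ""))
    print(transform(x$coefficients, estimate = round(estimate, 3),
                    se = round(se, 3), z = round(z, 2),
                    p = signif(p, 3)))
    invisible(x)
}

#' Stay probabilities by previous reward and transition
#'
#' The descriptive four-cell summary of the stay/switch pattern: mean
#' probability of repeating the previous stage-1 choice for rewarded-common,
#' rewarded-uncommon, unrewarded-common and unrewarded-uncommon previous
#' trials, per session and pooled, with between-subject standard errors.
#'
#' @param design A [build_stay_design()] data.frame.
#' @return Data.frame with columns `session` (`"all"` for pooled), `cell`
#'   (`"R+C"`, `"R+U"`, `"R-C"`, `"R-U"`), `p_stay`, `se`, `n`.
#' @export
stay_probability_summary <- function(design) {
    cells <- data.frame(reward = c(1, 1, -1, -1), trans = c(1, -1, 1, -1),
                        cell = c("R+C", "R+U", "R-C", "R-U"))
    one <- function(d, label) {
        do.call(rbind, lapply(seq_len(4), function(k) {
            sel <- d$reward_prev == cells$reward[k] &
                d$transition_prev == cells$trans[k]
            dd <- d[sel, ]
            if (nrow(dd) == 0)
                return(data.frame(session = label, cell = cells$cell[k],
                                  p_stay = NA_real_, se = NA_real_, n = 0L))
            per_subj <- tapply(dd$stay, dd$subject, mean)
            data.frame(session = label, cell = cells$cell[k],
                       p_stay = mean(dd$stay),
                       se = if (length(per_subj) > 1)
                           sd(per_subj) / sqrt(length(per_subj)) else NA_real_,
                       n = nrow(dd))
        }))
    }
    out <- one(design, "all")
    for (s in sort(unique(design$session)))
        out <- rbind(out, one(design[design$session == s, ], as.character(s)))
    rownames(out) <- NULL
    out
}

#' Pearson correlation between two coefficient vectors
#'
#' Matches the coefficient tables of two [fit_mixed_logistic()] /
#' [fit_mixed_linear()] results by term name and returns the Pearson
#' product-moment correlation with its p-value.
#'
#' @param result_a,result_b `mixed_fit` objects, or plain named numeric
#'   vectors of coefficients.
#' @return List with `r`, `p`, `n_terms` and the matched `terms`.
#' @export
coefficient_correlation <- function(result_a, result_b) {
    get_vec <- function(x) {
        if (inherits(x, "mixed_fit"))
            setNames(x$coefficients$estimate, x$coefficients$term)
        else x
    }
    a <- get_vec(result_a); b <- get_vec(result_b)
    common <- intersect(names(a), names(b))
    if (length(common) < 3) stopf("need at least 3 matched coefficients")
    ct <- cor.test(a[common], b[common], method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n_terms = length(common),
         terms = common)
}
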