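#' Agent parameters of the hybrid model
#'
#' The seven free parameters of the winning two-beta hybrid agent on their
#' natural scale: `bMB` and `bMF` weight the model-based and model-free
#' stage-1 values, `beta2` is the stage-2 softmax inverse temperature,
#' `alpha1`/`alpha2` are the stage-specific learning rates, `lambda` the
#' eligibility with which the stage-2 prediction error reaches stage-1
#' values, and `p` the perseveration bonus (`p > 0` repeat, `p < 0` switch)
#' added to the logit of the previously chosen stage-1 action.
#'
#' @param bMB,bMF,beta2 Non-negative inverse-temperature weights.
#' @param alpha1,alpha2,lambda Rates in `[0, 1]` (the sigmoid transform used
#'   in fitting keeps them strictly inside; the closed boundaries are valid
#'   for simulation, e.g. a pure final-reward learner with `lambda = 1`).
#' @param p Perseveration, any real.
#' @return Named numeric vector of class `agent_params`.
#' @export
#' @examples
#' agent_params(bMB = 1.5, bMF = 0.5)
agent_params <- function(bMB = 1, bMF = 1, beta2 = 1, alpha1 = 0.5,
                         alpha2 = 0.5, lambda = 0.5, p = 0) {
    if (bMB < 0 || bMF < 0 || beta2 < 0)
        stopf("bMB, bMF and beta2 must be non-negative")
    if (any(c(alpha1, alpha2, lambda) < 0) || any(c(alpha1, alpha2, lambda) > 1))
        stopf("alpha1, alpha2 and lambda must lie in [0, 1]")
    structure(c(bMB = bMB, bMF = bMF, beta2 = beta2, alpha1 = alpha1,
                alpha2 = alpha2, lambda = lambda, p = p),
              class = "agent_params")
}

as_agent_params <- function(x) {
    if (inherits(x, "agent_params")) return(x)
    x <- unlist(x)
    do.call(agent_params, as.list(x[c("bMB", "bMF", "beta2", "alpha1",
                                      "alpha2", "lambda", "p")]))
}

# Canonical natural 7-vector consumed by the compiled core. For the
# omega-parameterized family the stage-1 weights are beta1*omega and
# beta1*(1-omega); the two parameterizations span the same likelihoods.
canonical_params <- function(x) {
    x <- as_agent_params(x)
    as.numeric(x[c("bMB", "bMF", "beta2", "alpha1", "alpha2", "lambda", "p")])
}

## ---------------------------------------------------------------------------
## Model-variant registry

variant_def <- function(name, par_names, transforms, to_canonical, note = "") {
    structure(list(name = name, par_names = par_names,
                   transforms = transforms, n_params = length(par_names),
                   to_canonical = to_canonical, note = note),
              class = "model_variant")
}

# Fill the canonical layout from a named natural vector, defaulting absent
# parameters: lambda -> 0 (pure TD), p -> 0, shared alpha duplicated.
fill_canonical <- function(nat) {
    g <- function(nm, def) if (nm %in% names(nat)) unname(nat[[nm]]) else def
    a1 <- g("alpha1", g("alpha", NA))
    a2 <- g("alpha2", g("alpha", NA))
    c(wMB = g("bMB", NA), wMF = g("bMF", NA), beta2 = g("beta2", NA),
      alpha1 = a1, alpha2 = a2, lambda = g("lambda", 0), p = g("p", 0))
}

two_beta_canonical <- function(nat) fill_canonical(nat)

omega_canonical <- function(nat) {
    w <- unname(nat[["omega"]])
    b1 <- unname(nat[["beta1"]])
    nat2 <- c(bMB = b1 * w, bMF = b1 * (1 - w),
              nat[setdiff(names(nat), c("beta1", "omega"))])
    fill_canonical(nat2)
}

.variant_registry <- local({
    tb <- c(bMB = "exp", bMF = "exp")
    om <- c(beta1 = "exp", omega = "sigmoid")
    core2a <- c(beta2 = "exp", alpha1 = "sigmoid", alpha2 = "sigmoid")
    core1a <- c(beta2 = "exp", alpha = "sigmoid")
    lam <- c(lambda = "sigmoid"); pp <- c(p = "identity")
    mk <- function(name, tr, canon, note) {
        variant_def(name, names(tr), unname(tr), canon, note)
    }
    list(
        ll2bmfbmb2alr = mk("ll2bmfbmb2alr", c(tb, core2a, lam, pp),
                           two_beta_canonical,
                           "two betas (bMB, bMF), two alphas, lambda, perseveration"),
        ll2bmfbmb2al  = mk("ll2bmfbmb2al", c(tb, core2a, lam),
                           two_beta_canonical, "two betas, no perseveration"),
        ll2bmfbmb1alr = mk("ll2bmfbmb1alr", c(tb, core1a, lam, pp),
                           two_beta_canonical, "two betas, shared alpha"),
        ll2bmfbmb2ar  = mk("ll2bmfbmb2ar", c(tb, core2a, pp),
                           two_beta_canonical, "two betas, no eligibility trace"),
        llm2b2alr = mk("llm2b2alr", c(om, core2a, lam, pp), omega_canonical,
                       "original hybrid: omega-weighted mixture of MB and MF"),
        llm2b2al  = mk("llm2b2al", c(om, core2a, lam), omega_canonical,
                       "omega mixture, no perseveration"),
        llm2b1alr = mk("llm2b1alr", c(om, core1a, lam, pp), omega_canonical,
                       "omega mixture, shared alpha"),
        llm2b2ar  = mk("llm2b2ar", c(om, core2a, pp), omega_canonical,
                       "omega mixture, no eligibility trace")
    )
})

#' Model variants of the hybrid agent
#'
#' The registry toggles four structural choices: separate versus shared
#' learning rates, two stage-1 weights (`bMB`, `bMF`) versus an explicit
#' mixture (`beta1`, `omega`), presence of the eligibility trace `lambda`,
#' and presence of perseveration `p`. `ll2bmfbmb2alr` is the full two-beta
#' variant; `llm2b2alr` is the original omega-weighted hybrid.
#'
#' @param name Variant name; see `list_variants()`.
#' @return A `model_variant` object with fields `name`, `par_names`,
#'   `transforms`, `n_params` and `to_canonical`.
#' @export
#' @examples
#' model_variant("ll2bmfbmb2alr")$par_names
model_variant <- function(name = "ll2bmfbmb2alr") {
    if (inherits(name, "model_variant")) return(name)
    v <- .variant_registry[[name]]
    if (is.null(v)) stopf("unknown model variant '%s'; see list_variants()", name)
    v
}

#' @rdname model_variant
#' @export
list_variants <- function() names(.variant_registry)

## ---------------------------------------------------------------------------
## Parameter transforms

apply_transform <- function(u, kind) {
    switch(kind, exp = exp(u), sigmoid = logistic(u), identity = u,
           stopf("unknown transform '%s'", kind))
}

invert_transform <- function(x, kind) {
    switch(kind, exp = log(x), sigmoid = logit(x), identity = x,
           stopf("unknown transform '%s'", kind))
}

#' Transform unconstrained parameters to the natural scale
#'
#' Weights and inverse temperatures are exponentiated, rates and the
#' eligibility are passed through the logistic sigmoid, and perseveration is
#' untransformed, so that any real vector maps to a valid parameter set.
#'
#' @param unconstrained Numeric vector, one entry per free parameter of the
#'   variant.
#' @param variant A [model_variant()] or its name.
#' @return List with `natural` (named vector on the natural scale),
#'   `canonical` (the seven-element canonical layout used by the likelihood)
#'   and `unconstrained`.
#' @export
#' @examples
#' transform_params(rep(0, 7), "ll2bmfbmb2alr")$natural
transform_params <- function(unconstrained, variant = "ll2bmfbmb2alr") {
    variant <- model_variant(variant)
    if (length(unconstrained) != variant$n_params)
        stopf("variant '%s' expects %d parameters, got %d",
              variant$name, variant$n_params, length(unconstrained))
    if (any(!is.finite(unconstrained))) stopf("non-finite unconstrained parameters")
    nat <- mapply(apply_transform, unconstrained, variant$transforms)
    names(nat) <- variant$par_names
    list(natural = nat, canonical = variant$to_canonical(nat),
         unconstrained = unconstrained)
}

#' @rdname transform_params
#' @param natural Named numeric vector on the natural scale (names matching
#'   `variant$par_names`).
#' @export
inverse_transform_params <- function(natural, variant = "ll2bmfbmb2alr") {
    variant <- model_variant(variant)
    x <- natural[variant$par_names]
    mapply(invert_transform, x, variant$transforms)
}

## ---------------------------------------------------------------------------
## Value computation and updates (reference R implementations)

#' Model-based stage-1 action values
#'
#' Computes the prospective value of each stage-1 action from the current
#' stage-2 values and the instructed transition scheme: the best achievable
#' stage-2 value of the commonly reached state, weighted by `p_common`, plus
#' that of the other state weighted by `1 - p_common`. Transition
#' probabilities are fixed (instructed), not learned.
#'
#' @param q2 2 x 2 matrix of stage-2 values, `q2[state, action]`.
#' @param p_common Common-transition probability.
#' @return Numeric vector of length 2: model-based value per stage-1 action.
#' @export
#' @examples
#' compute_qmb(rbind(c(1, 0), c(0, 0)), 0.7)
compute_qmb <- function(q2, p_common = 0.7) {
    stopifnot(is.matrix(q2), all(dim(q2) == c(2, 2)), all(is.finite(q2)))
    m <- apply(q2, 1, max)
    c(p_common * m[1] + (1 - p_common) * m[2],
      p_common * m[2] + (1 - p_common) * m[1])
}

new_qstate <- function() {
    list(q1_mf = c(0, 0), q2 = matrix(0, 2, 2), prev_choice1 = NA_integer_)
}

#' Stage-1 choice probabilities
#'
#' Softmax over the stage-1 logits
#' `bMB * Qmb(a) + bMF * Qmf(a) + p * 1[a == previous choice]`. On the first
#' trial (no previous valid choice) the perseveration term is absent.
#'
#' @param qstate List with `q1_mf`, `q2`, `prev_choice1` (see
#'   [td_update()]).
#' @param params [agent_params()] (or coercible).
#' @param p_common Common-transition probability used in the model-based
#'   values.
#' @return Probability of each stage-1 action (sums to 1).
#' @export
stage1_choice_probs <- function(qstate, params, p_common = 0.7) {
    params <- as_agent_params(params)
    qmb <- compute_qmb(qstate$q2, p_common)
    rep_ind <- c(0, 0)
    if (!is.na(qstate$prev_choice1)) rep_ind[qstate$prev_choice1 + 1] <- 1
    softmax(params[["bMB"]] * qmb + params[["bMF"]] * qstate$q1_mf +
                params[["p"]] * rep_ind)
}

#' Stage-2 choice probabilities
#'
#' Softmax of `beta2 * q2[state2, ]`; `beta2 = 0` yields indifference.
#'
#' @param q2 2 x 2 stage-2 value matrix.
#' @param state2 Visited stage-2 state (0 or 1).
#' @param beta2 Inverse temperature.
#' @return Probability of each stage-2 action.
#' @export
stage2_choice_probs <- function(q2, state2, beta2) {
    softmax(beta2 * q2[state2 + 1, ])
}

#' SARSA(lambda) update after one trial
#'
#' Applies the model-free updates of the hybrid agent: the stage-1 value of
#' the chosen action moves toward the (pre-update) value of the visited
#' stage-2 option with rate `alpha1`, the stage-2 value moves toward the 0/1
#' reward with rate `alpha2`, and the stage-2 prediction error additionally
#' reaches the stage-1 value with weight `alpha1 * lambda`.
#'
#' @param qstate List with `q1_mf` (length-2), `q2` (2 x 2) and
#'   `prev_choice1`.
#' @param choice1,state2,choice2 Trial events (0/1 codes).
#' @param reward 0 or 1.
#' @param params [agent_params()].
#' @return The updated `qstate`.
#' @export
td_update <- function(qstate, choice1, state2, choice2, reward, params) {
    params <- as_agent_params(params)
    if (any(is.na(c(choice1, state2, choice2, reward))))
        stopf("td_update received a missed trial; caller must skip it")
    i1 <- choice1 + 1; is <- state2 + 1; i2 <- choice2 + 1
    d1 <- qstate$q2[is, i2] - qstate$q1_mf[i1]
    qstate$q1_mf[i1] <- qstate$q1_mf[i1] + params[["alpha1"]] * d1
    d2 <- reward - qstate$q2[is, i2]
    qstate$q2[is, i2] <- qstate$q2[is, i2] + params[["alpha2"]] * d2
    qstate$q1_mf[i1] <- qstate$q1_mf[i1] +
        params[["alpha1"]] * params[["lambda"]] * d2
    qstate$prev_choice1 <- choice1
    qstate
}

## ---------------------------------------------------------------------------
## Likelihood

# Pure-R reference likelihood, kept as an independent route against the
# compiled engine.
session_loglik_r <- function(canonical, trials, p_common) {
    q <- new_qstate()
    canonical <- unname(canonical)
    pars <- agent_params(bMB = canonical[1], bMF = canonical[2],
                         beta2 = canonical[3],
                         alpha1 = min(max(canonical[4], 1e-12), 1 - 1e-12),
                         alpha2 = min(max(canonical[5], 1e-12), 1 - 1e-12),
                         lambda = min(max(canonical[6], 1e-12), 1 - 1e-12),
                         p = canonical[7])
    ll <- 0
    for (i in seq_len(nrow(trials))) {
        tr <- trials[i, ]
        if (isTRUE(tr$missed)) next
        p1 <- stage1_choice_probs(q, pars, p_common)
        p2 <- stage2_choice_probs(q$q2, tr$state2, canonical[3])
        ll <- ll + log(p1[tr$choice1 + 1]) + log(p2[tr$choice2 + 1])
        q <- td_update(q, tr$choice1, tr$state2, tr$choice2, tr$reward, pars)
    }
    ll
}

# Closure computing the session log-likelihood as a function of the
# unconstrained vector, with data conversion and transform dispatch hoisted
# out of the optimizer loop.
make_unit_loglik <- function(trials, variant, p_common) {
    variant <- model_variant(variant)
    valid <- !trials$missed
    n <- nrow(trials)
    ch1 <- st2 <- ch2 <- rw <- integer(n)
    ch1[valid] <- as.integer(trials$choice1[valid])
    st2[valid] <- as.integer(trials$state2[valid])
    ch2[valid] <- as.integer(trials$choice2[valid])
    rw[valid] <- as.integer(trials$reward[valid])
    missed <- as.logical(trials$missed)
    exp_idx <- which(variant$transforms == "exp")
    sig_idx <- which(variant$transforms == "sigmoid")
    par_names <- variant$par_names
    to_canonical <- variant$to_canonical
    function(u) {
        nat <- u
        nat[exp_idx] <- exp(u[exp_idx])
        nat[sig_idx] <- plogis(u[sig_idx])
        names(nat) <- par_names
        cpp_session_loglik(to_canonical(nat), ch1, st2, ch2, rw, missed,
                           p_common)
    }
}

#' Log-likelihood of one session under a hybrid-model variant
#'
#' Sums the log choice probabilities at both stages over all valid
#' (non-missed) trials, updating the agent's values after each trial. Values
#' are initialized at zero at the start of the session.
#'
#' @param unconstrained Unconstrained parameter vector of the variant (see
#'   [transform_params()]).
#' @param trials Trial data.frame of a single subject-session unit (columns
#'   `choice1`, `state2`, `choice2`, `reward`, `missed`).
#' @param variant A [model_variant()] or name.
#' @param p_common Common-transition probability of the task.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation).
#' @return Scalar log-likelihood (<= 0).
#' @export
#' @examples
#' s <- simulate_session(agent_params(), task_config(n_trials = 10), seed = 1)
#' session_loglik(rep(0, 7), s$trials)
session_loglik <- function(unconstrained, trials, variant = "ll2bmfbmb2alr",
                           p_common = 0.7, engine = c("cpp", "r")) {
    engine <- match.arg(engine)
    if (nrow(trials) == 0) stopf("empty session")
    if (any(is.na(unconstrained))) stopf("NaN/NA parameters")
    canon <- transform_params(unconstrained, variant)$canonical
    if (engine == "r") return(session_loglik_r(canon, trials, p_common))
    valid <- !trials$missed
    ch1 <- ch2 <- st2 <- rw <- integer(nrow(trials))
    ch1[valid] <- trials$choice1[valid]; st2[valid] <- trials$state2[valid]
    ch2[valid] <- trials$choice2[valid]; rw[valid] <- trials$reward[valid]
    cpp_session_loglik(canon, as.integer(ch1), as.integer(st2),
                       as.integer(ch2), as.integer(rw),
                       as.logical(trials$missed), p_common)
}
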