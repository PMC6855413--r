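#' Task configuration for the two-step paradigm
#'
#' Bundles the generative settings of the task: number of trials per session,
#' the fixed common-transition probability, and the Gaussian random walk that
#' drives the reward probability of each second-stage option between two
#' reflecting boundaries.
#'
#' @param n_trials Trials per session (default 201).
#' @param p_common Probability of the common transition, in (0.5, 1]
#'   (default 0.7).
#' @param walk_sd Standard deviation of the Gaussian step of the reward
#'   random walk (default 0.025).
#' @param walk_lo,walk_hi Reflecting boundaries of the walk (defaults 0.25
#'   and 0.75).
#' @param walk_init Initial reward probabilities, a vector of length
#'   `n_stage2_states * n_actions_per_state` (state-major order) or a single
#'   value recycled to all options. `NULL` (default) draws each initial value
#'   uniformly in `[walk_lo, walk_hi]` when the walk is generated.
#' @param n_stage2_states Number of second-stage states (default 2).
#' @param n_actions_per_state Number of actions per second-stage state
#'   (default 2).
#' @param reward_value Currency units paid per rewarded trial (default 0.2).
#'   Presentation only; the model codes reward 0/1.
#' @param response_deadline_s Response deadline in seconds (default 2).
#' @param miss_rate Probability that a simulated trial is missed and excluded
#'   from learning and analysis (default 0).
#'
#' @return An object of class `twostep_config` (a named list).
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$p_common
task_config <- function(n_trials = 201, p_common = 0.7, walk_sd = 0.025,
                        walk_lo = 0.25, walk_hi = 0.75, walk_init = NULL,
                        n_stage2_states = 2, n_actions_per_state = 2,
                        reward_value = 0.2, response_deadline_s = 2.0,
                        miss_rate = 0) {
    if (n_trials < 1) stopf("n_trials must be >= 1")
    if (!(p_common > 0.5 && p_common <= 1))
        stopf("p_common must lie in (0.5, 1], got %g", p_common)
    if (walk_sd < 0) stopf("walk_sd must be non-negative")
    if (!(walk_lo < walk_hi))
        stopf("invalid walk boundaries: walk_lo (%g) must be < walk_hi (%g)",
              walk_lo, walk_hi)
    if (walk_lo <= 0 || walk_hi >= 1)
        stopf("walk boundaries must lie strictly inside (0, 1)")
    if (!is.null(walk_init)) {
        n_opt <- n_stage2_states * n_actions_per_state
        if (length(walk_init) == 1) walk_init <- rep(walk_init, n_opt)
        if (length(walk_init) != n_opt)
            stopf("walk_init must have length 1 or %d", n_opt)
        if (any(walk_init < walk_lo | walk_init > walk_hi))
            stopf("walk_init values must lie in [walk_lo, walk_hi]")
    }
    if (miss_rate < 0 || miss_rate >= 1) stopf("miss_rate must be in [0, 1)")
    structure(list(n_trials = as.integer(n_trials), p_common = p_common,
                   walk_sd = walk_sd, walk_lo = walk_lo, walk_hi = walk_hi,
                   walk_init = walk_init,
                   n_stage2_states = as.integer(n_stage2_states),
                   n_actions_per_state = as.integer(n_actions_per_state),
                   reward_value = reward_value,
                   response_deadline_s = response_deadline_s,
                   miss_rate = miss_rate),
              class = "twostep_config")
}

# Single reflection into [lo, hi]; steps are much smaller than the range at
# realistic walk_sd, so one reflection suffices.
reflect_into <- function(x, lo, hi) {
    x <- ifelse(x > hi, 2 * hi - x, x)
    ifelse(x < lo, 2 * lo - x, x)
}

#' Generate a reward-probability random walk
#'
#' Each second-stage option carries an independent Gaussian random walk with
#' reflecting boundaries: at each trial the previous probability receives a
#' `N(0, walk_sd)` step and is reflected back into `[walk_lo, walk_hi]`.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return A `twostep_walk`: numeric array of dimension
#'   `n_trials x n_stage2_states x n_actions_per_state` of reward
#'   probabilities, all within the reflecting boundaries.
#' @export
#' @examples
#' w <- generate_reward_walk(task_config(), seed = 1)
#' range(w)
generate_reward_walk <- function(config = task_config(), seed = NULL) {
    stopifnot(inherits(config, "twostep_config"))
    set_seed_if(seed)
    n_opt <- config$n_stage2_states * config$n_actions_per_state
    init <- config$walk_init
    if (is.null(init)) init <- runif(n_opt, config$walk_lo, config$walk_hi)
    probs <- matrix(NA_real_, config$n_trials, n_opt)
    probs[1, ] <- init
    if (config$n_trials > 1) {
        steps <- matrix(rnorm((config$n_trials - 1) * n_opt, 0, config$walk_sd),
                        config$n_trials - 1, n_opt)
        for (t in 2:config$n_trials) {
            probs[t, ] <- reflect_into(probs[t - 1, ] + steps[t - 1, ],
                                       config$walk_lo, config$walk_hi)
        }
    }
    # option a of state s sits in column (s-1)*n_actions + a (state-major)
    out <- aperm(array(probs, dim = c(config$n_trials,
                                      config$n_actions_per_state,
                                      config$n_stage2_states)), c(1, 3, 2))
    class(out) <- c("twostep_walk", class(out))
    out
}

# Flatten a walk array back to the n_trials x (state-major option) matrix the
# compiled simulator consumes.
walk_matrix <- function(walk) {
    d <- dim(walk)
    matrix(aperm(unclass(walk), c(1, 3, 2)), d[1], d[2] * d[3])
}

#' Sample second-stage states for first-stage choices
#'
#' Implements the fixed transition scheme: action `k` commonly leads to state
#' `k` with probability `p_common`, otherwise to the other state (labelled
#' uncommon).
#'
#' @param choice1 Integer vector of first-stage actions (0 or 1).
#' @param config A [task_config()].
#' @param seed Optional seed.
#' @return A data.frame with columns `state2` (0/1) and `transition`
#'   (`"common"`/`"uncommon"`), one row per element of `choice1`.
#' @export
#' @examples
#' sample_transition(c(0, 1, 0), task_config(), seed = 1)
sample_transition <- function(choice1, config = task_config(), seed = NULL) {
    if (!all(choice1 %in% c(0L, 1L))) stopf("choice1 must be 0 or 1")
    set_seed_if(seed)
    common <- runif(length(choice1)) < config$p_common
    state2 <- ifelse(common, choice1, 1L - choice1)
    data.frame(state2 = as.integer(state2),
               transition = ifelse(common, "common", "uncommon"),
               stringsAsFactors = FALSE)
}

#' Simulate one session of the two-step task
#'
#' Runs the hybrid agent in closed loop against the task: the agent chooses
#' at both stages, the environment samples the transition and the reward from
#' the random walk, and the agent updates its values after every valid
#' trial. Q values start at zero; reward is coded 0/1 for learning
#' regardless of `reward_value`.
#'
#' @param params An [agent_params()] object (natural scale).
#' @param config A [task_config()].
#' @param seed Optional seed (also governs walk generation if `walk` is
#'   `NULL`).
#' @param walk Optional pre-generated [generate_reward_walk()] array.
#' @param subject,session Labels stored in the trial table.
#' @return A list of class `twostep_session` with elements `trials` (a
#'   data.frame: subject, session, trial, choice1, state2, choice2,
#'   transition, reward, rt1, rt2, missed) and `walk`.
#' @export
#' @examples
#' s <- simulate_session(agent_params(), task_config(n_trials = 20), seed = 1)
#' head(s$trials)
simulate_session <- function(params, config = task_config(), seed = NULL,
                             walk = NULL, subject = 1L, session = 1L) {
    stopifnot(inherits(config, "twostep_config"))
    params <- as_agent_params(params)
    set_seed_if(seed)
    if (is.null(walk)) walk <- generate_reward_walk(config)
    wm <- walk_matrix(walk)
    sim <- cpp_simulate_session(canonical_params(params), wm,
                                config$p_common, config$miss_rate)
    n <- config$n_trials
    trials <- data.frame(
        subject = rep(subject, n), session = rep(as.integer(session), n),
        trial = seq_len(n) - 1L,
        choice1 = sim$choice1, state2 = sim$state2, choice2 = sim$choice2,
        transition = sim$transition, reward = sim$reward,
        rt1 = rep(NA_real_, n), rt2 = rep(NA_real_, n),
        missed = sim$missed, stringsAsFactors = FALSE)
    structure(list(trials = trials, walk = walk), class = "twostep_session")
}

#' Simulate a cohort of subject-by-session units
#'
#' Vectorizes [simulate_session()] over a table of per-unit agent
#' parameters. Each unit receives its own random stream derived
#' deterministically from the master seed and the unit's subject/session
#' labels, so results do not depend on row order.
#'
#' @param param_table A data.frame with columns `subject`, `session` and the
#'   seven parameter columns `bMB, bMF, beta2, alpha1, alpha2, lambda, p`
#'   (natural scale), one row per unit.
#' @param config A [task_config()].
#' @param seed Master integer seed.
#' @return A list of class `twostep_cohort` with `trials` (row-bound trial
#'   table over all units) and `walks` (named list of walk arrays, keyed
#'   `"subject:session"`).
#' @export
#' @examples
#' pt <- data.frame(subject = 1:2, session = 1L,
#'                  bMB = 1, bMF = 1, beta2 = 1, alpha1 = 0.5,
#'                  alpha2 = 0.5, lambda = 0.5, p = 0.2)
#' coh <- simulate_cohort(pt, task_config(n_trials = 10), seed = 1)
#' nrow(coh$trials)
simulate_cohort <- function(param_table, config = task_config(), seed = 1L) {
    if (nrow(param_table) == 0) stopf("param_table is empty")
    need <- c("subject", "session", "bMB", "bMF", "beta2", "alpha1",
              "alpha2", "lambda", "p")
    miss <- setdiff(need, names(param_table))
    if (length(miss)) stopf("param_table lacks columns: %s",
                            paste(miss, collapse = ", "))
    out <- vector("list", nrow(param_table))
    walks <- vector("list", nrow(param_table))
    keys <- character(nrow(param_table))
    for (i in seq_len(nrow(param_table))) {
        row <- param_table[i, ]
        pars <- agent_params(bMB = row$bMB, bMF = row$bMF, beta2 = row$beta2,
                             alpha1 = row$alpha1, alpha2 = row$alpha2,
                             lambda = row$lambda, p = row$p)
        s <- simulate_session(pars, config,
                              seed = unit_seed(seed, row$subject, row$session),
                              subject = row$subject, session = row$session)
        out[[i]] <- s$trials
        walks[[i]] <- s$walk
        keys[i] <- paste0(row$subject, ":", row$session)
    }
    names(walks) <- keys
    structure(list(trials = do.call(rbind, out), walks = walks),
              class = "twostep_cohort")
}
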