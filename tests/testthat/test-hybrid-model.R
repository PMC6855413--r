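test_that("parameter transforms map zero to unit weights and half rates, and invert", {
    tp <- transform_params(rep(0, 7), "ll2bmfbmb2alr")
    expect_equal(unname(tp$natural[["beta2"]]), 1)
    expect_equal(unname(tp$natural[["alpha1"]]), 0.5)
    expect_equal(unname(tp$natural[["p"]]), 0)

    u <- c(1.7, -0.3, 0.2, 0.9, -1.1, 0.0, 0.4)
    for (v in list_variants()) {
        nv <- model_variant(v)$n_params
        uu <- u[seq_len(nv)]
        back <- inverse_transform_params(transform_params(uu, v)$natural, v)
        expect_equal(unname(back), uu, tolerance = 1e-10)
    }
    expect_error(transform_params(c(Inf, rep(0, 6))), "finite")
    expect_error(transform_params(rep(0, 5), "ll2bmfbmb2alr"), "expects 7")
})

test_that("model-based values implement the fixed transition expectation", {
    expect_equal(compute_qmb(matrix(0, 2, 2), 0.7), c(0, 0))
    q2 <- rbind(c(1, 0), c(0, 0))
    expect_equal(compute_qmb(q2, 0.7), c(0.7, 0.3))
    q_sym <- rbind(c(0.4, 0.1), c(0.1, 0.4))
    qmb <- compute_qmb(q_sym, 0.7)
    expect_equal(qmb[1], qmb[2])
})

test_that("choice rules are softmax with perseveration on the previous action", {
    q <- twosteptask:::new_qstate()
    p_eq <- stage1_choice_probs(q, agent_params(bMB = 1, bMF = 1, p = 0))
    expect_equal(p_eq, c(0.5, 0.5))

    q$q2 <- rbind(c(1, 0), c(0, 0))  # Qmb = (0.7, 0.3) at p_common 0.7... scaled
    q$q2 <- q$q2 / 0.7 * 1           # make Qmb = (1, 3/7)
    probs <- stage1_choice_probs(q, agent_params(bMB = 1, bMF = 0, p = 0), 0.7)
    dq <- 1 - 3 / 7
    expect_equal(probs[1], exp(dq) / (exp(dq) + 1), tolerance = 1e-12)

    q0 <- twosteptask:::new_qstate()
    q0$prev_choice1 <- 0L
    pr <- stage1_choice_probs(q0, agent_params(bMB = 0, bMF = 0, p = 2))
    expect_equal(pr[1], exp(2) / (exp(2) + 1), tolerance = 1e-12)

    expect_equal(stage2_choice_probs(rbind(c(5, -3), c(0, 0)), 1, 0),
                 c(0.5, 0.5))
    p2 <- stage2_choice_probs(rbind(c(0.5, 0), c(0, 0)), 0, 2)
    expect_equal(p2[1], exp(1) / (exp(1) + 1), tolerance = 1e-12)
})

test_that("SARSA(lambda) update matches hand traces", {
    pars0 <- agent_params(alpha1 = 0, alpha2 = 0, lambda = 1)
    q <- twosteptask:::new_qstate()
    q2 <- td_update(q, 0, 1, 0, 1, pars0)
    expect_equal(q2$q1_mf, c(0, 0))
    expect_equal(q2$q2, matrix(0, 2, 2))
    expect_equal(q2$prev_choice1, 0)

    # all-zero values, reward 1, alpha = 0.5, lambda = 1:
    # delta1 = 0, delta2 = 1 -> q2[s,a] = 0.5, q1[c1] = 0.5 * 1 * 1 = 0.5
    pars <- agent_params(alpha1 = 0.5, alpha2 = 0.5, lambda = 1)
    q3 <- td_update(twosteptask:::new_qstate(), 0, 1, 1, 1, pars)
    expect_equal(q3$q2[2, 2], 0.5)
    expect_equal(q3$q1_mf[1], 0.5)

    # lambda = 0: stage-1 untouched since delta1 = 0
    parsl0 <- agent_params(alpha1 = 0.5, alpha2 = 0.5, lambda = 0)
    q4 <- td_update(twosteptask:::new_qstate(), 0, 1, 1, 1, parsl0)
    expect_equal(q4$q1_mf[1], 0)
    expect_equal(q4$q2[2, 2], 0.5)

    expect_error(td_update(twosteptask:::new_qstate(), NA, 1, 1, 1, pars),
                 "missed")
})

test_that("session log-likelihood matches closed forms and a hand trace", {
    tr <- trial_table(choice1 = c(0L, 1L), state2 = c(0L, 0L),
                      choice2 = c(1L, 0L), reward = c(1L, 0L))
    # all betas zero, p = 0: both stages uniform
    u_unif <- c(log(1e-12), log(1e-12), log(1e-12), 0, 0, 0, 0)
    expect_equal(session_loglik(u_unif, tr), -4 * log(2), tolerance = 1e-6)

    # hand-traced 2-trial session, natural params
    # bMB = bMF = beta2 = 1, alpha1 = alpha2 = 0.5, lambda = 1, p = 0
    u <- c(0, 0, 0, 0, 0, qlogis(1 - 1e-12), 0)
    # trial 1: all values zero -> P(c1) = .5, P(c2) = .5
    # updates: d1 = 0; d2 = 1 - 0 = 1 -> q2[s0, a1] = .5; q1[a0] = .5*1*1 = .5
    # trial 2 (choice1 = 1, state2 = 0, choice2 = 0, reward 0):
    #   Qmb(a0) = .7 * max(0, .5) + .3 * 0 = .35 ; Qmb(a1) = .3 * .5 = .15
    #   logits: a0 = .35 + .5 (q1) + 0, a1 = .15 -> P(a1) = 1/(1+exp(.85-.15))
    #   stage 2 in state 0: q2 = (0, .5), choice a0: P = 1/(1+exp(.5))
    ll_hand <- log(0.5) + log(0.5) +
        log(1 / (1 + exp(0.85 - 0.15))) + log(1 / (1 + exp(0.5)))
    expect_equal(session_loglik(u, tr, engine = "cpp"), ll_hand,
                 tolerance = 1e-10)
    expect_equal(session_loglik(u, tr, engine = "r"), ll_hand,
                 tolerance = 1e-10)

    # appending a missed trial changes nothing
    tr_m <- rbind(tr, trial_table(NA_integer_, NA_integer_, NA_integer_,
                                  NA_integer_, transition = NA, missed = TRUE))
    tr_m$trial <- seq_len(nrow(tr_m)) - 1L
    expect_equal(session_loglik(u, tr_m), session_loglik(u, tr))
    expect_error(session_loglik(c(NaN, rep(0, 6)), tr), "NaN")
})

test_that("compiled and reference engines agree on random sessions", {
    cfg <- task_config(n_trials = 40, miss_rate = 0.1)
    set.seed(42)
    for (k in 1:5) {
        s <- simulate_session(agent_params(bMB = runif(1, 0, 3),
                                           bMF = runif(1, 0, 3),
                                           beta2 = runif(1, 0, 4),
                                           alpha1 = runif(1, .1, .9),
                                           alpha2 = runif(1, .1, .9),
                                           lambda = runif(1, .1, .9),
                                           p = rnorm(1, 0, 0.5)), cfg)
        u <- rnorm(7, 0, 0.8)
        expect_equal(session_loglik(u, s$trials, engine = "cpp"),
                     session_loglik(u, s$trials, engine = "r"),
                     tolerance = 1e-10)
    }
})

test_that("likelihood is invariant to joint relabeling of actions and states", {
    cfg <- task_config(n_trials = 60)
    s <- simulate_session(agent_params(bMB = 1.5, bMF = 0.8, beta2 = 2,
                                       p = 0.3), cfg, seed = 8)
    tr <- s$trials
    flipped <- tr
    flipped$choice1 <- 1L - tr$choice1
    flipped$state2 <- 1L - tr$state2
    flipped$choice2 <- 1L - tr$choice2
    u <- c(0.3, -0.2, 0.5, 0.2, -0.4, 0.1, 0.25)
    expect_equal(session_loglik(u, flipped), session_loglik(u, tr),
                 tolerance = 1e-12)
})

test_that("the omega parameterization reproduces the two-beta model trial by trial", {
    cfg <- task_config(n_trials = 80, miss_rate = 0.05)
    s <- simulate_session(agent_params(bMB = 2, bMF = 1), cfg, seed = 13)
    rest <- c(0.4, 0.3, -0.2, 0.1, 0.25)  # beta2, alpha1, alpha2, lambda, p
    for (b in c(0.5, 2, 4)) {
        u_om <- c(log(b), qlogis(0.5), rest)
        u_tb <- c(log(b / 2), log(b / 2), rest)
        expect_equal(session_loglik(u_om, s$trials, "llm2b2alr"),
                     session_loglik(u_tb, s$trials, "ll2bmfbmb2alr"),
                     tolerance = 1e-12)
    }
    # general case: wMB = beta1 * omega, wMF = beta1 * (1 - omega)
    u_om <- c(log(3), qlogis(0.3), rest)
    u_tb <- c(log(3 * 0.3), log(3 * 0.7), rest)
    expect_equal(session_loglik(u_om, s$trials, "llm2b2alr"),
                 session_loglik(u_tb, s$trials, "ll2bmfbmb2alr"),
                 tolerance = 1e-12)
})

test_that("variant registry covers the toggles with both anchors", {
    expect_setequal(c("ll2bmfbmb2alr", "llm2b2alr") %in% list_variants(),
                    TRUE)
    expect_length(list_variants(), 8)
    expect_equal(model_variant("ll2bmfbmb2alr")$n_params, 7)
    expect_equal(model_variant("llm2b2alr")$n_params, 7)
    expect_equal(model_variant("ll2bmfbmb2al")$n_params, 6)
    # lambda-free variant: canonical lambda defaults to 0
    v <- model_variant("ll2bmfbmb2ar")
    canon <- transform_params(rep(0, 6), v)$canonical
    expect_equal(unname(canon[6]), 0)
    expect_error(model_variant("nope"), "unknown model variant")
})
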