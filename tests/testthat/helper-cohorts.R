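# Shared fixtures built in code.

param_table <- function(n_subjects, n_sessions = 1, bMB = 1, bMF = 1,
                        beta2 = 3, alpha1 = 0.55, alpha2 = 0.45,
                        lambda = 0.6, p = 0.1) {
    expand.grid(subject = seq_len(n_subjects), session = seq_len(n_sessions),
                bMB = bMB, bMF = bMF, beta2 = beta2, alpha1 = alpha1,
                alpha2 = alpha2, lambda = lambda, p = p)
}

# Hand-constructable trial table
trial_table <- function(choice1, state2, choice2, reward,
                        transition = ifelse(choice1 == state2, "common", "uncommon"),
                        missed = FALSE, subject = 1L, session = 1L) {
    n <- length(choice1)
    data.frame(subject = rep(subject, n), session = rep(session, n),
               trial = seq_len(n) - 1L, choice1 = choice1, state2 = state2,
               choice2 = choice2, transition = transition, reward = reward,
               rt1 = NA_real_, rt2 = NA_real_,
               missed = rep(missed, length.out = n))
}
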