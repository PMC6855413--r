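#' Specification for the session-trend power analysis
#'
#' Scenario for a simulation-based power analysis of detecting a linear
#' change of a model parameter across training sessions. Per-subject
#' parameter values are drawn from a reference natural-scale distribution
#' whose total variance is split into a stable between-subject part and a
#' session-to-session part according to the assumed test-retest reliability
#' (`reliability = 0` means all variation is session noise).
#'
#' @param n_subjects Cohort size (default 20).
#' @param n_sessions Sessions (default 5).
#' @param effect Fractional linear change of the mean from first to last
#'   session (e.g. 0.8 for an 80% increase).
#' @param reliability Assumed test-retest correlation in `[0, 1)` (default
#'   0).
#' @param alpha Significance level (default 0.05).
#' @param n_replicates Monte-Carlo replicates (default 1000).
#' @param dist Named list of reference distributions per parameter, each
#'   `c(mean = , sd = )` on the natural scale. Defaults to the package's
#'   synthetic reference values for `bMF` and `bMB`.
#' @param seed Integer seed.
#' @return Object of class `power_spec`.
#' @export
power_spec <- function(n_subjects = 20, n_sessions = 5, effect = 0,
                       reliability = 0, alpha = 0.05, n_replicates = 1000,
                       dist = list(bMF = c(mean = 0.8, sd = 0.6),
                                   bMB = c(mean = 1.0, sd = 0.9)),
                       seed = 1L) {
    if (reliability < 0 || reliability >= 1)
        stopf("reliability must lie in [0, 1)")
    if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
    structure(list(n_subjects = n_subjects, n_sessions = n_sessions,
                   effect = effect, reliability = reliability, alpha = alpha,
                   n_replicates = n_replicates, dist = dist,
                   seed = as.integer(seed)),
              class = "power_spec")
}

simulate_trend_pvalues <- function(spec, which) {
    d <- spec$dist[[which]]
    if (is.null(d)) stopf("no reference distribution for '%s'", which)
    mu <- d[["mean"]]; sigma <- d[["sd"]]
    S <- spec$n_sessions; n <- spec$n_subjects
    sd_b <- sigma * sqrt(spec$reliability)
    sd_w <- sigma * sqrt(1 - spec$reliability)
    trend <- mu * spec$effect * (seq_len(S) - 1) / (S - 1)
    lin <- contr.poly(S)[, 1]
    set_seed_if(spec$seed)
    vapply(seq_len(spec$n_replicates), function(r) {
        base <- rnorm(n, mu, sd_b)
        y <- matrix(rnorm(n * S, 0, sd_w), n, S) + base +
            matrix(trend, n, S, byrow = TRUE)
        scores <- as.vector(y %*% lin)
        t.test(scores)$p.value
    }, numeric(1))
}

#' Simulation-based power for a linear session trend
#'
#' Monte-Carlo power of detecting a fractional linear change of the parameter
#' mean across sessions, tested per replicate with the linear polynomial
#' contrast of the repeated-measures ANOVA (a one-sample t-test on the
#' per-subject linear contrast scores).
#'
#' @param spec A [power_spec()].
#' @param which Parameter name (`"bMF"` or `"bMB"` with the default
#'   reference distributions).
#' @return List with `power`, `mc_se` (Monte-Carlo standard error) and the
#'   `spec`.
#' @export
#' @examples
#' power_simulation(power_spec(effect = 1, n_replicates = 200), "bMF")$power
power_simulation <- function(spec, which = c("bMF", "bMB")) {
    which <- match.arg(which, choices = names(spec$dist))
    pv <- simulate_trend_pvalues(spec, which)
    pow <- mean(pv < spec$alpha)
    list(power = pow,
         mc_se = sqrt(pow * (1 - pow) / spec$n_replicates),
         spec = spec, parameter = which)
}

#' Smallest detectable fractional change
#'
#' Inverts [power_simulation()] by bisection on the effect size to find the
#' minimal fractional linear change across sessions detectable with the
#' target power.
#'
#' @param spec A [power_spec()] (its `effect` field is ignored).
#' @param which Parameter name.
#' @param target_power Desired power (default 0.8).
#' @param interval Search interval for the fractional change (default
#'   `c(0, 5)`).
#' @param tol Bisection tolerance on the effect (default 0.01).
#' @return List with `effect` (detectable fractional change), `power_at`
#'   (simulated power there) and the number of bisection steps.
#' @export
detectable_effect <- function(spec, which = c("bMF", "bMB"),
                              target_power = 0.8, interval = c(0, 5),
                              tol = 0.01) {
    which <- match.arg(which, choices = names(spec$dist))
    power_at <- function(effect) {
        s <- spec; s$effect <- effect
        mean(simulate_trend_pvalues(s, which) < spec$alpha)
    }
    lo <- interval[1]; hi <- interval[2]
    if (power_at(hi) < target_power)
        stopf("target power not reached within the search interval")
    steps <- 0
    while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (power_at(mid) >= target_power) hi <- mid else lo <- mid
        steps <- steps + 1
    }
    list(effect = hi, power_at = power_at(hi), steps = steps)
}
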