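#' Intraclass correlation ICC(2,k)
#'
#' Test-retest reliability of a subjects-by-sessions matrix as the two-way
#' random-effects, absolute-agreement, mean-of-k-ratings intraclass
#' correlation (Shrout-Fleiss type 2,k). Computed from the ANOVA
#' decomposition into between-subject (`MS_R`), between-session (`MS_C`) and
#' residual (`MS_E`) mean squares:
#' `ICC(2,k) = (MS_R - MS_E) / (MS_R + (MS_C - MS_E) / n)`.
#' The test of ICC = 0 uses `F = MS_R / MS_E`; the confidence interval
#' follows the standard single-rating bounds with a Satterthwaite
#' denominator, stepped up to k ratings by the Spearman-Brown relation.
#' Values below 0.4 are labelled poor, 0.4-0.75 moderate, above 0.75
#' excellent.
#'
#' @param mat Numeric matrix, subjects in rows, sessions in columns (>= 2
#'   each, no missing entries).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `ci` (length-2), `f`, `df1`, `df2`, `p`,
#'   `label`.
#' @export
#' @examples
#' m <- matrix(rnorm(100), 20, 5) + rnorm(20)
#' icc_2k(m)$icc
icc_2k <- function(mat, conf_level = 0.95) {
    mat <- as.matrix(mat)
    if (any(is.na(mat))) stopf("missing entries are not allowed")
    n <- nrow(mat); k <- ncol(mat)
    if (n < 2 || k < 2) stopf("need >= 2 subjects and >= 2 sessions")
    if (var(as.vector(mat)) == 0) stopf("matrix has zero total variance")
    grand <- mean(mat)
    row_m <- rowMeans(mat); col_m <- colMeans(mat)
    ms_r <- k * sum((row_m - grand)^2) / (n - 1)
    ms_c <- n * sum((col_m - grand)^2) / (k - 1)
    sse <- sum((mat - outer(row_m, rep(1, k)) -
                    outer(rep(1, n), col_m) + grand)^2)
    ms_e <- sse / ((n - 1) * (k - 1))
    icc1 <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
    icck <- (ms_r - ms_e) / (ms_r + (ms_c - ms_e) / n)
    # F test of ICC = 0
    f0 <- ms_r / ms_e
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    p <- pf(f0, df1, df2, lower.tail = FALSE)
    # CI for the single-rating agreement ICC (McGraw & Wong), then
    # Spearman-Brown step-up to k ratings
    alpha <- 1 - conf_level
    a <- k * icc1 / (n * (1 - icc1))
    b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
    v <- (a * ms_c + b * ms_e)^2 /
        ((a * ms_c)^2 / (k - 1) + (b * ms_e)^2 / ((n - 1) * (k - 1)))
    f_l <- qf(1 - alpha / 2, n - 1, v)
    f_u <- qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (ms_r - f_l * ms_e) /
        (f_l * (k * ms_c + (k * n - k - n) * ms_e) + n * ms_r)
    hi1 <- n * (f_u * ms_r - ms_e) /
        (k * ms_c + (k * n - k - n) * ms_e + n * f_u * ms_r)
    sb <- function(r1) k * r1 / (1 + (k - 1) * r1)
    label <- if (icck < 0.4) "poor" else if (icck <= 0.75) "moderate" else "excellent"
    list(icc = icck, ci = c(sb(lo1), sb(hi1)), f = f0, df1 = df1, df2 = df2,
         p = p, label = label)
}

#' Coefficient of variation in percent
#'
#' Within-subject repeatability: for each subject the standard deviation of
#' the sessions divided by the absolute subject mean, averaged over subjects
#' and expressed in percent. The confidence interval is a subject-level
#' percentile bootstrap.
#'
#' @param mat Subjects-by-sessions matrix.
#' @param conf_level Confidence level (default 0.95).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap.
#' @return List with `cv` (percent), `ci` (percent), `per_subject`.
#' @export
cv_percent <- function(mat, conf_level = 0.95, n_boot = 2000, seed = 1L) {
    mat <- as.matrix(mat)
    means <- rowMeans(mat)
    if (any(means == 0)) stopf("subject mean of exactly 0: CV undefined")
    per <- apply(mat, 1, sd) / abs(means) * 100
    set_seed_if(seed)
    n <- nrow(mat)
    boots <- replicate(n_boot, mean(per[sample.int(n, n, replace = TRUE)]))
    alpha <- 1 - conf_level
    list(cv = mean(per),
         ci = unname(quantile(boots, c(alpha / 2, 1 - alpha / 2))),
         per_subject = per)
}

#' One-way repeated-measures ANOVA over sessions
#'
#' Tests a session effect on a subjects-by-sessions matrix with the standard
#' within-subject decomposition (`F = MS_session / MS_error` where the error
#' is the subject-by-session interaction), reports all pairwise session
#' comparisons with Bonferroni-adjusted paired t-tests, and orthogonal
#' polynomial contrasts (linear, quadratic, ... up to `k - 1`) evaluated as
#' one-sample t-tests on the per-subject contrast scores.
#'
#' @param mat Subjects-by-sessions matrix.
#' @return List with `f`, `df`, `p`, `pairwise` (data.frame with raw and
#'   Bonferroni p), `contrasts` (data.frame per polynomial order).
#' @export
rm_anova <- function(mat) {
    mat <- as.matrix(mat)
    n <- nrow(mat); k <- ncol(mat)
    if (k < 2) stopf("need >= 2 sessions")
    grand <- mean(mat)
    row_m <- rowMeans(mat); col_m <- colMeans(mat)
    ss_s <- n * sum((col_m - grand)^2)
    ss_e <- sum((mat - outer(row_m, rep(1, k)) -
                     outer(rep(1, n), col_m) + grand)^2)
    df1 <- k - 1; df2 <- (n - 1) * (k - 1)
    f <- (ss_s / df1) / (ss_e / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
    pairs <- t(utils::combn(k, 2))
    pw <- data.frame(a = pairs[, 1], b = pairs[, 2])
    pw$p_raw <- apply(pairs, 1, function(ij)
        t.test(mat[, ij[1]], mat[, ij[2]], paired = TRUE)$p.value)
    pw$p_bonferroni <- pmin(1, pw$p_raw * nrow(pw))
    cm <- contr.poly(k)
    labels <- c("linear", "quadratic", "cubic", "quartic",
                paste0("order", 5:max(5, k - 1)))[seq_len(k - 1)]
    ctr <- do.call(rbind, lapply(seq_len(k - 1), function(j) {
        scores <- as.vector(mat %*% cm[, j])
        tt <- t.test(scores)
        data.frame(contrast = labels[j], estimate = mean(scores),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
    }))
    list(f = f, df = c(df1, df2), p = p, pairwise = pw, contrasts = ctr)
}

#' Pairwise Pearson correlations between two sets of measures
#'
#' Correlates each column of `x` with each column of `y` by Pearson
#' product-moment correlation.
#'
#' @param x,y Numeric matrices (or data.frames) with matching row counts.
#' @return Data.frame with `x`, `y`, `r`, `p` per column pair.
#' @export
pearson_table <- function(x, y) {
    x <- as.matrix(x); y <- as.matrix(y)
    if (nrow(x) != nrow(y)) stopf("x and y must have the same number of rows")
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))
    out <- expand.grid(x = colnames(x), y = colnames(y),
                       stringsAsFactors = FALSE)
    res <- apply(out, 1, function(row) {
        ct <- cor.test(x[, row[["x"]]], y[, row[["y"]]])
        c(ct$estimate, ct$p.value)
    })
    out$r <- res[1, ]; out$p <- res[2, ]
    out
}
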