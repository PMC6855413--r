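#' Modified Beer-Lambert coefficients
#'
#' Extinction coefficients and differential pathlength factors for the
#' dual-wavelength (760/850 nm) conversion of optical-density changes into
#' oxy- and deoxy-hemoglobin concentration changes. The default values are
#' the instrument constants used throughout the package: absorption
#' coefficients for O2Hb of 1486 (760 nm) and 2526 (850 nm), for HHb of 3843
#' (760 nm) and 1798 (850 nm); DPF 7.25 (760 nm) and 6.38 (850 nm). They are
#' used verbatim as dimensionless defaults, so concentrations come out in
#' arbitrary units.
#'
#' @param extinction 2 x 2 matrix, rows = wavelengths (760, 850), columns =
#'   chromophores (O2Hb, HHb); must be invertible.
#' @param dpf Differential pathlength factor per wavelength.
#' @param distance_mm Source-detector distance in millimetres (default 30).
#' @return Object of class `mbll_coefficients`.
#' @export
mbll_coefficients <- function(extinction = rbind(`760` = c(O2Hb = 1486, HHb = 3843),
                                                 `850` = c(O2Hb = 2526, HHb = 1798)),
                              dpf = c(`760` = 7.25, `850` = 6.38),
                              distance_mm = 30) {
    extinction <- as.matrix(extinction)
    if (!all(dim(extinction) == c(2, 2))) stopf("extinction must be 2 x 2")
    if (abs(det(extinction)) < .Machine$double.eps * 100)
        stopf("extinction matrix is singular")
    structure(list(extinction = extinction, dpf = as.numeric(dpf),
                   distance_mm = distance_mm),
              class = "mbll_coefficients")
}

# System matrix A such that delta_OD = A %*% c(dO2Hb, dHHb)
mbll_matrix <- function(coef) {
    coef$extinction * (coef$dpf * coef$distance_mm)
}

#' Optical-density time series container
#'
#' @param delta_od Array `time x channel x wavelength` (wavelength order
#'   760, 850) of optical-density changes, or a `time x 2` matrix for a
#'   single channel.
#' @param sampling_rate Sampling rate in Hz.
#' @return Object of class `optical_series`.
#' @export
optical_series <- function(delta_od, sampling_rate) {
    if (is.matrix(delta_od))
        delta_od <- array(delta_od, dim = c(nrow(delta_od), 1, ncol(delta_od)))
    if (length(dim(delta_od)) != 3 || dim(delta_od)[3] < 2)
        stopf("delta_od must be time x channel x (>= 2 wavelengths)")
    if (any(!is.finite(delta_od))) stopf("non-finite optical densities")
    structure(list(delta_od = delta_od, sampling_rate = sampling_rate),
              class = "optical_series")
}

#' Convert optical densities to hemoglobin concentration changes
#'
#' Solves, per sample and channel, the modified Beer-Lambert system
#' `delta_OD(lambda) = epsilon(lambda, chrom) * delta_c * d * DPF(lambda)`
#' for the two chromophores, and returns oxy-, deoxy- and total hemoglobin
#' changes (`delta_thb = delta_o2hb + delta_hhb`, in arbitrary concentration
#' units).
#'
#' @param od An [optical_series()].
#' @param coef [mbll_coefficients()].
#' @return Object of class `hemo_series` with matrices `delta_o2hb`,
#'   `delta_hhb`, `delta_thb` (`time x channel`) and `sampling_rate`.
#' @export
#' @examples
#' od <- optical_series(matrix(0, 10, 2), sampling_rate = 10)
#' range(mbll_convert(od, mbll_coefficients())$delta_thb)
mbll_convert <- function(od, coef = mbll_coefficients()) {
    stopifnot(inherits(od, "optical_series"))
    A_inv <- solve(mbll_matrix(coef))
    d <- dim(od$delta_od)
    o2hb <- hhb <- matrix(NA_real_, d[1], d[2])
    for (ch in seq_len(d[2])) {
        conc <- od$delta_od[, ch, 1:2, drop = FALSE]
        conc <- matrix(conc, d[1], 2) %*% t(A_inv)
        o2hb[, ch] <- conc[, 1]
        hhb[, ch] <- conc[, 2]
    }
    structure(list(delta_o2hb = o2hb, delta_hhb = hhb,
                   delta_thb = o2hb + hhb,
                   sampling_rate = od$sampling_rate),
              class = "hemo_series")
}

#' Preprocess a hemodynamic (or optical) time series
#'
#' Baseline-corrects (first-sample subtraction), linearly detrends, and
#' band-pass filters (zero-phase 3rd-order Butterworth via forward-backward
#' filtering) every channel.
#'
#' @param x A `hemo_series`, or a numeric matrix `time x channel`.
#' @param sampling_rate Required when `x` is a plain matrix.
#' @param detrend Remove a linear trend per channel (default TRUE).
#' @param band Band-pass edges in Hz, `c(lo, hi)`, inside `(0, Nyquist)`;
#'   default `c(0.01, 0.2)`. `NULL` skips filtering.
#' @return Same type as the input, processed.
#' @export
preprocess <- function(x, sampling_rate = NULL, detrend = TRUE,
                       band = c(0.01, 0.2)) {
    if (inherits(x, "hemo_series")) {
        fs <- x$sampling_rate
        for (f in c("delta_o2hb", "delta_hhb"))
            x[[f]] <- preprocess_matrix(x[[f]], fs, detrend, band)
        x$delta_thb <- x$delta_o2hb + x$delta_hhb
        return(x)
    }
    if (is.null(sampling_rate)) stopf("sampling_rate required for matrix input")
    preprocess_matrix(as.matrix(x), sampling_rate, detrend, band)
}

preprocess_matrix <- function(m, fs, detrend, band) {
    nyq <- fs / 2
    if (!is.null(band)) {
        if (band[1] <= 0 || band[2] >= nyq || band[1] >= band[2])
            stopf("band edges must satisfy 0 < lo < hi < Nyquist (%g Hz)", nyq)
        bf <- signal::butter(3, band / nyq, type = "pass")
    }
    t_idx <- seq_len(nrow(m))
    apply(m, 2, function(y) {
        y <- y - y[1]
        if (detrend) y <- stats::residuals(lm(y ~ t_idx))
        if (!is.null(band)) y <- signal::filtfilt(bf, y)
        y
    })
}

#' Canonical NIRS hemodynamic response function
#'
#' Double-gamma impulse response with a configurable peak (default 5 s) and
#' a late undershoot, normalized to unit peak amplitude.
#'
#' @param duration_s Length of the kernel in seconds (default 30).
#' @param sampling_rate Hz.
#' @param peak_s Time-to-peak in seconds (default 5).
#' @param undershoot_ratio Relative amplitude of the undershoot (default
#'   1/6).
#' @return Numeric vector of kernel samples.
#' @export
nirs_hrf <- function(duration_s = 30, sampling_rate = 10, peak_s = 5,
                     undershoot_ratio = 1 / 6) {
    t <- seq(0, duration_s, by = 1 / sampling_rate)
    shape1 <- 6
    rate1 <- (shape1 - 1) / peak_s
    shape2 <- 16
    rate2 <- (shape2 - 1) / (peak_s * 3)
    h <- stats::dgamma(t, shape1, rate1) -
        undershoot_ratio * stats::dgamma(t, shape2, rate2)
    h / max(h)
}

#' Trial-wise GLM amplitudes
#'
#' Estimates one amplitude per trial and channel by least squares: the design
#' matrix holds one regressor per trial (a stick function at the choice
#' onset convolved with the hemodynamic response function) plus polynomial
#' drift terms.
#'
#' @param y Signal matrix `time x channel` (e.g. `delta_thb`), or a
#'   `hemo_series` (its `delta_thb` is used).
#' @param onsets_s Trial onset times in seconds.
#' @param sampling_rate Hz (taken from a `hemo_series` input).
#' @param hrf Kernel vector (default [nirs_hrf()] at the data's sampling
#'   rate).
#' @param drift_order Polynomial drift order (default 1: intercept +
#'   linear).
#' @return Matrix `n_trials x n_channels` of amplitude estimates.
#' @export
glm_trial_amplitudes <- function(y, onsets_s, sampling_rate = NULL,
                                 hrf = NULL, drift_order = 1) {
    if (inherits(y, "hemo_series")) {
        sampling_rate <- y$sampling_rate
        y <- y$delta_thb
    }
    if (is.null(sampling_rate)) stopf("sampling_rate required")
    y <- as.matrix(y)
    n <- nrow(y)
    if (any(onsets_s < 0 | onsets_s > (n - 1) / sampling_rate))
        stopf("onsets outside the recording")
    if (is.null(hrf)) hrf <- nirs_hrf(sampling_rate = sampling_rate)
    X <- sapply(onsets_s, function(on) {
        stick <- numeric(n)
        stick[round(on * sampling_rate) + 1] <- 1
        conv <- stats::convolve(stick, rev(hrf), type = "open")[seq_len(n)]
        conv
    })
    t_norm <- seq_len(n) / n
    drift <- sapply(0:drift_order, function(k) t_norm^k)
    X <- cbind(X, drift)
    if (qr(X)$rank < ncol(X))
        stopf(paste("rank-deficient trial design: onsets are too dense for",
                    "the HRF; increase inter-trial spacing"))
    beta <- qr.solve(X, y)
    beta[seq_along(onsets_s), , drop = FALSE]
}

#' Synthesize an optical-density recording
#'
#' Forward model used for end-to-end testing: builds an oxy-hemoglobin
#' concentration series by convolving per-trial amplitudes with the HRF
#' (deoxy-hemoglobin is a scaled negative copy), converts it to
#' optical densities with the modified Beer-Lambert forward model, and adds
#' physiological sinusoids plus white noise.
#'
#' @param amplitudes Numeric vector, one amplitude per trial, or a matrix
#'   `n_trials x n_channels`.
#' @param onsets_s Trial onsets in seconds.
#' @param duration_s Recording length (default: last onset + 30 s).
#' @param sampling_rate Hz (default 10).
#' @param coef [mbll_coefficients()].
#' @param noise_sd White-noise SD on the optical densities (default 1e-4).
#' @param physio_amp Amplitude of the physiological oscillations (default
#'   1e-4); Mayer-wave (0.1 Hz) and cardiac-band components.
#' @param hhb_ratio Deoxy amplitude as a negative fraction of oxy (default
#'   0.4).
#' @param seed Seed.
#' @return An [optical_series()]; the true concentration series is attached
#'   as attributes `truth_o2hb` and `truth_hhb`.
#' @export
synth_nirs <- function(amplitudes, onsets_s, duration_s = NULL,
                       sampling_rate = 10, coef = mbll_coefficients(),
                       noise_sd = 1e-4, physio_amp = 1e-4, hhb_ratio = 0.4,
                       seed = NULL) {
    set_seed_if(seed)
    amplitudes <- as.matrix(amplitudes)
    n_ch <- ncol(amplitudes)
    if (is.null(duration_s)) duration_s <- max(onsets_s) + 30
    n <- round(duration_s * sampling_rate)
    hrf <- nirs_hrf(sampling_rate = sampling_rate)
    o2hb <- matrix(0, n, n_ch)
    for (ch in seq_len(n_ch)) {
        stick <- numeric(n)
        idx <- round(onsets_s * sampling_rate) + 1
        stick[idx] <- amplitudes[, ch]
        o2hb[, ch] <- stats::convolve(stick, rev(hrf), type = "open")[seq_len(n)]
    }
    hhb <- -hhb_ratio * o2hb
    A <- mbll_matrix(coef)
    tt <- seq_len(n) / sampling_rate
    od <- array(NA_real_, dim = c(n, n_ch, 2))
    for (ch in seq_len(n_ch)) {
        clean <- cbind(o2hb[, ch], hhb[, ch]) %*% t(A)
        for (w in 1:2) {
            physio <- physio_amp * (sin(2 * pi * 0.1 * tt + w) +
                                        0.5 * sin(2 * pi * 1.1 * tt))
            od[, ch, w] <- clean[, w] + physio + rnorm(n, 0, noise_sd)
        }
    }
    out <- optical_series(od, sampling_rate)
    attr(out, "truth_o2hb") <- o2hb
    attr(out, "truth_hhb") <- hhb
    out
}
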