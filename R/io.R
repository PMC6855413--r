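#' Read and write trial tables
#'
#' Trial data are exchanged as UTF-8 CSV with header
#' `subject,session,trial,choice1,state2,choice2,transition,reward,rt1,rt2,missed`.
#' Missed trials keep empty choice fields; the round trip through
#' `write_trials()`/`read_trials()` is lossless.
#'
#' @param path File path.
#' @return `read_trials()` returns the validated trial data.frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                   na.strings = c("NA", ""))
    need <- c("subject", "session", "trial", "choice1", "state2", "choice2",
              "transition", "reward", "rt1", "rt2", "missed")
    miss <- setdiff(need, names(df))
    if (length(miss)) stopf("trial file lacks required column(s): %s",
                            paste(miss, collapse = ", "))
    if (nrow(df) == 0) {
        warnf("trial file '%s' contains a header but no rows", path)
        df$missed <- as.logical(df$missed)
        return(df[need])
    }
    df$missed <- as.logical(df$missed)
    for (col in c("choice1", "state2", "choice2", "reward", "trial", "session"))
        df[[col]] <- as.integer(df[[col]])
    for (col in c("rt1", "rt2")) df[[col]] <- as.numeric(df[[col]])
    df$transition <- as.character(df$transition)
    validate_trials(df)
    df[need]
}

#' @rdname read_trials
#' @param trials Trial data.frame (e.g. `simulate_cohort(...)$trials`).
#' @export
write_trials <- function(trials, path) {
    validate_trials(trials)
    write.csv(trials, path, row.names = FALSE, fileEncoding = "UTF-8",
              na = "")
    invisible(path)
}

validate_trials <- function(df) {
    check <- function(ok, what) {
        bad <- which(!ok)
        if (length(bad)) stopf("invalid trial data: %s (first offending row: %d)",
                               what, bad[1])
    }
    v <- !df$missed
    check(!is.na(df$missed), "missed flag must be TRUE/FALSE")
    check(!v | df$choice1 %in% c(0, 1), "choice1 must be 0 or 1 on valid trials")
    check(!v | df$state2 %in% c(0, 1), "state2 must be 0 or 1 on valid trials")
    check(!v | df$choice2 %in% c(0, 1), "choice2 must be 0 or 1 on valid trials")
    check(!v | df$reward %in% c(0, 1), "reward must be 0 or 1 on valid trials")
    check(!v | df$transition %in% c("common", "uncommon"),
          "transition must be 'common' or 'uncommon' on valid trials")
    invisible(df)
}

# Split a cohort-level trial table into per-unit tables (subject x session),
# in a stable order.
split_units <- function(trials) {
    key <- interaction(trials$subject, trials$session, drop = TRUE, sep = ":")
    split(trials, key)
}
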