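# Internal helpers shared across modules.

logistic <- function(x) 1 / (1 + exp(-x))

logit <- function(p) log(p / (1 - p))

softmax <- function(x) {
    e <- exp(x - max(x))
    e / sum(e)
}

log_sum_exp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

#' @noRd
set_seed_if <- function(seed) {
    if (!is.null(seed)) set.seed(seed)
    invisible(NULL)
}

# Deterministic per-unit stream seed, keyed by unit identity (not position)
# so that permuting the unit table leaves each unit's data unchanged.
unit_seed <- function(master, subject, session) {
    key <- sum(utf8ToInt(paste0(as.character(subject), "#", as.character(session))) *
                   seq_len(nchar(paste0(subject, "#", session))))
    as.integer((as.numeric(master) * 48271 + key * 16807) %% 2147483647) + 1L
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)
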