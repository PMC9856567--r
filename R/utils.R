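## Internal helpers: curve validation and deterministic rounding.

## Validate a penetrance curve: numeric(85), values in [0,1], lifetime sum <= 1.
## `what` names the curve in error messages. Returns the curve invisibly.
checkAcp <- function(x, what = "penetrance curve", sumTol = 1e-9) {
    if (!is.numeric(x) || length(x) != MAX_AGE)
        stop(what, " must be a numeric vector of length ", MAX_AGE,
             " (ages 1..", MAX_AGE, ")", call. = FALSE)
    if (anyNA(x))
        stop(what, " contains missing values", call. = FALSE)
    if (any(x < 0) || any(x > 1))
        stop(what, " has probabilities outside [0, 1]", call. = FALSE)
    s <- sum(x)
    if (s > 1 + sumTol)
        stop(what, " has lifetime probability mass ", format(s),
             " exceeding 1", call. = FALSE)
    invisible(x)
}

## Validate a discrete hazard curve: numeric(85) in [0,1].
checkHazard <- function(x, what = "hazard curve") {
    if (!is.numeric(x) || length(x) != MAX_AGE)
        stop(what, " must be a numeric vector of length ", MAX_AGE,
             call. = FALSE)
    if (anyNA(x) || any(x < 0) || any(x > 1))
        stop(what, " has hazards outside [0, 1]", call. = FALSE)
    invisible(x)
}

## Round-half-up to `digits` decimal places. R's round() is round-half-even;
## displays use the conventional half-up rule (0.5 -> 1).
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

## Round a probability to the nearest whole percent, half up.
toPercent <- function(p) roundHalfUp(100 * p)

## Scalar type checks used by constructors.
assertScalar <- function(x, what, kind = c("numeric", "character", "logical")) {
    kind <- match.arg(kind)
    ok <- switch(kind,
                 numeric = is.numeric(x) && length(x) == 1L && !is.na(x),
                 character = is.character(x) && length(x) == 1L && !is.na(x),
                 logical = is.logical(x) && length(x) == 1L && !is.na(x))
    if (!ok)
        stop(what, " must be a single non-missing ", kind, " value",
             call. = FALSE)
    invisible(x)
}

assertEnum <- function(x, levels, what) {
    assertScalar(x, what, "character")
    if (!x %in% levels)
        stop(what, " must be one of: ", paste(levels, collapse = ", "),
             " (got '", x, "')", call. = FALSE)
    invisible(x)
}

## Format a stratum key for error messages.
formatStratum <- function(cancer, gene, sex, race, ethnicity) {
    paste0("(cancer=", cancer, ", gene=", gene, ", sex=", sex,
           ", race=", race, ", ethnicity=", ethnicity, ")")
}
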