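## Measure-conversion and discrete-hazard arithmetic. All functions are pure
## transformations over plain numeric(85) curves.

#' Apply a relative risk to a penetrance curve
#'
#' Multiplies every age-specific onset probability by \code{rr}. This is the
#' direct penetrance modification for interventions reported as relative
#' risks.
#'
#' @param curve Numeric vector of 85 onset probabilities.
#' @param rr Relative risk, nonnegative.
#' @return Modified curve.
#' @examples
#' curve <- numeric(85); curve[50] <- 0.02
#' applyRR(curve, 0.44)[50]   # 0.0088
#' @export
applyRR <- function(curve, rr) {
    checkAcp(curve)
    assertScalar(rr, "rr", "numeric")
    if (rr < 0) stop("rr must be nonnegative", call. = FALSE)
    out <- curve * rr
    if (any(out > 1))
        stop("relative risk drives a probability above 1; inputs are ",
             "inconsistent", call. = FALSE)
    checkAcp(out, "post-intervention curve")
    out
}

#' Convert an odds ratio to a relative risk at a baseline probability
#'
#' \code{OR / ((1 - p0) + OR * p0)}: the standard conversion of an odds
#' ratio to a relative risk given the baseline outcome probability
#' \code{p0}. Converges to the OR as \code{p0 -> 0} and preserves the
#' direction of effect.
#'
#' @param orValue Odds ratio, positive.
#' @param p0 Baseline onset probability at the age in question, in [0, 1).
#' @return Relative risk.
#' @examples
#' orToRR(1.2, 0.05)   # 1.18812...
#' @export
orToRR <- function(orValue, p0) {
    if (any(orValue <= 0)) stop("odds ratio must be positive", call. = FALSE)
    if (any(p0 < 0) || any(p0 >= 1))
        stop("baseline probability must lie in [0, 1)", call. = FALSE)
    orValue / ((1 - p0) + orValue * p0)
}

#' Continuous-exposure effect size
#'
#' Compounds a per-step odds or hazard ratio over a (possibly fractional)
#' exposure change: \code{(1 + sigma * perStep)^delta}, where \code{sigma}
#' is +1 when the change increases risk and -1 when it decreases risk, and
#' \code{delta} is the magnitude of the change in step units (BMI points,
#' or 5-kg weight steps). Note the deliberate asymmetry of the model as
#' published: a gain followed by an equal loss does not return the measure
#' to 1 (\code{(1 + v)^d * (1 - v)^d != 1}).
#'
#' @param sigma Direction, +1 or -1.
#' @param delta Magnitude of the exposure change in step units,
#'   nonnegative, possibly fractional.
#' @param perStep Per-step effect size (e.g. 0.07 per BMI point, 0.20 per
#'   5 kg), greater than -1.
#' @return The compounded ratio; 1 when \code{delta} is 0.
#' @examples
#' continuousEffect(+1, 1, 0.20)   # 1.20
#' continuousEffect(-1, 2, 0.07)   # 0.93^2 = 0.8649
#' @export
continuousEffect <- function(sigma, delta, perStep) {
    if (!sigma %in% c(-1, 1)) stop("sigma must be +1 or -1", call. = FALSE)
    assertScalar(delta, "delta", "numeric")
    if (delta < 0) stop("delta must be nonnegative", call. = FALSE)
    assertScalar(perStep, "perStep", "numeric")
    base <- 1 + sigma * perStep
    if (base <= 0)
        stop("per-step ratio 1 + sigma * perStep must be positive",
             call. = FALSE)
    base^delta
}

#' Convert a penetrance curve to discrete hazards
#'
#' The discrete hazard at age a is the onset probability at a divided by
#' the probability of being onset-free entering a:
#' \code{lambda(a) = ACP(a) / (1 - sum(ACP(1..a-1)))}. This is the working
#' scale on which hazard ratios act.
#'
#' @param curve Numeric vector of 85 onset probabilities.
#' @return Numeric vector of 85 hazards, each in [0, 1].
#' @seealso \code{\link{hazardToAcp}}, the exact inverse.
#' @export
acpToHazard <- function(curve) {
    checkAcp(curve)
    atRisk <- 1 - c(0, cumsum(curve)[-MAX_AGE])
    lam <- numeric(MAX_AGE)
    pos <- curve > 0
    if (any(pos & atRisk <= 0))
        stop("onset probability with no surviving mass: cumulative ",
             "penetrance reaches 1 before a nonzero ACP", call. = FALSE)
    lam[pos] <- curve[pos] / atRisk[pos]
    ## guard against floating-point overshoot at exhaustion
    lam <- pmin(lam, 1)
    checkHazard(lam)
    lam
}

#' Convert discrete hazards back to a penetrance curve
#'
#' Exact algebraic inverse of \code{\link{acpToHazard}}, computed by
#' forward recursion in age:
#' \code{ACP(a) = lambda(a) * (1 - sum(ACP(1..a-1)))}. The lifetime sum of
#' the result never exceeds 1, and
#' \code{hazardToAcp(acpToHazard(curve))} reproduces \code{curve}.
#'
#' @param hazards Numeric vector of 85 hazards in [0, 1].
#' @return Numeric vector of 85 onset probabilities.
#' @export
hazardToAcp <- function(hazards) {
    checkHazard(hazards)
    ## ACP(a) = lambda(a) * prod_{t<a} (1 - lambda(t))
    surv <- cumprod(1 - hazards)
    acp <- hazards * c(1, surv[-MAX_AGE])
    checkAcp(acp, "reconstructed curve")
    acp
}

#' Evaluate a time-varying hazard-ratio schedule
#'
#' Piecewise-linear interpolation through the schedule knots
#' (years-since-initiation, measure), anchored at an implicit (0, 1.0)
#' no-effect point at initiation, and held constant at the last knot's
#' value beyond the final follow-up time.
#'
#' @param schedule Two-column matrix of strictly increasing knot times and
#'   positive measures, or a list of (time, measure) pairs.
#' @param t Years since initiation, nonnegative (vectorized).
#' @return Interpolated measure value(s).
#' @examples
#' asp <- rbind(c(2, 0.56), c(5, 0.63), c(10, 0.65))
#' evalHrSchedule(asp, c(2, 3.5, 15))   # 0.560 0.595 0.650
#' @export
evalHrSchedule <- function(schedule, t) {
    if (is.list(schedule))
        schedule <- matrix(unlist(schedule), ncol = 2L, byrow = TRUE)
    if (!is.matrix(schedule) || ncol(schedule) != 2L || nrow(schedule) == 0L)
        stop("schedule must be a non-empty two-column (time, measure) matrix",
             call. = FALSE)
    if (any(diff(schedule[, 1L]) <= 0))
        stop("schedule knot times must be strictly increasing", call. = FALSE)
    if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
    knotsT <- c(0, schedule[, 1L])
    knotsV <- c(1, schedule[, 2L])
    stats::approx(knotsT, knotsV, xout = pmin(t, max(knotsT)),
                  method = "linear", rule = 2)$y
}

#' Apply a hazard-ratio schedule to a penetrance curve
#'
#' Converts the curve to discrete hazards, multiplies the hazard at each
#' age \code{a >= startAge} by the schedule evaluated at
#' \code{a - startAge} years since initiation (ages before \code{startAge}
#' are untouched), clamps hazards at 1, and converts back to penetrances.
#' A constant schedule of 1 is the identity; on a curve with a single
#' nonzero age at \code{startAge} a constant schedule reduces to plain
#' relative-risk multiplication.
#'
#' @param curve Numeric vector of 85 onset probabilities.
#' @param schedule Knot matrix as in \code{\link{evalHrSchedule}}, or a
#'   single constant hazard ratio.
#' @param startAge Age at which the intervention starts, 1..85.
#' @return Modified curve.
#' @export
applyHrSchedule <- function(curve, schedule, startAge = 1L) {
    checkAcp(curve)
    if (is.numeric(schedule) && !is.matrix(schedule) &&
        length(schedule) == 1L) {
        ## constant hazard ratio as a degenerate one-knot schedule
        schedule <- matrix(c(1, schedule), ncol = 2L)
        ## constant from t = 0: override the (0,1) anchor by evaluating the
        ## flat schedule directly
        hrAt <- function(tt) rep(schedule[1L, 2L], length(tt))
    } else {
        hrAt <- function(tt) evalHrSchedule(schedule, tt)
    }
    assertScalar(startAge, "startAge", "numeric")
    if (startAge < 1 || startAge > MAX_AGE)
        stop("startAge must lie in 1..", MAX_AGE, call. = FALSE)
    lam <- acpToHazard(curve)
    idx <- AGE_GRID >= startAge
    lam[idx] <- pmin(lam[idx] * hrAt(AGE_GRID[idx] - startAge), 1)
    hazardToAcp(lam)
}

#' Apply a constant hazard ratio to a penetrance curve
#'
#' Convenience wrapper: hazard conversion, constant multiplication at every
#' age, back-conversion.
#'
#' @param curve Numeric vector of 85 onset probabilities.
#' @param hr Constant hazard ratio, positive.
#' @return Modified curve.
#' @export
applyConstantHR <- function(curve, hr) {
    assertScalar(hr, "hr", "numeric")
    if (hr <= 0) stop("hr must be positive", call. = FALSE)
    applyHrSchedule(curve, hr, startAge = 1L)
}

#' Apply an odds ratio to a penetrance curve age by age
#'
#' Converts the odds ratio to an age-specific relative risk against each
#' age's baseline onset probability, then multiplies.
#'
#' @param curve Numeric vector of 85 onset probabilities.
#' @param orValue Odds ratio, positive.
#' @return Modified curve.
#' @export
applyOR <- function(curve, orValue) {
    checkAcp(curve)
    rr <- orToRR(orValue, curve)
    out <- curve * rr
    checkAcp(out, "post-intervention curve")
    out
}
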