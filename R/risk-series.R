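## Future-risk evaluation (survival conditioning) and the RiskSeries type.

#' Survival probability at the current age
#'
#' Probability of being free of the cancer through age \code{aCur}:
#' \code{1 - sum(ACP(1..aCur))}.
#'
#' @param curve Numeric vector of 85 onset probabilities.
#' @param aCur Current age, 0..85 (0 gives 1: no mass spent).
#' @return Probability in (0, 1].
#' @export
survivalAt <- function(curve, aCur) {
    checkAcp(curve)
    assertScalar(aCur, "aCur", "numeric")
    if (aCur < 0 || aCur > MAX_AGE)
        stop("aCur must lie in 0..", MAX_AGE, call. = FALSE)
    s <- 1 - if (aCur == 0) 0 else sum(curve[seq_len(aCur)])
    if (s <= 0)
        stop("no surviving probability mass at age ", aCur,
             " (cumulative penetrance has reached 1)", call. = FALSE)
    s
}

#' Future risk over a half-open age interval
#'
#' The probability of first onset in \code{(aCur, aFut]} conditional on
#' being cancer-free at \code{aCur}:
#' \code{sum(ACP(aCur+1..aFut)) / survivalAt(curve, aCur)}.
#'
#' @param curve Numeric vector of 85 onset probabilities.
#' @param aCur Current age.
#' @param aFut Future horizon age, \code{aCur <= aFut <= 85}.
#' @return Conditional probability; 0 when \code{aFut == aCur}.
#' @examples
#' curve <- numeric(85); curve[1:3] <- 0.1
#' futureRisk(curve, 1, 3)   # 0.2 / 0.9
#' @export
futureRisk <- function(curve, aCur, aFut) {
    assertScalar(aFut, "aFut", "numeric")
    if (aFut < aCur || aFut > MAX_AGE)
        stop("aFut must lie in aCur..", MAX_AGE, call. = FALSE)
    s <- survivalAt(curve, aCur)
    if (aFut == aCur) return(0)
    sum(curve[(aCur + 1):aFut]) / s
}

#' Build a RiskSeries from a penetrance curve
#'
#' Evaluates \code{\link{futureRisk}} at every horizon from the current
#' age (value 0) through 85.
#'
#' @param curve Numeric vector of 85 onset probabilities.
#' @param aCur Current age, 1..84.
#' @param cancer Cancer type label.
#' @param variant Series label: "baseline", "general", an intervention id,
#'   or "composed".
#' @return A \code{\linkS4class{RiskSeries}}.
#' @export
makeRiskSeries <- function(curve, aCur, cancer, variant = "baseline") {
    checkAcp(curve)
    s <- survivalAt(curve, aCur)
    horizons <- as.integer(aCur:MAX_AGE)
    cum <- unname(c(0, cumsum(curve[(aCur + 1):MAX_AGE]) / s))
    obj <- new("RiskSeries", cancer = cancer, variant = variant,
               horizonAges = horizons, cumulative = cum)
    validObject(obj)
    obj
}

#' @rdname riskAt
#' @export
setMethod("riskAt", "RiskSeries", function(x, age) {
    age <- min(age, MAX_AGE)
    i <- match(as.integer(age), x@horizonAges)
    if (is.na(i))
        stop("horizon age ", age, " outside the series support ",
             x@horizonAges[1L], "..", MAX_AGE, call. = FALSE)
    x@cumulative[i]
})

#' @rdname lifetimeRisk
#' @export
setMethod("lifetimeRisk", "RiskSeries",
          function(x) x@cumulative[length(x@cumulative)])

setMethod("show", "RiskSeries", function(object) {
    cat("RiskSeries (", object@cancer, ", ", object@variant, "): ",
        "ages ", object@horizonAges[1L], "..", MAX_AGE,
        ", lifetime risk ", sprintf("%.4f", lifetimeRisk(object)), "\n",
        sep = "")
    invisible(NULL)
})

#' Compose single-intervention series additively
#'
#' Joint effect of simultaneous interventions under the additivity
#' assumption: at each horizon the reductions achieved by each single
#' intervention relative to baseline are summed and subtracted from the
#' baseline, floored at zero. With no singles the baseline is returned;
#' with one, that single's series. A surgery (zero) series drives the
#' composition to zero.
#'
#' @param baseline Baseline \code{\linkS4class{RiskSeries}}.
#' @param singles List of single-intervention \code{RiskSeries} sharing
#'   the baseline's cancer and horizons.
#' @return Composed \code{\linkS4class{RiskSeries}} (variant
#'   \code{"composed"}), pointwise at most the baseline.
#' @export
composeSeries <- function(baseline, singles = list()) {
    stopifnot(is(baseline, "RiskSeries"))
    if (!length(singles)) {
        out <- baseline
        out@variant <- "composed"
        return(out)
    }
    red <- numeric(length(baseline@cumulative))
    for (s in singles) {
        stopifnot(is(s, "RiskSeries"))
        if (s@cancer != baseline@cancer ||
            !identical(s@horizonAges, baseline@horizonAges))
            stop("single-intervention series must share the baseline's ",
                 "cancer and horizons", call. = FALSE)
        red <- red + (baseline@cumulative - s@cumulative)
    }
    cum <- pmax(0, baseline@cumulative - red)
    ## additive over-subtraction can break monotonicity at the floor;
    ## restore it by running max (values remain <= baseline, >= 0)
    cum <- cummax(cum)
    obj <- new("RiskSeries", cancer = baseline@cancer, variant = "composed",
               horizonAges = baseline@horizonAges, cumulative = cum)
    validObject(obj)
    obj
}

#' Lifetime risk relative to the general population
#'
#' Ratio of the user's cumulative risk by age 85 to the matched
#' general-population value. A zero general-population lifetime risk makes
#' the ratio undefined: the value is \code{NA} with attribute
#' \code{undefined = TRUE}, never infinite.
#'
#' @param user User \code{\linkS4class{RiskSeries}}.
#' @param general Matched general-population \code{RiskSeries}.
#' @return Ratio (numeric scalar), or \code{NA} flagged undefined.
#' @export
relativeLifetimeRisk <- function(user, general) {
    stopifnot(is(user, "RiskSeries"), is(general, "RiskSeries"))
    g <- lifetimeRisk(general)
    if (g == 0)
        return(structure(NA_real_, undefined = TRUE))
    lifetimeRisk(user) / g
}
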