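## Baseline adjustment: screening-mixture deconvolution, lifetime capping,
## BMI personalization, and stratification from relative measures.

#' Deconvolve a screening-contaminated penetrance curve
#'
#' Literature colorectal baselines were estimated on cohorts mixing
#' screened and unscreened subjects. Writing the mixed curve as
#' \code{(1 - p) * unscreened + p * screened} with
#' \code{screened = rr * unscreened}, the unscreened curve is recovered
#' elementwise as \code{mixed / ((1 - p) + p * rr)}. Re-mixing the result
#' reproduces the input exactly.
#'
#' The output is an intermediate: its lifetime sum may exceed 1 when the
#' mixed curve's mass is large and \code{rr < 1}; in the colorectal
#' pipeline it is always followed by \code{\link{capLifetime}}.
#'
#' @param mixed Numeric vector of 85 onset probabilities (mixed cohort).
#' @param p Proportion of the cohort that adhered to screening, in [0, 1].
#' @param rr Screening relative risk, positive.
#' @return The unscreened curve (values in [0, 1]; sum unconstrained).
#' @seealso \code{\link{mixScreened}} for the forward direction.
#' @examples
#' m <- numeric(85); m[60] <- 0.01
#' deconvolveMixture(m, 0.818, 0.44)[60]   # 0.0184529...
#' @export
deconvolveMixture <- function(mixed, p, rr) {
    checkAcp(mixed, "mixed curve")
    assertScalar(p, "p", "numeric")
    assertScalar(rr, "rr", "numeric")
    if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
    if (rr <= 0) stop("rr must be positive", call. = FALSE)
    denom <- (1 - p) + p * rr
    if (denom <= 0) stop("mixture denominator is not positive", call. = FALSE)
    out <- mixed / denom
    if (any(out > 1))
        stop("deconvolved probability exceeds 1 at some age; mixed curve ",
             "and screening parameters are inconsistent", call. = FALSE)
    out
}

#' Re-mix screened and unscreened curves
#'
#' Forward mixture: \code{(1 - p) * unscreened + p * rr * unscreened}.
#' Exact inverse of \code{\link{deconvolveMixture}}.
#'
#' @param unscreened Numeric vector of 85 onset probabilities.
#' @param p Screened proportion in [0, 1].
#' @param rr Screening relative risk, positive.
#' @return The mixed-cohort curve.
#' @export
mixScreened <- function(unscreened, p, rr) {
    unscreened * ((1 - p) + p * rr)
}

#' Cap the lifetime risk of a penetrance curve
#'
#' If the curve's lifetime sum exceeds \code{cap}, every age's probability
#' is scaled by \code{cap / sum} so the lifetime sum equals the cap
#' exactly (a shape-preserving proportional rescale); otherwise the curve
#' is returned unchanged.
#'
#' @param curve Numeric vector of 85 onset probabilities (sum may exceed 1
#'   for deconvolved intermediates).
#' @param cap Lifetime cap in (0, 1], default 0.90.
#' @return Curve with lifetime sum \code{min(sum(curve), cap)}.
#' @export
capLifetime <- function(curve, cap = 0.90) {
    assertScalar(cap, "cap", "numeric")
    if (cap <= 0 || cap > 1) stop("cap must lie in (0, 1]", call. = FALSE)
    if (!is.numeric(curve) || length(curve) != MAX_AGE || any(curve < 0))
        stop("curve must be 85 nonnegative probabilities", call. = FALSE)
    s <- sum(curve)
    if (s <= cap) return(curve)
    curve * (cap / s)
}

#' Personalize a baseline curve by body-mass index
#'
#' Adjusts a sex-averaged baseline to the user's BMI. The user's BMI is
#' first clamped to the [25, 30] band (values below the overweight
#' threshold and above the obesity reference are pulled to the nearest
#' bound so extreme BMIs do not distort the baseline), and the difference
#' from the sex-specific reference mean BMI (27.1 male / 26.0 female) is
#' converted into a constant measure via the continuous-exposure model:
#' \itemize{
#'   \item \code{path = "HR"} (colorectal): HR = \code{(1 +- 0.07)^|dBMI|}
#'     applied on the hazard scale at every age;
#'   \item \code{path = "OR"} (endometrial): the BMI difference is converted
#'     to weight via \code{dKg = dBMI * height^2}, OR =
#'     \code{(1 +- 0.20)^(|dKg|/5)}, converted to an age-specific relative
#'     risk against each age's baseline probability, then multiplied.
#' }
#'
#' @param curve Numeric vector of 85 onset probabilities.
#' @param userBmi The user's raw BMI in kg/m^2.
#' @param sex "male" or "female" (selects the reference mean).
#' @param height Height in meters (needed for the OR path).
#' @param path "HR" or "OR".
#' @param perStep Per-step effect size; defaults to 0.07 (HR path, per BMI
#'   point) or 0.20 (OR path, per 5 kg).
#' @param constants Named list of model constants (reference BMIs and clamp
#'   bounds); defaults to the shipped registry's values.
#' @return The personalized curve; unchanged when the effective BMI equals
#'   the reference mean.
#' @export
personalizeBmi <- function(curve, userBmi, sex, height = NULL,
                           path = c("HR", "OR"), perStep = NULL,
                           constants = NULL) {
    checkAcp(curve)
    path <- match.arg(path)
    assertEnum(sex, SEX_LEVELS, "sex")
    assertScalar(userBmi, "userBmi", "numeric")
    if (userBmi <= 0) stop("userBmi must be positive", call. = FALSE)
    if (is.null(constants))
        constants <- registryConstants(readInterventionRegistry())
    if (is.null(perStep))
        perStep <- if (path == "HR") 0.07 else 0.20
    refBmi <- if (sex == "male") constants$ref_bmi_male
              else constants$ref_bmi_female
    effBmi <- min(max(userBmi, constants$bmi_clamp_low),
                  constants$bmi_clamp_high)
    dBmi <- effBmi - refBmi
    if (dBmi == 0) return(curve)
    sigma <- sign(dBmi)
    if (path == "HR") {
        hr <- continuousEffect(sigma, abs(dBmi), perStep)
        applyConstantHR(curve, hr)
    } else {
        if (is.null(height))
            stop("height is required for the OR path", call. = FALSE)
        assertScalar(height, "height", "numeric")
        if (height <= 0) stop("height must be positive", call. = FALSE)
        dKg <- dBmi * height^2
        orValue <- continuousEffect(sigma, abs(dKg) / 5, perStep)
        applyOR(curve, orValue)
    }
}

#' Derive a carrier stratum from a general-population curve
#'
#' Builds a race/ethnicity-conditioned carrier curve from the matching
#' general-population curve and a published carrier-vs-population relative
#' measure: relative risks multiply directly; odds ratios are converted to
#' age-specific relative risks first; hazard ratios act on the hazard
#' scale.
#'
#' @param general Numeric vector of 85 general-population onset
#'   probabilities for the target race/ethnicity.
#' @param measureKind "RR", "OR" or "HR".
#' @param value The relative measure, positive.
#' @return The derived carrier curve.
#' @export
stratifyFromRelative <- function(general, measureKind = c("RR", "OR", "HR"),
                                 value) {
    measureKind <- match.arg(measureKind)
    assertScalar(value, "value", "numeric")
    if (value <= 0) stop("measure value must be positive", call. = FALSE)
    switch(measureKind,
           RR = applyRR(general, value),
           OR = applyOR(general, value),
           HR = applyConstantHR(general, value))
}

#' Adjusted personalized baseline curve for one cancer
#'
#' Assembles the user-ready baseline from the raw database stratum:
#' colorectal curves are deconvolved from the screening mixture
#' (adherence 0.818, screening RR 0.44) and capped at a 90 % lifetime
#' risk; colorectal (MLH1 carriers, HR path) and endometrial (OR path)
#' curves are then personalized to the user's BMI. Other cancers pass
#' through unchanged.
#'
#' @param db An \code{\linkS4class{AcpDatabase}}.
#' @param profile A \code{\linkS4class{RiskProfile}}.
#' @param registry An \code{\linkS4class{InterventionRegistry}}.
#' @param cancer Cancer type.
#' @return Numeric vector of 85 onset probabilities.
#' @export
adjustedBaseline <- function(db, profile, registry, cancer) {
    stopifnot(is(db, "AcpDatabase"), is(profile, "RiskProfile"),
              is(registry, "InterventionRegistry"))
    cst <- registryConstants(registry)
    curve <- acpCurve(db, cancer, profile@gene, profile@sex,
                      profile@race, profile@ethnicity)
    if (cancer == "colorectal") {
        colo <- interventionParam(registry, "colonoscopy", "colorectal")
        curve <- deconvolveMixture(curve, cst$colonoscopy_adherence_p,
                                   colo@value)
        curve <- capLifetime(curve, cst$lifetime_cap)
        wc <- interventionParam(registry, "weight_change", "colorectal")
        if (profile@gene %in% wc@generalizedGenes)
            curve <- personalizeBmi(curve, bmi(profile), profile@sex,
                                    path = "HR", perStep = wc@perStepValue,
                                    constants = cst)
    } else if (cancer == "endometrial") {
        wc <- interventionParam(registry, "weight_change", "endometrial")
        if (profile@gene %in% wc@generalizedGenes)
            curve <- personalizeBmi(curve, bmi(profile), profile@sex,
                                    height = profile@height,
                                    path = "OR", perStep = wc@perStepValue,
                                    constants = cst)
    }
    checkAcp(curve, paste("adjusted baseline for", cancer))
    curve
}
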