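## The per-profile engine: intervention application, menu construction,
## and assembly of the full per-cancer risk picture.

#' Post-intervention penetrance curve
#'
#' Dispatches one intervention onto an adjusted baseline curve:
#' \itemize{
#'   \item colonoscopy: relative-risk multiplication (RR 0.44);
#'   \item aspirin: the time-varying hazard-ratio schedule applied on the
#'     hazard scale from the user's current age;
#'   \item weight_change (weight loss): the continuous-exposure model with
#'     direction -1, magnitude from the chosen pounds -- hazard-ratio path
#'     for colorectal, odds-ratio path (per-age conversion) for
#'     endometrial;
#'   \item hysterectomy / oophorectomy: the curve is zeroed.
#' }
#'
#' @param baseline Numeric vector of 85 onset probabilities (the adjusted
#'   personalized baseline).
#' @param profile A \code{\linkS4class{RiskProfile}}.
#' @param cancer Cancer type the curve describes.
#' @param param The matching \code{\linkS4class{InterventionParam}}.
#' @param weightLossLb Pounds of weight loss (weight_change only).
#' @return The post-intervention curve.
#' @export
postInterventionCurve <- function(baseline, profile, cancer, param,
                                  weightLossLb = 0) {
    stopifnot(is(profile, "RiskProfile"), is(param, "InterventionParam"))
    checkAcp(baseline)
    if (param@cancer != cancer)
        stop("parameter '", param@id, "' applies to ", param@cancer,
             ", not ", cancer, call. = FALSE)
    if (!profile@gene %in% param@generalizedGenes)
        stop("intervention '", param@id, "' is not applicable to ",
             profile@gene, " carriers for ", cancer, call. = FALSE)
    switch(param@id,
        colonoscopy = applyRR(baseline, param@value),
        aspirin = applyHrSchedule(baseline, param@schedule,
                                  startAge = profile@currentAge),
        weight_change = {
            lb <- as.numeric(weightLossLb)
            if (lb < 0) stop("weight loss must be nonnegative", call. = FALSE)
            if (lb == 0) return(baseline)
            dKg <- lb / LB_PER_KG
            if (param@stepUnit == "bmi_point") {
                dBmi <- dKg / profile@height^2
                hr <- continuousEffect(-1, dBmi, param@perStepValue)
                applyHrSchedule(baseline, hr,
                                startAge = profile@currentAge)
            } else if (param@stepUnit == "kg5") {
                orValue <- continuousEffect(-1, dKg / 5, param@perStepValue)
                applyOR(baseline, orValue)
            } else {
                stop("unknown step unit '", param@stepUnit, "'",
                     call. = FALSE)
            }
        },
        hysterectomy = numeric(MAX_AGE),
        oophorectomy = numeric(MAX_AGE),
        stop("unknown intervention '", param@id, "'", call. = FALSE))
}

#' Build the intervention menu for a profile
#'
#' Determines which interventions the profile may toggle: colonoscopy and
#' aspirin when colorectal cancer is associated with the profile's gene;
#' prophylactic surgeries for females without the corresponding prior
#' surgery when the organ's cancer-gene association exists; and the
#' weight-loss range. The weight-loss options run in whole pounds from 0
#' to the pounds equivalent of \code{min(5, BMI - 25)} BMI points (so no
#' positive option is offered at or below the normal-range threshold of
#' BMI 25, and very obese users cannot overstate the effect).
#'
#' @param profile A \code{\linkS4class{RiskProfile}}.
#' @param registry An \code{\linkS4class{InterventionRegistry}}.
#' @return Named list: logical flags \code{colonoscopy}, \code{aspirin},
#'   \code{hysterectomy}, \code{oophorectomy}; integer vector
#'   \code{weightLossRangeLb} (always contains 0); and
#'   \code{weightLossTargets}, the cancers a weight loss would act on for
#'   this profile.
#' @export
buildMenu <- function(profile, registry) {
    stopifnot(is(profile, "RiskProfile"), is(registry, "InterventionRegistry"))
    cst <- registryConstants(registry)
    gene <- profile@gene
    sex <- profile@sex
    cancers <- setdiff(associatedCancers(gene, sex), profile@priorCancers)

    eligible <- function(id, cancer) {
        cancer %in% cancers &&
            gene %in% interventionParam(registry, id, cancer)@generalizedGenes
    }
    colonoscopy <- eligible("colonoscopy", "colorectal")
    aspirin <- eligible("aspirin", "colorectal")
    hysterectomy <- sex == "female" && !profile@hysterectomyDone &&
        eligible("hysterectomy", "endometrial")
    oophorectomy <- sex == "female" && !profile@oophorectomyDone &&
        eligible("oophorectomy", "ovarian")

    userBmi <- bmi(profile)
    maxBmiDrop <- min(cst$max_weight_loss_bmi_points,
                      max(0, userBmi - cst$bmi_clamp_low))
    maxLb <- floor(maxBmiDrop * profile@height^2 * LB_PER_KG)
    targets <- character(0)
    if (eligible("weight_change", "colorectal"))
        targets <- c(targets, "colorectal")
    if ("endometrial" %in% cancers &&
        gene %in% interventionParam(registry, "weight_change",
                                    "endometrial")@generalizedGenes &&
        !profile@hysterectomyDone)
        targets <- c(targets, "endometrial")

    list(colonoscopy = colonoscopy, aspirin = aspirin,
         hysterectomy = hysterectomy, oophorectomy = oophorectomy,
         weightLossRangeLb = 0:maxLb,
         weightLossTargets = targets)
}

#' Full per-profile risk computation
#'
#' For each cancer associated with the profile's gene and sex that is not
#' in the prior-cancer history, computes: the adjusted personalized
#' baseline series; one series per selected applicable intervention; the
#' additively composed series; and the matched general-population series
#' for the profile's sex, race and ethnicity. Organs already removed by a
#' prior prophylactic surgery contribute a zero baseline.
#'
#' @param profile A \code{\linkS4class{RiskProfile}}.
#' @param selection A selection from \code{\link{interventionSelection}},
#'   or \code{NULL} for baseline only.
#' @param db An \code{\linkS4class{AcpDatabase}}.
#' @param registry An \code{\linkS4class{InterventionRegistry}}.
#' @return Named list (one element per cancer), each with components
#'   \code{baseline}, \code{singles} (named list of
#'   \code{\linkS4class{RiskSeries}}), \code{composed}, \code{general} and
#'   \code{relative} (lifetime relative risk vs the general population).
#' @examples
#' db <- simulateAcpDatabase(seed = 1)
#' reg <- readInterventionRegistry()
#' pr <- RiskProfile("MLH1", "female", 40, height = 1.65, weight = 70)
#' sel <- interventionSelection(pr, reg, colonoscopy = TRUE)
#' res <- profileRisks(pr, sel, db, reg)
#' lifetimeRisk(res$colorectal$composed)
#' @export
profileRisks <- function(profile, selection = NULL, db, registry) {
    stopifnot(is(profile, "RiskProfile"), is(db, "AcpDatabase"),
              is(registry, "InterventionRegistry"))
    if (is.null(selection))
        selection <- interventionSelection(profile, registry)
    aCur <- profile@currentAge
    cancers <- setdiff(associatedCancers(profile@gene, profile@sex),
                       profile@priorCancers)
    out <- list()
    for (cancer in cancers) {
        base <- adjustedBaseline(db, profile, registry, cancer)
        if ((cancer == "endometrial" && profile@hysterectomyDone) ||
            (cancer == "ovarian" && profile@oophorectomyDone))
            base <- numeric(MAX_AGE)
        baseSeries <- makeRiskSeries(base, aCur, cancer, "baseline")
        general <- makeRiskSeries(
            acpCurve(db, cancer, "NONE", profile@sex, profile@race,
                     profile@ethnicity),
            aCur, cancer, "general")

        singles <- list()
        addSingle <- function(id, curve) {
            singles[[id]] <<- makeRiskSeries(curve, aCur, cancer, id)
        }
        if (cancer == "colorectal") {
            if (selection$colonoscopy)
                addSingle("colonoscopy", postInterventionCurve(
                    base, profile, cancer,
                    interventionParam(registry, "colonoscopy", cancer)))
            if (selection$aspirin)
                addSingle("aspirin", postInterventionCurve(
                    base, profile, cancer,
                    interventionParam(registry, "aspirin", cancer)))
        }
        if (selection$weightLossLb > 0) {
            wc <- tryCatch(
                interventionParam(registry, "weight_change", cancer),
                error = function(e) NULL)
            if (!is.null(wc) && profile@gene %in% wc@generalizedGenes)
                addSingle("weight_change", postInterventionCurve(
                    base, profile, cancer, wc,
                    weightLossLb = selection$weightLossLb))
        }
        if (cancer == "endometrial" && selection$hysterectomy)
            addSingle("hysterectomy", numeric(MAX_AGE))
        if (cancer == "ovarian" && selection$oophorectomy)
            addSingle("oophorectomy", numeric(MAX_AGE))

        composed <- composeSeries(baseSeries, singles)
        out[[cancer]] <- list(baseline = baseSeries, singles = singles,
                              composed = composed, general = general,
                              relative = relativeLifetimeRisk(baseSeries,
                                                              general))
    }
    out
}
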