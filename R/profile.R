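## RiskProfile construction, JSON input with unit handling, and the
## intervention selection.

#' Construct a RiskProfile
#'
#' @param gene Lynch syndrome gene carrying the pathogenic variant.
#' @param sex "male" or "female".
#' @param currentAge Current age in whole years, 1..84.
#' @param race,ethnicity Stratification labels; default to the
#'   unknown-value levels "All_Races"/"All_Ethnicities".
#' @param height Height in meters.
#' @param weight Weight in kilograms.
#' @param priorCancers Character vector of prior cancer diagnoses.
#' @param hysterectomyDone,oophorectomyDone Prior prophylactic surgery
#'   flags.
#' @return A validated \code{\linkS4class{RiskProfile}}.
#' @examples
#' RiskProfile("MLH1", "female", 40, height = 1.65, weight = 70)
#' @export
RiskProfile <- function(gene, sex, currentAge,
                        race = "All_Races", ethnicity = "All_Ethnicities",
                        height, weight, priorCancers = character(0),
                        hysterectomyDone = FALSE, oophorectomyDone = FALSE) {
    obj <- new("RiskProfile", gene = gene, sex = sex,
               currentAge = as.integer(currentAge), race = race,
               ethnicity = ethnicity, height = height, weight = weight,
               priorCancers = priorCancers,
               hysterectomyDone = hysterectomyDone,
               oophorectomyDone = oophorectomyDone)
    validObject(obj)
    obj
}

#' @rdname bmi
#' @export
setMethod("bmi", "RiskProfile", function(x) x@weight / x@height^2)

setMethod("show", "RiskProfile", function(object) {
    cat("RiskProfile:", object@gene, "carrier,", object@sex, "age",
        object@currentAge, "\n")
    cat("  race/ethnicity:", object@race, "/", object@ethnicity, "\n")
    cat(sprintf("  height %.2f m, weight %.1f kg (BMI %.1f)\n",
                object@height, object@weight, bmi(object)))
    if (length(object@priorCancers))
        cat("  prior cancers:", paste(object@priorCancers, collapse = ", "),
            "\n")
    if (object@hysterectomyDone) cat("  prior hysterectomy\n")
    if (object@oophorectomyDone) cat("  prior oophorectomy\n")
    invisible(NULL)
})

## unit conversion helpers
heightToMeters <- function(value, unit) {
    switch(unit,
           m = value, cm = value / 100, "in" = value * 0.0254,
           stop("unknown height unit '", unit, "' (use m, cm or in)",
                call. = FALSE))
}

weightToKg <- function(value, unit) {
    switch(unit,
           kg = value, lb = value / LB_PER_KG,
           stop("unknown weight unit '", unit, "' (use kg or lb)",
                call. = FALSE))
}

#' Read a user profile from JSON
#'
#' Accepts the shipped profile schema (see
#' \code{system.file("schemas", "profile.schema.json", package =
#' "lynchRisk")}): gene, sex, current age, optional race/ethnicity, height
#' and weight with explicit unit tags (\code{m}/\code{cm}/\code{in},
#' \code{kg}/\code{lb}; converted internally to metric), prior cancers and
#' surgery flags.
#'
#' @param path Path to a profile JSON document.
#' @return A validated \code{\linkS4class{RiskProfile}}.
#' @export
readProfile <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    need <- c("gene", "sex", "current_age", "height", "weight")
    miss <- setdiff(need, names(doc))
    if (length(miss))
        stop("profile is missing fields: ", paste(miss, collapse = ", "),
             call. = FALSE)
    getUnitValue <- function(x, what) {
        if (!is.list(x) || is.null(x$value) || is.null(x$unit))
            stop("profile ", what, " must be {\"value\": ..., \"unit\": ...}",
                 call. = FALSE)
        x
    }
    h <- getUnitValue(doc$height, "height")
    w <- getUnitValue(doc$weight, "weight")
    RiskProfile(
        gene = doc$gene, sex = doc$sex,
        currentAge = doc$current_age,
        race = if (is.null(doc$race)) "All_Races" else doc$race,
        ethnicity = if (is.null(doc$ethnicity)) "All_Ethnicities"
                    else doc$ethnicity,
        height = heightToMeters(h$value, h$unit),
        weight = weightToKg(w$value, w$unit),
        priorCancers = as.character(unlist(doc$prior_cancers)),
        hysterectomyDone = isTRUE(doc$hysterectomy_done),
        oophorectomyDone = isTRUE(doc$oophorectomy_done))
}

#' Construct an intervention selection
#'
#' Validates a set of intervention toggles against the menu available to
#' the profile (see \code{\link{buildMenu}}): selections are restricted to
#' menu-eligible items and the chosen weight loss must fall inside the
#' offered range.
#'
#' @param profile A \code{\linkS4class{RiskProfile}}.
#' @param registry An \code{\linkS4class{InterventionRegistry}}.
#' @param colonoscopy,aspirin,hysterectomy,oophorectomy Logical toggles.
#' @param weightLossLb Whole pounds of weight loss from the offered range
#'   (0 = none).
#' @return Named list of validated selections (class
#'   \code{"lynchSelection"}).
#' @export
interventionSelection <- function(profile, registry,
                                  colonoscopy = FALSE, aspirin = FALSE,
                                  weightLossLb = 0,
                                  hysterectomy = FALSE,
                                  oophorectomy = FALSE) {
    stopifnot(is(profile, "RiskProfile"), is(registry, "InterventionRegistry"))
    menu <- buildMenu(profile, registry)
    sel <- list(colonoscopy = isTRUE(colonoscopy), aspirin = isTRUE(aspirin),
                weightLossLb = as.integer(weightLossLb),
                hysterectomy = isTRUE(hysterectomy),
                oophorectomy = isTRUE(oophorectomy))
    for (id in c("colonoscopy", "aspirin", "hysterectomy", "oophorectomy"))
        if (sel[[id]] && !menu[[id]])
            stop("intervention '", id, "' is not on the menu for this ",
                 "profile", call. = FALSE)
    if (!sel$weightLossLb %in% menu$weightLossRangeLb)
        stop("weight loss of ", sel$weightLossLb, " lb is outside the ",
             "offered range 0..", max(menu$weightLossRangeLb), " lb",
             call. = FALSE)
    structure(sel, class = "lynchSelection")
}

#' Read an intervention selection from JSON
#'
#' @param path Path to a selection JSON document (schema shipped under
#'   \code{schemas/}).
#' @param profile,registry Used to validate the selection against the
#'   profile's menu.
#' @return A validated selection list.
#' @export
readSelection <- function(path, profile, registry) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    interventionSelection(
        profile, registry,
        colonoscopy = isTRUE(doc$colonoscopy),
        aspirin = isTRUE(doc$aspirin),
        weightLossLb = if (is.null(doc$weight_loss_lb)) 0
                       else doc$weight_loss_lb,
        hysterectomy = isTRUE(doc$hysterectomy),
        oophorectomy = isTRUE(doc$oophorectomy))
}
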