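## Intervention registry: JSON loading, validation, accessors.

newInterventionParam <- function(id, cancer, measureKind, application,
                                 value = NA_real_,
                                 perStepValue = NA_real_, stepUnit = "",
                                 schedule = NULL,
                                 applicableGenes = character(0),
                                 generalizedGenes = character(0),
                                 note = "") {
    if (is.null(schedule)) {
        schedule <- matrix(numeric(0), ncol = 2L)
    } else {
        schedule <- matrix(as.numeric(unlist(schedule)), ncol = 2L,
                           byrow = is.list(schedule))
    }
    colnames(schedule) <- c("years_since_initiation", "measure")
    new("InterventionParam", id = id, cancer = cancer,
        measureKind = measureKind, application = application,
        value = as.numeric(value), perStepValue = as.numeric(perStepValue),
        stepUnit = stepUnit, schedule = schedule,
        applicableGenes = as.character(applicableGenes),
        generalizedGenes = as.character(generalizedGenes),
        note = note)
}

#' Load an intervention-parameter registry
#'
#' Reads a JSON registry document holding the model constants and one entry
#' per intervention effect (measure kind, binary/continuous application,
#' reported value or per-step value, optional time-since-initiation
#' schedule, applicable and generalized gene sets, report caveat text).
#' With no argument, loads the registry shipped with the package, which is
#' pre-populated with the published constants: colonoscopy RR 0.44 under
#' 0.818 adherence; the aspirin HR schedule (2 y, 0.56), (5 y, 0.63),
#' (10 y, 0.65); the 7 % per BMI point colorectal HR step; the 20 % per
#' 5 kg endometrial OR step; exact zeroing for prophylactic hysterectomy
#' and oophorectomy; the 90 % lifetime cap and sex-specific reference BMIs
#' 27.1 / 26.0 kg/m^2.
#'
#' @param path Path to a registry JSON document; defaults to the shipped
#'   \code{paper_registry.json}.
#' @return An \code{\linkS4class{InterventionRegistry}}.
#' @examples
#' reg <- readInterventionRegistry()
#' interventionParam(reg, "aspirin")
#' @export
readInterventionRegistry <- function(path = defaultRegistryPath()) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
    if (is.null(doc$constants) || is.null(doc$interventions))
        stop("registry document must have 'constants' and 'interventions'",
             call. = FALSE)
    cst <- lapply(doc$constants, as.numeric)
    params <- lapply(doc$interventions, function(p) {
        param <- tryCatch(
            newInterventionParam(
                id = p$id, cancer = p$cancer,
                measureKind = p$measure_kind, application = p$application,
                value = if (is.null(p$value)) NA_real_ else p$value,
                perStepValue = if (is.null(p$per_step_value)) NA_real_
                               else p$per_step_value,
                stepUnit = if (is.null(p$step_unit)) "" else p$step_unit,
                schedule = p$schedule,
                applicableGenes = unlist(p$applicable_genes),
                generalizedGenes = unlist(p$generalized_genes),
                note = if (is.null(p$note)) "" else p$note),
            error = function(e) stop("invalid registry entry '", p$id,
                                     "': ", conditionMessage(e),
                                     call. = FALSE))
        validObject(param)
        param
    })
    reg <- new("InterventionRegistry", params = params, constants = cst)
    validObject(reg)
    reg
}

#' Path of the shipped default registry
#' @return File path of \code{paper_registry.json} inside the installed
#'   package.
#' @export
defaultRegistryPath <- function()
    system.file("extdata", "paper_registry.json", package = "lynchRisk",
                mustWork = TRUE)

#' @rdname interventionParam
#' @export
setMethod("interventionParam", "InterventionRegistry",
          function(x, id, cancer = NULL) {
    assertEnum(id, INTERVENTION_IDS, "id")
    hit <- vapply(x@params, function(p)
        p@id == id && (is.null(cancer) || p@cancer == cancer), logical(1))
    if (!any(hit))
        stop("no registry entry for intervention '", id, "'",
             if (!is.null(cancer)) paste0(" and cancer '", cancer, "'"),
             call. = FALSE)
    if (sum(hit) > 1L)
        stop("intervention '", id, "' has entries for several cancers; ",
             "pass `cancer` to disambiguate", call. = FALSE)
    x@params[[which(hit)]]
})

#' @rdname registryConstants
#' @export
setMethod("registryConstants", "InterventionRegistry",
          function(x) x@constants)

setMethod("show", "InterventionRegistry", function(object) {
    cat("InterventionRegistry with", length(object@params), "effects\n")
    for (p in object@params) {
        desc <- if (p@measureKind == "ZERO") "risk set to zero"
                else if (nrow(p@schedule) > 0L)
                    paste0("HR schedule with ", nrow(p@schedule), " knots")
                else if (p@application == "continuous")
                    paste0(p@measureKind, " step ", p@perStepValue, " per ",
                           p@stepUnit)
                else paste0(p@measureKind, " = ", p@value)
        cat("  ", format(p@id, width = 13), p@cancer, ": ", desc, "\n",
            sep = "")
    }
    invisible(NULL)
})

setMethod("show", "InterventionParam", function(object) {
    cat("InterventionParam '", object@id, "' (", object@cancer, ", ",
        object@measureKind, ", ", object@application, ")\n", sep = "")
    if (!is.na(object@value)) cat("  value: ", object@value, "\n")
    if (!is.na(object@perStepValue))
        cat("  per-step: ", object@perStepValue, " per ", object@stepUnit,
            "\n", sep = "")
    if (nrow(object@schedule) > 0L) {
        cat("  schedule:\n")
        print(object@schedule)
    }
    cat("  study genes: ", paste(object@applicableGenes, collapse = ", "),
        "\n  applied to:  ", paste(object@generalizedGenes, collapse = ", "),
        "\n", sep = "")
    invisible(NULL)
})
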