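## Generics for the container accessors.

#' Extract one penetrance curve from an AcpDatabase
#'
#' @param x An \code{\linkS4class{AcpDatabase}}.
#' @param cancer,gene,sex,race,ethnicity Stratum key components.
#' @param ... Further arguments for methods.
#' @return Numeric vector of 85 onset probabilities (ages 1..85).
#' @export
setGeneric("acpCurve", function(x, cancer, gene, sex,
                                race = "All_Races",
                                ethnicity = "All_Ethnicities", ...)
    standardGeneric("acpCurve"))

#' Stratum table of an AcpDatabase
#' @param x An \code{\linkS4class{AcpDatabase}}.
#' @return data.frame of stratum keys with lifetime risk summaries.
#' @export
setGeneric("strataTable", function(x) standardGeneric("strataTable"))

#' Number of strata
#' @param x An \code{\linkS4class{AcpDatabase}}.
#' @return Integer scalar.
#' @export
setGeneric("nStrata", function(x) standardGeneric("nStrata"))

#' Look up an intervention parameter
#' @param x An \code{\linkS4class{InterventionRegistry}}.
#' @param id Intervention identifier.
#' @param cancer Optional cancer type to disambiguate (weight_change carries
#'   one entry per affected cancer).
#' @return An \code{\linkS4class{InterventionParam}}.
#' @export
setGeneric("interventionParam", function(x, id, cancer = NULL)
    standardGeneric("interventionParam"))

#' Model constants of a registry
#' @param x An \code{\linkS4class{InterventionRegistry}}.
#' @return Named list of scalar constants.
#' @export
setGeneric("registryConstants", function(x)
    standardGeneric("registryConstants"))

#' Body-mass index of a profile
#' @param x A \code{\linkS4class{RiskProfile}}.
#' @return BMI in kg/m^2 (weight / height^2).
#' @export
setGeneric("bmi", function(x) standardGeneric("bmi"))

#' Cumulative risk of a series at a horizon age
#' @param x A \code{\linkS4class{RiskSeries}}.
#' @param age Horizon age (clamped to the series support on the right).
#' @return Probability.
#' @export
setGeneric("riskAt", function(x, age) standardGeneric("riskAt"))

#' Lifetime (age-85) cumulative risk of a series
#' @param x A \code{\linkS4class{RiskSeries}}.
#' @return Probability.
#' @export
setGeneric("lifetimeRisk", function(x) standardGeneric("lifetimeRisk"))
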