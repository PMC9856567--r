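## S4 container classes. Penetrance curves are plain numeric(85) vectors;
## the containers own the invariants and enforce them on construction.

#' AcpDatabase: age-specific conditional penetrance curves by stratum
#'
#' Container for the penetrance database. Each stratum is identified by
#' (cancer, gene, sex, race, ethnicity) and carries a dense curve of 85
#' probabilities: the probability of first onset of that cancer at exactly
#' age a (the age-specific conditional penetrance, ACP), for a = 1..85.
#'
#' Validity enforces: controlled-vocabulary labels; sex-compatible cancer
#' sites; carrier strata restricted to the supported gene-cancer association
#' matrix (\code{\link{geneCancerAssociations}}); every curve with values in
#' [0, 1] and lifetime mass at most 1; and, for every carrier stratum, the
#' presence of the matching general-population stratum (gene \code{"NONE"},
#' same cancer/sex/race/ethnicity) needed for relative-risk display.
#'
#' @slot strata data.frame with columns cancer, gene, sex, race, ethnicity
#'   (one row per stratum).
#' @slot acp numeric matrix, rows aligned with \code{strata}, 85 columns
#'   (ages 1..85).
#' @slot provenance character vector of free-text source labels per stratum.
#' @slot metadata list of table-level metadata (e.g. schema version).
#'
#' @seealso \code{\link{readAcpTable}}, \code{\link{simulateAcpDatabase}},
#'   \code{\link{acpCurve}}
#' @export
setClass("AcpDatabase",
         representation(strata = "data.frame",
                        acp = "matrix",
                        provenance = "character",
                        metadata = "list"))

setValidity("AcpDatabase", function(object) {
    st <- object@strata
    need <- c("cancer", "gene", "sex", "race", "ethnicity")
    if (!all(need %in% names(st)))
        return(paste("strata must have columns:", paste(need, collapse = ", ")))
    if (nrow(st) != nrow(object@acp) || ncol(object@acp) != MAX_AGE)
        return("acp matrix must have one row per stratum and 85 age columns")
    if (length(object@provenance) != nrow(st))
        return("provenance must have one entry per stratum")
    bad <- function(col, levels)
        any(!st[[col]] %in% levels)
    if (bad("cancer", CANCER_TYPES)) return("unknown cancer label")
    if (bad("gene", GENE_LEVELS)) return("unknown gene label")
    if (bad("sex", SEX_LEVELS)) return("unknown sex label")
    if (bad("race", RACE_LEVELS)) return("unknown race label")
    if (bad("ethnicity", ETHNICITY_LEVELS)) return("unknown ethnicity label")
    key <- do.call(paste, c(st[need], sep = "|"))
    if (anyDuplicated(key))
        return(paste("duplicated stratum:", key[duplicated(key)][1L]))
    for (i in seq_len(nrow(st))) {
        lab <- formatStratum(st$cancer[i], st$gene[i], st$sex[i],
                             st$race[i], st$ethnicity[i])
        if (!isStratumAdmissible(st$cancer[i], st$gene[i], st$sex[i]))
            return(paste("inadmissible stratum", lab,
                         "(sex-incompatible site or unsupported",
                         "gene-cancer association)"))
        cv <- object@acp[i, ]
        if (anyNA(cv) || any(cv < 0) || any(cv > 1))
            return(paste("probabilities outside [0, 1] in stratum", lab))
        if (sum(cv) > 1 + 1e-9)
            return(paste("lifetime probability mass", format(sum(cv)),
                         "exceeds 1 in stratum", lab))
    }
    ## every carrier stratum needs its general-population partner
    carrier <- st$gene != "NONE"
    if (any(carrier)) {
        gpKey <- paste(st$cancer, "NONE", st$sex, st$race, st$ethnicity,
                       sep = "|")
        present <- gpKey[carrier] %in% key
        if (!all(present)) {
            i <- which(carrier)[which(!present)[1L]]
            return(paste("carrier stratum",
                         formatStratum(st$cancer[i], st$gene[i], st$sex[i],
                                       st$race[i], st$ethnicity[i]),
                         "lacks its matching general-population stratum"))
        }
    }
    TRUE
})

#' InterventionParam: one published risk modifier
#'
#' Describes a single intervention effect: its measure currency (relative
#' risk, odds ratio, hazard ratio, or an exact zeroing), whether it applies
#' as a binary switch or on a continuous exposure scale, the reported value
#' or per-step value, an optional time-since-initiation schedule of measure
#' knots, and the genes it applies to. \code{applicableGenes} are the genes
#' in the source study; \code{generalizedGenes} are the genes the effect is
#' extended to by stated assumption (always a superset).
#'
#' @slot id intervention identifier (one of \code{INTERVENTION_IDS}).
#' @slot cancer cancer type the effect applies to.
#' @slot measureKind "RR", "OR", "HR" or "ZERO".
#' @slot application "binary" or "continuous".
#' @slot value reported measure for binary application (NA when a schedule
#'   or continuous model is used).
#' @slot perStepValue per-unit effect size for continuous application.
#' @slot stepUnit unit of one exposure step ("bmi_point" or "kg5").
#' @slot schedule two-column matrix (years since initiation, measure);
#'   zero rows when no schedule.
#' @slot applicableGenes genes supported by the source study.
#' @slot generalizedGenes genes the effect is extended to.
#' @slot note free-text caveat surfaced verbatim in reports.
#' @export
setClass("InterventionParam",
         representation(id = "character", cancer = "character",
                        measureKind = "character", application = "character",
                        value = "numeric", perStepValue = "numeric",
                        stepUnit = "character", schedule = "matrix",
                        applicableGenes = "character",
                        generalizedGenes = "character",
                        note = "character"))

setValidity("InterventionParam", function(object) {
    if (!object@id %in% INTERVENTION_IDS) return("unknown intervention id")
    if (!object@cancer %in% CANCER_TYPES) return("unknown cancer")
    if (!object@measureKind %in% c("RR", "OR", "HR", "ZERO"))
        return("measureKind must be RR, OR, HR or ZERO")
    if (!object@application %in% c("binary", "continuous"))
        return("application must be binary or continuous")
    sched <- object@schedule
    if (ncol(sched) != 2L)
        return("schedule must be a two-column (time, measure) matrix")
    if (nrow(sched) > 0L) {
        if (any(diff(sched[, 1L]) <= 0))
            return("schedule knot times must be strictly increasing")
        if (any(sched[, 2L] <= 0))
            return("schedule measures must be positive")
    }
    if (object@application == "binary") {
        if (object@measureKind == "ZERO") {
            ## exact zeroing carries value 0 and no schedule
            if (nrow(sched) > 0L) return("ZERO measures take no schedule")
        } else if (is.na(object@value) && nrow(sched) == 0L) {
            return("binary application requires a value or a schedule")
        } else if (!is.na(object@value) && object@value <= 0) {
            return("binary measure must be positive")
        }
    } else {
        if (is.na(object@perStepValue) || !nzchar(object@stepUnit))
            return("continuous application requires perStepValue and stepUnit")
        if (object@perStepValue <= -1)
            return("perStepValue must exceed -1")
    }
    if (!all(object@applicableGenes %in% LS_GENES) ||
        !all(object@generalizedGenes %in% LS_GENES))
        return("gene sets must be Lynch syndrome genes")
    if (!all(object@applicableGenes %in% object@generalizedGenes))
        return("generalizedGenes must contain applicableGenes")
    TRUE
})

#' InterventionRegistry: the intervention parameter set plus model constants
#'
#' @slot params list of \code{\linkS4class{InterventionParam}}.
#' @slot constants named list of scalar model constants: colonoscopy
#'   adherence proportion, lifetime cap, sex-specific reference mean BMIs,
#'   the BMI clamp bounds, the maximum weight-loss span in BMI points, the
#'   personograph icon count and the display rounding granularity.
#' @seealso \code{\link{readInterventionRegistry}}
#' @export
setClass("InterventionRegistry",
         representation(params = "list", constants = "list"))

REQUIRED_CONSTANTS <- c("colonoscopy_adherence_p", "lifetime_cap",
                        "ref_bmi_male", "ref_bmi_female",
                        "bmi_clamp_low", "bmi_clamp_high",
                        "max_weight_loss_bmi_points",
                        "personograph_icons", "display_rounding_pct")

setValidity("InterventionRegistry", function(object) {
    if (!all(vapply(object@params, is, logical(1), "InterventionParam")))
        return("params must all be InterventionParam objects")
    cst <- object@constants
    miss <- setdiff(REQUIRED_CONSTANTS, names(cst))
    if (length(miss))
        return(paste("missing constants:", paste(miss, collapse = ", ")))
    num <- vapply(cst[REQUIRED_CONSTANTS], function(x)
        is.numeric(x) && length(x) == 1L && !is.na(x) && x > 0, logical(1))
    if (!all(num)) return("constants must be positive scalars")
    if (cst$bmi_clamp_low >= cst$bmi_clamp_high)
        return("bmi_clamp_low must be below bmi_clamp_high")
    if (cst$colonoscopy_adherence_p > 1 || cst$lifetime_cap > 1)
        return("proportions must not exceed 1")
    TRUE
})

#' RiskProfile: a user's covariates and histories
#'
#' @slot gene Lynch syndrome gene carrying the pathogenic variant.
#' @slot sex "male" or "female".
#' @slot currentAge current age in whole years, 1..84.
#' @slot race,ethnicity registry stratification labels; unknown values map
#'   to "All_Races"/"All_Ethnicities".
#' @slot height height in meters.
#' @slot weight weight in kilograms.
#' @slot priorCancers cancer types already diagnosed (excluded from output;
#'   recurrence risk is out of scope).
#' @slot hysterectomyDone,oophorectomyDone prior prophylactic surgery flags
#'   (female only).
#' @seealso \code{\link{RiskProfile}}, \code{\link{readProfile}}
#' @export
setClass("RiskProfile",
         representation(gene = "character", sex = "character",
                        currentAge = "integer", race = "character",
                        ethnicity = "character", height = "numeric",
                        weight = "numeric", priorCancers = "character",
                        hysterectomyDone = "logical",
                        oophorectomyDone = "logical"))

setValidity("RiskProfile", function(object) {
    if (!object@gene %in% LS_GENES) return("gene must be a Lynch syndrome gene")
    if (!object@sex %in% SEX_LEVELS) return("unknown sex")
    if (object@currentAge < 1L || object@currentAge >= MAX_AGE)
        return("currentAge must be in 1..84")
    if (!object@race %in% RACE_LEVELS) return("unknown race")
    if (!object@ethnicity %in% ETHNICITY_LEVELS) return("unknown ethnicity")
    if (object@height <= 0 || object@weight <= 0)
        return("height and weight must be positive")
    if (!all(object@priorCancers %in% CANCER_TYPES))
        return("unknown prior cancer type")
    if (object@sex != "female" &&
        (object@hysterectomyDone || object@oophorectomyDone))
        return("female-only surgery flags require sex = female")
    TRUE
})

#' RiskSeries: cumulative future risk by horizon age
#'
#' The conditional probability of first onset in the half-open age interval
#' (current age, horizon], given cancer-free survival to the current age,
#' evaluated at every horizon from the current age (value 0) to 85.
#'
#' @slot cancer cancer type.
#' @slot variant "baseline", "general", an intervention id, or "composed".
#' @slot horizonAges integer horizons currentAge..85.
#' @slot cumulative future-risk values per horizon, nondecreasing in [0, 1].
#' @export
setClass("RiskSeries",
         representation(cancer = "character", variant = "character",
                        horizonAges = "integer", cumulative = "numeric"))

setValidity("RiskSeries", function(object) {
    if (!object@cancer %in% CANCER_TYPES) return("unknown cancer")
    h <- object@horizonAges
    v <- object@cumulative
    if (length(h) != length(v)) return("horizonAges/cumulative length mismatch")
    if (length(h) == 0L) return("empty series")
    if (h[length(h)] != MAX_AGE) return("series must extend to age 85")
    if (any(diff(h) != 1L)) return("horizons must be consecutive ages")
    if (anyNA(v) || any(v < -1e-12) || any(v > 1 + 1e-12))
        return("cumulative values must lie in [0, 1]")
    if (any(diff(v) < -1e-9))
        return("cumulative risk must be nondecreasing in horizon age")
    if (abs(v[1L]) > 1e-12)
        return("risk at the current-age horizon must be 0")
    TRUE
})
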