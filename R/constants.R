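## Controlled vocabularies and the gene-cancer association matrix.

#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats dbeta runif setNames
#' @importFrom utils read.table write.table modifyList
NULL

#' Age grid of the penetrance model
#'
#' All penetrance curves are dense vectors over integer ages 1..85; age 85 is
#' the lifetime horizon ("by age 85").
#'
#' @format Integer vector of length 85.
#' @export
AGE_GRID <- 1:85

#' Maximum model age (lifetime horizon)
#' @export
MAX_AGE <- 85L

#' Controlled vocabulary: cancer types
#' @export
CANCER_TYPES <- c("brain", "colorectal", "endometrial", "gastric", "ovarian",
                  "pancreatic", "prostate", "small_intestine",
                  "urinary_bladder")

#' Controlled vocabulary: Lynch syndrome genes plus the general-population code
#'
#' \code{"NONE"} encodes the no-pathogenic-variant (general population)
#' stratum, whose penetrances come from population registries.
#' @export
GENE_LEVELS <- c("MLH1", "MSH2", "MSH6", "PMS2", "EPCAM", "NONE")

#' Lynch syndrome susceptibility genes (pathogenic-variant carriers only)
#' @export
LS_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2", "EPCAM")

#' Controlled vocabulary: sex
#' @export
SEX_LEVELS <- c("male", "female")

#' Controlled vocabulary: race (registry stratification levels)
#'
#' \code{"All_Races"} is used for individuals with an unknown or unreported
#' race.
#' @export
RACE_LEVELS <- c("All_Races", "AIAN", "API", "Black", "White")

#' Controlled vocabulary: ethnicity
#' @export
ETHNICITY_LEVELS <- c("All_Ethnicities", "Hispanic", "Non_Hispanic")

#' Controlled vocabulary: intervention identifiers
#' @export
INTERVENTION_IDS <- c("colonoscopy", "aspirin", "weight_change",
                      "hysterectomy", "oophorectomy")

## Female-only and male-only cancer sites.
FEMALE_ONLY_CANCERS <- c("endometrial", "ovarian")
MALE_ONLY_CANCERS <- c("prostate")

## Pounds per kilogram, fixed for the weight-loss menu.
LB_PER_KG <- 2.20462

#' Gene-cancer association matrix
#'
#' Returns the logical matrix of supported gene-cancer associations: a curve
#' for a carrier stratum may only exist where the literature established a
#' significantly elevated risk for that gene-cancer pair. Blank cells (e.g.
#' prostate for MLH1) are disallowed strata. The general-population code
#' \code{"NONE"} is associated with every cancer.
#'
#' @return Logical matrix with cancers as rows and genes (\code{LS_GENES})
#'   as columns.
#' @examples
#' geneCancerAssociations()["prostate", ]
#' @export
geneCancerAssociations <- function() {
    m <- matrix(FALSE, nrow = length(CANCER_TYPES), ncol = length(LS_GENES),
                dimnames = list(CANCER_TYPES, LS_GENES))
    m["brain", c("MLH1", "MSH2", "MSH6")] <- TRUE
    m["colorectal", c("MLH1", "MSH2", "MSH6", "PMS2", "EPCAM")] <- TRUE
    m["endometrial", c("MLH1", "MSH2", "MSH6")] <- TRUE
    m["gastric", c("MLH1", "MSH2", "MSH6")] <- TRUE
    m["ovarian", c("MLH1", "MSH2", "MSH6", "PMS2")] <- TRUE
    m["pancreatic", c("MLH1", "MSH2")] <- TRUE
    m["prostate", "MSH2"] <- TRUE
    m["small_intestine", c("MLH1", "MSH2", "MSH6")] <- TRUE
    m["urinary_bladder", c("MLH1", "MSH2", "MSH6")] <- TRUE
    m
}

#' Is a gene-cancer stratum admissible?
#'
#' Checks sex compatibility (endometrial/ovarian are female-only, prostate is
#' male-only) and, for carrier strata, membership in the association matrix.
#' \code{gene = "NONE"} is admissible for every sex-compatible cancer.
#'
#' @param cancer Cancer type.
#' @param gene Gene level (one of \code{GENE_LEVELS}).
#' @param sex Sex level.
#' @return Logical scalar.
#' @export
isStratumAdmissible <- function(cancer, gene, sex) {
    if (cancer %in% FEMALE_ONLY_CANCERS && sex != "female") return(FALSE)
    if (cancer %in% MALE_ONLY_CANCERS && sex != "male") return(FALSE)
    if (gene == "NONE") return(TRUE)
    geneCancerAssociations()[cancer, gene]
}

#' Cancers associated with a Lynch syndrome gene for a given sex
#'
#' @param gene One of \code{LS_GENES}.
#' @param sex One of \code{SEX_LEVELS}.
#' @return Character vector of cancer types.
#' @export
associatedCancers <- function(gene, sex) {
    gene <- match.arg(gene, LS_GENES)
    sex <- match.arg(sex, SEX_LEVELS)
    cc <- CANCER_TYPES[geneCancerAssociations()[, gene]]
    cc[vapply(cc, isStratumAdmissible, logical(1), gene = gene, sex = sex)]
}
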