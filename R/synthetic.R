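## Deterministic synthetic penetrance generator. Real penetrance tables are
## derived from literature and registry data and are not shipped; the
## generator produces structurally identical databases with controlled
## lifetime risks and onset modes for testing and demonstration.

## One discretized unimodal curve on ages 1..85 with integer argmax == mode
## and sum == target. Shape is a Beta density over the age range whose
## continuous mode is placed exactly at `mode`; `concentration` sets the
## spread (larger = tighter peak).
unimodalAcp <- function(target, mode, concentration) {
    if (!is.numeric(target) || target <= 0 || target >= 1)
        stop("target lifetime risk must lie in (0, 1)", call. = FALSE)
    if (!is.numeric(mode) || mode < 1 || mode > MAX_AGE)
        stop("onset mode must lie in 1..", MAX_AGE, call. = FALSE)
    m0 <- mode / (MAX_AGE + 1)
    alpha <- 1 + concentration * m0
    beta <- 1 + concentration * (1 - m0)
    dens <- dbeta(AGE_GRID / (MAX_AGE + 1), alpha, beta)
    curve <- dens * (target / sum(dens))
    checkAcp(curve, "synthetic curve")
    curve
}

#' Simulate a synthetic ACP database
#'
#' Builds an \code{\linkS4class{AcpDatabase}} whose curves are discretized
#' unimodal (Beta-shaped) onset densities: each stratum is given a target
#' lifetime risk (the curve's sum, exactly) and an onset-age mode (the
#' curve's integer argmax, exactly). For every carrier stratum a matching
#' general-population stratum (gene \code{"NONE"}) is generated at its own
#' lower target so relative-risk displays work. The only randomness is the
#' per-stratum concentration of the Beta shape, drawn from the seed, so the
#' output is fully deterministic given \code{seed}.
#'
#' @param spec data.frame with columns \code{cancer, gene, sex, race,
#'   ethnicity, lifetime_risk, onset_mode, gp_lifetime_risk, gp_onset_mode}
#'   (one row per carrier stratum; the \code{gp_*} columns describe the
#'   paired general-population stratum). Defaults to
#'   \code{\link{syntheticStrataSpec}()}.
#' @param seed Integer seed.
#' @return A validated \code{\linkS4class{AcpDatabase}}.
#' @examples
#' db <- simulateAcpDatabase(seed = 7)
#' sum(acpCurve(db, "colorectal", "MLH1", "male"))
#' @export
simulateAcpDatabase <- function(spec = syntheticStrataSpec(), seed) {
    assertScalar(seed, "seed", "numeric")
    spec <- as.data.frame(spec, stringsAsFactors = FALSE)
    need <- c("cancer", "gene", "sex", "race", "ethnicity",
              "lifetime_risk", "onset_mode", "gp_lifetime_risk",
              "gp_onset_mode")
    if (!all(need %in% names(spec)))
        stop("spec must have columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    if (any(spec$lifetime_risk >= 1) || any(spec$gp_lifetime_risk >= 1))
        stop("target lifetime risks must lie in (0, 1)", call. = FALSE)

    ## carrier rows then the unique general-population partners
    gp <- unique(data.frame(cancer = spec$cancer, gene = "NONE",
                            sex = spec$sex, race = spec$race,
                            ethnicity = spec$ethnicity,
                            lifetime_risk = spec$gp_lifetime_risk,
                            onset_mode = spec$gp_onset_mode,
                            stringsAsFactors = FALSE))
    all <- rbind(spec[c("cancer", "gene", "sex", "race", "ethnicity",
                        "lifetime_risk", "onset_mode")], gp)

    oldSeed <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, .GlobalEnv))
    set.seed(as.integer(seed) %% .Machine$integer.max)
    conc <- runif(nrow(all), min = 8, max = 16)

    acp <- t(vapply(seq_len(nrow(all)), function(i)
        unimodalAcp(all$lifetime_risk[i], all$onset_mode[i], conc[i]),
        numeric(MAX_AGE)))
    db <- newAcpDatabase(all[c("cancer", "gene", "sex", "race", "ethnicity")],
                         acp,
                         provenance = rep("synthetic", nrow(all)),
                         metadata = list(schema_version = ACP_SCHEMA_VERSION,
                                         seed = as.integer(seed)))
    validObject(db)
    db
}

#' Default synthetic stratum specification
#'
#' One carrier stratum per admissible gene-cancer-sex combination in the
#' association matrix (race/ethnicity left at the unknown-value defaults),
#' with lifetime-risk targets and onset modes chosen to echo the broad
#' pattern reported for Lynch syndrome cohorts: colorectal and endometrial
#' risks of tens of percent with onset modes in the 50s-60s, rarer sites at
#' a few percent with later modes, and general-population targets an order
#' of magnitude or more below the carrier targets.
#'
#' @return data.frame accepted by \code{\link{simulateAcpDatabase}}.
#' @export
syntheticStrataSpec <- function() {
    ## carrier target lifetime risk, onset mode, GP target, GP mode per cancer
    base <- list(
        brain           = c(0.03, 60, 0.006, 62),
        colorectal      = c(0.45, 55, 0.040, 68),
        endometrial     = c(0.35, 54, 0.030, 62),
        gastric         = c(0.06, 65, 0.009, 70),
        ovarian         = c(0.10, 52, 0.012, 63),
        pancreatic      = c(0.05, 68, 0.015, 70),
        prostate        = c(0.20, 68, 0.110, 70),
        small_intestine = c(0.04, 58, 0.003, 65),
        urinary_bladder = c(0.05, 65, 0.020, 72))
    ## mild gene gradient: MLH1/MSH2 highest, MSH6 intermediate, PMS2/EPCAM low
    geneScale <- c(MLH1 = 1.0, MSH2 = 1.0, MSH6 = 0.7, PMS2 = 0.35,
                   EPCAM = 0.5)
    assoc <- geneCancerAssociations()
    rows <- list()
    for (cancer in rownames(assoc)) {
        sexes <- if (cancer %in% FEMALE_ONLY_CANCERS) "female"
                 else if (cancer %in% MALE_ONLY_CANCERS) "male"
                 else SEX_LEVELS
        for (gene in colnames(assoc)[assoc[cancer, ]]) {
            for (sex in sexes) {
                b <- base[[cancer]]
                rows[[length(rows) + 1L]] <- data.frame(
                    cancer = cancer, gene = gene, sex = sex,
                    race = "All_Races", ethnicity = "All_Ethnicities",
                    lifetime_risk = round(b[1] * geneScale[[gene]], 4),
                    onset_mode = b[2],
                    gp_lifetime_risk = b[3], gp_onset_mode = b[4],
                    stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
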