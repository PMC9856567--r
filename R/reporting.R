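## Risk-conveyance layer: rounding happens here and only here. Upstream
## values are full precision.

#' Five-year and lifetime risk snapshots
#'
#' Returns the two focused snapshots used by the bar and personograph
#' displays: cumulative risk within five years (horizon
#' \code{min(currentAge + 5, 85)}) and by age 85, each rounded half-up to
#' the nearest whole percent.
#'
#' @param series A \code{\linkS4class{RiskSeries}}.
#' @param currentAge The user's current age (the series' first horizon).
#' @return Named numeric vector \code{c(within_5y = ..., by_85 = ...)} in
#'   whole percent.
#' @examples
#' curve <- numeric(85); curve[41:85] <- 0.005
#' snapshotSeries(makeRiskSeries(curve, 40, "colorectal"), 40)
#' @export
snapshotSeries <- function(series, currentAge) {
    stopifnot(is(series, "RiskSeries"))
    c(within_5y = toPercent(riskAt(series, min(currentAge + 5, MAX_AGE))),
      by_85 = toPercent(riskAt(series, MAX_AGE)))
}

#' Personograph icon count
#'
#' Quantizes a probability onto the 20-icon personograph (5 % granularity):
#' \code{roundHalfUp(risk * 20)}, an integer in 0..20.
#'
#' @param risk Probability in [0, 1] (vectorized).
#' @param icons Number of icons, default 20.
#' @return Integer count(s) of shaded icons.
#' @examples
#' personographCounts(0.37)   # 7 icons = 35%
#' @export
personographCounts <- function(risk, icons = 20L) {
    if (any(risk < 0) || any(risk > 1))
        stop("risk must lie in [0, 1]", call. = FALSE)
    as.integer(roundHalfUp(risk * icons))
}

#' Lifetime absolute and relative risk table
#'
#' One row per cancer: the user's absolute lifetime risk (nearest 1 %),
#' the matched general-population lifetime risk (nearest 1 %), and their
#' ratio to one decimal, ordered by descending user risk. An undefined
#' ratio (zero general-population risk) is rendered as \code{"—"}.
#'
#' @param results Output of \code{\link{profileRisks}}.
#' @param variant Which user series to tabulate: \code{"baseline"} or
#'   \code{"composed"}.
#' @return data.frame with columns \code{cancer, user_pct, general_pct,
#'   relative, relative_label}.
#' @export
lifetimeTable <- function(results, variant = c("baseline", "composed")) {
    variant <- match.arg(variant)
    rows <- lapply(names(results), function(cancer) {
        r <- results[[cancer]]
        user <- lifetimeRisk(r[[variant]])
        gen <- lifetimeRisk(r$general)
        rel <- relativeLifetimeRisk(r[[variant]], r$general)
        data.frame(cancer = cancer,
                   user_pct = toPercent(user),
                   general_pct = toPercent(gen),
                   relative = as.numeric(rel),
                   relative_label = if (isTRUE(attr(rel, "undefined")))
                       "—" else
                       sprintf("%.1f×", roundHalfUp(rel, 1)),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$user_pct, out$cancer), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Visualization payload for one cancer
#'
#' Builds the numbers behind each display style:
#' \itemize{
#'   \item \code{"line"}: yearly cumulative percents (nearest 1 %) from
#'     the current age to 85, one series per variant;
#'   \item \code{"bar"}: the two snapshots (within 5 years, by 85) in
#'     whole percent;
#'   \item \code{"personograph"}: the same two snapshots as shaded icon
#'     counts out of 20.
#' }
#'
#' @param cancerResult One element of \code{\link{profileRisks}} output.
#' @param style "line", "bar" or "personograph".
#' @param currentAge The profile's current age.
#' @return Named list with the style, horizons/labels and the per-variant
#'   quantized values (baseline, each single, composed, general).
#' @export
visualizationData <- function(cancerResult,
                              style = c("line", "bar", "personograph"),
                              currentAge) {
    style <- match.arg(style)
    seriesSet <- c(list(baseline = cancerResult$baseline),
                   cancerResult$singles,
                   list(composed = cancerResult$composed,
                        general = cancerResult$general))
    if (style == "line") {
        vals <- lapply(seriesSet, function(s) toPercent(s@cumulative))
        list(style = "line",
             horizon_ages = cancerResult$baseline@horizonAges,
             percent = vals)
    } else if (style == "bar") {
        vals <- lapply(seriesSet, snapshotSeries, currentAge = currentAge)
        list(style = "bar",
             snapshot_labels = c("within_5y", "by_85"),
             percent = vals)
    } else {
        vals <- lapply(seriesSet, function(s)
            c(within_5y = personographCounts(
                  riskAt(s, min(currentAge + 5, MAX_AGE))),
              by_85 = personographCounts(riskAt(s, MAX_AGE))))
        list(style = "personograph", icons_total = 20L,
             snapshot_labels = c("within_5y", "by_85"),
             icons = vals)
    }
}

#' Render the personalized risk report
#'
#' Builds the deterministic report document: a machine-readable payload
#' (profile summary, lifetime table, quantized visualization data per
#' selected cancer, the verbatim caveat notes of every selected
#' intervention, and a references appendix from the database provenance)
#' plus a human-readable Markdown rendering. Identical inputs produce a
#' byte-identical document.
#'
#' @param profile A \code{\linkS4class{RiskProfile}}.
#' @param results Output of \code{\link{profileRisks}}.
#' @param registry The \code{\linkS4class{InterventionRegistry}} used.
#' @param selection The validated selection used.
#' @param cancers Cancers to include; default all in \code{results}.
#' @param style Visualization style for the report.
#' @param includeAppendix Include the assumptions/references appendix.
#' @return List with elements \code{payload} (list) and \code{markdown}
#'   (character vector of lines).
#' @export
renderReport <- function(profile, results, registry, selection,
                         cancers = names(results),
                         style = c("line", "bar", "personograph"),
                         includeAppendix = TRUE) {
    style <- match.arg(style)
    bad <- setdiff(cancers, names(results))
    if (length(bad))
        stop("report requests cancer(s) not in the results: ",
             paste(bad, collapse = ", "), call. = FALSE)
    aCur <- profile@currentAge

    selectedIds <- c("colonoscopy", "aspirin", "hysterectomy",
                     "oophorectomy")[c(selection$colonoscopy,
                                       selection$aspirin,
                                       selection$hysterectomy,
                                       selection$oophorectomy)]
    if (selection$weightLossLb > 0)
        selectedIds <- c(selectedIds, "weight_change")
    caveats <- list()
    for (p in registry@params)
        if (p@id %in% selectedIds && nzchar(p@note))
            caveats[[paste(p@id, p@cancer, sep = ".")]] <- p@note

    tab <- lifetimeTable(results[cancers], variant = "composed")
    viz <- lapply(results[cancers], visualizationData, style = style,
                  currentAge = aCur)

    payload <- list(
        profile = list(gene = profile@gene, sex = profile@sex,
                       current_age = profile@currentAge,
                       race = profile@race, ethnicity = profile@ethnicity,
                       bmi = round(bmi(profile), 2)),
        selection = unclass(selection),
        lifetime_table = tab,
        visualization = viz,
        caveats = caveats)

    md <- c("# Personalized cancer risk report",
            "",
            sprintf("Profile: %s carrier, %s, age %d (BMI %.1f).",
                    profile@gene, profile@sex, profile@currentAge,
                    bmi(profile)),
            "",
            "## Lifetime risks (with selected interventions)",
            "",
            "| Cancer | Your risk | Average person | Relative |",
            "|---|---|---|---|",
            sprintf("| %s | %d%% | %d%% | %s |", tab$cancer, tab$user_pct,
                    tab$general_pct, tab$relative_label),
            "")
    for (cancer in tab$cancer) {
        v <- viz[[cancer]]
        md <- c(md, sprintf("## %s (%s view)", cancer, style), "")
        if (style == "line") {
            md <- c(md, sprintf(
                "Cumulative risk by age 85: baseline %d%%, with selections %d%%.",
                v$percent$baseline[length(v$percent$baseline)],
                v$percent$composed[length(v$percent$composed)]), "")
        } else if (style == "bar") {
            md <- c(md, sprintf(
                "Within 5 years: %d%% | By age 85: %d%% (with selections).",
                v$percent$composed[["within_5y"]],
                v$percent$composed[["by_85"]]), "")
        } else {
            md <- c(md, sprintf(
                "Shaded icons out of 20 -- within 5 years: %d | by age 85: %d (with selections).",
                v$icons$composed[["within_5y"]],
                v$icons$composed[["by_85"]]), "")
        }
    }
    if (length(caveats)) {
        md <- c(md, "## Notes on your selected interventions", "",
                unlist(lapply(caveats, function(x) c(paste0("- ", x)))))
    }
    if (includeAppendix) {
        md <- c(md, "", "## Assumptions and references", "",
                "- Risks are probabilities of a first diagnosis; risk of",
                "  recurrence for cancers already diagnosed is not assessed.",
                "- Intervention effects are combined additively; surgical",
                "  removal of an organ sets that organ's risk to zero.",
                "- Estimates are rounded for display; underlying",
                "  computations are full precision.")
    }
    list(payload = payload, markdown = md)
}

#' Write a rendered report to disk
#'
#' @param report Output of \code{\link{renderReport}}.
#' @param jsonPath,mdPath Output paths (either may be \code{NULL} to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
writeReport <- function(report, jsonPath = NULL, mdPath = NULL) {
    if (!is.null(jsonPath))
        jsonlite::write_json(report$payload, jsonPath, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    if (!is.null(mdPath))
        writeLines(report$markdown, mdPath, useBytes = TRUE)
    invisible(c(json = jsonPath, md = mdPath))
}
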