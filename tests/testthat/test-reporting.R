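test_that("snapshots use +5y/85 horizons with half-up percent rounding", {
    curve <- numeric(85)
    curve[41:45] <- c(0.05, 0.05, 0.05, 0.05, 0.026)
    s <- makeRiskSeries(curve, 40, "colorectal")
    ## cumulative at 45 is 0.226 -> 23%
    expect_equal(unname(snapshotSeries(s, 40)["within_5y"]), 23)
    ## zero series
    z <- makeRiskSeries(numeric(85), 40, "colorectal")
    expect_equal(unname(snapshotSeries(z, 40)), c(0, 0))
    ## near the horizon the 5-year snapshot truncates at 85
    s83 <- makeRiskSeries(curve, 83, "colorectal")
    expect_equal(unname(snapshotSeries(s83, 83)["within_5y"]),
                 unname(snapshotSeries(s83, 83)["by_85"]))
    ## exact half rounds up
    hc <- numeric(85); hc[50] <- 0.125
    expect_equal(unname(snapshotSeries(
        makeRiskSeries(hc, 40, "colorectal"), 40)["by_85"]), 13)
})

test_that("personograph quantization uses 20 icons at 5% granularity", {
    expect_equal(personographCounts(0), 0L)
    expect_equal(personographCounts(1), 20L)
    expect_equal(personographCounts(0.37), 7L)
    expect_equal(personographCounts(0.375), 8L)   # half up
    ## monotone nondecreasing and surjective onto 0..20
    grid <- personographCounts(seq(0, 1, by = 0.001))
    expect_true(all(diff(grid) >= 0))
    expect_setequal(unique(grid), 0:20)
    expect_error(personographCounts(1.2), "\\[0, 1\\]")
})

test_that("the lifetime table rounds, ranks and guards ratios", {
    mk <- function(cancer, userSum, genSum) {
        u <- numeric(85); u[60:69] <- userSum / 10
        g <- numeric(85); if (genSum > 0) g[60:69] <- genSum / 10
        list(baseline = makeRiskSeries(u, 30, cancer),
             singles = list(),
             composed = makeRiskSeries(u, 30, cancer, "composed"),
             general = makeRiskSeries(g, 30, cancer, "general"))
    }
    res <- list(colorectal = mk("colorectal", 0.40, 0.02),
                gastric = mk("gastric", 0.10, 0.01),
                brain = mk("brain", 0.30, 0))
    tab <- lifetimeTable(res, "baseline")
    ## ordered by descending user risk
    expect_equal(tab$cancer, c("colorectal", "brain", "gastric"))
    crc <- tab[tab$cancer == "colorectal", ]
    expect_equal(crc$user_pct, 40)
    expect_equal(crc$general_pct, 2)
    expect_equal(crc$relative_label, "20.0×")
    ## undefined ratio rendered as an em dash
    expect_equal(tab$relative_label[tab$cancer == "brain"], "—")
})

test_that("rounding happens only in the display layer", {
    curve <- numeric(85); curve[50] <- 0.123456
    s <- makeRiskSeries(curve, 40, "colorectal")
    ## engine output is full precision...
    expect_equal(lifetimeRisk(s), 0.123456)
    ## ...and only the display quantizes it
    expect_equal(unname(snapshotSeries(s, 40)["by_85"]), 12)
})

test_that("visualization payloads match their style contracts", {
    db <- simulateAcpDatabase(seed = 5)
    reg <- readInterventionRegistry()
    pr <- RiskProfile("MLH1", "male", 40, height = 1.75, weight = 85)
    sel <- interventionSelection(pr, reg, colonoscopy = TRUE)
    res <- profileRisks(pr, sel, db, reg)
    vLine <- visualizationData(res$colorectal, "line", 40)
    expect_equal(vLine$horizon_ages, 40:85)
    expect_true(all(vLine$percent$baseline == round(vLine$percent$baseline)))
    ## displayed percents never decrease with horizon age
    for (series in vLine$percent)
        expect_true(all(diff(series) >= 0))
    vBar <- visualizationData(res$colorectal, "bar", 40)
    expect_equal(vBar$snapshot_labels, c("within_5y", "by_85"))
    expect_length(vBar$percent$composed, 2)
    vIcons <- visualizationData(res$colorectal, "personograph", 40)
    expect_equal(vIcons$icons_total, 20L)
    expect_true(all(unlist(vIcons$icons) %in% 0:20))
})

test_that("reports are deterministic and carry intervention caveats", {
    db <- simulateAcpDatabase(seed = 5)
    reg <- readInterventionRegistry()
    pr <- RiskProfile("MLH1", "female", 45, height = 1.65, weight = 75)
    sel <- interventionSelection(pr, reg, colonoscopy = TRUE,
                                 aspirin = TRUE)
    res <- profileRisks(pr, sel, db, reg)
    r1 <- renderReport(pr, res, reg, sel, style = "bar")
    r2 <- renderReport(pr, res, reg, sel, style = "bar")
    expect_identical(r1, r2)
    ## colonoscopy selected -> the 3-year-interval caveat appears verbatim
    md <- paste(r1$markdown, collapse = "\n")
    expect_match(md, "every 3 years")
    expect_match(md, "600 mg")
    ## baseline-only report has no caveats section
    sel0 <- interventionSelection(pr, reg)
    r0 <- renderReport(pr, profileRisks(pr, sel0, db, reg), reg, sel0)
    expect_false(any(grepl("Notes on your selected",
                           r0$markdown)))
    ## unknown cancer in the spec is an error
    expect_error(renderReport(pr, res, reg, sel, cancers = "prostate"),
                 "not in the results")
    ## written artifacts round-trip
    jsonPath <- withr::local_tempfile(fileext = ".json")
    mdPath <- withr::local_tempfile(fileext = ".md")
    writeReport(r1, jsonPath = jsonPath, mdPath = mdPath)
    expect_true(file.exists(jsonPath) && file.exists(mdPath))
    payload <- jsonlite::fromJSON(jsonPath)
    expect_equal(payload$profile$gene, "MLH1")
})
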