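test_that("ACP CSV loading constructs validated curves and fills gaps", {
    rows <- sprintf("colorectal,MLH1,male,All_Races,All_Ethnicities,%d,0.01",
                    40:49)
    gp <- sprintf("colorectal,NONE,male,All_Races,All_Ethnicities,%d,0.001",
                  40:49)
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(acpCsvText(c(rows, gp)), path)
    expect_message(db <- readAcpTable(path), "filled")
    curve <- acpCurve(db, "colorectal", "MLH1", "male")
    expect_equal(sum(curve), 0.10)
    expect_equal(curve[40:49], rep(0.01, 10))
    expect_equal(curve[1:39], rep(0, 39))
})

test_that("invalid ACP rows are rejected with informative errors", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(acpCsvText(
        "colorectal,MLH1,male,All_Races,All_Ethnicities,40,-0.01"), path)
    expect_error(readAcpTable(path), "out of \\[0, 1\\]")

    writeLines(acpCsvText(sprintf(
        "colorectal,MLH1,male,All_Races,All_Ethnicities,%d,0.02", 1:60)),
        path)
    expect_error(readAcpTable(path), "exceeds 1.*MLH1")

    writeLines(acpCsvText(
        "colorectal,XYZ9,male,All_Races,All_Ethnicities,40,0.01"), path)
    expect_error(readAcpTable(path), "unknown gene")

    writeLines(acpCsvText(
        "colorectal,MLH1,male,All_Races,All_Ethnicities,90,0.01"), path)
    expect_error(readAcpTable(path), "outside 1..85")

    writeLines(acpCsvText(
        "colorectal,MLH1,male,All_Races,All_Ethnicities,40,0.01",
        header = "# schema: acp-csv/999"), path)
    expect_error(readAcpTable(path), "schema version mismatch")
})

test_that("write/read round trip reproduces probabilities bit-exactly", {
    db <- tinyDb()
    path <- withr::local_tempfile(fileext = ".csv")
    writeAcpTable(db, path)
    db2 <- readAcpTable(path)
    k1 <- order(strataTable(db)$gene)
    k2 <- order(strataTable(db2)$gene)
    expect_identical(db@acp[k1, ], db2@acp[k2, ],
                     ignore_attr = FALSE)
})

test_that("the association matrix gates stratum construction", {
    ## prostate is only associated with MSH2; an MLH1 prostate stratum is a
    ## blank cell and must fail database validity
    strata <- data.frame(
        cancer = c("prostate", "prostate"),
        gene = c("MLH1", "NONE"),
        sex = "male", race = "All_Races", ethnicity = "All_Ethnicities",
        stringsAsFactors = FALSE)
    acp <- matrix(0, 2, 85); acp[, 60] <- 0.01
    expect_error(
        lynchRisk:::newAcpDatabase(strata, acp) |> methods::validObject(),
        "inadmissible stratum")
    ## sex-incompatible pairs are likewise absent
    strata2 <- data.frame(cancer = "endometrial", gene = "NONE",
                          sex = "male", race = "All_Races",
                          ethnicity = "All_Ethnicities",
                          stringsAsFactors = FALSE)
    expect_error(
        lynchRisk:::newAcpDatabase(strata2, acp[1, , drop = FALSE]) |>
            methods::validObject(),
        "inadmissible stratum")
})

test_that("carrier strata require their general-population partner", {
    strata <- data.frame(cancer = "colorectal", gene = "MLH1", sex = "male",
                         race = "All_Races", ethnicity = "All_Ethnicities",
                         stringsAsFactors = FALSE)
    acp <- matrix(0, 1, 85); acp[, 60] <- 0.01
    expect_error(
        lynchRisk:::newAcpDatabase(strata, acp) |> methods::validObject(),
        "general-population stratum")
})

test_that("synthetic generation hits targets exactly and is deterministic", {
    spec <- data.frame(cancer = "colorectal", gene = "MLH1", sex = "male",
                       race = "All_Races", ethnicity = "All_Ethnicities",
                       lifetime_risk = 0.40, onset_mode = 60,
                       gp_lifetime_risk = 0.02, gp_onset_mode = 68,
                       stringsAsFactors = FALSE)
    db <- simulateAcpDatabase(spec, seed = 7)
    curve <- acpCurve(db, "colorectal", "MLH1", "male")
    expect_equal(sum(curve), 0.40, tolerance = 1e-12)
    expect_equal(which.max(curve), 60)
    ## same spec + seed => identical tables
    db2 <- simulateAcpDatabase(spec, seed = 7)
    expect_identical(db@acp, db2@acp)
    ## different seed changes the shape but not the targets
    db3 <- simulateAcpDatabase(spec, seed = 8)
    expect_false(identical(db@acp, db3@acp))
    expect_equal(sum(acpCurve(db3, "colorectal", "MLH1", "male")), 0.40,
                 tolerance = 1e-12)
    ## constructed lifetime ratio (0.40 / 0.02 = 20) is recovered by the
    ## downstream relative-risk operation on unconditional lifetime series
    gp <- acpCurve(db, "colorectal", "NONE", "male")
    rel <- relativeLifetimeRisk(makeRiskSeries(curve, 0, "colorectal"),
                                makeRiskSeries(gp, 0, "colorectal"))
    expect_equal(as.numeric(rel), 20, tolerance = 1e-9)
    ## target >= 1 is rejected
    spec$lifetime_risk <- 1.0
    expect_error(simulateAcpDatabase(spec, seed = 1), "\\(0, 1\\)")
})

test_that("every generated curve satisfies the penetrance invariants", {
    db <- simulateAcpDatabase(seed = 11)
    expect_true(all(db@acp >= 0) && all(db@acp <= 1))
    expect_true(all(rowSums(db@acp) <= 1 + 1e-9))
    ## unimodality: no interior local minimum below both neighbours
    for (i in seq_len(nStrata(db))) {
        d <- diff(db@acp[i, ])
        sign_changes <- sum(diff(sign(d[d != 0])) != 0)
        expect_lte(sign_changes, 1)
    }
})

test_that("default registry carries the published constants", {
    reg <- readInterventionRegistry()
    cst <- registryConstants(reg)
    expect_equal(cst$colonoscopy_adherence_p, 0.818)
    expect_equal(cst$lifetime_cap, 0.90)
    expect_equal(cst$ref_bmi_male, 27.1)
    expect_equal(cst$ref_bmi_female, 26.0)

    asp <- interventionParam(reg, "aspirin")
    expect_equal(nrow(asp@schedule), 3L)
    expect_equal(unname(asp@schedule[, 2]), c(0.56, 0.63, 0.65))

    colo <- interventionParam(reg, "colonoscopy")
    expect_equal(colo@value, 0.44)
    expect_setequal(colo@applicableGenes, c("MLH1", "MSH2"))
    expect_setequal(colo@generalizedGenes, LS_GENES)

    wcc <- interventionParam(reg, "weight_change", "colorectal")
    expect_equal(wcc@perStepValue, 0.07)
    expect_identical(wcc@generalizedGenes, "MLH1")
    wce <- interventionParam(reg, "weight_change", "endometrial")
    expect_equal(wce@perStepValue, 0.20)

    for (id in c("hysterectomy", "oophorectomy"))
        expect_equal(interventionParam(reg, id)@measureKind, "ZERO")
})

test_that("registry validation rejects a non-increasing schedule", {
    doc <- jsonlite::fromJSON(defaultRegistryPath(),
                              simplifyVector = FALSE)
    doc$interventions[[2]]$schedule <- list(list(2, 0.56), list(2, 0.63))
    path <- withr::local_tempfile(fileext = ".json")
    jsonlite::write_json(doc, path, auto_unbox = TRUE)
    expect_error(readInterventionRegistry(path), "strictly increasing")
})
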