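test_that("survival and future risk follow the conditioning formulas", {
    curve <- sparseCurve(1:3, rep(0.1, 3))
    expect_equal(survivalAt(curve, 0), 1)
    expect_equal(survivalAt(curve, 2), 0.8)
    expect_equal(survivalAt(numeric(85), 50), 1)
    expect_equal(futureRisk(curve, 1, 3), 0.2 / 0.9)
    expect_equal(futureRisk(curve, 2, 2), 0)
    expect_equal(futureRisk(curve, 0, 85), sum(curve))
    ## nondecreasing in horizon
    rc <- randomCurve()
    risks <- vapply(30:85, function(a) futureRisk(rc, 30, a), numeric(1))
    expect_true(all(diff(risks) >= 0))
    ## ACP values beyond the horizon never change the result
    rc2 <- rc; rc2[80:85] <- 0
    expect_equal(futureRisk(rc, 30, 70), futureRisk(rc2, 30, 70))
})

test_that("future risk agrees with a microsimulation oracle", {
    set.seed(2024)
    for (i in 1:5) {
        curve <- randomCurve(maxSum = 0.8)
        aCur <- sample(20:50, 1)
        aFut <- sample((aCur + 5):85, 1)
        n <- 200000
        draws <- sample(0:85, n, replace = TRUE,
                        prob = c(1 - sum(curve), curve))
        eligible <- draws == 0 | draws > aCur
        hit <- draws > aCur & draws <= aFut
        est <- sum(hit) / sum(eligible)
        se <- sqrt(est * (1 - est) / sum(eligible))
        expect_lt(abs(futureRisk(curve, aCur, aFut) - est),
                  3 * se + 1e-12)
    }
})

test_that("intervention dispatch matches each measure's pathway", {
    reg <- readInterventionRegistry()
    pr <- RiskProfile("MLH1", "female", 40, height = 1.65, weight = 80)
    base <- sparseCurve(45:70, rep(0.01, 26))
    ## colonoscopy: plain RR 0.44
    single <- sparseCurve(50, 0.05)
    out <- postInterventionCurve(single, pr, "colorectal",
                                 interventionParam(reg, "colonoscopy"))
    expect_equal(out[50], 0.022)
    ## aspirin: schedule applied from the current age
    asp <- postInterventionCurve(base, pr, "colorectal",
                                 interventionParam(reg, "aspirin"))
    expect_equal(asp, applyHrSchedule(base, aspirinSchedule(),
                                      startAge = 40))
    ## zero pounds of weight loss leaves the baseline unchanged
    wce <- interventionParam(reg, "weight_change", "endometrial")
    expect_identical(
        postInterventionCurve(base, pr, "endometrial", wce,
                              weightLossLb = 0), base)
    ## endometrial weight loss: OR path with 5-kg steps
    out2 <- postInterventionCurve(base, pr, "endometrial", wce,
                                  weightLossLb = 11)
    orExp <- 0.8^((11 / 2.20462) / 5)
    expect_equal(out2, applyOR(base, orExp))
    ## surgery zeroes the curve, hence all future risk
    hys <- postInterventionCurve(base, pr, "endometrial",
                                 interventionParam(reg, "hysterectomy"))
    expect_equal(hys, numeric(85))
    expect_equal(futureRisk(hys, 40, 85), 0)
    ## inapplicable gene-cancer pair is a menu violation
    pr2 <- RiskProfile("PMS2", "female", 40, height = 1.65, weight = 80)
    expect_error(postInterventionCurve(base, pr2, "endometrial",
                                       interventionParam(reg, "hysterectomy")),
                 "not applicable")
})

test_that("composition is additive in risk reductions, floored at zero", {
    curve <- sparseCurve(45:70, rep(0.012, 26))
    base <- makeRiskSeries(curve, 40, "colorectal", "baseline")
    s1 <- makeRiskSeries(applyRR(curve, 0.5), 40, "colorectal", "a")
    s2 <- makeRiskSeries(applyRR(curve, 0.8), 40, "colorectal", "b")
    comp <- composeSeries(base, list(s1, s2))
    expected <- pmax(0, base@cumulative -
                        (base@cumulative - s1@cumulative) -
                        (base@cumulative - s2@cumulative))
    expect_equal(comp@cumulative, expected)
    ## empty singles: baseline; one single: that series
    expect_equal(composeSeries(base)@cumulative, base@cumulative)
    expect_equal(composeSeries(base, list(s1))@cumulative, s1@cumulative)
    ## worked example: baseline 0.30, singles 0.15 and 0.25 -> 0.10
    expect_equal(0.30 - ((0.30 - 0.15) + (0.30 - 0.25)), 0.10)
    ## a surgery zero series drives the composition to zero
    zero <- makeRiskSeries(numeric(85), 40, "colorectal", "surgery")
    compz <- composeSeries(base, list(s1, zero))
    expect_equal(compz@cumulative, numeric(length(base@cumulative)))
    ## composed is always within [0, baseline]
    expect_true(all(comp@cumulative <= base@cumulative + 1e-12))
    expect_true(all(comp@cumulative >= 0))
    ## mismatched horizons are rejected
    s3 <- makeRiskSeries(curve, 41, "colorectal", "c")
    expect_error(composeSeries(base, list(s3)), "horizons")
})

test_that("menu logic enforces BMI bounds and gene eligibility", {
    reg <- readInterventionRegistry()
    ## BMI 24: no positive weight-loss option
    pr <- RiskProfile("MLH1", "female", 40, height = 1.70,
                      weight = 24 * 1.70^2)
    expect_identical(buildMenu(pr, reg)$weightLossRangeLb, 0:0)
    ## BMI 40, height 1.70: five-BMI-point branch binds -> 31 lb
    pr2 <- RiskProfile("MLH1", "female", 40, height = 1.70,
                       weight = 40 * 1.70^2)
    expect_equal(max(buildMenu(pr2, reg)$weightLossRangeLb),
                 floor(5 * 1.70^2 * 2.20462))
    expect_equal(max(buildMenu(pr2, reg)$weightLossRangeLb), 31)
    ## BMI 27, height 1.60: BMI-25 branch binds -> 11 lb
    pr3 <- RiskProfile("MLH1", "female", 40, height = 1.60,
                       weight = 27 * 1.60^2)
    expect_equal(max(buildMenu(pr3, reg)$weightLossRangeLb), 11)

    ## eligibility across all 5 genes x 2 sexes matches the association
    ## matrix and registry gene sets
    assoc <- geneCancerAssociations()
    for (gene in LS_GENES) {
        for (sex in SEX_LEVELS) {
            p <- RiskProfile(gene, sex, 40, height = 1.70, weight = 80)
            menu <- buildMenu(p, reg)
            expect_equal(menu$colonoscopy, assoc["colorectal", gene],
                         info = paste(gene, sex, "colonoscopy"))
            expect_equal(menu$aspirin, assoc["colorectal", gene],
                         info = paste(gene, sex, "aspirin"))
            expect_equal(menu$hysterectomy,
                         sex == "female" && assoc["endometrial", gene],
                         info = paste(gene, sex, "hysterectomy"))
            expect_equal(menu$oophorectomy,
                         sex == "female" && assoc["ovarian", gene],
                         info = paste(gene, sex, "oophorectomy"))
        }
    }
    ## prior surgery removes the offer
    pr4 <- RiskProfile("MLH1", "female", 40, height = 1.70, weight = 80,
                       hysterectomyDone = TRUE)
    expect_false(buildMenu(pr4, reg)$hysterectomy)
    expect_true(buildMenu(pr4, reg)$oophorectomy)
})

test_that("profileRisks assembles the per-cancer picture", {
    db <- simulateAcpDatabase(seed = 3)
    reg <- readInterventionRegistry()
    ## prior colorectal cancer removes the colorectal series
    prHist <- RiskProfile("MLH1", "male", 45, height = 1.75, weight = 80,
                          priorCancers = "colorectal")
    resHist <- profileRisks(prHist, NULL, db, reg)
    expect_false("colorectal" %in% names(resHist))
    expect_true("gastric" %in% names(resHist))
    ## no selections: composed equals baseline everywhere
    pr <- RiskProfile("MSH6", "male", 50, height = 1.80, weight = 85)
    res <- profileRisks(pr, NULL, db, reg)
    for (cc in names(res))
        expect_equal(res[[cc]]$composed@cumulative,
                     res[[cc]]$baseline@cumulative)
    ## one intervention: composed equals that single series
    sel <- interventionSelection(pr, reg, colonoscopy = TRUE)
    res2 <- profileRisks(pr, sel, db, reg)
    expect_equal(res2$colorectal$composed@cumulative,
                 res2$colorectal$singles$colonoscopy@cumulative)
    ## every composed series is pointwise <= baseline and >= 0
    pr3 <- RiskProfile("MLH1", "female", 40, height = 1.65, weight = 80)
    sel3 <- interventionSelection(pr3, reg, colonoscopy = TRUE,
                                  aspirin = TRUE, weightLossLb = 5,
                                  hysterectomy = TRUE)
    res3 <- profileRisks(pr3, sel3, db, reg)
    for (cc in names(res3)) {
        expect_true(all(res3[[cc]]$composed@cumulative <=
                            res3[[cc]]$baseline@cumulative + 1e-12))
        expect_true(all(res3[[cc]]$composed@cumulative >= 0))
    }
    expect_equal(lifetimeRisk(res3$endometrial$composed), 0)
    ## missing stratum yields a descriptive error
    expect_error(profileRisks(
        RiskProfile("MLH1", "male", 40, race = "Black",
                    height = 1.75, weight = 80), NULL, db, reg),
        "no penetrance stratum")
})

test_that("relative lifetime risk guards division by zero", {
    curve <- sparseCurve(50:60, rep(0.04, 11))
    gen <- sparseCurve(50:60, rep(0.04, 11) / 22)
    user <- makeRiskSeries(curve, 40, "colorectal")
    general <- makeRiskSeries(gen, 40, "colorectal", "general")
    expect_equal(as.numeric(relativeLifetimeRisk(user, user)), 1)
    rel <- relativeLifetimeRisk(user, general)
    expect_equal(as.numeric(rel),
                 lifetimeRisk(user) / lifetimeRisk(general))
    zero <- makeRiskSeries(numeric(85), 40, "colorectal", "general")
    relz <- relativeLifetimeRisk(user, zero)
    expect_true(is.na(relz))
    expect_true(attr(relz, "undefined"))
})

test_that("profile selections are validated against the menu", {
    reg <- readInterventionRegistry()
    pr <- RiskProfile("MSH2", "male", 40, height = 1.75, weight = 80)
    expect_error(interventionSelection(pr, reg, hysterectomy = TRUE),
                 "not on the menu")
    expect_error(interventionSelection(pr, reg, weightLossLb = 500),
                 "outside")
    sel <- interventionSelection(pr, reg, colonoscopy = TRUE)
    expect_true(sel$colonoscopy)
})
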