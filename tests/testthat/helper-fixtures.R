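## Shared fixtures, built in code at test time.

## A single-stratum curve with given (age, value) pairs, zeros elsewhere.
sparseCurve <- function(ages, values) {
    x <- numeric(85)
    x[ages] <- values
    x
}

## Random valid penetrance curve: positive mass on a contiguous late-onset
## window, lifetime sum drawn in (0, maxSum), per-age values kept below 0.5
## so measure conversions stay in range.
randomCurve <- function(maxSum = 0.95) {
    a0 <- sample(20:60, 1)
    a1 <- sample(a0:85, 1)
    w <- runif(a1 - a0 + 1)
    target <- runif(1, 0.01, maxSum)
    x <- sparseCurve(a0:a1, w * target / sum(w))
    if (max(x) > 0.5) x <- x * (0.5 / max(x))
    x
}

## Small two-stratum database (one carrier + its general-population pair)
## written straight through the constructor used by the readers.
tinyDb <- function() {
    simulateAcpDatabase(
        data.frame(cancer = "colorectal", gene = "MLH1", sex = "male",
                   race = "All_Races", ethnicity = "All_Ethnicities",
                   lifetime_risk = 0.40, onset_mode = 60,
                   gp_lifetime_risk = 0.02, gp_onset_mode = 68,
                   stringsAsFactors = FALSE),
        seed = 7)
}

## ACP CSV text for hand-built stratum rows.
acpCsvText <- function(rows, header = "# schema: acp-csv/1") {
    c(header, "cancer,gene,sex,race,ethnicity,age,acp", rows)
}

aspirinSchedule <- function()
    interventionParam(readInterventionRegistry(), "aspirin")@schedule
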