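## AcpDatabase construction, accessors, CSV interchange.

## Internal constructor from a strata data.frame + matrix.
newAcpDatabase <- function(strata, acp, provenance = NULL, metadata = list()) {
    strata <- as.data.frame(strata, stringsAsFactors = FALSE)
    rownames(strata) <- NULL
    if (is.null(provenance)) provenance <- rep("", nrow(strata))
    dimnames(acp) <- list(NULL, paste0("age", AGE_GRID))
    new("AcpDatabase", strata = strata, acp = acp,
        provenance = provenance, metadata = metadata)
}

acpKey <- function(cancer, gene, sex, race, ethnicity)
    paste(cancer, gene, sex, race, ethnicity, sep = "|")

dbKeys <- function(x)
    with(x@strata, acpKey(cancer, gene, sex, race, ethnicity))

#' @rdname acpCurve
#' @export
setMethod("acpCurve", "AcpDatabase",
          function(x, cancer, gene, sex, race = "All_Races",
                   ethnicity = "All_Ethnicities", ...) {
    assertEnum(cancer, CANCER_TYPES, "cancer")
    assertEnum(gene, GENE_LEVELS, "gene")
    assertEnum(sex, SEX_LEVELS, "sex")
    assertEnum(race, RACE_LEVELS, "race")
    assertEnum(ethnicity, ETHNICITY_LEVELS, "ethnicity")
    i <- match(acpKey(cancer, gene, sex, race, ethnicity), dbKeys(x))
    if (is.na(i))
        stop("no penetrance stratum ",
             formatStratum(cancer, gene, sex, race, ethnicity),
             " in the database", call. = FALSE)
    unname(drop(x@acp[i, ]))
})

#' @rdname strataTable
#' @export
setMethod("strataTable", "AcpDatabase", function(x) {
    out <- x@strata
    out$lifetime_risk <- rowSums(x@acp)
    out$provenance <- x@provenance
    out
})

#' @rdname nStrata
#' @export
setMethod("nStrata", "AcpDatabase", function(x) nrow(x@strata))

setMethod("show", "AcpDatabase", function(object) {
    st <- object@strata
    cat("AcpDatabase with", nrow(st), "strata over ages 1..", MAX_AGE, "\n")
    cat("  cancers:", paste(sort(unique(st$cancer)), collapse = ", "), "\n")
    cat("  genes:  ", paste(sort(unique(st$gene)), collapse = ", "), "\n")
    ver <- object@metadata$schema_version
    if (!is.null(ver)) cat("  schema: ", ver, "\n")
    invisible(NULL)
})

ACP_SCHEMA_VERSION <- "acp-csv/1"

#' Read an ACP table from CSV
#'
#' Reads the one-row-per-stratum-age interchange format: columns
#' \code{cancer, gene, sex, race, ethnicity, age, acp}, UTF-8, with
#' \code{#}-prefixed header comments carrying the schema version and
#' provenance. Ages missing within 1..85 for a stratum are filled with 0
#' (reported via a message); unknown labels, malformed rows and
#' invariant violations are errors naming the offending row or stratum.
#'
#' @param path Path to the CSV file.
#' @param schemaVersion Expected schema label recorded in the header
#'   comment; a mismatch is an error.
#' @return A validated \code{\linkS4class{AcpDatabase}}.
#' @seealso \code{\link{writeAcpTable}} for the inverse; the round trip is
#'   bit-exact.
#' @export
readAcpTable <- function(path, schemaVersion = ACP_SCHEMA_VERSION) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    headerLines <- character(0)
    con <- file(path, "r", encoding = "UTF-8")
    on.exit(close(con))
    repeat {
        line <- readLines(con, n = 1L)
        if (!length(line) || !startsWith(line, "#")) break
        headerLines <- c(headerLines, line)
    }
    close(con); on.exit(NULL)
    verLine <- grep("^# *schema:", headerLines, value = TRUE)
    if (length(verLine)) {
        ver <- trimws(sub("^# *schema:", "", verLine[1L]))
        if (!identical(ver, schemaVersion))
            stop("schema version mismatch: file declares '", ver,
                 "', expected '", schemaVersion, "'", call. = FALSE)
    }
    df <- tryCatch(
        read.table(path, header = TRUE, sep = ",", comment.char = "#",
                   colClasses = c(cancer = "character", gene = "character",
                                  sex = "character", race = "character",
                                  ethnicity = "character", age = "integer",
                                  acp = "numeric"),
                   fileEncoding = "UTF-8"),
        error = function(e) stop("malformed ACP CSV: ", conditionMessage(e),
                                 call. = FALSE))
    need <- c("cancer", "gene", "sex", "race", "ethnicity", "age", "acp")
    if (!all(need %in% names(df)))
        stop("ACP CSV must have columns: ", paste(need, collapse = ", "),
             call. = FALSE)
    if (anyNA(df$age) || anyNA(df$acp)) {
        bad <- which(is.na(df$age) | is.na(df$acp))[1L]
        stop("malformed row ", bad, " in ACP CSV (missing age or acp)",
             call. = FALSE)
    }
    if (any(df$age < 1L | df$age > MAX_AGE)) {
        bad <- which(df$age < 1L | df$age > MAX_AGE)[1L]
        stop("row ", bad, ": age ", df$age[bad], " outside 1..", MAX_AGE,
             call. = FALSE)
    }
    for (col in c("cancer", "gene", "sex", "race", "ethnicity")) {
        levels <- switch(col, cancer = CANCER_TYPES, gene = GENE_LEVELS,
                         sex = SEX_LEVELS, race = RACE_LEVELS,
                         ethnicity = ETHNICITY_LEVELS)
        badv <- setdiff(unique(df[[col]]), levels)
        if (length(badv))
            stop("unknown ", col, " label(s): ", paste(badv, collapse = ", "),
                 call. = FALSE)
    }
    if (any(df$acp < 0 | df$acp > 1)) {
        i <- which(df$acp < 0 | df$acp > 1)[1L]
        stop("probability out of [0, 1] in stratum ",
             formatStratum(df$cancer[i], df$gene[i], df$sex[i], df$race[i],
                           df$ethnicity[i]), " at age ", df$age[i],
             call. = FALSE)
    }
    key <- acpKey(df$cancer, df$gene, df$sex, df$race, df$ethnicity)
    uk <- unique(key)
    first <- match(uk, key)
    strata <- df[first, c("cancer", "gene", "sex", "race", "ethnicity")]
    acp <- matrix(0, nrow = length(uk), ncol = MAX_AGE)
    nFilled <- 0L
    for (j in seq_along(uk)) {
        rows <- df[key == uk[j], ]
        if (anyDuplicated(rows$age))
            stop("duplicate age rows in stratum ",
                 formatStratum(rows$cancer[1L], rows$gene[1L], rows$sex[1L],
                               rows$race[1L], rows$ethnicity[1L]),
                 call. = FALSE)
        acp[j, rows$age] <- rows$acp
        nFilled <- nFilled + (MAX_AGE - nrow(rows))
        if (sum(acp[j, ]) > 1 + 1e-9)
            stop("lifetime probability mass ", format(sum(acp[j, ])),
                 " exceeds 1 in stratum ",
                 formatStratum(rows$cancer[1L], rows$gene[1L], rows$sex[1L],
                               rows$race[1L], rows$ethnicity[1L]),
                 call. = FALSE)
    }
    if (nFilled > 0L)
        message("filled ", nFilled, " missing stratum-age cells with 0")
    prov <- grep("^# *provenance:", headerLines, value = TRUE)
    prov <- if (length(prov)) trimws(sub("^# *provenance:", "", prov[1L])) else ""
    db <- newAcpDatabase(strata, acp,
                         provenance = rep(prov, length(uk)),
                         metadata = list(schema_version = schemaVersion))
    validObject(db)
    db
}

#' Write an ACP table to CSV
#'
#' Inverse of \code{\link{readAcpTable}}: writes one row per stratum-age
#' with full-precision probabilities (17 significant digits, so that the
#' read/write round trip is bit-exact), preceded by \code{#} header
#' comments recording the schema version and provenance.
#'
#' @param db An \code{\linkS4class{AcpDatabase}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAcpTable <- function(db, path) {
    stopifnot(is(db, "AcpDatabase"))
    st <- db@strata
    n <- nrow(st)
    rows <- data.frame(
        cancer = rep(st$cancer, each = MAX_AGE),
        gene = rep(st$gene, each = MAX_AGE),
        sex = rep(st$sex, each = MAX_AGE),
        race = rep(st$race, each = MAX_AGE),
        ethnicity = rep(st$ethnicity, each = MAX_AGE),
        age = rep(AGE_GRID, times = n),
        acp = sprintf("%.17g", as.vector(t(db@acp))),
        stringsAsFactors = FALSE)
    ver <- db@metadata$schema_version
    if (is.null(ver)) ver <- ACP_SCHEMA_VERSION
    prov <- unique(db@provenance)
    prov <- prov[nzchar(prov)][1]
    header <- c(paste0("# schema: ", ver),
                if (!is.na(prov)) paste0("# provenance: ", prov))
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(header, con)
    write.table(rows, con, sep = ",", quote = FALSE, row.names = FALSE)
    close(con)
    invisible(path)
}
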