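# Encounter parsing, condition dictionaries, indicator-matrix construction
# and matrix round-trips.

write_encounters <- function(rows, path = tempfile(fileext = ".csv")) {
    writeLines(c("patient_id,icd9", rows), path)
    path
}

test_that("loadEncounters parses valid rows and reports malformed ones", {
    p <- write_encounters(c('P1,303.90', 'P1,401.1', 'P2,250.00'))
    enc <- loadEncounters(p)
    expect_equal(nrow(enc), 3)
    expect_equal(length(unique(enc$patient_id)), 2)
    expect_equal(nrow(attr(enc, "parse_report")), 0)

    p2 <- write_encounters(c('P1,303.90', 'P2,abc', 'P3,V45.81', 'P4,E935.2'))
    expect_warning(enc2 <- loadEncounters(p2), "malformed")
    expect_equal(nrow(enc2), 3)
    rep <- attr(enc2, "parse_report")
    expect_equal(rep$line, 3L)  # line number includes the header
    expect_equal(rep$icd9, "abc")
})

test_that("loadEncounters errors on missing columns and empty files", {
    p <- tempfile(fileext = ".csv")
    writeLines("patient_id,code", p)
    expect_error(loadEncounters(p), "missing required column")
    p2 <- write_encounters(character())
    expect_error(loadEncounters(p2), "empty input")
})

test_that("indicator matrix applies prefix matching and min_occurrences", {
    dict <- list(alcohol_like = c("303.*"), htn = c("401.*"),
                 dm = c("250.00"))
    p <- write_encounters(c("P1,303.90", "P1,303.90", "P2,303",
                            "P2,401.1", "P3,250.00", "P3,250.01"))
    enc <- loadEncounters(p)
    m <- buildIndicatorMatrix(enc, dict)
    X <- indicators(m)
    # prefix "303.*" matches both "303.90" and bare "303"
    expect_equal(unname(X[, "alcohol_like"]), c(1, 1, 0))
    expect_equal(unname(X[, "htn"]), c(0, 1, 0))
    # exact pattern "250.00" does not match "250.01"
    expect_equal(unname(X["P3", "dm"]), 1)
    # all-zero rows are retained (filtering is a later stage)
    expect_true(all(rownames(X) == c("P1", "P2", "P3")))
    # min_occurrences = 2: only duplicated encounters qualify
    m2 <- buildIndicatorMatrix(enc, dict, min_occurrences = 2)
    expect_equal(unname(indicators(m2)[, "alcohol_like"]), c(1, 0, 0))
    expect_equal(sum(indicators(m2)[, "htn"]), 0)
})

test_that("indicator construction is idempotent under row duplication and
           matches a brute-force marginal scan", {
    set.seed(41)
    dict <- list(a = c("303.*"), b = c("401.*", "402.*"), c = c("250.*"))
    codes <- c("303.1", "303.90", "401.0", "402.9", "250.00", "799.9")
    rows <- sprintf("P%d,%s", sample(1:8, 40, TRUE), sample(codes, 40, TRUE))
    p <- write_encounters(rows)
    enc <- loadEncounters(p)
    m1 <- buildIndicatorMatrix(enc, dict)
    enc_dup <- rbind(enc, enc)
    m2 <- buildIndicatorMatrix(enc_dup, dict)
    expect_equal(indicators(m2)[rownames(indicators(m1)), ],
                 indicators(m1))
    # brute-force column marginals
    for (cond in names(dict)) {
        pats <- dict[[cond]]
        match1 <- vapply(seq_len(nrow(enc)), function(r) {
            any(vapply(pats, function(pt)
                startsWith(gsub(".", "", enc$icd9[r], fixed = TRUE),
                           gsub(".", "", sub("\\.?\\*$", "", pt), fixed = TRUE)),
                logical(1)))
        }, logical(1))
        expect_equal(sum(indicators(m1)[, cond]),
                     length(unique(enc$patient_id[match1])))
    }
})

test_that("dictionary reading accepts YAML record and map formats", {
    y1 <- tempfile(fileext = ".yaml")
    writeLines(c("alcohol:", "  - '303.*'", "htn:", "  - '401.*'"), y1)
    d1 <- readConditionDictionary(y1)
    expect_named(d1, c("alcohol", "htn"))
    j <- tempfile(fileext = ".json")
    writeLines('[{"name":"alcohol","code_patterns":["303.*"]},
                {"name":"htn","code_patterns":["401.*"]}]', j)
    d2 <- readConditionDictionary(j)
    expect_equal(d1, d2)
    shipped <- system.file("extdata", "condition_dictionary_synthetic.yaml",
                           package = "comirt")
    expect_gt(length(readConditionDictionary(shipped)), 10)
})

test_that("matrix CSV round-trip is the identity, including missing cells", {
    m <- tiny_matrix()
    p <- tempfile(fileext = ".csv")
    writeMatrix(m, p)
    m2 <- readMatrix(p)
    expect_identical(indicators(m2), indicators(m))
    # empty matrix round-trips as a header-only file
    m0 <- m[integer(0), ]
    p0 <- tempfile(fileext = ".csv")
    writeMatrix(m0, p0)
    expect_equal(dim(readMatrix(p0)), c(0, 4))
})

test_that("non-binary cells are format errors naming row and column", {
    p <- tempfile(fileext = ".csv")
    writeLines(c("patient_id,htn,diabetes", "P1,1,0", "P2,0,2"), p)
    expect_error(readMatrix(p), 'row 2, col "diabetes"')
})
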