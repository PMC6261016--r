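# Reading encounter records and condition dictionaries, and building the
# patients x conditions indicator matrix from ICD-9 codes.

# ICD-9 lexical form: 3 digits, or V + 2 digits, or E + 3 digits, each with an
# optional decimal part (up to 2 digits; 1 for E codes).
.icd9Regex <- "^([0-9]{3}(\\.[0-9]{1,2})?|V[0-9]{2}(\\.[0-9]{1,2})?|E[0-9]{3}(\\.[0-9])?)$"

.isValidICD9 <- function(code) grepl(.icd9Regex, code)

# Comparison form: decimal point stripped, so prefix families work by simple
# string prefix ("303.*" => prefix "303" matches "303", "303.9", "303.90").
.normalizeICD9 <- function(code) gsub(".", "", code, fixed = TRUE)

#' Load encounter records from CSV
#'
#' Reads long-format encounter records (one row per diagnosis code per
#' encounter). Required columns: \code{patient_id}, \code{icd9}; optional:
#' \code{setting} (inpatient/outpatient/community) and \code{date}
#' (ISO 8601). Rows whose code fails the ICD-9 lexical check are dropped and
#' reported (with line numbers) in the \code{"parse_report"} attribute and a
#' warning; all other rows are kept in file order.
#'
#' @param path CSV file path.
#' @param sep field separator (default ",").
#' @return data.frame of encounters with attribute \code{"parse_report"}
#'   (data.frame: line, patient_id, icd9, reason).
#' @export
loadEncounters <- function(path, sep = ",") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, sep = sep, colClasses = "character",
                          check.names = FALSE)
    req <- c("patient_id", "icd9")
    miss <- setdiff(req, names(df))
    if (length(miss))
        stop("format error: missing required column(s): ",
             paste(miss, collapse = ", "))
    if (nrow(df) == 0) stop("empty input: no encounter rows in ", path)
    bad_id <- !nzchar(trimws(df$patient_id))
    bad_code <- !.isValidICD9(trimws(df$icd9))
    bad <- bad_id | bad_code
    report <- data.frame(
        line = which(bad) + 1L,  # +1 for the header line
        patient_id = df$patient_id[bad],
        icd9 = df$icd9[bad],
        reason = ifelse(bad_id[bad], "empty patient_id",
                        "malformed ICD-9 code"),
        stringsAsFactors = FALSE)
    if (nrow(report))
        warning(sprintf("%d malformed encounter row(s) rejected", nrow(report)))
    out <- df[!bad, , drop = FALSE]
    out$patient_id <- trimws(out$patient_id)
    out$icd9 <- trimws(out$icd9)
    rownames(out) <- NULL
    attr(out, "parse_report") <- report
    out
}

#' Read a condition-definition dictionary
#'
#' A dictionary maps condition names to ICD-9 code patterns (exact codes or
#' prefix wildcards such as \code{"303.*"}), emulating the code-family tables
#' used by comorbidity scales. Accepted formats: YAML or JSON, either a list
#' of \code{\{name, code_patterns\}} records or a named map of pattern lists.
#'
#' @param path YAML/JSON file path.
#' @return Named list: condition name -> character vector of patterns.
#' @export
readConditionDictionary <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.data.frame(raw))  # JSON array of {name, code_patterns} records
        raw <- lapply(seq_len(nrow(raw)), function(i)
            list(name = raw$name[i],
                 code_patterns = unlist(raw$code_patterns[i])))
    dict <- if (!is.null(names(raw)) && !is.list(raw[[1]])) {
        lapply(raw, as.character)
    } else if (all(vapply(raw, function(e)
        all(c("name", "code_patterns") %in% names(e)), logical(1)))) {
        stats::setNames(lapply(raw, function(e) as.character(e$code_patterns)),
                        vapply(raw, function(e) e$name, character(1)))
    } else {
        lapply(raw, function(e) as.character(unlist(e)))
    }
    .validateDictionary(dict)
    dict
}

.validateDictionary <- function(dict) {
    if (!length(dict)) stop("condition dictionary is empty")
    if (is.null(names(dict)) || anyDuplicated(names(dict)))
        stop("condition names must be unique and non-empty")
    for (nm in names(dict)) {
        pats <- dict[[nm]]
        if (!length(pats)) stop("condition '", nm, "' has no patterns")
        bare <- sub("\\.?\\*$", "", pats)
        ok <- .isValidICD9(pats) |
            grepl("^([0-9]{1,3}|V[0-9]{0,2}|E[0-9]{0,3})(\\.[0-9]{0,2})?$", bare)
        if (!all(ok))
            stop("condition '", nm, "' has invalid pattern(s): ",
                 paste(pats[!ok], collapse = ", "))
    }
    invisible(TRUE)
}

# One pattern -> function of normalized codes. "X.*"/"X*" are prefix
# patterns; anything else is an exact (normalized) code.
.matchesPattern <- function(codes_norm, pattern) {
    if (grepl("\\*$", pattern)) {
        pref <- .normalizeICD9(sub("\\.?\\*$", "", pattern))
        startsWith(codes_norm, pref)
    } else {
        codes_norm == .normalizeICD9(pattern)
    }
}

#' Build the binary indicator matrix from encounters
#'
#' Cell (p, c) is 1 iff patient p has at least \code{min_occurrences}
#' encounters whose ICD-9 code matches any pattern of condition c, else 0.
#' Matching is by string prefix on the decimal-stripped code, so pattern
#' \code{"303.*"} matches "303", "303.9" and "303.90". Patients with no
#' matching codes keep an all-zero row (cohort filtering is a later stage).
#' Missingness never arises here: absence of a code is coded 0.
#'
#' @param encounters data.frame from \code{\link{loadEncounters}}.
#' @param dictionary named list from \code{\link{readConditionDictionary}}.
#' @param min_occurrences positive integer; encounters required before a
#'   condition is flagged (default 1, i.e. any single occurrence).
#' @param settings optional character vector restricting encounter settings.
#' @param window optional length-2 Date (or ISO string) vector; when the
#'   encounters carry dates, only encounters within [window[1], window[2]]
#'   are counted.
#' @return \code{\link{DiagnosisMatrix-class}}, one row per distinct patient
#'   (first-appearance order), one column per dictionary entry.
#' @export
buildIndicatorMatrix <- function(encounters, dictionary, min_occurrences = 1,
                                 settings = NULL, window = NULL) {
    .validateDictionary(dictionary)
    stopifnot(min_occurrences >= 1)
    df <- encounters
    if (!is.null(settings) && "setting" %in% names(df))
        df <- df[df$setting %in% settings, , drop = FALSE]
    if (!is.null(window) && "date" %in% names(df)) {
        d <- as.Date(df$date)
        df <- df[!is.na(d) & d >= as.Date(window[1]) &
                     d <= as.Date(window[2]), , drop = FALSE]
    }
    pats_all <- unique(encounters$patient_id)
    codes_norm <- .normalizeICD9(df$icd9)
    conds <- names(dictionary)
    M <- matrix(0, length(pats_all), length(conds),
                dimnames = list(pats_all, conds))
    hit_by_cond <- vector("list", length(conds))
    for (ci in seq_along(conds)) {
        hit <- rep(FALSE, nrow(df))
        for (p in dictionary[[ci]])
            hit <- hit | .matchesPattern(codes_norm, p)
        hit_by_cond[[ci]] <- hit
        if (any(hit)) {
            cnt <- table(df$patient_id[hit])
            ok <- names(cnt)[cnt >= min_occurrences]
            M[ok, ci] <- 1
        }
    }
    # warn (once) when a single encounter row matched two conditions
    if (length(conds) > 1 && nrow(df) > 0) {
        nmatch <- Reduce(`+`, lapply(hit_by_cond, as.integer))
        if (any(nmatch > 1))
            warning(sprintf(
                "%d encounter(s) matched patterns of multiple conditions; all matching columns were set",
                sum(nmatch > 1)))
    }
    DiagnosisMatrix(M)
}

#' Read / write a DiagnosisMatrix as CSV
#'
#' Layout: first column \code{patient_id}, remaining columns one per
#' condition, cells in \{0, 1, NA-token\}. \code{writeMatrix} followed by
#' \code{readMatrix} is the identity on values, ids and column order.
#'
#' @param path CSV file path.
#' @param na_token string representing missing cells (default "NA").
#' @return \code{readMatrix}: a \code{\link{DiagnosisMatrix-class}};
#'   \code{writeMatrix}: the path, invisibly.
#' @export
readMatrix <- function(path, na_token = "NA") {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
    if (!"patient_id" %in% names(df))
        stop("format error: first column must be patient_id")
    ids <- df$patient_id
    cols <- setdiff(names(df), "patient_id")
    M <- matrix(NA_real_, nrow(df), length(cols),
                dimnames = list(ids, cols))
    for (j in seq_along(cols)) {
        v <- df[[cols[j]]]
        isna <- v == na_token | is.na(v)
        num <- suppressWarnings(as.numeric(v))
        bad <- !isna & (is.na(num) | !(num %in% c(0, 1)))
        if (any(bad))
            stop(sprintf("format error: non-binary cell at (row %d, col \"%s\"): \"%s\"",
                         which(bad)[1], cols[j], v[which(bad)[1]]))
        M[!isna, j] <- num[!isna]
    }
    DiagnosisMatrix(M)
}

#' @rdname readMatrix
#' @param matrix a DiagnosisMatrix.
#' @export
writeMatrix <- function(matrix, path, na_token = "NA") {
    stopifnot(is(matrix, "DiagnosisMatrix"))
    M <- indicators(matrix)
    ids <- rownames(M)
    if (is.null(ids)) ids <- character(nrow(M))
    df <- data.frame(patient_id = ids, check.names = FALSE,
                     stringsAsFactors = FALSE)
    for (j in seq_len(ncol(M))) df[[colnames(M)[j]]] <- M[, j]
    utils::write.csv(df, path, row.names = FALSE, na = na_token,
                     quote = FALSE)
    invisible(path)
}
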