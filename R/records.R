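# VA records: loading, inclusion filtering, age stratification.

# Months-to-days conversion and the 59-completed-months cap used throughout.
DAYS_PER_MONTH <- 30.4375
MAX_AGE_DAYS <- 1826L  # floor(59 * 30.4375) = 1795 < 1826 = 60 * 30.4375 rounded
NEONATE_MAX_DAYS <- 27L

RESERVED_COLUMNS <- c("record_id", "live_birth", "age_at_death_days",
                      "age_at_death_months", "questionnaire_type",
                      "interview_complete", "survey_weight",
                      "stratum_id", "psu_id", "comparator_cause")

#' Construct a VA record table
#'
#' One row per deceased child. Reserved columns: `record_id`, `live_birth`
#' (`"yes"`/`"no"`/`"unknown"`), `age_at_death_days`, `questionnaire_type`
#' (`"neonatal"`/`"child"`), `survey_weight` (> 0), `stratum_id`, `psu_id`,
#' and optionally `age_at_death_months`, `interview_complete`,
#' `comparator_cause`. All remaining columns must be codebook item ids;
#' binary/categorical responses are character, counts and durations numeric.
#'
#' @param df A data.frame with the columns above.
#' @param codebook The [va_codebook()] the response columns belong to.
#' @return A `va_records` data.frame carrying the codebook as an attribute.
#' @export
va_records <- function(df, codebook) {
  stopifnot(is.data.frame(df), inherits(codebook, "va_codebook"))
  extra <- setdiff(names(df), c(RESERVED_COLUMNS, codebook_ids(codebook)))
  if (length(extra)) {
    stop("columns not in codebook or reserved set: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  needed <- c("record_id", "live_birth", "age_at_death_days",
              "questionnaire_type", "survey_weight", "stratum_id", "psu_id")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("missing reserved columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$record_id)) stop("duplicate record_id", call. = FALSE)
  bad_w <- !is.na(df$survey_weight) & df$survey_weight <= 0
  if (any(bad_w)) {
    stop("non-positive survey_weight for record(s): ",
         paste(df$record_id[bad_w], collapse = ", "), call. = FALSE)
  }
  attr(df, "codebook") <- codebook
  class(df) <- c("va_records", "data.frame")
  df
}

records_codebook <- function(records) {
  cb <- attr(records, "codebook")
  if (is.null(cb)) stop("records carry no codebook attribute", call. = FALSE)
  cb
}

parse_response <- function(x, item) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", item$missing_codes)] <- NA_character_
  if (item$kind %in% c("count", "duration_days")) {
    out <- suppressWarnings(as.numeric(x))
    out[!is.na(out) & out < 0] <- NA_real_
    out
  } else {
    low <- tolower(x)
    if (item$kind == "binary") {
      low[low %in% c("y", "1", "true")] <- "yes"
      low[low %in% c("n", "0", "false")] <- "no"
      low[!low %in% c("yes", "no") & !is.na(low)] <- NA_character_
    } else {
      low[!low %in% item$allowed_values & !is.na(low)] <- NA_character_
    }
    low
  }
}

#' Load VA records from CSV
#'
#' Every non-reserved column must be a codebook item; an unknown column is
#' a hard error naming the offenders. Missing codes declared in the
#' codebook (plus empty cells) are mapped to `NA`. An unparseable age is
#' loaded as a missing age (the record is then dropped later by the
#' inclusion filter, not at load time). If `age_at_death_days` is missing
#' but `age_at_death_months` is present, days are derived with the
#' 30.4375 days/month convention.
#'
#' @param path CSV path (UTF-8, one row per death).
#' @param codebook A [va_codebook()].
#' @return A [va_records()] table with the same number of rows as the CSV.
#' @export
load_records <- function(path, codebook) {
  stopifnot(inherits(codebook, "va_codebook"))
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = character())
  unknown <- setdiff(names(raw), c(RESERVED_COLUMNS, codebook_ids(codebook)))
  if (length(unknown)) {
    stop("unknown column(s) not in codebook: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  blank_na <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "NA")] <- NA_character_
    x
  }
  num <- function(x) suppressWarnings(as.numeric(blank_na(x)))
  col <- function(nm) if (nm %in% names(raw)) raw[[nm]] else rep(NA_character_, n)

  age_days <- num(col("age_at_death_days"))
  age_months <- num(col("age_at_death_months"))
  use_m <- is.na(age_days) & !is.na(age_months)
  age_days[use_m] <- round(age_months[use_m] * DAYS_PER_MONTH)
  age_days[!is.na(age_days) & age_days < 0] <- NA_real_

  df <- data.frame(
    record_id = blank_na(col("record_id")),
    live_birth = tolower(blank_na(col("live_birth"))),
    age_at_death_days = as.integer(round(age_days)),
    questionnaire_type = tolower(blank_na(col("questionnaire_type"))),
    interview_complete = tolower(blank_na(col("interview_complete"))),
    survey_weight = num(col("survey_weight")),
    stratum_id = blank_na(col("stratum_id")),
    psu_id = blank_na(col("psu_id")),
    comparator_cause = blank_na(col("comparator_cause")),
    stringsAsFactors = FALSE
  )
  for (id in intersect(codebook_ids(codebook), names(raw))) {
    df[[id]] <- parse_response(raw[[id]], codebook[[id]])
  }
  if (!"interview_complete" %in% names(raw)) df$interview_complete <- NULL
  if (!"comparator_cause" %in% names(raw)) df$comparator_cause <- NULL
  va_records(df, codebook)
}

#' Write VA records to CSV
#' @param records A [va_records()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Age stratum of an included record
#'
#' Neonates are 0--27 completed days; post-neonatal children are 28 days to
#' 59 completed months (1826 days). The boundary is sharp: 27 days is a
#' neonate, 28 days is a child.
#'
#' @param age_at_death_days Integer vector of ages at death in days.
#' @return Character vector, `"neonate"` or `"child"`.
#' @export
stratify <- function(age_at_death_days) {
  if (any(is.na(age_at_death_days))) {
    stop("cannot stratify a record with missing age (should have been ",
         "excluded)", call. = FALSE)
  }
  if (any(age_at_death_days < 0 | age_at_death_days > MAX_AGE_DAYS)) {
    stop("age out of the 0-", MAX_AGE_DAYS, " day range", call. = FALSE)
  }
  ifelse(age_at_death_days <= NEONATE_MAX_DAYS, "neonate", "child")
}

#' Apply the five study inclusion criteria
#'
#' A record is retained only if it (1) is a live birth, (2) died between
#' 0 and 59 completed months, (3) has a complete interview, (4) has
#' sufficient information on age at death, and (5) was administered the
#' age-appropriate questionnaire. Each excluded record is logged with the
#' first failed criterion in that order. Completeness uses the
#' `interview_complete` flag when the column is present; otherwise a record
#' is complete when fewer than `max_missing_fraction` of the codebook items
#' present in the table are missing.
#'
#' @param records A [va_records()] table.
#' @param max_missing_fraction Fallback completeness threshold (default 0.5).
#' @return A list with `included` (a `va_records` table) and `exclusion_log`
#'   (data.frame `record_id`, `criterion`, `reason`; zero rows when nothing
#'   was excluded).
#' @export
apply_inclusion_criteria <- function(records, max_missing_fraction = 0.5) {
  stopifnot(inherits(records, "va_records"))
  cb <- records_codebook(records)
  item_cols <- intersect(codebook_ids(cb), names(records))

  n <- nrow(records)
  crit <- integer(n)   # 0 = included, else first failed criterion
  reason <- character(n)
  fail <- function(idx, k, why) {
    hit <- idx & crit == 0L
    crit[hit] <<- k
    reason[hit] <<- why
  }

  age <- records$age_at_death_days
  fail(is.na(records$live_birth) | records$live_birth != "yes",
       1L, "not live birth")
  fail(!is.na(age) & (age < 0L | age > MAX_AGE_DAYS),
       2L, "age out of range")
  if ("interview_complete" %in% names(records)) {
    fail(is.na(records$interview_complete) |
           records$interview_complete != "yes",
         3L, "incomplete interview")
  } else if (length(item_cols)) {
    resp <- as.data.frame(records)[item_cols]
    miss_frac <- rowMeans(is.na(resp))
    fail(miss_frac >= max_missing_fraction, 3L, "incomplete interview")
  }
  fail(is.na(age), 4L, "insufficient age information")
  ok_age <- crit == 0L
  stratum <- rep(NA_character_, n)
  stratum[ok_age] <- stratify(age[ok_age])
  expected_q <- ifelse(stratum == "neonate", "neonatal", "child")
  fail(ok_age & (is.na(records$questionnaire_type) |
                   records$questionnaire_type != expected_q),
       5L, "age-inappropriate questionnaire")

  keep <- crit == 0L
  included <- records[keep, , drop = FALSE]
  attr(included, "codebook") <- cb
  class(included) <- c("va_records", "data.frame")
  list(
    included = included,
    exclusion_log = data.frame(
      record_id = records$record_id[!keep],
      criterion = crit[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}
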