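## Input model: bottle-level records, cohort container, validation, adult filter.
##
## The input dialect is one row per BC bottle:
##   patient_id,age_years,center,area,hospital_service,sample_id,bottle_id,
##   specimen_origin,bottle_type,collected_at,status,organisms,volume_ml
## collected_at ISO-8601 (minute precision required, seconds preserved);
## organisms semicolon-separated, empty = none; empty string = missing.

BOTTLE_COLUMNS <- c(
  "patient_id", "age_years", "center", "area", "hospital_service",
  "sample_id", "bottle_id", "specimen_origin", "bottle_type",
  "collected_at", "status", "organisms", "volume_ml"
)

SPECIMEN_ORIGINS <- c("PV", "CVC", "OTHER_DEVICE")
BOTTLE_TYPES <- c("AEROBIC", "ANAEROBIC", "OTHER")
STATUSES <- c("POSITIVE", "NEGATIVE")

#' Parse timestamps of the bottle dialect
#'
#' Accepts ISO-8601 with `T` or space separator, with or without seconds;
#' values are interpreted in UTC (the export carries no zone).
#'
#' @param x character vector.
#' @return POSIXct (UTC); `NA` where unparsable.
#' @keywords internal
parse_timestamp <- function(x) {
  x <- trimws(as.character(x))
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  todo <- !is.na(x) & nzchar(x)
  for (f in fmts) {
    if (!any(todo)) break
    p <- as.POSIXct(x[todo], format = f, tz = "UTC")
    ok <- !is.na(p)
    idx <- which(todo)[ok]
    out[idx] <- p[ok]
    todo[idx] <- FALSE
  }
  out
}

format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Split a semicolon-separated organism field
#'
#' @param x character vector (one element per bottle).
#' @return list of character vectors; empty vector for bottles without
#'   identifications.
#' @export
split_organisms <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

#' Normalize a species name for matching
#'
#' Lower-cases and squeezes internal whitespace; matching throughout the
#' package is case-insensitive on these normalized names.
#'
#' @param x character vector of species names.
#' @return normalized character vector.
#' @export
normalize_species <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

#' Construct a validated cohort of blood-culture bottles
#'
#' Validates a bottle-level data frame against the input dialect and wraps
#' the accepted rows, the study period and a rejects report into a
#' `bc_cohort` object. Validation is total: every row is either accepted or
#' appears (at least once, once per offending field) in the rejects report.
#'
#' Row-level rules: enumerated fields must be one of their allowed values;
#' `collected_at` must parse; a NEGATIVE bottle must carry no organisms;
#' `volume_ml`, when present, must lie in `[0, volume_cap]`; identifier and
#' location fields must be non-empty. A duplicated `bottle_id` is a fatal
#' error (the file is corrupt, not a bad row).
#'
#' @param records data frame with the columns of the bottle dialect.
#' @param period_start,period_end optional POSIXct bounds of the
#'   surveillance period; default to the observed collection range.
#' @param provenance free-text metadata string.
#' @param volume_cap sanity cap for `volume_ml` in mL (default 15).
#' @return object of class `bc_cohort`: list with `records` (accepted
#'   rows, typed), `rejects` (row, bottle_id, field, reason), `period_start`,
#'   `period_end`, `provenance`, `volume_cap`.
#' @export
bc_cohort <- function(records, period_start = NULL, period_end = NULL,
                      provenance = "", volume_cap = 15) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(BOTTLE_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- records[BOTTLE_COLUMNS]

  ## fatal duplicate-key scan before row-level validation
  ids <- as.character(records$bottle_id)
  dup <- unique(ids[duplicated(ids) & !is.na(ids) & nzchar(ids)])
  if (length(dup)) {
    stop("duplicate bottle_id value(s): ",
         paste(head(dup, 5L), collapse = ", "),
         if (length(dup) > 5L) " ..." else "")
  }

  n <- nrow(records)
  chr <- function(v) {
    v <- as.character(v)
    v[is.na(v)] <- ""
    trimws(v)
  }
  rec <- data.frame(
    patient_id = chr(records$patient_id),
    age_years = suppressWarnings(as.integer(records$age_years)),
    center = chr(records$center),
    area = chr(records$area),
    hospital_service = chr(records$hospital_service),
    sample_id = chr(records$sample_id),
    bottle_id = chr(records$bottle_id),
    specimen_origin = toupper(chr(records$specimen_origin)),
    bottle_type = toupper(chr(records$bottle_type)),
    collected_at = if (inherits(records$collected_at, "POSIXct")) {
      as.POSIXct(records$collected_at, tz = "UTC")
    } else {
      parse_timestamp(records$collected_at)
    },
    status = toupper(chr(records$status)),
    organisms = chr(records$organisms),
    volume_ml = suppressWarnings(as.numeric(records$volume_ml)),
    stringsAsFactors = FALSE
  )

  rejects <- list()
  flag <- function(rows, field, reason) {
    if (length(rows)) {
      rejects[[length(rejects) + 1L]] <<- data.frame(
        row = rows, bottle_id = rec$bottle_id[rows],
        field = field, reason = reason, stringsAsFactors = FALSE)
    }
  }
  for (f in c("patient_id", "center", "area", "hospital_service",
              "sample_id", "bottle_id")) {
    flag(which(!nzchar(rec[[f]])), f, "missing_field")
  }
  flag(which(!rec$specimen_origin %in% SPECIMEN_ORIGINS),
       "specimen_origin", "invalid_enum")
  flag(which(!rec$bottle_type %in% BOTTLE_TYPES), "bottle_type", "invalid_enum")
  flag(which(!rec$status %in% STATUSES), "status", "invalid_enum")
  flag(which(is.na(rec$collected_at)), "collected_at", "unparsable_timestamp")
  flag(which(!is.na(rec$age_years) & rec$age_years < 0L),
       "age_years", "negative_age")
  has_org <- lengths(split_organisms(rec$organisms)) > 0L
  flag(which(rec$status == "NEGATIVE" & has_org),
       "organisms", "organisms_on_negative_bottle")
  flag(which(!is.na(rec$volume_ml) &
               (rec$volume_ml < 0 | rec$volume_ml > volume_cap)),
       "volume_ml", "volume_out_of_range")

  rejects <- if (length(rejects)) {
    do.call(rbind, rejects)
  } else {
    data.frame(row = integer(), bottle_id = character(),
               field = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  bad <- unique(rejects$row)
  accepted <- if (length(bad)) rec[-bad, , drop = FALSE] else rec
  rownames(accepted) <- NULL

  if (is.null(period_start)) {
    period_start <- if (nrow(accepted)) min(accepted$collected_at) else
      as.POSIXct(NA, tz = "UTC")
  }
  if (is.null(period_end)) {
    period_end <- if (nrow(accepted)) max(accepted$collected_at) else
      as.POSIXct(NA, tz = "UTC")
  }
  out_of_period <- which(
    !is.na(period_start) & !is.na(period_end) &
      (accepted$collected_at < period_start |
         accepted$collected_at > period_end))
  if (length(out_of_period)) {
    rejects <- rbind(rejects, data.frame(
      row = out_of_period, bottle_id = accepted$bottle_id[out_of_period],
      field = "collected_at", reason = "outside_period",
      stringsAsFactors = FALSE))
    accepted <- accepted[-out_of_period, , drop = FALSE]
    rownames(accepted) <- NULL
  }

  structure(
    list(records = accepted, rejects = rejects,
         period_start = as.POSIXct(period_start, tz = "UTC"),
         period_end = as.POSIXct(period_end, tz = "UTC"),
         provenance = provenance, volume_cap = volume_cap),
    class = "bc_cohort")
}

#' @export
print.bc_cohort <- function(x, ...) {
  cat("<bc_cohort>\n")
  cat(sprintf("  bottles:  %d accepted, %d reject record(s)\n",
              nrow(x$records), nrow(x$rejects)))
  cat(sprintf("  patients: %d\n", length(unique(x$records$patient_id))))
  cat(sprintf("  centers:  %d\n", length(unique(x$records$center))))
  if (nrow(x$records)) {
    cat(sprintf("  period:   %s .. %s\n",
                format_timestamp(x$period_start),
                format_timestamp(x$period_end)))
  }
  invisible(x)
}

#' @export
summary.bc_cohort <- function(object, ...) {
  r <- object$records
  out <- list(
    n_bottles = nrow(r),
    n_patients = length(unique(r$patient_id)),
    n_rejected = length(unique(object$rejects$row)),
    n_positive = sum(r$status == "POSITIVE"),
    n_missing_volume = sum(is.na(r$volume_ml)),
    centers = sort(unique(r$center)),
    areas = sort(unique(r$area)))
  class(out) <- "summary.bc_cohort"
  out
}

#' @export
print.summary.bc_cohort <- function(x, ...) {
  cat(sprintf(
    "Cohort: %d bottles / %d patients (%d row(s) rejected)\n",
    x$n_bottles, x$n_patients, x$n_rejected))
  cat(sprintf("  positive bottles: %d; missing volume: %d\n",
              x$n_positive, x$n_missing_volume))
  cat("  centers:", paste(x$centers, collapse = ", "), "\n")
  cat("  areas:  ", paste(x$areas, collapse = ", "), "\n")
  invisible(x)
}

#' Read bottle-level records from CSV or JSONL
#'
#' Reads the documented dialect and validates it through [bc_cohort()].
#' The rejects report is attached to the returned cohort (`$rejects`).
#'
#' @param path input file.
#' @param format `"csv"` or `"jsonl"`; default guessed from the extension.
#' @param ... passed to [bc_cohort()] (`period_start`, `period_end`,
#'   `volume_cap`, ...).
#' @return a [bc_cohort()].
#' @export
read_bottles <- function(path, format = c("auto", "csv", "jsonl"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "csv") {
    read.csv(path, colClasses = "character", check.names = FALSE,
             na.strings = character())
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      as.data.frame(setNames(rep(list(character()), length(BOTTLE_COLUMNS)),
                             BOTTLE_COLUMNS))
    } else {
      rows <- lapply(lines, function(l) {
        v <- jsonlite::fromJSON(l)
        v <- lapply(v, function(x) if (is.null(x)) NA else x)
        as.data.frame(v, stringsAsFactors = FALSE)
      })
      data.table::rbindlist(rows, fill = TRUE)
    }
  }
  cohort <- bc_cohort(df, provenance = path, ...)
  if (nrow(cohort$rejects)) {
    message(sprintf("read_bottles: rejected %d row(s); see $rejects",
                    length(unique(cohort$rejects$row))))
  }
  cohort
}

#' Write a cohort back to the input dialect
#'
#' Round-trips losslessly through [read_bottles()]: missing `volume_ml`
#' and empty `organisms` are preserved as empty fields (CSV) or `null`
#' (JSONL), never coerced to 0.
#'
#' @param cohort a [bc_cohort()].
#' @param path output file.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "jsonl")) {
  stopifnot(inherits(cohort, "bc_cohort"))
  format <- match.arg(format)
  r <- cohort$records
  out <- r
  out$collected_at <- format_timestamp(r$collected_at)
  if (format == "csv") {
    out$age_years <- ifelse(is.na(r$age_years), "", as.character(r$age_years))
    out$volume_ml <- ifelse(is.na(r$volume_ml), "",
                            format(r$volume_ml, trim = TRUE, digits = 15))
    write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  } else {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    if (nrow(out)) {
      for (i in seq_len(nrow(out))) {
        rec <- as.list(out[i, , drop = FALSE])
        rec <- lapply(rec, function(x) if (is.na(x)) NULL else x)
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"),
                   con)
      }
    }
  }
  invisible(path)
}

#' Restrict a cohort to adult patients
#'
#' Keeps records with `age_years >= min_age`. Records with missing age are
#' either routed to the rejects report (`missing_age = "reject"`, default)
#' or kept (`"keep"`).
#'
#' @param cohort a [bc_cohort()].
#' @param min_age inclusive minimum age in years (default 18).
#' @param missing_age `"reject"` or `"keep"`.
#' @return the filtered [bc_cohort()]; the number of removed bottles is
#'   reported via `message()`.
#' @export
filter_adults <- function(cohort, min_age = 18,
                          missing_age = c("reject", "keep")) {
  stopifnot(inherits(cohort, "bc_cohort"))
  missing_age <- match.arg(missing_age)
  r <- cohort$records
  na_age <- is.na(r$age_years)
  keep <- (!na_age & r$age_years >= min_age) |
    (na_age & missing_age == "keep")
  if (missing_age == "reject" && any(na_age)) {
    cohort$rejects <- rbind(cohort$rejects, data.frame(
      row = which(na_age), bottle_id = r$bottle_id[na_age],
      field = "age_years", reason = "missing_age", stringsAsFactors = FALSE))
  }
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message(sprintf("filter_adults: removed %d bottle(s) below age %d%s",
                    n_removed, min_age,
                    if (missing_age == "reject" && any(na_age))
                      " (incl. missing age)" else ""))
  }
  cohort$records <- r[keep, , drop = FALSE]
  rownames(cohort$records) <- NULL
  cohort
}

#' Write the rejects report of a cohort
#'
#' @param cohort a [bc_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rejects <- function(cohort, path) {
  stopifnot(inherits(cohort, "bc_cohort"))
  write.csv(cohort$rejects, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
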