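# records_io: harmonized record schema, CSV dialects, person expansion ----

#' Dataset identifiers and harmonized schema
#'
#' The four surveillance datasets handled by the package, in canonical
#' order: the Commercial Fishing Incident Database (CFID), the Oregon
#' Trauma Registry (OTR), the Vessel Casualty database (VC), and the
#' Nonfatal Injuries database (NFI). All pair reports use this order.
#'
#' @format Character vectors of dataset ids and harmonized column names.
#' @name fl_schema
NULL

#' @rdname fl_schema
#' @export
FL_DATASET_IDS <- c("CFID", "OTR", "VC", "NFI")

#' @rdname fl_schema
#' @export
FL_COLUMNS <- c(
  "record_id", "dataset", "level", "incident_date", "incident_state",
  "vessel_official_number", "latitude", "longitude", "people_on_board",
  "person_index", "miles_from_shore", "narrative"
)

dataset_rank <- function(id) match(id, FL_DATASET_IDS)

canonical_pair <- function(a, b) {
  if (dataset_rank(a) <= dataset_rank(b)) c(a, b) else c(b, a)
}

pair_label <- function(a, b) paste(canonical_pair(a, b), collapse = "-")

# Person-level rows expanded from an incident carry the parent incident id
# ahead of a "#<k>" suffix; stripping it recovers the incident identity.
incident_id_of <- function(record_id) sub("#[0-9]+$", "", record_id)

empty_records <- function() {
  data.frame(
    record_id = character(0), dataset = character(0), level = character(0),
    incident_date = as.Date(character(0)), incident_state = character(0),
    vessel_official_number = character(0), latitude = numeric(0),
    longitude = numeric(0), people_on_board = integer(0),
    person_index = integer(0), miles_from_shore = numeric(0),
    narrative = character(0), incident_id = character(0),
    stringsAsFactors = FALSE
  )
}

#' Construct a harmonized dataset container
#'
#' Wraps a normalized record table together with its dataset identity, date
#' range, region, and incident/person counts. Most users obtain these from
#' [load_dataset()] or [generate_universe()] rather than calling the
#' constructor directly.
#'
#' @param dataset_id One of `"CFID"`, `"OTR"`, `"VC"`, `"NFI"`.
#' @param records Normalized record `data.frame` (see [FL_COLUMNS]).
#' @param date_range Optional `Date` vector of length 2.
#' @param region Optional character vector of USPS state codes.
#' @param person_info Does this dataset carry personnel information? The
#'   Vessel Casualty database does not (it records vessel damage only), so
#'   its person count is 0 and it is never expanded to person level.
#' @return An object of class `fl_dataset`.
#' @export
new_dataset <- function(dataset_id, records, date_range = NULL, region = NULL,
                        person_info = !identical(dataset_id, "VC")) {
  dataset_id <- match.arg(dataset_id, FL_DATASET_IDS)
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$record_id)) {
    fl_stop("duplicate record_id within dataset %s: %s", dataset_id,
            paste(unique(records$record_id[duplicated(records$record_id)]),
                  collapse = ", "),
            class = "fl_validation_error")
  }
  bad_pi <- (records$level == "person" & is.na(records$person_index)) |
    (records$level == "incident" & !is.na(records$person_index))
  if (any(bad_pi)) {
    fl_stop("person_index must be present iff level = person (rows: %s)",
            paste(which(bad_pi), collapse = ", "),
            class = "fl_validation_error")
  }
  if (!is.null(date_range)) {
    date_range <- as.Date(date_range)
    out_of_range <- !is.na(records$incident_date) &
      (records$incident_date < date_range[1] | records$incident_date > date_range[2])
    if (any(out_of_range)) {
      fl_stop("%d record(s) outside the configured date range %s..%s (rows: %s)",
              sum(out_of_range), date_range[1], date_range[2],
              paste(head(which(out_of_range), 10), collapse = ", "),
              class = "fl_validation_error")
    }
  }
  n_person <- if (!person_info) {
    0L
  } else if (all(records$level == "person")) {
    nrow(records)
  } else {
    sum(pmax(ifelse(is.na(records$people_on_board), 1L, records$people_on_board), 1L))
  }
  structure(
    list(
      dataset_id = dataset_id,
      records = records,
      date_range = date_range,
      region = region %||% sort(unique(records$incident_state[!is.na(records$incident_state)])),
      person_info = person_info,
      counts = c(incidents = length(unique(records$incident_id)),
                 records = nrow(records),
                 persons = as.integer(n_person))
    ),
    class = "fl_dataset"
  )
}

#' @export
print.fl_dataset <- function(x, ...) {
  cat(sprintf("<fl_dataset %s: %d records (%d incidents, %d persons)>\n",
              x$dataset_id, x$counts[["records"]], x$counts[["incidents"]],
              x$counts[["persons"]]))
  if (!is.null(x$date_range)) {
    cat(sprintf("  date range: %s to %s\n", x$date_range[1], x$date_range[2]))
  }
  if (length(x$region)) {
    cat("  region:", paste(x$region, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.fl_dataset <- function(x) dim(x$records)

parse_incident_dates <- function(x) {
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    parsed <- as.Date(x[ok], tryFormats = c("%Y-%m-%d", "%Y/%m/%d"),
                      optional = TRUE)
    # a wildly out-of-range year means the string was not really ISO-ordered
    # (e.g. a day-first date latching onto the year slot)
    yr <- as.integer(format(parsed, "%Y"))
    parsed[!is.na(yr) & (yr < 1900 | yr > 2100)] <- NA
    out[ok] <- parsed
  }
  out
}

parse_number <- function(x, col, rows_base = seq_along(x)) {
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    fl_stop("unparseable %s in row(s): %s", col,
            paste(head(rows_base[bad], 10), collapse = ", "),
            class = "fl_validation_error")
  }
  out
}

# Vectorized normalization shared by load_dataset() and normalize_record().
normalize_records <- function(raw, dataset_id = NULL, default_level = "incident") {
  stopifnot(is.data.frame(raw))
  missing_cols <- setdiff(c("record_id", "incident_date"), names(raw))
  if (length(missing_cols)) {
    fl_stop("missing required column(s): %s", paste(missing_cols, collapse = ", "),
            class = "fl_schema_error")
  }
  n <- nrow(raw)
  chr <- function(col) {
    x <- if (col %in% names(raw)) as.character(raw[[col]]) else rep(NA_character_, n)
    x <- trimws(x)
    x[is.na(x) | !nzchar(x)] <- NA_character_
    x
  }

  record_id <- chr("record_id")
  if (anyNA(record_id)) {
    fl_stop("missing record_id in row(s): %s",
            paste(head(which(is.na(record_id)), 10), collapse = ", "),
            class = "fl_validation_error")
  }

  dataset <- chr("dataset")
  if (!is.null(dataset_id)) dataset[is.na(dataset)] <- dataset_id
  level <- chr("level")
  level[is.na(level)] <- default_level
  if (!all(level %in% c("incident", "person"))) {
    fl_stop("level must be 'incident' or 'person' (rows: %s)",
            paste(head(which(!level %in% c("incident", "person")), 10), collapse = ", "),
            class = "fl_validation_error")
  }

  date_raw <- chr("incident_date")
  incident_date <- parse_incident_dates(date_raw)
  bad_date <- !is.na(date_raw) & is.na(incident_date)
  if (any(bad_date)) {
    fl_stop("unparseable incident_date in row(s): %s",
            paste(head(which(bad_date), 10), collapse = ", "),
            class = "fl_validation_error")
  }
  if (anyNA(incident_date)) {
    fl_stop("missing incident_date in row(s): %s",
            paste(head(which(is.na(incident_date)), 10), collapse = ", "),
            class = "fl_validation_error")
  }

  incident_state <- toupper(chr("incident_state"))
  bad_state <- !is.na(incident_state) & !grepl("^[A-Z]{2}$", incident_state)
  if (any(bad_state)) {
    fl_stop("incident_state must be a USPS 2-letter code (rows: %s)",
            paste(head(which(bad_state), 10), collapse = ", "),
            class = "fl_validation_error")
  }

  vessel <- toupper(gsub("\\s+", "", chr("vessel_official_number")))
  vessel[!is.na(vessel) & !nzchar(vessel)] <- NA_character_

  latitude <- parse_number(chr("latitude"), "latitude")
  if (any(!is.na(latitude) & abs(latitude) > 90)) {
    fl_stop("latitude outside [-90, 90] in row(s): %s",
            paste(head(which(!is.na(latitude) & abs(latitude) > 90), 10), collapse = ", "),
            class = "fl_validation_error")
  }
  longitude <- parse_number(chr("longitude"), "longitude")
  if (any(!is.na(longitude) & (longitude < -180 | longitude > 180))) {
    fl_stop("longitude outside [-180, 180] in row(s): %s",
            paste(head(which(!is.na(longitude) & abs(longitude) > 180), 10), collapse = ", "),
            class = "fl_validation_error")
  }
  # These data are all from the US Pacific coast (east-positive WGS84
  # longitudes are negative there); a positive longitude indicates a
  # west-positive sign convention and is rejected rather than silently kept.
  if (any(!is.na(longitude) & longitude > 0)) {
    fl_stop("positive longitude (west-positive sign convention?) in row(s): %s",
            paste(head(which(!is.na(longitude) & longitude > 0), 10), collapse = ", "),
            class = "fl_validation_error")
  }

  people <- parse_number(chr("people_on_board"), "people_on_board")
  if (any(!is.na(people) & people < 0)) {
    fl_stop("negative people_on_board in row(s): %s",
            paste(head(which(!is.na(people) & people < 0), 10), collapse = ", "),
            class = "fl_validation_error")
  }
  person_index <- parse_number(chr("person_index"), "person_index")
  if (any(!is.na(person_index) & person_index < 1)) {
    fl_stop("person_index must be a positive integer (rows: %s)",
            paste(head(which(!is.na(person_index) & person_index < 1), 10), collapse = ", "),
            class = "fl_validation_error")
  }
  person_index[level == "incident"] <- NA_real_
  person_index[level == "person" & is.na(person_index)] <- 1

  miles <- parse_number(chr("miles_from_shore"), "miles_from_shore")
  if (any(!is.na(miles) & miles < 0)) {
    fl_stop("negative miles_from_shore in row(s): %s",
            paste(head(which(!is.na(miles) & miles < 0), 10), collapse = ", "),
            class = "fl_validation_error")
  }

  data.frame(
    record_id = record_id,
    dataset = dataset,
    level = level,
    incident_date = incident_date,
    incident_state = incident_state,
    vessel_official_number = vessel,
    latitude = latitude,
    longitude = longitude,
    people_on_board = as.integer(people),
    person_index = as.integer(person_index),
    miles_from_shore = miles,
    narrative = chr("narrative"),
    incident_id = incident_id_of(record_id),
    stringsAsFactors = FALSE
  )
}

#' Normalize one raw record
#'
#' Applies the harmonization rules used throughout the package: vessel
#' numbers are uppercased with whitespace stripped, states uppercased, empty
#' strings mapped to missing, dates parsed to ISO calendar dates, latitude
#' bounded to \[-90, 90\], and positive (west-positive convention)
#' longitudes rejected.
#'
#' @param raw A named list or one-row data frame with at least `record_id`
#'   and `incident_date`.
#' @param dataset_id Optional dataset id filled in when `raw` lacks one.
#' @return A one-row normalized record `data.frame`.
#' @examples
#' normalize_record(list(record_id = "X1", incident_date = "2010-8-15",
#'                       vessel_official_number = " or1234ab "))
#' @export
normalize_record <- function(raw, dataset_id = NULL) {
  if (!is.data.frame(raw)) raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  normalize_records(raw, dataset_id = dataset_id)
}

#' Read one dataset dialect into the harmonized schema
#'
#' Reads a UTF-8 CSV with a header row, maps source columns onto the
#' harmonized schema through `schema_config`, normalizes every record, and
#' returns an [new_dataset()] container. Unparseable rows raise row-numbered
#' validation errors rather than being silently dropped.
#'
#' @param path CSV file path.
#' @param dataset_id One of `"CFID"`, `"OTR"`, `"VC"`, `"NFI"`.
#' @param schema_config Optional named character vector mapping harmonized
#'   field names to source column names, e.g.
#'   `c(incident_date = "EventDate")`. Unmapped harmonized fields are taken
#'   from identically-named columns when present.
#' @param date_range Optional length-2 date range; when supplied, records
#'   outside it fail validation.
#' @param region Optional region (state codes) annotation.
#' @return An `fl_dataset`.
#' @export
load_dataset <- function(path, dataset_id, schema_config = NULL,
                         date_range = NULL, region = NULL) {
  if (!file.exists(path)) {
    fl_stop("file does not exist: %s", path, class = "fl_schema_error")
  }
  dataset_id <- match.arg(dataset_id, FL_DATASET_IDS)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = character(0), fileEncoding = "UTF-8")
  if (!is.null(schema_config)) {
    missing_src <- setdiff(unname(schema_config), names(raw))
    if (length(missing_src)) {
      fl_stop("schema_config refers to missing column(s): %s",
              paste(missing_src, collapse = ", "), class = "fl_schema_error")
    }
    for (harm in names(schema_config)) {
      raw[[harm]] <- raw[[schema_config[[harm]]]]
    }
  }
  default_level <- switch(dataset_id, OTR = "person", "incident")
  records <- if (nrow(raw) == 0) empty_records() else {
    normalize_records(raw, dataset_id = dataset_id, default_level = default_level)
  }
  new_dataset(dataset_id, records, date_range = date_range, region = region)
}

#' Write a dataset to the harmonized CSV schema
#'
#' Dates are written as `YYYY-MM-DD` and missing values as empty cells.
#' Numeric fields use R's shortest round-trip representation, so a
#' load-write-load cycle preserves all field values exactly.
#'
#' @param d An `fl_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path) {
  stopifnot(inherits(d, "fl_dataset"))
  r <- d$records
  out <- data.frame(
    record_id = r$record_id,
    dataset = r$dataset,
    level = r$level,
    incident_date = format(r$incident_date, "%Y-%m-%d"),
    incident_state = r$incident_state,
    vessel_official_number = r$vessel_official_number,
    latitude = as.character(r$latitude),
    longitude = as.character(r$longitude),
    people_on_board = as.character(r$people_on_board),
    person_index = as.character(r$person_index),
    miles_from_shore = as.character(r$miles_from_shore),
    narrative = r$narrative,
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Expand incident-level rows to person-level cases
#'
#' Each incident row affecting `k` persons becomes `k` person rows sharing
#' all incident fields, with `person_index` 1..k and record ids
#' `"<incident_id>#<k>"`. An incident with a missing or zero person count
#' produces one person row. The Vessel Casualty dataset carries no personnel
#' information and is never expanded.
#'
#' @param d An `fl_dataset`.
#' @param count_field Column holding the number of affected persons.
#' @return A person-level `fl_dataset`.
#' @export
expand_person_level <- function(d, count_field = "people_on_board") {
  stopifnot(inherits(d, "fl_dataset"))
  if (!d$person_info) {
    fl_stop("dataset %s carries no personnel information and cannot be expanded",
            d$dataset_id, class = "fl_validation_error")
  }
  r <- d$records
  if (nrow(r) == 0 || all(r$level == "person")) {
    return(d)
  }
  counts <- r[[count_field]]
  if (any(!is.na(counts) & counts < 0)) {
    fl_stop("negative person count in row(s): %s",
            paste(which(!is.na(counts) & counts < 0), collapse = ", "),
            class = "fl_validation_error")
  }
  k <- ifelse(is.na(counts) | counts < 1, 1L, as.integer(counts))
  idx <- rep.int(seq_len(nrow(r)), k)
  out <- r[idx, , drop = FALSE]
  out$person_index <- sequence(k)
  out$level <- "person"
  out$incident_id <- r$record_id[idx]
  out$record_id <- paste0(r$record_id[idx], "#", out$person_index)
  rownames(out) <- NULL
  new_dataset(d$dataset_id, out, date_range = d$date_range, region = d$region,
              person_info = d$person_info)
}
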