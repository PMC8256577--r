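# comparison: full pair index and per-pair field agreement vectors --------

FL_MATCH_FIELDS <- c("incident_date", "incident_state",
                     "vessel_official_number", "latlon", "people_on_board")

#' Specify matching variables and tolerances
#'
#' Agreement is binary per field: dates agree within
#' `date_tolerance_days`, latitude/longitude agree when *both* axes are
#' within `latlon_tolerance_deg` (one joint field), and states, vessel
#' numbers and people-on-board counts agree on normalized exact equality.
#' A field missing on either side sets the missing flag; the score is then
#' forced by `missing_policy`: `"disagree"` scores 0 (the default, which is
#' what drives the very low decision thresholds these data need), while
#' `"ignore"` drops the field from probabilistic scoring.
#'
#' @param fields Ordered subset of
#'   `c("incident_date", "incident_state", "vessel_official_number",
#'   "latlon", "people_on_board")`.
#' @param date_tolerance_days Non-negative integer, default 1 day.
#' @param latlon_tolerance_deg Non-negative number, default 0.5 degrees
#'   (about 50 km at these latitudes).
#' @param missing_policy `"disagree"` or `"ignore"`.
#' @return An object of class `matching_spec`.
#' @export
matching_spec <- function(fields,
                          date_tolerance_days = 1L,
                          latlon_tolerance_deg = 0.5,
                          missing_policy = c("disagree", "ignore")) {
  missing_policy <- match.arg(missing_policy)
  if (length(fields) < 1) {
    fl_stop("matching_spec needs at least one field", class = "fl_config_error")
  }
  bad <- setdiff(fields, FL_MATCH_FIELDS)
  if (length(bad)) {
    fl_stop("unknown matching field(s): %s", paste(bad, collapse = ", "),
            class = "fl_config_error")
  }
  if (date_tolerance_days < 0 || latlon_tolerance_deg < 0) {
    fl_stop("tolerances must be non-negative", class = "fl_config_error")
  }
  structure(
    list(fields = fields,
         date_tolerance_days = as.integer(date_tolerance_days),
         latlon_tolerance_deg = latlon_tolerance_deg,
         missing_policy = missing_policy),
    class = "matching_spec"
  )
}

#' Full cross-product pair index between two datasets
#'
#' Every record in one dataset is paired with every record in the other:
#' exactly `nrow(a) * nrow(b)` pairs in deterministic order (a-order major,
#' b-order minor). Self-linkage (the same dataset twice) is refused.
#'
#' @param a,b `fl_dataset` objects with different dataset ids.
#' @return An object of class `fl_pair_index` with row indices `i`, `j`.
#' @export
full_index <- function(a, b) {
  stopifnot(inherits(a, "fl_dataset"), inherits(b, "fl_dataset"))
  if (identical(a$dataset_id, b$dataset_id)) {
    fl_stop("full_index needs two distinct datasets (self-deduplication is out of scope)",
            class = "fl_config_error")
  }
  na <- nrow(a$records)
  nb <- nrow(b$records)
  structure(
    list(i = rep(seq_len(na), each = nb),
         j = rep.int(seq_len(nb), na),
         n_a = na, n_b = nb,
         dataset_a = a$dataset_id, dataset_b = b$dataset_id),
    class = "fl_pair_index"
  )
}

#' @export
length.fl_pair_index <- function(x) length(x$i)

#' @export
print.fl_pair_index <- function(x, ...) {
  cat(sprintf("<fl_pair_index %s x %s: %d * %d = %d pairs>\n",
              x$dataset_a, x$dataset_b, x$n_a, x$n_b, length(x$i)))
  invisible(x)
}

# Vectorized per-field agreement over an index. Returns score (integer,
# NA only under the "ignore" missing policy) and the missing flag.
compare_field <- function(field, ra, rb, i, j, spec) {
  if (field == "latlon") {
    la <- ra$latitude[i]; lb <- rb$latitude[j]
    oa <- ra$longitude[i]; ob <- rb$longitude[j]
    miss <- is.na(la) | is.na(lb) | is.na(oa) | is.na(ob)
    agree <- !miss & abs(la - lb) <= spec$latlon_tolerance_deg &
      abs(oa - ob) <= spec$latlon_tolerance_deg
  } else if (field == "incident_date") {
    da <- as.integer(ra$incident_date)[i]
    db <- as.integer(rb$incident_date)[j]
    miss <- is.na(da) | is.na(db)
    agree <- !miss & abs(da - db) <= spec$date_tolerance_days
  } else {
    va <- ra[[field]][i]
    vb <- rb[[field]][j]
    miss <- is.na(va) | is.na(vb)
    agree <- !miss & va == vb
  }
  score <- as.integer(agree)
  if (spec$missing_policy == "disagree") {
    score[miss] <- 0L
  } else {
    score[miss] <- NA_integer_
  }
  list(score = score, missing = miss)
}

field_available <- function(field, records) {
  cols <- if (field == "latlon") c("latitude", "longitude") else field
  any(!is.na(unlist(records[cols], use.names = FALSE)))
}

check_fields_present <- function(spec, a, b) {
  for (f in spec$fields) {
    if (!field_available(f, a$records) && !field_available(f, b$records)) {
      fl_stop("matching field '%s' is entirely absent from both datasets (%s, %s)",
              f, a$dataset_id, b$dataset_id, class = "fl_config_error")
    }
  }
}

#' Compare all pairs of two datasets
#'
#' Computes the binary agreement vector for every pair of the full index
#' (or a supplied index), in index order. The result is the input to every
#' classifier in the package.
#'
#' @param a,b `fl_dataset` objects.
#' @param spec A [matching_spec()].
#' @param index Optional pre-built [full_index()] (defaults to the full
#'   cross-product).
#' @return An object of class `comparison_matrix` holding the pair index,
#'   a pairs-by-fields integer score matrix and the per-field missing
#'   flags.
#' @export
build_comparison_matrix <- function(a, b, spec, index = NULL) {
  stopifnot(inherits(spec, "matching_spec"))
  index <- index %||% full_index(a, b)
  if (nrow(a$records) > 0 && nrow(b$records) > 0) {
    check_fields_present(spec, a, b)
  }
  k <- length(spec$fields)
  n <- length(index$i)
  scores <- matrix(0L, nrow = n, ncol = k, dimnames = list(NULL, spec$fields))
  missing <- matrix(FALSE, nrow = n, ncol = k, dimnames = list(NULL, spec$fields))
  for (f in spec$fields) {
    cmp <- compare_field(f, a$records, b$records, index$i, index$j, spec)
    scores[, f] <- cmp$score
    missing[, f] <- cmp$missing
  }
  structure(
    list(index = index,
         ids_a = a$records$record_id, ids_b = b$records$record_id,
         inc_a = a$records$incident_id, inc_b = b$records$incident_id,
         scores = scores, missing = missing, spec = spec,
         dataset_a = a$dataset_id, dataset_b = b$dataset_id),
    class = "comparison_matrix"
  )
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("<comparison_matrix %s x %s: %d pairs, fields: %s>\n",
              x$dataset_a, x$dataset_b, nrow(x$scores),
              paste(colnames(x$scores), collapse = ", ")))
  invisible(x)
}

# Pair id table for a comparison matrix (or a logical/integer subset of it).
cm_pairs <- function(cm, rows = NULL) {
  i <- cm$index$i
  j <- cm$index$j
  if (!is.null(rows)) {
    i <- i[rows]
    j <- j[rows]
  }
  data.frame(
    dataset_a = rep_len(cm$dataset_a, length(i)), record_id_a = cm$ids_a[i],
    dataset_b = rep_len(cm$dataset_b, length(i)), record_id_b = cm$ids_b[j],
    stringsAsFactors = FALSE
  )
}

#' Compare a single record pair
#'
#' @param ra,rb Harmonized records (named lists or one-row data frames, as
#'   produced by [normalize_record()]).
#' @param spec A [matching_spec()].
#' @return A list with the per-field `scores` and `missing` flags.
#' @examples
#' spec <- matching_spec(c("incident_date", "incident_state"))
#' ra <- normalize_record(list(record_id = "a", incident_date = "2010-08-15",
#'                             incident_state = "OR"))
#' rb <- normalize_record(list(record_id = "b", incident_date = "2010-08-16",
#'                             incident_state = "OR"))
#' compare_pair(ra, rb, spec)$scores  # date within 1 day scores 1
#' @export
compare_pair <- function(ra, rb, spec) {
  stopifnot(inherits(spec, "matching_spec"))
  if (!is.data.frame(ra)) ra <- normalize_record(ra)
  if (!is.data.frame(rb)) rb <- normalize_record(rb)
  scores <- integer(length(spec$fields))
  missing <- logical(length(spec$fields))
  names(scores) <- names(missing) <- spec$fields
  for (f in spec$fields) {
    cmp <- compare_field(f, ra, rb, 1L, 1L, spec)
    scores[f] <- cmp$score
    missing[f] <- cmp$missing
  }
  structure(
    list(pair = c(ra$record_id[1], rb$record_id[1]),
         scores = scores, missing = missing),
    class = "fl_comparison"
  )
}
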