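# evaluation: confusion counts, quality metrics, match accounting --------

as_pair_keys <- function(x) {
  if (is.data.frame(x)) pair_keys(x$record_id_a, x$record_id_b) else as.character(x)
}

#' Confusion counts over the full pair universe
#'
#' TP/FP/FN are set operations between the links and the labeled positive
#' pairs; TN is the remainder of the evaluation universe, which is the full
#' cross-product of the two datasets (so TN dominates all other cells).
#'
#' @param links Linked pairs (`fl_link_set`, a data frame with
#'   `record_id_a`/`record_id_b`, or a character key vector).
#' @param truth The positive pairs, same forms.
#' @param total_pairs Size of the evaluation universe (`|A| * |B|`).
#' @return Class `fl_confusion`: named integer vector TP, FP, FN, TN.
#' @export
confusion_counts <- function(links, truth, total_pairs) {
  lk <- unique(as_pair_keys(links))
  tk <- unique(as_pair_keys(truth))
  n_union <- length(union(lk, tk))
  if (total_pairs < n_union) {
    fl_stop("total_pairs (%d) smaller than |links U positives| (%d)",
            total_pairs, n_union, class = "fl_validation_error")
  }
  tp <- length(intersect(lk, tk))
  out <- c(TP = tp, FP = length(lk) - tp, FN = length(tk) - tp,
           TN = as.integer(total_pairs) - n_union + tp - (length(lk) - tp) - 0L)
  out["TN"] <- as.integer(total_pairs) - out[["TP"]] - out[["FP"]] - out[["FN"]]
  structure(as.integer(out), names = names(out), class = "fl_confusion")
}

#' Precision, recall and f-score from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `f = 2 * precision * recall / (precision + recall)`; any 0/0 is 0 by
#' convention (so f = 0 whenever TP = 0, matching how zero-link runs are
#' reported).
#'
#' @param counts An `fl_confusion` or named vector with TP, FP, FN.
#' @return Named list with `precision`, `recall`, `f_score`, all in
#'   `[0, 1]`.
#' @export
linkage_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]])
  fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]])
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f <- safe_div(2 * precision * recall, precision + recall)
  list(precision = precision, recall = recall, f_score = f)
}

DEFAULT_DISJOINT <- list(c("CFID", "VC"), c("CFID", "NFI"))

#' Flag matches falling in by-definition disjoint dataset pairs
#'
#' The vessel-disaster database should not overlap the vessel-casualty or
#' nonfatal-injury databases; an accepted true match inside such a pair
#' reveals the same case recorded twice. The first dataset of each
#' disjointness entry is the authoritative one (the record that should
#' exist); the partner record is the unintended duplicate.
#'
#' @param matches Data frame of accepted matches with `dataset_a`,
#'   `dataset_b` and optionally `n_cases` (person cases per match row,
#'   default 1 — close-match groups carry their person multiplicity).
#' @param disjointness List of dataset-id pairs declared non-overlapping.
#' @return `matches` with a logical `is_duplicate` column; the total
#'   flagged case count is in attribute `duplicate_cases`.
#' @export
flag_duplicates <- function(matches, disjointness = DEFAULT_DISJOINT) {
  disjoint_labels <- vapply(disjointness, function(p) pair_label(p[1], p[2]),
                            character(1))
  labels <- mapply(pair_label, matches$dataset_a, matches$dataset_b)
  matches$is_duplicate <- labels %in% disjoint_labels
  n_cases <- matches$n_cases %||% rep(1L, nrow(matches))
  attr(matches, "duplicate_cases") <- sum(n_cases[matches$is_duplicate])
  matches
}

record_signature <- function(records, idx, fields) {
  parts <- lapply(fields, function(f) {
    if (f == "latlon") {
      paste(records$latitude[idx], records$longitude[idx])
    } else {
      as.character(records[[f]][idx])
    }
  })
  do.call(paste, c(parts, sep = "\x1f"))
}

#' Detect close-match groups among accepted links
#'
#' A link is *close* when one record links to two or more person records of
#' a single incident that are indistinguishable on all matching variables —
#' the situation of several crew members injured in one incident and
#' recorded identically. Groups are reported, not resolved: each group's
#' unresolvable person-case count is the larger of its two record sets.
#'
#' @param links An `fl_link_set` or pair data frame between `a` and `b`.
#' @param a,b The `fl_dataset` objects behind the links.
#' @param spec The [matching_spec()] defining indistinguishability.
#' @return Class `fl_close_groups`: list of groups (records on each side,
#'   links, `n_close`), with the total in attribute-free field
#'   `total_close`.
#' @export
flag_close_matches <- function(links, a, b, spec) {
  links <- as.data.frame(links)
  if (nrow(links) == 0) {
    return(structure(list(groups = list(), total_close = 0L,
                          close_links = links[0, , drop = FALSE]),
                     class = "fl_close_groups"))
  }
  ia <- match(links$record_id_a, a$records$record_id)
  ib <- match(links$record_id_b, b$records$record_id)
  if (anyNA(ia) || anyNA(ib)) {
    fl_stop("link refers to unknown record id(s)", class = "fl_validation_error")
  }
  sig_a <- record_signature(a$records, ia, spec$fields)
  sig_b <- record_signature(b$records, ib, spec$fields)
  inc_a <- a$records$incident_id[ia]
  inc_b <- b$records$incident_id[ib]

  # ambiguous in the a->b direction: an a-record linked to >=2 b-records of
  # one incident sharing one signature (and vice versa)
  amb <- rep(FALSE, nrow(links))
  for (dir in c("ab", "ba")) {
    key <- if (dir == "ab") paste(links$record_id_a, inc_b, sig_b, sep = "\x1f")
           else paste(links$record_id_b, inc_a, sig_a, sep = "\x1f")
    partner <- if (dir == "ab") links$record_id_b else links$record_id_a
    multi <- vapply(split(partner, key), function(x) length(unique(x)) >= 2L,
                    logical(1))
    amb <- amb | multi[key]
  }
  if (!any(amb)) {
    return(structure(list(groups = list(), total_close = 0L,
                          close_links = links[0, , drop = FALSE]),
                     class = "fl_close_groups"))
  }
  close_links <- links[amb, , drop = FALSE]
  # connected components over the ambiguous links' records
  nodes <- unique(c(paste0("A\x1f", close_links$record_id_a),
                    paste0("B\x1f", close_links$record_id_b)))
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  na_ <- match(paste0("A\x1f", close_links$record_id_a), nodes)
  nb_ <- match(paste0("B\x1f", close_links$record_id_b), nodes)
  for (r in seq_len(nrow(close_links))) {
    ra <- find(na_[r]); rb <- find(nb_[r])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_along(nodes), find, integer(1))
  link_comp <- comp[na_]
  groups <- lapply(split(seq_len(nrow(close_links)), link_comp), function(rows) {
    g <- close_links[rows, , drop = FALSE]
    ra <- unique(g$record_id_a)
    rb <- unique(g$record_id_b)
    list(records_a = ra, records_b = rb, links = g,
         n_close = max(length(ra), length(rb)))
  })
  names(groups) <- NULL
  structure(list(groups = groups,
                 total_close = sum(vapply(groups, `[[`, integer(1), "n_close")),
                 close_links = close_links),
            class = "fl_close_groups")
}

#' @export
print.fl_close_groups <- function(x, ...) {
  cat(sprintf("<fl_close_groups: %d group(s), %d unresolvable person case(s)>\n",
              length(x$groups), x$total_close))
  invisible(x)
}

#' Per-field agreement and completeness among accepted matches
#'
#' Recreates the relative accuracy/completeness view of the matched pairs:
#' for each field, the fraction of matched pairs agreeing within the study
#' tolerance among pairs where both sides are present, and the fraction
#' with the field missing on either side.
#'
#' @param matches Data frame of accepted match record-id pairs.
#' @param a,b The `fl_dataset` objects.
#' @param fields Fields to report (defaults to every comparable field
#'   plus miles from shore and people on board).
#' @param spec Tolerances to apply ([matching_spec()] defaults).
#' @return Data frame with `field`, `n_compared`, `agreement`,
#'   `missing_either`.
#' @export
field_agreement_report <- function(matches, a, b,
                                   fields = c("incident_date", "incident_state",
                                              "vessel_official_number", "latlon",
                                              "people_on_board", "miles_from_shore"),
                                   spec = matching_spec(setdiff(fields, "miles_from_shore"))) {
  if (nrow(matches) < 1) {
    fl_stop("field agreement needs at least one accepted match",
            class = "fl_validation_error")
  }
  ia <- match(matches$record_id_a, a$records$record_id)
  ib <- match(matches$record_id_b, b$records$record_id)
  rows <- lapply(fields, function(f) {
    if (f == "miles_from_shore") {
      va <- a$records$miles_from_shore[ia]
      vb <- b$records$miles_from_shore[ib]
      miss <- is.na(va) | is.na(vb)
      agree <- !miss & va == vb
    } else {
      cmp <- compare_field(f, a$records, b$records, ia, ib, spec)
      miss <- cmp$missing
      agree <- !miss & cmp$score == 1L
    }
    data.frame(field = f, n_compared = sum(!miss),
               agreement = if (any(!miss)) mean(agree[!miss]) else NA_real_,
               missing_either = mean(miss), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Study-level match accounting
#'
#' Performs the bookkeeping that turns per-pair accepted matches into the
#' study's headline numbers: duplicate flags within by-definition disjoint
#' pairs, multi-dataset overlap cases (connected components of accepted
#' links spanning three or more datasets), and the post-deduplication
#' remainder. Deduplication removes the non-authoritative record of every
#' duplicate (those cases should exist only in the authoritative dataset),
#' so any link whose endpoint is purged disappears with it — this is how a
#' triple-overlap case collapses to a single surviving match.
#'
#' @param matches Accepted true matches: data frame with `dataset_a`,
#'   `record_id_a`, `dataset_b`, `record_id_b` at incident level.
#' @param close_groups Optional `fl_close_groups` (their links join the
#'   component graph and their person cases join the duplicate count when
#'   they fall in a disjoint pair).
#' @param disjointness Dataset pairs declared non-overlapping; the first id
#'   of each entry is authoritative.
#' @return Class `fl_match_accounting`: totals and per-pair breakdowns.
#' @export
account_matches <- function(matches, close_groups = NULL,
                            disjointness = DEFAULT_DISJOINT) {
  matches <- as.data.frame(matches)
  if (nrow(matches) == 0 &&
      (is.null(close_groups) || length(close_groups$groups) == 0)) {
    return(structure(
      list(true_total = 0L, true_per_pair = integer(0), close_cases_total = 0L,
           duplicate_true = 0L, duplicate_close_cases = 0L, duplicates_total = 0L,
           multiset_cases = 0L, absorbed = 0L, remainder_total = 0L,
           remainder_per_pair = integer(0), purged_records = character(0)),
      class = "fl_match_accounting"))
  }
  matches$pair <- as.character(mapply(pair_label, matches$dataset_a, matches$dataset_b))
  disjoint_labels <- vapply(disjointness, function(p) pair_label(p[1], p[2]),
                            character(1))
  authoritative <- setNames(vapply(disjointness, `[`, character(1), 1),
                            disjoint_labels)
  matches$is_duplicate <- matches$pair %in% disjoint_labels

  node <- function(ds, id) paste(ds, id, sep = "\x1f")
  purged <- character(0)
  for (r in which(matches$is_duplicate)) {
    auth <- authoritative[[matches$pair[r]]]
    if (matches$dataset_a[r] == auth) {
      purged <- c(purged, node(matches$dataset_b[r], matches$record_id_b[r]))
    } else {
      purged <- c(purged, node(matches$dataset_a[r], matches$record_id_a[r]))
    }
  }

  close_cases <- 0L
  close_edges <- NULL
  if (!is.null(close_groups) && length(close_groups$groups)) {
    cl <- close_groups$close_links
    cl$pair <- mapply(pair_label, cl$dataset_a, cl$dataset_b)
    cl_inc_a <- incident_id_of(cl$record_id_a)
    cl_inc_b <- incident_id_of(cl$record_id_b)
    close_edges <- data.frame(a = node(cl$dataset_a, cl_inc_a),
                              b = node(cl$dataset_b, cl_inc_b),
                              stringsAsFactors = FALSE)
    dup_groups <- vapply(close_groups$groups, function(g) {
      g$links$pair <- mapply(pair_label, g$links$dataset_a, g$links$dataset_b)
      all(g$links$pair %in% disjoint_labels)
    }, logical(1))
    close_cases <- sum(vapply(close_groups$groups[dup_groups], `[[`, integer(1),
                              "n_close"))
    for (g in close_groups$groups[dup_groups]) {
      lk <- g$links
      for (r in seq_len(nrow(lk))) {
        auth <- authoritative[[pair_label(lk$dataset_a[r], lk$dataset_b[r])]]
        if (lk$dataset_a[r] == auth) {
          purged <- c(purged, node(lk$dataset_b[r], incident_id_of(lk$record_id_b[r])))
        } else {
          purged <- c(purged, node(lk$dataset_a[r], incident_id_of(lk$record_id_a[r])))
        }
      }
    }
  }
  purged <- unique(purged)

  # multi-dataset overlap: connected components over all accepted links
  edges <- data.frame(a = node(matches$dataset_a, matches$record_id_a),
                      b = node(matches$dataset_b, matches$record_id_b),
                      stringsAsFactors = FALSE)
  if (!is.null(close_edges)) edges <- unique(rbind(edges, close_edges))
  nodes <- unique(c(edges$a, edges$b))
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ea <- match(edges$a, nodes)
  eb <- match(edges$b, nodes)
  for (r in seq_along(ea)) {
    ra <- find(ea[r]); rb <- find(eb[r])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_along(nodes), find, integer(1))
  comp_datasets <- tapply(sub("\x1f.*$", "", nodes), comp,
                          function(x) length(unique(x)))
  multiset_cases <- sum(comp_datasets >= 3)

  surv_a <- !(node(matches$dataset_a, matches$record_id_a) %in% purged)
  surv_b <- !(node(matches$dataset_b, matches$record_id_b) %in% purged)
  remainder <- !matches$is_duplicate & surv_a & surv_b
  absorbed <- !matches$is_duplicate & !remainder

  if (any(matches$is_duplicate & remainder)) {
    fl_stop("integrity error: a match is both a duplicate and a unique remainder",
            class = "fl_integrity_error")
  }

  per_pair <- function(mask) {
    tab <- table(matches$pair[mask])
    setNames(as.integer(tab), names(tab))
  }
  structure(
    list(
      true_total = nrow(matches),
      true_per_pair = per_pair(rep(TRUE, nrow(matches))),
      close_cases_total = if (is.null(close_groups)) 0L else close_groups$total_close,
      duplicate_true = sum(matches$is_duplicate),
      duplicate_close_cases = close_cases,
      duplicates_total = sum(matches$is_duplicate) + close_cases,
      multiset_cases = as.integer(multiset_cases),
      absorbed = sum(absorbed),
      remainder_total = sum(remainder),
      remainder_per_pair = per_pair(remainder),
      purged_records = purged
    ),
    class = "fl_match_accounting"
  )
}

#' @export
print.fl_match_accounting <- function(x, ...) {
  cat("Match accounting\n")
  cat(sprintf("  true matches:          %d\n", x$true_total))
  cat(sprintf("  close-match cases:     %d\n", x$close_cases_total))
  cat(sprintf("  duplicates (incl. close): %d\n", x$duplicates_total))
  cat(sprintf("  multi-dataset cases:   %d\n", x$multiset_cases))
  cat(sprintf("  post-dedup remainder:  %d\n", x$remainder_total))
  if (length(x$remainder_per_pair)) {
    cat("  remainder by pair:",
        paste(sprintf("%s=%d", names(x$remainder_per_pair), x$remainder_per_pair),
              collapse = ", "), "\n")
  }
  invisible(x)
}
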