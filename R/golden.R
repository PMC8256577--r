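# golden: labeled match/non-match pairs for supervised classifiers -------

#' Propose candidate matches with a rudimentary deterministic rule
#'
#' Returns every pair whose rule fields *all* agree (score 1 under the
#' rule's tolerances; a missing field disagrees). This is the high-precision
#' shortlist that is then verified — against the planted ground truth in
#' synthetic mode, or by a human review file in real mode — to seed the
#' golden dataset.
#'
#' @param a,b `fl_dataset` objects.
#' @param rule A [matching_spec()]; the pair's matching variables at the
#'   study tolerances by default.
#' @return A data frame of candidate record-id pairs, in index order.
#' @export
propose_candidates <- function(a, b, rule) {
  cm <- build_comparison_matrix(a, b, rule)
  keep <- rowSums(cm$scores == 1L, na.rm = TRUE) == ncol(cm$scores)
  out <- cm_pairs(cm, keep)
  rownames(out) <- NULL
  out
}

truth_keys <- function(gt, include_close = FALSE) {
  links <- gt$links
  if (!include_close) links <- links[is.na(links$close_group_id), , drop = FALSE]
  c(pair_keys(links$record_id_a, links$record_id_b),
    pair_keys(links$record_id_b, links$record_id_a))
}

#' Verify candidate pairs against an oracle
#'
#' In synthetic mode the oracle is the planted ground truth: a candidate is
#' a verified match when its incident-level pair is planted as a certain
#' (non-close) link; ambiguous multi-person pairs are rejected, since their
#' true person-level status is not known even in principle. In real mode
#' the oracle is a review data frame with columns `record_id_a`,
#' `record_id_b`, `verdict` (`match`/`nonmatch`/`pending`); candidates that
#' are unreviewed or pending raise an error listing the pairs rather than
#' being guessed.
#'
#' @param candidates Candidate pair data frame from [propose_candidates()].
#' @param oracle An `fl_ground_truth` or a review data frame.
#' @return The verified match pairs (same columns as `candidates`).
#' @export
verify_candidates <- function(candidates, oracle) {
  if (nrow(candidates) == 0) return(candidates)
  if (inherits(oracle, "fl_ground_truth")) {
    keys <- pair_keys(incident_id_of(candidates$record_id_a),
                      incident_id_of(candidates$record_id_b))
    keep <- keys %in% truth_keys(oracle, include_close = FALSE)
    out <- candidates[keep, , drop = FALSE]
  } else if (is.data.frame(oracle)) {
    need <- c("record_id_a", "record_id_b", "verdict")
    if (!all(need %in% names(oracle))) {
      fl_stop("review file must have columns: %s", paste(need, collapse = ", "),
              class = "fl_schema_error")
    }
    okeys <- pair_keys(oracle$record_id_a, oracle$record_id_b)
    ckeys <- pair_keys(candidates$record_id_a, candidates$record_id_b)
    verdict <- oracle$verdict[match(ckeys, okeys)]
    pending <- is.na(verdict) | verdict == "pending"
    if (any(pending)) {
      pairs <- paste(candidates$record_id_a[pending], candidates$record_id_b[pending],
                     sep = " / ")
      fl_stop("candidate pair(s) pending review: %s",
              paste(head(pairs, 10), collapse = "; "),
              class = "fl_pending_review_error",
              data = list(pending_pairs = candidates[pending, , drop = FALSE]))
    }
    out <- candidates[verdict == "match", , drop = FALSE]
  } else {
    fl_stop("oracle must be an fl_ground_truth or a review data frame",
            class = "fl_config_error")
  }
  rownames(out) <- NULL
  out
}

#' Fabricate non-match pairs from scrambled real records
#'
#' Samples real records from each dataset and independently permutes every
#' field column across the sample (dates among dates, vessels among
#' vessels), preserving marginal field distributions while destroying joint
#' structure. Any fake pair that would satisfy the candidate-proposal rule
#' is rejected and regenerated; generation fails after `10 * n` candidate
#' draws.
#'
#' @param a,b `fl_dataset` objects (each with at least 2 records).
#' @param n Number of non-match pairs required.
#' @param rule The proposal [matching_spec()] that fakes must *not* satisfy.
#' @param seed Integer seed (same seed, same output).
#' @return A list with fake record tables `records_a`, `records_b` (one row
#'   per pair, synthetic record ids) of class `fl_scrambled`.
#' @export
scramble_nonmatches <- function(a, b, n, rule, seed = 1L) {
  stopifnot(inherits(a, "fl_dataset"), inherits(b, "fl_dataset"))
  if (n < 1) fl_stop("n must be >= 1", class = "fl_config_error")
  if (nrow(a$records) < 2 || nrow(b$records) < 2) {
    fl_stop("cannot scramble a dataset with fewer than 2 records",
            class = "fl_generation_error")
  }
  scramble_cols <- c("incident_date", "incident_state", "vessel_official_number",
                     "latitude", "longitude", "people_on_board",
                     "miles_from_shore")
  with_seed(derive_seed(seed, "scramble"), {
    fake_block <- function(d, m) {
      rows <- d$records[sample.int(nrow(d$records), m, replace = TRUE), ,
                        drop = FALSE]
      for (col in scramble_cols) {
        rows[[col]] <- rows[[col]][sample.int(m)]
      }
      rows
    }
    acc_a <- NULL
    acc_b <- NULL
    drawn <- 0L
    while (is.null(acc_a) || nrow(acc_a) < n) {
      need <- n - if (is.null(acc_a)) 0L else nrow(acc_a)
      if (drawn + need > 10L * n) {
        fl_stop("could not generate %d scrambled non-matches within %d attempts",
                n, 10L * n, class = "fl_generation_error")
      }
      fa <- fake_block(a, need)
      fb <- fake_block(b, need)
      drawn <- drawn + need
      # re-apply the proposal rule pairwise; survivors are true non-matches
      pass <- logical(need)
      for (f in rule$fields) {
        cmp <- compare_field(f, fa, fb, seq_len(need), seq_len(need), rule)
        pass <- if (f == rule$fields[1]) cmp$score == 1L else pass & cmp$score == 1L
      }
      keep <- !pass
      acc_a <- rbind(acc_a, fa[keep, , drop = FALSE])
      acc_b <- rbind(acc_b, fb[keep, , drop = FALSE])
    }
    acc_a <- acc_a[seq_len(n), , drop = FALSE]
    acc_b <- acc_b[seq_len(n), , drop = FALSE]
    acc_a$record_id <- sprintf("SCR-%s-%04d", a$dataset_id, seq_len(n))
    acc_b$record_id <- sprintf("SCR-%s-%04d", b$dataset_id, seq_len(n))
    acc_a$incident_id <- acc_a$record_id
    acc_b$incident_id <- acc_b$record_id
    rownames(acc_a) <- rownames(acc_b) <- NULL
    structure(list(records_a = acc_a, records_b = acc_b,
                   dataset_a = a$dataset_id, dataset_b = b$dataset_id, n = n),
              class = "fl_scrambled")
  })
}

#' Assemble a labeled golden dataset
#'
#' Computes comparison vectors (with the working tolerances, which may be
#' wider than the proposal rule's) for the verified matches and the
#' scrambled non-matches, attaches labels and provenance, and shuffles rows
#' deterministically.
#'
#' @param matches Verified match pairs ([verify_candidates()] output).
#' @param nonmatches An `fl_scrambled` object.
#' @param a,b The source `fl_dataset` objects for the match side.
#' @param spec The working [matching_spec()].
#' @param seed Shuffle seed.
#' @return An object of class `fl_golden` with the score matrix, labels
#'   (`match`/`nonmatch`), provenance (`verified`/`scrambled`) and pair ids.
#' @export
assemble_golden <- function(matches, nonmatches, a, b, spec, seed = 1L) {
  stopifnot(inherits(nonmatches, "fl_scrambled"), inherits(spec, "matching_spec"))
  if (nrow(matches) == 0 || nonmatches$n == 0) {
    fl_stop("golden dataset needs at least one match and one non-match",
            class = "fl_validation_error")
  }
  ia <- match(matches$record_id_a, a$records$record_id)
  ib <- match(matches$record_id_b, b$records$record_id)
  if (anyNA(ia) || anyNA(ib)) {
    fl_stop("match pair refers to unknown record id(s)", class = "fl_validation_error")
  }
  mkeys <- pair_keys(matches$record_id_a, matches$record_id_b)
  nkeys <- pair_keys(nonmatches$records_a$record_id, nonmatches$records_b$record_id)
  if (anyDuplicated(c(mkeys, nkeys))) {
    fl_stop("a pair id appears in both the match and non-match sets",
            class = "fl_validation_error")
  }
  k <- length(spec$fields)
  vec_block <- function(ra, rb, i, j) {
    m <- length(i)
    scores <- matrix(0L, m, k, dimnames = list(NULL, spec$fields))
    missing <- matrix(FALSE, m, k, dimnames = list(NULL, spec$fields))
    for (f in spec$fields) {
      cmp <- compare_field(f, ra, rb, i, j, spec)
      scores[, f] <- cmp$score
      missing[, f] <- cmp$missing
    }
    list(scores = scores, missing = missing)
  }
  mb <- vec_block(a$records, b$records, ia, ib)
  nb <- vec_block(nonmatches$records_a, nonmatches$records_b,
                  seq_len(nonmatches$n), seq_len(nonmatches$n))
  scores <- rbind(mb$scores, nb$scores)
  missing <- rbind(mb$missing, nb$missing)
  labels <- c(rep("match", nrow(matches)), rep("nonmatch", nonmatches$n))
  provenance <- c(rep("verified", nrow(matches)), rep("scrambled", nonmatches$n))
  pairs <- data.frame(
    record_id_a = c(matches$record_id_a, nonmatches$records_a$record_id),
    record_id_b = c(matches$record_id_b, nonmatches$records_b$record_id),
    stringsAsFactors = FALSE
  )
  ord <- with_seed(derive_seed(seed, "golden-shuffle"),
                   sample.int(length(labels)))
  structure(
    list(scores = scores[ord, , drop = FALSE],
         missing = missing[ord, , drop = FALSE],
         labels = labels[ord], provenance = provenance[ord],
         pairs = pairs[ord, , drop = FALSE], spec = spec,
         dataset_a = a$dataset_id, dataset_b = b$dataset_id),
    class = "fl_golden"
  )
}

#' @export
print.fl_golden <- function(x, ...) {
  cat(sprintf("<fl_golden %s-%s: %d matches, %d non-matches, fields: %s>\n",
              x$dataset_a, x$dataset_b, sum(x$labels == "match"),
              sum(x$labels == "nonmatch"), paste(x$spec$fields, collapse = ", ")))
  invisible(x)
}
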