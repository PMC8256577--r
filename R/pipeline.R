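# pipeline: orchestrate the full six-pair, four-classifier study ---------

study_pairs <- function() {
  list(c("CFID", "OTR"), c("CFID", "VC"), c("CFID", "NFI"),
       c("OTR", "VC"), c("OTR", "NFI"), c("VC", "NFI"))
}

FL_CLASSIFIERS <- c("naive_bayes", "logistic_regression", "svm", "ecm")

#' Default matching variables per dataset pair
#'
#' Pairs involving the trauma registry can only match on incident date and
#' state (the registry records no vessel information and its positions are
#' mostly missing); all other pairs match on date, vessel official number
#' and latitude/longitude. People on board is available as an optional
#' extra field via `extra_fields`.
#'
#' @param extra_fields Fields appended to every pair's spec (e.g.
#'   `"people_on_board"`).
#' @return Named list of [matching_spec()] objects keyed by pair label.
#' @export
default_matching_specs <- function(extra_fields = character(0)) {
  otr_fields <- c("incident_date", "incident_state")
  vessel_fields <- c("incident_date", "vessel_official_number", "latlon")
  specs <- list(
    "CFID-OTR" = otr_fields, "CFID-VC" = vessel_fields,
    "CFID-NFI" = vessel_fields, "OTR-VC" = otr_fields,
    "OTR-NFI" = otr_fields, "VC-NFI" = vessel_fields
  )
  lapply(specs, function(f) matching_spec(unique(c(f, extra_fields))))
}

#' Default decision thresholds per pair and classifier
#'
#' The probabilistic classifiers need thresholds far below the textbook
#' 0.5 to capture every true match in these small, noisy datasets: naive
#' Bayes and logistic regression run at 0.005 (0.01 for the NFI-VC pair),
#' ECM at 0.5 (0.2 for the OTR-NFI pair), and the SVM is fixed at 0.5.
#'
#' @return Data frame with `pair`, `classifier`, `threshold`.
#' @export
default_thresholds <- function() {
  pairs <- vapply(study_pairs(), function(p) pair_label(p[1], p[2]), character(1))
  grid <- expand.grid(pair = pairs, classifier = FL_CLASSIFIERS,
                      stringsAsFactors = FALSE)
  grid$threshold <- ifelse(grid$classifier %in% c("naive_bayes", "logistic_regression"),
                           ifelse(grid$pair == "VC-NFI", 0.01, 0.005),
                           ifelse(grid$classifier == "ecm" & grid$pair == "OTR-NFI",
                                  0.2, 0.5))
  grid
}

#' Configure a linkage study
#'
#' @param mode `"synthetic"` (generate the universe, evaluate against the
#'   planted truth) or `"real"` (load datasets from `paths`, verify golden
#'   candidates against `review_files`).
#' @param universe A [universe_config()] (synthetic mode).
#' @param paths Named list of dataset CSV paths (real mode).
#' @param review_files Named list (by pair label) of review CSVs with
#'   columns `record_id_a`, `record_id_b`, `verdict` (real mode).
#' @param classifiers Subset of
#'   `c("naive_bayes", "logistic_regression", "svm", "ecm")`.
#' @param matching Per-pair [matching_spec()] list
#'   ([default_matching_specs()]).
#' @param thresholds Data frame from [default_thresholds()] (or edited).
#' @param nonmatch_ratio,min_nonmatches Scrambled non-matches per golden
#'   set: `max(ratio * matches, min)`.
#' @param accounting_classifier Whose links drive the study-level match
#'   accounting.
#' @param seed Study seed (defaults to the universe seed).
#' @return An object of class `study_config`.
#' @export
study_config <- function(mode = c("synthetic", "real"),
                         universe = universe_config(),
                         paths = NULL, review_files = NULL,
                         classifiers = FL_CLASSIFIERS,
                         matching = default_matching_specs(),
                         thresholds = default_thresholds(),
                         nonmatch_ratio = 10L, min_nonmatches = 50L,
                         accounting_classifier = "naive_bayes",
                         seed = NULL) {
  mode <- match.arg(mode)
  bad <- setdiff(classifiers, FL_CLASSIFIERS)
  if (length(bad)) {
    fl_stop("unknown classifier(s): %s", paste(bad, collapse = ", "),
            class = "fl_config_error")
  }
  valid_pairs <- vapply(study_pairs(), function(p) pair_label(p[1], p[2]), character(1))
  if (!all(names(matching) %in% valid_pairs)) {
    fl_stop("matching specs must be keyed by the six dataset-pair labels",
            class = "fl_config_error")
  }
  if (mode == "real" && is.null(paths)) {
    fl_stop("real mode requires dataset paths", class = "fl_config_error")
  }
  structure(
    list(mode = mode, universe = universe, paths = paths,
         review_files = review_files, classifiers = classifiers,
         matching = matching, thresholds = thresholds,
         nonmatch_ratio = nonmatch_ratio, min_nonmatches = min_nonmatches,
         accounting_classifier = accounting_classifier,
         seed = as.integer(seed %||% universe$seed)),
    class = "study_config"
  )
}

threshold_for <- function(thresholds, pair, classifier) {
  hit <- thresholds$threshold[thresholds$pair == pair &
                                thresholds$classifier == classifier]
  if (!length(hit)) {
    if (classifier == "svm") 0.5 else 0.005
  } else {
    hit[1]
  }
}

fit_for <- function(classifier, golden, cm, seed) {
  if (classifier != "ecm" && is.null(golden)) {
    fl_stop("no golden matches for this pair: supervised classifier cannot be trained",
            class = "fl_no_golden_error")
  }
  switch(classifier,
         naive_bayes = fit_naive_bayes(golden),
         logistic_regression = fit_logistic(golden),
         svm = fit_svm(golden, seed = seed),
         ecm = fit_ecm(cm))
}

aggregate_close_groups <- function(group_list) {
  groups <- do.call(c, lapply(group_list, `[[`, "groups"))
  close_links <- do.call(rbind, lapply(group_list, `[[`, "close_links"))
  structure(
    list(groups = groups %||% list(),
         total_close = sum(vapply(group_list, `[[`, integer(1), "total_close")),
         close_links = close_links),
    class = "fl_close_groups"
  )
}

#' Run the full linkage study
#'
#' Executes all six dataset pairs with the selected classifiers: builds the
#' full comparison index, derives the golden dataset (rudimentary proposal,
#' oracle verification, scrambled non-matches), fits and applies each
#' classifier at its threshold, and computes Table-style quality metrics
#' against the golden matches over the full cross-product. In synthetic
#' mode the accepted links of the accounting classifier are then confirmed
#' against the planted ground truth and rolled up into the study-level
#' match accounting (true matches, close matches, duplicates, multi-dataset
#' cases, post-dedup remainder). A failure in one (pair, classifier) cell
#' is recorded and the remaining cells continue.
#'
#' @param cfg A [study_config()].
#' @return An object of class `linkage_study`.
#' @export
run_study <- function(cfg = study_config()) {
  stopifnot(inherits(cfg, "study_config"))
  if (cfg$mode == "synthetic") {
    universe <- generate_universe(cfg$universe)
    datasets <- universe$datasets
    truth <- universe$truth
  } else {
    universe <- NULL
    truth <- NULL
    datasets <- lapply(setNames(FL_DATASET_IDS, FL_DATASET_IDS), function(ds) {
      load_dataset(cfg$paths[[ds]], ds)
    })
  }
  cfid_person <- expand_person_level(datasets$CFID)
  view_for <- function(ds, other) {
    if (ds == "CFID" && other %in% c("OTR", "NFI")) cfid_person else datasets[[ds]]
  }

  metrics_rows <- list()
  links_store <- list()
  golden_rows <- list()
  failures <- list()
  truth_true <- list()
  truth_close <- list()
  agreement_rows <- list()
  pending_review <- list()

  for (pr in study_pairs()) {
    lab <- pair_label(pr[1], pr[2])
    da <- view_for(pr[1], pr[2])
    db <- view_for(pr[2], pr[1])
    spec <- cfg$matching[[lab]]
    if (is.null(spec)) spec <- default_matching_specs()[[lab]]
    cm <- build_comparison_matrix(da, db, spec)
    combos <- nrow(cm$scores)

    # golden dataset: proposal (all rule fields agree) + oracle verification
    cand <- cm_pairs(cm, rowSums(cm$scores == 1L, na.rm = TRUE) == ncol(cm$scores))
    golden <- NULL
    verified <- cand[0, , drop = FALSE]
    if (cfg$mode == "synthetic") {
      verified <- verify_candidates(cand, truth)
    } else {
      review_path <- cfg$review_files[[lab]]
      if (is.null(review_path)) {
        pending_review[[lab]] <- cand
      } else {
        verified <- verify_candidates(cand, read.csv(review_path,
                                                     colClasses = "character"))
      }
    }
    if (nrow(verified) >= 1 && combos > nrow(verified)) {
      n_non <- max(cfg$nonmatch_ratio * nrow(verified), cfg$min_nonmatches)
      nonm <- scramble_nonmatches(da, db, n_non, spec,
                                  seed = derive_seed(cfg$seed, paste0("nonmatch-", lab)))
      golden <- assemble_golden(verified, nonm, da, db, spec,
                                seed = derive_seed(cfg$seed, paste0("golden-", lab)))
    }
    golden_rows[[lab]] <- data.frame(
      pair = lab, candidates = nrow(cand), golden_matches = nrow(verified),
      golden_nonmatches = if (is.null(golden)) 0L else sum(golden$labels == "nonmatch"),
      stringsAsFactors = FALSE
    )

    links_store[[lab]] <- list()
    for (cl in cfg$classifiers) {
      thr <- threshold_for(cfg$thresholds, lab, cl)
      cell <- tryCatch({
        model <- fit_for(cl, golden, cm, seed = derive_seed(cfg$seed, paste0("svm-", lab)))
        links <- classify_links(predict(model, cm), thr)
        cc <- confusion_counts(links, verified, combos)
        mets <- linkage_metrics(cc)
        list(links = links, cc = cc, mets = mets, status = "ok")
      }, error = function(e) {
        status <- if (inherits(e, "fl_no_golden_error")) {
          paste0("skipped: ", conditionMessage(e))
        } else {
          paste0("failed: ", conditionMessage(e))
        }
        list(links = NULL, cc = c(TP = NA, FP = NA, FN = NA, TN = NA),
             mets = list(precision = NA, recall = NA, f_score = NA),
             status = status)
      })
      if (startsWith(cell$status, "failed")) {
        failures[[length(failures) + 1L]] <- data.frame(
          pair = lab, classifier = cl, reason = cell$status, stringsAsFactors = FALSE)
      } else if (identical(cell$status, "ok")) {
        links_store[[lab]][[cl]] <- cell$links
      }
      metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
        pair = lab, classifier = cl, threshold = thr, combinations = combos,
        golden_matches = nrow(verified),
        TP = cell$cc[["TP"]], FP = cell$cc[["FP"]], FN = cell$cc[["FN"]],
        TN = cell$cc[["TN"]], precision = cell$mets$precision,
        recall = cell$mets$recall, f_score = cell$mets$f_score,
        status = cell$status, stringsAsFactors = FALSE
      )
    }

    # confirm the accounting classifier's links against the planted truth
    acc_cl <- cfg$accounting_classifier
    if (!is.null(truth) && !is.null(links_store[[lab]][[acc_cl]])) {
      lk <- as.data.frame(links_store[[lab]][[acc_cl]])
      keys <- pair_keys(incident_id_of(lk$record_id_a), incident_id_of(lk$record_id_b))
      confirmed <- lk[keys %in% truth_keys(truth, include_close = TRUE), , drop = FALSE]
      cg <- flag_close_matches(confirmed, da, db, spec)
      close_keys <- pair_keys(cg$close_links$record_id_a, cg$close_links$record_id_b)
      is_close <- pair_keys(confirmed$record_id_a, confirmed$record_id_b) %in% close_keys
      true_links <- confirmed[!is_close, , drop = FALSE]
      inc_pairs <- unique(data.frame(
        dataset_a = pr[1], record_id_a = incident_id_of(true_links$record_id_a),
        dataset_b = pr[2], record_id_b = incident_id_of(true_links$record_id_b),
        stringsAsFactors = FALSE))
      rownames(inc_pairs) <- NULL
      truth_true[[lab]] <- inc_pairs
      truth_close[[lab]] <- cg
      if (nrow(true_links)) {
        fa <- field_agreement_report(true_links, da, db)
        fa$pair <- lab
        agreement_rows[[lab]] <- fa
      }
    }
  }

  metrics <- do.call(rbind, metrics_rows)
  rownames(metrics) <- NULL

  accounting <- NULL
  true_matches <- NULL
  close_groups <- NULL
  if (!is.null(truth) && length(truth_true)) {
    true_matches <- do.call(rbind, truth_true)
    rownames(true_matches) <- NULL
    close_groups <- aggregate_close_groups(truth_close)
    accounting <- account_matches(true_matches, close_groups)
  }

  structure(
    list(mode = cfg$mode, metrics = metrics,
         golden_summary = do.call(rbind, golden_rows),
         links = links_store, true_matches = true_matches,
         close_groups = close_groups, accounting = accounting,
         field_agreement = if (length(agreement_rows)) do.call(rbind, agreement_rows) else NULL,
         unmatched = if (!is.null(truth)) truth$unmatched else NULL,
         pending_review = pending_review,
         universe = universe, config = cfg, failures = failures),
    class = "linkage_study"
  )
}

#' @export
print.linkage_study <- function(x, ...) {
  cat(sprintf("Linkage study (%s mode): %d pairs x %d classifier(s)\n",
              x$mode, length(unique(x$metrics$pair)),
              length(unique(x$metrics$classifier))))
  show <- x$metrics[, c("pair", "classifier", "threshold", "golden_matches",
                        "TP", "FP", "FN", "f_score")]
  show$f_score <- round(show$f_score, 2)
  print(show, row.names = FALSE)
  if (!is.null(x$accounting)) {
    cat("\n")
    print(x$accounting)
  }
  if (length(x$failures)) {
    cat(sprintf("\n%d cell(s) failed; see $failures\n", length(x$failures)))
  }
  invisible(x)
}

#' @export
summary.linkage_study <- function(object, ...) {
  out <- list(
    metrics = object$metrics,
    true_match_total = if (is.null(object$true_matches)) NA_integer_ else nrow(object$true_matches),
    close_cases = if (is.null(object$close_groups)) NA_integer_ else object$close_groups$total_close,
    accounting = object$accounting
  )
  class(out) <- "summary.linkage_study"
  out
}

#' @export
print.summary.linkage_study <- function(x, ...) {
  print(x$metrics[, c("pair", "classifier", "TP", "FP", "FN", "f_score")],
        row.names = FALSE)
  if (!is.null(x$accounting)) print(x$accounting)
  invisible(x)
}

#' Write the study's report files
#'
#' Emits `metrics.csv` (one row per pair and classifier; f-scores to two
#' decimals as in study reports, full precision in the R object),
#' `matches.csv` (confirmed true matches with duplicate flags),
#' `field_agreement.csv`, and `accounting.json`. With `write_scores = TRUE`
#' the per-pair link sets of every classifier are also exported.
#'
#' @param study A `linkage_study`.
#' @param dir Output directory.
#' @param write_scores Also export the accepted links per classifier.
#' @return `dir`, invisibly.
#' @export
write_study_reports <- function(study, dir, write_scores = FALSE) {
  stopifnot(inherits(study, "linkage_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  metrics <- study$metrics
  metrics$precision <- round(metrics$precision, 2)
  metrics$recall <- round(metrics$recall, 2)
  metrics$f_score <- round(metrics$f_score, 2)
  write.csv(metrics, file.path(dir, "metrics.csv"), row.names = FALSE, na = "")
  if (!is.null(study$true_matches)) {
    matches <- flag_duplicates(study$true_matches)
    write.csv(matches, file.path(dir, "matches.csv"), row.names = FALSE, na = "")
  }
  if (!is.null(study$field_agreement)) {
    write.csv(study$field_agreement, file.path(dir, "field_agreement.csv"),
              row.names = FALSE, na = "")
  }
  if (!is.null(study$accounting)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      fl_stop("jsonlite is required to write accounting.json", class = "fl_config_error")
    }
    acc <- study$accounting
    acc$purged_records <- NULL
    jsonlite::write_json(unclass(acc), file.path(dir, "accounting.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (write_scores) {
    for (lab in names(study$links)) {
      for (cl in names(study$links[[lab]])) {
        fn <- sprintf("links_%s_%s.csv", gsub("-", "_", lab), cl)
        write.csv(as.data.frame(study$links[[lab]][[cl]]), file.path(dir, fn),
                  row.names = FALSE, na = "")
      }
    }
  }
  invisible(dir)
}
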