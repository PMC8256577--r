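# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, expr, envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# The default synthetic universe at the study conditions.
default_universe <- function(seed = 101L) {
  memo("universe", generate_universe(universe_config(seed = seed)))
}

# Naive-Bayes-only end-to-end study over the default universe.
default_nb_study <- function(seed = 101L) {
  memo("nb_study", run_study(study_config(universe = universe_config(seed = seed),
                                          classifiers = "naive_bayes")))
}

# A noise-free universe: degenerate jitter, no missingness, no state-only
# vessels -- every planted pair agrees exactly on all matching variables.
noise_free_universe <- function(seed = 77L) {
  memo("clean_universe", {
    pm <- perturbation_model(
      date_jitter = c(`-1` = 0, `0` = 1, `1` = 0),
      latlon_view_jitter_deg = 0,
      latlon_missing_rate = c(CFID = 0, OTR = 0, VC = 0, NFI = 0),
      state_missing_rate = c(CFID = 0, OTR = 0, VC = 0, NFI = 0),
      vessel_substitution_rate = 0,
      people_missing_rate = 0, miles_missing_rate = 0,
      narrative_missing_rate = 0)
    generate_universe(universe_config(seed = seed, perturbation = pm,
                                      otr_nfi_missing_state = 0L))
  })
}

# Small handmade datasets for unit tests.
tiny_records <- function(ids, dataset, dates, states = "OR", vessels = NA,
                         lat = NA, lon = NA, people = NA, level = "incident") {
  n <- length(ids)
  normalize_record(data.frame(
    record_id = ids, dataset = rep_len(dataset, n), level = rep_len(level, n),
    incident_date = dates,
    incident_state = rep_len(states, n),
    vessel_official_number = rep_len(vessels, n),
    latitude = rep_len(lat, n), longitude = rep_len(lon, n),
    people_on_board = rep_len(people, n),
    stringsAsFactors = FALSE
  ), dataset_id = dataset)
}

tiny_dataset <- function(...) {
  r <- tiny_records(...)
  new_dataset(r$dataset[1], r)
}

# Look up one record of a dataset by id as a one-row data frame.
record_by_id <- function(d, id) {
  row <- d$records[d$records$record_id == id, , drop = FALSE]
  stopifnot(nrow(row) == 1)
  row
}

# A small golden dataset built directly from score patterns.
golden_from_scores <- function(scores, labels, fields = colnames(scores)) {
  colnames(scores) <- fields
  structure(
    list(scores = scores, missing = matrix(FALSE, nrow(scores), ncol(scores)),
         labels = labels, provenance = ifelse(labels == "match", "verified", "scrambled"),
         pairs = data.frame(record_id_a = sprintf("a%d", seq_len(nrow(scores))),
                            record_id_b = sprintf("b%d", seq_len(nrow(scores))),
                            stringsAsFactors = FALSE),
         spec = matching_spec(rep_len(c("incident_date", "incident_state",
                                        "vessel_official_number", "latlon",
                                        "people_on_board"), ncol(scores))[seq_len(ncol(scores))]),
         dataset_a = "CFID", dataset_b = "VC"),
    class = "fl_golden"
  )
}
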