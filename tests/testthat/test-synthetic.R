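test_that("default universe reproduces the study's dataset dimensions", {
  u <- default_universe()
  expect_equal(u$datasets$CFID$counts[["records"]], 1315)
  expect_equal(u$datasets$CFID$counts[["persons"]], 2966)
  expect_equal(u$datasets$VC$counts[["records"]], 524)
  expect_equal(u$datasets$VC$counts[["persons"]], 0)
  expect_equal(u$datasets$NFI$counts[["records"]], 232)
  expect_equal(u$datasets$OTR$counts[["records"]], 11)
  expect_equal(nrow(expand_person_level(u$datasets$CFID)$records), 2966)
})

test_that("planted overlap structure matches the configured counts", {
  u <- default_universe()
  gt <- u$truth
  counts <- c(
    `CFID-OTR` = nrow(ground_truth_pairs(gt, "CFID", "OTR")),
    `CFID-VC` = nrow(ground_truth_pairs(gt, "CFID", "VC")),
    `CFID-NFI` = nrow(ground_truth_pairs(gt, "CFID", "NFI")),
    `OTR-VC` = nrow(ground_truth_pairs(gt, "OTR", "VC")),
    `OTR-NFI` = nrow(ground_truth_pairs(gt, "OTR", "NFI")),
    `VC-NFI` = nrow(ground_truth_pairs(gt, "VC", "NFI"))
  )
  expect_equal(unname(counts), c(5, 9, 12, 0, 5, 10))
  expect_equal(sum(counts), 41)
  # close matches: 3 multi-person groups totalling 8 person cases
  expect_equal(nrow(gt$close_groups), 3)
  expect_equal(sum(gt$close_groups$n_persons), 8)
  # unmatched trauma-registry cases with their justifications
  expect_equal(sum(gt$unmatched$reason == "out_of_region"), 2)
  expect_equal(sum(gt$unmatched$reason == "recreational"), 2)

  # symmetry: (a,b) equals (b,a) under pair reversal
  ab <- ground_truth_pairs(gt, "CFID", "VC")
  ba <- ground_truth_pairs(gt, "VC", "CFID")
  expect_setequal(paste(ab$record_id_a, ab$record_id_b),
                  paste(ba$record_id_b, ba$record_id_a))
  expect_error(ground_truth_pairs(gt, "CFID", "CFID"), class = "fl_config_error")
})

test_that("planted pairs agree on their matching variables by construction", {
  u <- default_universe()
  specs <- default_matching_specs()
  state_misses <- 0L
  for (pr in list(c("CFID", "OTR"), c("CFID", "VC"), c("CFID", "NFI"),
                  c("OTR", "NFI"), c("VC", "NFI"))) {
    spec <- specs[[paste(pr, collapse = "-")]]
    gtp <- ground_truth_pairs(u$truth, pr[1], pr[2])
    for (r in seq_len(nrow(gtp))) {
      ra <- record_by_id(u$datasets[[pr[1]]], gtp$record_id_a[r])
      rb <- record_by_id(u$datasets[[pr[2]]], gtp$record_id_b[r])
      cmp <- compare_pair(ra, rb, spec)
      if (any(cmp$scores == 0)) {
        # the single engineered exception: one OTR-NFI link with state removed
        expect_equal(paste(sort(pr), collapse = "-"), "NFI-OTR")
        expect_equal(unname(cmp$scores["incident_state"]), 0L)
        expect_true(cmp$missing[["incident_state"]])
        expect_equal(unname(cmp$scores["incident_date"]), 1L)
        state_misses <- state_misses + 1L
      }
    }
  }
  expect_equal(state_misses, 1L)
})

test_that("noise-free perturbation makes planted pairs agree exactly", {
  u <- noise_free_universe()
  spec <- matching_spec(c("incident_date", "incident_state",
                          "vessel_official_number", "latlon"),
                        date_tolerance_days = 0, latlon_tolerance_deg = 0)
  gtp <- ground_truth_pairs(u$truth, "CFID", "VC")
  for (r in seq_len(nrow(gtp))) {
    ra <- record_by_id(u$datasets$CFID, gtp$record_id_a[r])
    rb <- record_by_id(u$datasets$VC, gtp$record_id_b[r])
    expect_true(all(compare_pair(ra, rb, spec)$scores == 1L))
  }
})

test_that("generated records respect their dataset's date range", {
  u <- default_universe()
  for (ds in names(u$datasets)) {
    d <- u$datasets[[ds]]
    expect_true(all(d$records$incident_date >= d$date_range[1] &
                      d$records$incident_date <= d$date_range[2]), info = ds)
  }
})

test_that("generation is deterministic: same seed, byte-identical CSVs", {
  cfg <- universe_config(seed = 404)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_universe(generate_universe(cfg), d1)
  write_universe(generate_universe(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # while a different seed produces different data
  write_universe(generate_universe(universe_config(seed = 405)), d2)
  expect_false(identical(readLines(file.path(d1, "cfid.csv")),
                         readLines(file.path(d2, "cfid.csv"))))
})

test_that("zero overlap spec yields an empty ground truth", {
  cfg <- universe_config(
    seed = 5,
    overlap = list(CFID_OTR = 0L, CFID_VC = 0L, CFID_NFI = 0L, OTR_VC = 0L,
                   OTR_NFI = 0L, NFI_VC = 0L, CFID_OTR_NFI = 0L, CFID_NFI_VC = 0L),
    close_person_counts = integer(0),
    otr_nfi_missing_state = 0L,
    unmatched_otr = c(out_of_region = 0L, recreational = 0L))
  u <- generate_universe(cfg)
  expect_equal(nrow(u$truth$links), 0)
  expect_equal(nrow(ground_truth_pairs(u$truth, "CFID", "VC")), 0)
  expect_equal(u$datasets$OTR$counts[["records"]], 11)
})

test_that("infeasible overlap specs fail before any generation", {
  expect_error(universe_config(overlap = list(
    CFID_OTR = 2L, CFID_VC = 9L, CFID_NFI = 12L, OTR_VC = 0L, OTR_NFI = 5L,
    NFI_VC = 10L, CFID_OTR_NFI = 3L, CFID_NFI_VC = 1L)),
    class = "fl_config_error")  # triples exceed the pairwise total
  expect_error(universe_config(sizes = list(CFID_incidents = 1315L,
                                            CFID_persons = 2966L,
                                            VC = 524L, NFI = 20L, OTR = 11L)),
               class = "fl_config_error")  # planted NFI rows exceed its size
  expect_error(perturbation_model(date_jitter = c(`-1` = 0.5, `0` = 0.2, `1` = 0.5)),
               class = "fl_config_error")
  expect_error(perturbation_model(vessel_substitution_rate = 1.2),
               class = "fl_config_error")
})

test_that("perturb_record honors the identity limit and jitter bounds", {
  pm0 <- perturbation_model(
    date_jitter = c(`-1` = 0, `0` = 1, `1` = 0),
    latlon_view_jitter_deg = 0,
    latlon_missing_rate = c(CFID = 0, OTR = 0, VC = 0, NFI = 0),
    state_missing_rate = c(CFID = 0, OTR = 0, VC = 0, NFI = 0),
    vessel_substitution_rate = 0, people_missing_rate = 0,
    miles_missing_rate = 0, narrative_missing_rate = 0)
  r <- tiny_records("C9", "CFID", "2011-04-05", vessels = "123456",
                    lat = "44.1", lon = "-124.5", people = "3")
  set.seed(1)
  out <- perturb_record(r, pm0, new_id = "CFID-0001")
  expect_equal(out$record_id, "CFID-0001")
  out$record_id <- r$record_id
  out$incident_id <- r$incident_id
  expect_equal(out, r)

  # position jitter never exceeds +/-0.5 degrees per axis
  pm <- perturbation_model()
  set.seed(2)
  deltas <- replicate(500, {
    p <- perturb_record(r, pm)
    c(abs(p$latitude - r$latitude), abs(p$longitude - r$longitude))
  })
  expect_true(all(deltas[!is.na(deltas)] <= 0.5))
})

test_that("date jitter frequencies match the configured distribution", {
  # binomial oracle: empirical offset shares within 3 sigma of p
  pm <- perturbation_model(date_jitter = c(`-1` = 0.25, `0` = 0.5, `1` = 0.25))
  r <- tiny_records("C9", "CFID", "2011-04-05")
  n <- 10000
  set.seed(3)
  offs <- replicate(n, as.integer(perturb_record(r, pm)$incident_date - r$incident_date))
  for (off in c(-1, 0, 1)) {
    p <- pm$date_jitter[[as.character(off)]]
    expect_lt(abs(mean(offs == off) - p), 3 * sqrt(p * (1 - p) / n))
  }
})
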