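test_that("linkage metrics follow the precision/recall/f definitions", {
  m <- linkage_metrics(c(TP = 4, FP = 6, FN = 1, TN = 32615))
  expect_equal(m$precision, 0.4)
  expect_equal(m$recall, 0.8)
  expect_equal(round(m$f_score, 2), 0.53)

  m2 <- linkage_metrics(c(TP = 8, FP = 0, FN = 1, TN = 0))
  expect_equal(round(m2$f_score, 2), 0.94)

  # 0/0 convention: zero true positives give zero metrics, not NaN
  m3 <- linkage_metrics(c(TP = 0, FP = 0, FN = 5, TN = 100))
  expect_equal(unlist(m3), c(precision = 0, recall = 0, f_score = 0))

  # f = 1 iff no errors with TP > 0; always within [0, 1]
  expect_equal(linkage_metrics(c(TP = 3, FP = 0, FN = 0))$f_score, 1)
  set.seed(19)
  for (i in 1:25) {
    mm <- linkage_metrics(c(TP = sample(0:20, 1), FP = sample(0:20, 1),
                            FN = sample(0:20, 1)))
    expect_true(all(unlist(mm) >= 0 & unlist(mm) <= 1))
  }
})

test_that("confusion counts partition the full pair universe", {
  links <- data.frame(record_id_a = c("a1", "a2"), record_id_b = c("b1", "b2"))
  truth <- data.frame(record_id_a = c("a1", "a2", "a3"),
                      record_id_b = c("b1", "b2", "b3"))
  cc <- confusion_counts(links, truth, 100)
  expect_equal(unname(cc[]), c(2L, 0L, 1L, 97L))
  expect_equal(sum(cc), 100)

  # perfect and silent classifiers
  expect_equal(unname(confusion_counts(truth[1:2, ], truth[1:2, ], 100)[]),
               c(2L, 0L, 0L, 98L))
  expect_equal(unname(confusion_counts(links[0, ], truth, 100)[]),
               c(0L, 0L, 3L, 97L))
  # shuffled pair order changes nothing
  expect_equal(confusion_counts(links[2:1, ], truth[c(3, 1, 2), ], 100), cc)
  expect_error(confusion_counts(links, truth, 2), class = "fl_validation_error")
})

test_that("duplicate flags follow the declared disjointness structure", {
  st <- default_nb_study()
  matches <- flag_duplicates(st$true_matches)
  by_pair <- table(paste(matches$dataset_a, matches$dataset_b, sep = "-"),
                   matches$is_duplicate)
  expect_equal(unname(by_pair["CFID-VC", "TRUE"]), 9)
  expect_equal(unname(by_pair["CFID-NFI", "TRUE"]), 12)
  expect_equal(sum(matches$is_duplicate), 21)

  # including the close-match person cases, the CFID-NFI pair carries 20 flags
  close_rows <- data.frame(dataset_a = "CFID", dataset_b = "NFI",
                           n_cases = c(3L, 3L, 2L))
  all_rows <- rbind(cbind(matches[, c("dataset_a", "dataset_b")], n_cases = 1L),
                    close_rows)
  flagged <- flag_duplicates(all_rows)
  cfid_nfi <- flagged$dataset_a == "CFID" & flagged$dataset_b == "NFI"
  expect_equal(sum(flagged$n_cases[cfid_nfi & flagged$is_duplicate]), 20)
  expect_equal(attr(flagged, "duplicate_cases"), 29)

  # no disjointness declared, no flags
  none <- flag_duplicates(matches, disjointness = list())
  expect_false(any(none$is_duplicate))
})

test_that("close-match groups capture unresolvable multi-person incidents", {
  # one OTR record linking three indistinguishable persons of one incident
  a <- tiny_dataset("T1", "OTR", "2012-06-01", level = "person")
  crew <- tiny_records(c("C1#1", "C1#2", "C1#3"), "CFID",
                       "2012-06-01", level = "person")
  b <- new_dataset("CFID", crew)
  links <- data.frame(dataset_a = "OTR", record_id_a = "T1",
                      dataset_b = "CFID", record_id_b = c("C1#1", "C1#2", "C1#3"),
                      stringsAsFactors = FALSE)
  spec <- matching_spec(c("incident_date", "incident_state"))
  cg <- flag_close_matches(links, a, b, spec)
  expect_equal(length(cg$groups), 1)
  expect_equal(nrow(cg$close_links), 3)
  expect_equal(cg$total_close, 3)

  # one-to-one links are never close
  one <- links[1, ]
  expect_equal(length(flag_close_matches(one, a, b, spec)$groups), 0)

  # the default synthetic run carries exactly 8 close person cases
  st <- default_nb_study()
  expect_equal(st$close_groups$total_close, 8)
  expect_equal(length(st$close_groups$groups), 3)
  expect_setequal(vapply(st$close_groups$groups, `[[`, integer(1), "n_close"),
                  c(3L, 3L, 2L))
})

test_that("field agreement reflects the planted accuracy model", {
  # noise-free universe: everything compared agrees
  u0 <- noise_free_universe()
  gtp <- ground_truth_pairs(u0$truth, "CFID", "VC")
  fa0 <- field_agreement_report(gtp, u0$datasets$CFID, u0$datasets$VC,
                                fields = c("incident_date", "incident_state",
                                           "vessel_official_number", "latlon"))
  expect_true(all(fa0$agreement == 1))

  # default study: miles from shore never agrees, state always does
  st <- default_nb_study()
  fa <- st$field_agreement
  miles <- fa[fa$field == "miles_from_shore", ]
  expect_true(all(miles$agreement[miles$n_compared > 0] == 0))
  state <- fa[fa$field == "incident_state", ]
  expect_true(all(state$agreement[state$n_compared > 0] == 1))
  dates <- fa[fa$field == "incident_date", ]
  expect_true(all(dates$agreement == 1))  # within +/-1 day by construction

  expect_error(field_agreement_report(gtp[0, ], u0$datasets$CFID, u0$datasets$VC),
               class = "fl_validation_error")
})

test_that("match accounting reproduces the dedup and overlap arithmetic", {
  st <- default_nb_study()
  acc <- st$accounting
  expect_equal(acc$true_total, 41)
  expect_equal(acc$duplicate_true, 21)
  expect_equal(acc$duplicates_total, 29)
  expect_equal(acc$multiset_cases, 4)
  expect_equal(acc$absorbed, 4)
  expect_equal(acc$remainder_total, 16)
  expect_equal(acc$remainder_per_pair[["CFID-OTR"]], 5)
  expect_equal(acc$remainder_per_pair[["OTR-NFI"]], 2)
  expect_equal(acc$remainder_per_pair[["VC-NFI"]], 9)
  # conservation: true = remainder + duplicates + component-absorbed
  expect_equal(acc$true_total,
               acc$remainder_total + acc$duplicate_true + acc$absorbed)

  # no links anywhere: all-zero accounting
  none <- account_matches(st$true_matches[0, ])
  expect_equal(none$true_total, 0)
  expect_equal(none$remainder_total, 0)
  expect_equal(none$multiset_cases, 0)
})
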