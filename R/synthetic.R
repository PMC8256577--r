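# synthetic_data: four linked synthetic datasets with planted truth ------

# Approximate coastal bounding boxes (lat_lo, lat_hi, lon_lo, lon_hi) used
# to place incidents; realism of coastlines is a non-goal.
STATE_BOX <- list(
  OR = c(42.0, 46.2, -125.5, -123.9),
  WA = c(46.2, 48.5, -125.5, -123.5),
  CA = c(32.5, 42.0, -125.0, -117.0),
  AK = c(51.5, 61.0, -170.0, -140.0),
  MA = c(41.2, 42.9, -71.0, -69.9),
  LA = c(28.9, 30.1, -93.8, -89.0),
  TX = c(26.0, 29.7, -97.4, -93.8),
  FL = c(24.5, 30.4, -87.6, -80.0),
  NJ = c(38.9, 40.5, -74.9, -73.9),
  VA = c(36.5, 38.0, -76.4, -75.5)
)

CFID_STATE_PROB <- c(AK = 0.28, WA = 0.12, OR = 0.08, CA = 0.08, MA = 0.10,
                     LA = 0.08, TX = 0.06, FL = 0.10, NJ = 0.05, VA = 0.05)

#' Field accuracy and missingness model for the synthetic universe
#'
#' Describes how each dataset's view of a latent incident is perturbed:
#' dates jittered by at most one day, positions jittered so that two views
#' of the same incident differ by at most `2 * latlon_view_jitter_deg`
#' degrees per axis, per-dataset missingness for position and state, a
#' share of the fleet identified by a state registration number instead of
#' a USCG official number, and miles-from-shore drawn independently per
#' view (so it never agrees between datasets).
#'
#' @param date_jitter Named probabilities for offsets -1, 0, +1 days;
#'   must sum to 1.
#' @param latlon_view_jitter_deg Half-width of the uniform per-view
#'   position jitter per axis. The default 0.25 keeps any two views of one
#'   incident within +/-0.5 degrees of each other.
#' @param latlon_missing_rate Named per-dataset missing rates for
#'   latitude/longitude (high for the trauma registry).
#' @param state_missing_rate Named per-dataset missing rates for the
#'   incident state.
#' @param vessel_substitution_rate Share of the synthetic fleet carrying a
#'   state registration number in place of an official number.
#' @param people_missing_rate,miles_missing_rate,narrative_missing_rate
#'   Scalar missing rates.
#' @param miles_range Range of the per-view miles-from-shore draw.
#' @return An object of class `perturbation_model`.
#' @export
perturbation_model <- function(date_jitter = c(`-1` = 0.15, `0` = 0.70, `1` = 0.15),
                               latlon_view_jitter_deg = 0.25,
                               latlon_missing_rate = c(CFID = 0.10, OTR = 0.70,
                                                       VC = 0.10, NFI = 0.10),
                               state_missing_rate = c(CFID = 0.01, OTR = 0.00,
                                                      VC = 0.02, NFI = 0.02),
                               vessel_substitution_rate = 0.10,
                               people_missing_rate = 0.03,
                               miles_missing_rate = 0.05,
                               narrative_missing_rate = 0.02,
                               miles_range = c(0, 60)) {
  if (!isTRUE(all.equal(sum(date_jitter), 1)) || length(date_jitter) != 3) {
    fl_stop("date_jitter must give probabilities for offsets -1, 0, +1 summing to 1",
            class = "fl_config_error")
  }
  rates <- c(latlon_missing_rate, state_missing_rate, vessel_substitution_rate,
             people_missing_rate, miles_missing_rate, narrative_missing_rate)
  if (any(rates < 0 | rates > 1)) {
    fl_stop("all rates must lie in [0, 1]", class = "fl_config_error")
  }
  structure(
    list(date_jitter = date_jitter,
         latlon_view_jitter_deg = latlon_view_jitter_deg,
         latlon_missing_rate = latlon_missing_rate,
         state_missing_rate = state_missing_rate,
         vessel_substitution_rate = vessel_substitution_rate,
         people_missing_rate = people_missing_rate,
         miles_missing_rate = miles_missing_rate,
         narrative_missing_rate = narrative_missing_rate,
         miles_range = miles_range),
    class = "perturbation_model"
  )
}

#' Configuration of the synthetic linked universe
#'
#' The defaults reproduce the study conditions: dataset sizes and date
#' ranges of the four surveillance datasets (CFID 1,315 incidents / 2,966
#' person cases; Vessel Casualty 524; Nonfatal Injuries 232; Oregon Trauma
#' Registry 11), the planted pairwise overlap structure (CFID-OTR 5,
#' CFID-VC 9, CFID-NFI 12, OTR-VC 0, OTR-NFI 5 of which one has a missing
#' state, NFI-VC 10; 3 CFID-OTR-NFI and 1 CFID-NFI-VC triple overlaps), the
#' three multi-person incidents (3+3+2 = 8 person cases) that yield the
#' close matches, and the four unmatched trauma-registry cases (two outside
#' the covered region, two recreational).
#'
#' Pairwise overlap counts include the contribution of triple overlaps
#' (e.g. the 5 CFID-OTR matches comprise 2 pure pairs and 3 triples).
#'
#' @param seed Integer seed; all random streams derive from it.
#' @param sizes Named list of dataset sizes.
#' @param date_ranges Named list of length-2 date ranges.
#' @param overlap Named list of planted overlap counts.
#' @param close_person_counts Person multiplicities of the ambiguous
#'   multi-person CFID-NFI incidents (each at least 2).
#' @param otr_nfi_missing_state How many pure OTR-NFI links have the state
#'   removed on the NFI side.
#' @param unmatched_otr Named counts of unmatched trauma-registry cases.
#' @param fleet_size Number of vessels in the synthetic fleet. Vessels are
#'   reused across incidents so the vessel number is discriminating but not
#'   unique.
#' @param perturbation A [perturbation_model()].
#' @return An object of class `universe_config`.
#' @export
universe_config <- function(seed = 1L,
                            sizes = list(CFID_incidents = 1315L,
                                         CFID_persons = 2966L,
                                         VC = 524L, NFI = 232L, OTR = 11L),
                            date_ranges = list(
                              CFID = c("2000-01-04", "2017-12-04"),
                              VC = c("2010-08-15", "2014-12-31"),
                              NFI = c("2002-01-12", "2016-10-19"),
                              OTR = c("2009-05-08", "2016-07-06")),
                            overlap = list(CFID_OTR = 5L, CFID_VC = 9L,
                                           CFID_NFI = 12L, OTR_VC = 0L,
                                           OTR_NFI = 5L, NFI_VC = 10L,
                                           CFID_OTR_NFI = 3L, CFID_NFI_VC = 1L),
                            close_person_counts = c(3L, 3L, 2L),
                            otr_nfi_missing_state = 1L,
                            unmatched_otr = c(out_of_region = 2L, recreational = 2L),
                            fleet_size = 1500L,
                            perturbation = perturbation_model()) {
  cfg <- structure(
    list(seed = as.integer(seed), sizes = sizes,
         date_ranges = lapply(date_ranges, as.Date),
         overlap = overlap,
         close_person_counts = as.integer(close_person_counts),
         otr_nfi_missing_state = as.integer(otr_nfi_missing_state),
         unmatched_otr = unmatched_otr,
         fleet_size = as.integer(fleet_size),
         perturbation = perturbation),
    class = "universe_config"
  )
  validate_universe_config(cfg)
  cfg
}

# Derived latent structure: pure pair counts and per-dataset usage.
universe_plan <- function(cfg) {
  ov <- cfg$overlap
  pure <- list(
    cfid_otr = ov$CFID_OTR - ov$CFID_OTR_NFI,
    cfid_vc = ov$CFID_VC - ov$CFID_NFI_VC,
    cfid_nfi = ov$CFID_NFI - ov$CFID_OTR_NFI - ov$CFID_NFI_VC,
    otr_vc = ov$OTR_VC,
    otr_nfi = ov$OTR_NFI - ov$CFID_OTR_NFI,
    nfi_vc = ov$NFI_VC - ov$CFID_NFI_VC
  )
  n_close <- length(cfg$close_person_counts)
  used <- list(
    CFID = pure$cfid_otr + pure$cfid_vc + pure$cfid_nfi +
      ov$CFID_OTR_NFI + ov$CFID_NFI_VC + n_close,
    OTR = pure$cfid_otr + pure$otr_vc + pure$otr_nfi + ov$CFID_OTR_NFI +
      sum(cfg$unmatched_otr),
    VC = pure$cfid_vc + pure$otr_vc + pure$nfi_vc + ov$CFID_NFI_VC,
    NFI_rows = pure$cfid_nfi + pure$otr_nfi + pure$nfi_vc +
      ov$CFID_OTR_NFI + ov$CFID_NFI_VC + sum(cfg$close_person_counts)
  )
  list(pure = pure, used = used, n_close = n_close)
}

validate_universe_config <- function(cfg) {
  plan <- universe_plan(cfg)
  if (any(unlist(plan$pure) < 0)) {
    fl_stop("overlap spec infeasible: a triple overlap exceeds its pairwise total",
            class = "fl_config_error")
  }
  if (length(cfg$close_person_counts) && any(cfg$close_person_counts < 2)) {
    fl_stop("close_person_counts must all be >= 2 (ambiguity needs multiple persons)",
            class = "fl_config_error")
  }
  sz <- cfg$sizes
  if (plan$used$CFID > sz$CFID_incidents || plan$used$OTR > sz$OTR ||
      plan$used$VC > sz$VC || plan$used$NFI_rows > sz$NFI) {
    fl_stop("overlap spec infeasible: planted incidents exceed a dataset's size",
            class = "fl_config_error")
  }
  if (cfg$otr_nfi_missing_state > plan$pure$otr_nfi) {
    fl_stop("otr_nfi_missing_state exceeds the number of pure OTR-NFI links",
            class = "fl_config_error")
  }
  shared_cfid_persons <- plan$used$CFID - plan$n_close + sum(cfg$close_person_counts)
  unshared_cfid <- sz$CFID_incidents - plan$used$CFID
  unshared_persons <- sz$CFID_persons - shared_cfid_persons
  if (unshared_persons < unshared_cfid) {
    fl_stop("CFID person total too small for the configured incident count",
            class = "fl_config_error")
  }
  invisible(cfg)
}

rand_days <- function(n, lo, hi) {
  as.Date(lo + floor(runif(n) * (as.numeric(hi) - as.numeric(lo) + 1)),
          origin = "1970-01-01")
}

range_intersection <- function(ranges) {
  lo <- max(vapply(ranges, function(r) as.numeric(r[1]), numeric(1)))
  hi <- min(vapply(ranges, function(r) as.numeric(r[2]), numeric(1)))
  if (lo > hi) {
    fl_stop("empty date-range intersection for a planted overlap",
            class = "fl_config_error")
  }
  c(lo, hi)
}

# Allocate per-incident person counts (each >= 1) summing exactly to total.
alloc_person_counts <- function(n, total) {
  if (n == 0) return(integer(0))
  k <- 1L + rpois(n, max(total / n - 1, 0.01))
  repeat {
    diff <- total - sum(k)
    if (diff == 0) return(k)
    if (diff > 0) {
      idx <- sample.int(n, min(diff, n))
      k[idx] <- k[idx] + 1L
    } else {
      cand <- which(k > 1L)
      idx <- cand[sample.int(length(cand), min(-diff, length(cand)))]
      k[idx] <- k[idx] - 1L
    }
  }
}

make_fleet <- function(n, substitution_rate) {
  official <- sprintf("%06d", sample.int(900000L, n) + 99999L)
  reg_state <- sample(c("OR", "WA", "AK", "CA"), n, replace = TRUE,
                      prob = c(0.35, 0.35, 0.2, 0.1))
  state_reg <- paste0(reg_state, sprintf("%04d", sample.int(9999L, n, replace = TRUE)),
                      replicate(n, paste0(sample(LETTERS, 2, replace = TRUE), collapse = "")))
  # A fixed share of the fleet has no official number on file; those
  # vessels are identified by their state registration in every dataset,
  # so matched records still agree on the vessel field.
  state_only <- runif(n) < substitution_rate
  data.frame(display_number = ifelse(state_only, state_reg, official),
             state_only = state_only, stringsAsFactors = FALSE)
}

draw_latlon <- function(states) {
  boxes <- STATE_BOX[states]
  default_box <- c(30, 48, -126, -70)
  t(vapply(boxes, function(b) {
    if (is.null(b)) b <- default_box
    c(runif(1, b[1], b[2]), runif(1, b[3], b[4]))
  }, numeric(2)))
}

# Keep distinct latent incidents jointly distinct on (date, vessel): any
# two incidents of the same vessel are at least `min_gap` days apart, so
# the planted ground truth is the unique correct answer even at a +/-1 day
# matching tolerance.
enforce_date_vessel_separation <- function(dates, vessel, lo, hi,
                                           min_gap = 4L, max_iter = 200L) {
  for (iter in seq_len(max_iter)) {
    ord <- order(vessel, dates)
    v <- vessel[ord]
    d <- as.numeric(dates[ord])
    n <- length(ord)
    close_pairs <- which(v[-1] == v[-n] & (d[-1] - d[-n]) < min_gap)
    if (!length(close_pairs)) return(dates)
    redraw <- unique(ord[close_pairs + 1L])
    dates[redraw] <- rand_days(length(redraw), lo[redraw], hi[redraw])
  }
  fl_stop("failed to separate incidents on (date, vessel) after %d rounds", max_iter,
          class = "fl_generation_error")
}

#' Generate the four linked synthetic datasets with planted ground truth
#'
#' Draws latent incidents (unique on the joint date/vessel signature except
#' for planted overlaps), gives each member dataset an independently
#' perturbed view of its incidents, and returns the four datasets together
#' with the exact-by-construction ground truth. Deterministic given the
#' config seed.
#'
#' @param config A [universe_config()].
#' @return An object of class `fl_universe`: a list with `datasets` (named
#'   list of [new_dataset()] objects), `truth` (class `fl_ground_truth`)
#'   and the `config`.
#' @export
generate_universe <- function(config = universe_config()) {
  stopifnot(inherits(config, "universe_config"))
  validate_universe_config(config)
  plan <- universe_plan(config)
  pm <- config$perturbation
  dr <- config$date_ranges
  sz <- config$sizes

  with_seed(derive_seed(config$seed, "universe"), {
    fleet <- make_fleet(config$fleet_size, pm$vessel_substitution_rate)

    # -- latent incident table ------------------------------------------
    role_members <- list(
      cfid_otr = c("CFID", "OTR"), cfid_vc = c("CFID", "VC"),
      cfid_nfi = c("CFID", "NFI"), otr_vc = c("OTR", "VC"),
      otr_nfi = c("OTR", "NFI"), nfi_vc = c("VC", "NFI"),
      cfid_otr_nfi = c("CFID", "OTR", "NFI"),
      cfid_nfi_vc = c("CFID", "VC", "NFI"),
      cfid_nfi_close = c("CFID", "NFI"),
      cfid_only = "CFID", vc_only = "VC", nfi_only = "NFI", otr_only = "OTR",
      otr_out_of_region = "OTR", otr_recreational = "OTR"
    )
    counts <- c(
      cfid_otr = plan$pure$cfid_otr, cfid_vc = plan$pure$cfid_vc,
      cfid_nfi = plan$pure$cfid_nfi, otr_vc = plan$pure$otr_vc,
      otr_nfi = plan$pure$otr_nfi, nfi_vc = plan$pure$nfi_vc,
      cfid_otr_nfi = config$overlap$CFID_OTR_NFI,
      cfid_nfi_vc = config$overlap$CFID_NFI_VC,
      cfid_nfi_close = plan$n_close,
      cfid_only = sz$CFID_incidents - plan$used$CFID,
      vc_only = sz$VC - plan$used$VC,
      nfi_only = sz$NFI - plan$used$NFI_rows,
      otr_only = sz$OTR - plan$used$OTR,
      otr_out_of_region = unname(config$unmatched_otr["out_of_region"]) %||% 0L,
      otr_recreational = unname(config$unmatched_otr["recreational"]) %||% 0L
    )
    counts["otr_only"] <- counts["otr_only"] +
      sum(config$unmatched_otr) - counts["otr_out_of_region"] - counts["otr_recreational"]

    role <- rep(names(counts), counts)
    n_lat <- length(role)
    members <- role_members[role]

    lo <- numeric(n_lat); hi <- numeric(n_lat)
    for (idx in seq_len(n_lat)) {
      rng <- range_intersection(dr[members[[idx]]])
      lo[idx] <- rng[1] + 1  # one-day inset keeps jittered views in range
      hi[idx] <- rng[2] - 1
    }
    date <- rand_days(n_lat, lo, hi)
    vessel <- sample.int(config$fleet_size, n_lat, replace = TRUE)
    date <- enforce_date_vessel_separation(date, vessel, lo, hi)

    shared <- lengths(members) >= 2
    state <- character(n_lat)
    in_otr <- vapply(members, function(m) "OTR" %in% m, logical(1))
    state[in_otr] <- "OR"
    state[shared & !in_otr] <- sample(c("OR", "WA"), sum(shared & !in_otr),
                                      replace = TRUE)
    for (r in c("cfid_only", "vc_only", "nfi_only")) {
      sel <- role == r
      if (!any(sel)) next
      state[sel] <- switch(r,
        cfid_only = sample(names(CFID_STATE_PROB), sum(sel), replace = TRUE,
                           prob = CFID_STATE_PROB),
        vc_only = sample(c("OR", "WA"), sum(sel), replace = TRUE),
        nfi_only = sample(c("OR", "WA", "CA"), sum(sel), replace = TRUE,
                          prob = c(0.4, 0.4, 0.2)))
    }
    state[role == "otr_only"] <- "OR"
    state[role == "otr_out_of_region"] <- "CA"
    state[role == "otr_recreational"] <- "OR"

    pos <- draw_latlon(state)
    pos[role == "otr_out_of_region", 1] <- 41.76 + runif(counts["otr_out_of_region"], -0.1, 0.1)
    pos[role == "otr_out_of_region", 2] <- -124.20 + runif(counts["otr_out_of_region"], -0.1, 0.1)

    persons <- rep(1L, n_lat)
    persons[role == "cfid_nfi_close"] <- config$close_person_counts
    cfid_only_idx <- which(role == "cfid_only")
    shared_cfid_persons <- plan$used$CFID - plan$n_close + sum(config$close_person_counts)
    persons[cfid_only_idx] <- alloc_person_counts(
      length(cfid_only_idx), sz$CFID_persons - shared_cfid_persons)

    latent <- data.frame(
      role = role, date = date, vessel = vessel, state = state,
      lat = pos[, 1], lon = pos[, 2], persons = persons,
      shared = shared, stringsAsFactors = FALSE
    )
    # jitter direction per incident: views of a shared incident move within
    # a one-day window, so matched records differ by at most one day
    latent$jitter_dir <- sample(c(-1L, 1L), n_lat, replace = TRUE)

    # engineered missing state: on the NFI view of pure OTR-NFI links
    miss_state_latent <- head(which(role == "otr_nfi"), config$otr_nfi_missing_state)

    q_jitter <- unname(pm$date_jitter["-1"] + pm$date_jitter["1"])

    build_view <- function(ds) {
      sel <- which(vapply(members, function(m) ds %in% m, logical(1)))
      n <- length(sel)
      l <- latent[sel, , drop = FALSE]
      off <- integer(n)
      is_sh <- l$shared
      off[is_sh] <- l$jitter_dir[is_sh] * (runif(sum(is_sh)) < q_jitter)
      off[!is_sh] <- sample(c(-1L, 0L, 1L), sum(!is_sh), replace = TRUE,
                            prob = pm$date_jitter[c("-1", "0", "1")])
      j <- pm$latlon_view_jitter_deg
      lat <- l$lat + runif(n, -j, j)
      lon <- l$lon + runif(n, -j, j)
      latlon_missing <- runif(n) < pm$latlon_missing_rate[[ds]]
      # positions are forced present on the planted views of the datasets
      # that use latitude/longitude as a matching variable
      if (ds != "OTR") latlon_missing[is_sh] <- FALSE
      lat[latlon_missing] <- NA_real_
      lon[latlon_missing] <- NA_real_
      st <- l$state
      st_missing <- runif(n) < pm$state_missing_rate[[ds]]
      st_missing[is_sh] <- FALSE
      if (ds == "NFI") st_missing[sel %in% miss_state_latent] <- TRUE
      st[st_missing] <- NA_character_
      vn <- fleet$display_number[l$vessel]
      if (ds == "OTR") vn <- rep(NA_character_, n)
      ppl <- l$persons
      # CFID person counts stay complete: they drive the person-level
      # expansion, whose total is part of the dataset's definition
      if (ds != "CFID") ppl[runif(n) < pm$people_missing_rate] <- NA_integer_
      # ... and stay present on planted views so a shared multi-person
      # incident expands to its latent person multiplicity
      ppl[is_sh] <- l$persons[is_sh]
      if (ds == "OTR") ppl <- rep(NA_integer_, n)
      miles <- runif(n, pm$miles_range[1], pm$miles_range[2])
      miles[runif(n) < pm$miles_missing_rate] <- NA_real_
      if (ds == "OTR") miles <- rep(NA_real_, n)
      narr <- paste0("Vessel incident off ", ifelse(is.na(st), "unknown state", st),
                     ", ", format(l$date, "%Y"), ".")
      narr[l$role == "otr_recreational"] <-
        "Injured while fishing recreationally from a private boat."
      narr[runif(n) < pm$narrative_missing_rate] <- NA_character_
      data.frame(
        latent = sel,
        incident_date = l$date + off,
        incident_state = st,
        vessel_official_number = vn,
        latitude = lat, longitude = lon,
        people_on_board = ppl,
        miles_from_shore = miles,
        narrative = narr,
        persons = l$persons,
        stringsAsFactors = FALSE
      )
    }

    views <- lapply(setNames(FL_DATASET_IDS, FL_DATASET_IDS), build_view)

    # -- assemble datasets (shuffled order, regenerated record ids) -----
    id_map <- list()  # dataset -> latent index -> record id (incident level)
    datasets <- list()
    for (ds in FL_DATASET_IDS) {
      v <- views[[ds]]
      ord <- sample.int(nrow(v))
      v <- v[ord, , drop = FALSE]
      width <- if (ds == "OTR") 2 else 4
      base_id <- sprintf(paste0(ds, "-%0", width, "d"), seq_len(nrow(v)))
      id_map[[ds]] <- setNames(base_id, v$latent)

      person_level <- ds %in% c("OTR", "NFI")
      if (person_level) {
        k <- v$persons
        ridx <- rep.int(seq_len(nrow(v)), k)
        pidx <- sequence(k)
        rec <- v[ridx, , drop = FALSE]
        rec_id <- ifelse(k[ridx] > 1, paste0(base_id[ridx], "#", pidx), base_id[ridx])
        records <- data.frame(
          record_id = rec_id, dataset = ds, level = "person",
          incident_date = rec$incident_date, incident_state = rec$incident_state,
          vessel_official_number = rec$vessel_official_number,
          latitude = rec$latitude, longitude = rec$longitude,
          people_on_board = rec$people_on_board, person_index = pidx,
          miles_from_shore = rec$miles_from_shore, narrative = rec$narrative,
          incident_id = base_id[ridx], stringsAsFactors = FALSE
        )
      } else {
        records <- data.frame(
          record_id = base_id, dataset = ds, level = "incident",
          incident_date = v$incident_date, incident_state = v$incident_state,
          vessel_official_number = v$vessel_official_number,
          latitude = v$latitude, longitude = v$longitude,
          people_on_board = v$people_on_board, person_index = NA_integer_,
          miles_from_shore = v$miles_from_shore, narrative = v$narrative,
          incident_id = base_id, stringsAsFactors = FALSE
        )
      }
      rownames(records) <- NULL
      region <- switch(ds, CFID = names(CFID_STATE_PROB), OTR = "OR",
                       VC = c("OR", "WA"), NFI = c("OR", "WA", "CA"))
      datasets[[ds]] <- new_dataset(ds, records, date_range = dr[[ds]],
                                    region = region, person_info = ds != "VC")
    }

    # -- ground truth ---------------------------------------------------
    truth_rows <- list()
    close_counter <- 0L
    for (idx in which(latent$shared)) {
      mem <- members[[idx]]
      is_close <- latent$role[idx] == "cfid_nfi_close"
      if (is_close) close_counter <- close_counter + 1L
      combos <- combn(mem, 2)
      for (cc in seq_len(ncol(combos))) {
        pr <- canonical_pair(combos[1, cc], combos[2, cc])
        person_resolvable <- !is_close && latent$persons[idx] == 1L &&
      !"VC" %in% pr
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          dataset_a = pr[1], record_id_a = unname(id_map[[pr[1]]][as.character(idx)]),
          dataset_b = pr[2], record_id_b = unname(id_map[[pr[2]]][as.character(idx)]),
          link_level = if (person_resolvable) "person" else "incident",
          is_duplicate = pair_label(pr[1], pr[2]) %in% c("CFID-VC", "CFID-NFI"),
          close_group_id = if (is_close) sprintf("G%d", close_counter) else NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
    truth_df <- if (length(truth_rows)) do.call(rbind, truth_rows) else {
      data.frame(dataset_a = character(0), record_id_a = character(0),
                 dataset_b = character(0), record_id_b = character(0),
                 link_level = character(0), is_duplicate = logical(0),
                 close_group_id = character(0), stringsAsFactors = FALSE)
    }
    close_idx <- which(latent$role == "cfid_nfi_close")
    close_groups <- data.frame(
      group_id = if (length(close_idx)) sprintf("G%d", seq_along(close_idx)) else character(0),
      n_persons = latent$persons[close_idx],
      cfid_id = unname(id_map[["CFID"]][as.character(close_idx)]),
      nfi_id = unname(id_map[["NFI"]][as.character(close_idx)]),
      stringsAsFactors = FALSE
    )
    unmatched_idx <- which(latent$role %in% c("otr_out_of_region", "otr_recreational"))
    unmatched <- data.frame(
      dataset = rep("OTR", length(unmatched_idx)),
      record_id = unname(id_map[["OTR"]][as.character(unmatched_idx)]),
      reason = ifelse(latent$role[unmatched_idx] == "otr_out_of_region",
                      "out_of_region", "recreational"),
      stringsAsFactors = FALSE
    )
    truth <- structure(
      list(links = truth_df, close_groups = close_groups, unmatched = unmatched),
      class = "fl_ground_truth"
    )

    structure(list(datasets = datasets, truth = truth, config = config),
              class = "fl_universe")
  })
}

#' @export
print.fl_universe <- function(x, ...) {
  cat("<fl_universe>\n")
  for (ds in names(x$datasets)) {
    d <- x$datasets[[ds]]
    cat(sprintf("  %-4s %5d records (%d incidents, %d persons)\n", ds,
                d$counts[["records"]], d$counts[["incidents"]], d$counts[["persons"]]))
  }
  cat(sprintf("  planted links: %d (%d close groups, %d unmatched OTR cases)\n",
              nrow(x$truth$links), nrow(x$truth$close_groups), nrow(x$truth$unmatched)))
  invisible(x)
}

#' @export
print.fl_ground_truth <- function(x, ...) {
  cat(sprintf("<fl_ground_truth: %d planted links, %d close groups>\n",
              nrow(x$links), nrow(x$close_groups)))
  invisible(x)
}

#' Planted truth pairs for one dataset combination
#'
#' Symmetric in the two dataset ids: the returned `record_id_a` column
#' always refers to the first requested dataset. Close-match groups are
#' included when `include_close = TRUE` (they are incident-level links not
#' resolvable to the person level).
#'
#' @param gt An `fl_ground_truth`.
#' @param a,b Dataset ids.
#' @param include_close Include ambiguous multi-person links?
#' @return A data frame of incident-level record-id pairs.
#' @export
ground_truth_pairs <- function(gt, a, b, include_close = FALSE) {
  stopifnot(inherits(gt, "fl_ground_truth"))
  a <- match.arg(a, FL_DATASET_IDS)
  b <- match.arg(b, FL_DATASET_IDS)
  if (identical(a, b)) {
    fl_stop("ground_truth_pairs needs two distinct datasets", class = "fl_config_error")
  }
  pr <- canonical_pair(a, b)
  rows <- gt$links[gt$links$dataset_a == pr[1] & gt$links$dataset_b == pr[2], ,
                   drop = FALSE]
  if (!include_close) rows <- rows[is.na(rows$close_group_id), , drop = FALSE]
  if (identical(pr[1], a)) {
    out <- rows[, c("record_id_a", "record_id_b", "link_level", "is_duplicate",
                    "close_group_id")]
  } else {
    out <- data.frame(record_id_a = rows$record_id_b, record_id_b = rows$record_id_a,
                      link_level = rows$link_level, is_duplicate = rows$is_duplicate,
                      close_group_id = rows$close_group_id, stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Perturb a single record with the field accuracy model
#'
#' Applies the marginal perturbations: a date offset drawn from the jitter
#' distribution, a uniform position jitter with `|delta|` bounded by the
#' model's per-view half-width, and missingness draws for state, position
#' and people on board. The record id is replaced when `new_id` is given
#' (each dataset regenerates its own ids; latent identity lives only in
#' the ground truth).
#'
#' @param r A harmonized record (one-row data frame or named list).
#' @param m A [perturbation_model()].
#' @param new_id Optional replacement record id.
#' @param dataset_id Dataset whose missingness rates apply (defaults to the
#'   record's own dataset, falling back to CFID rates).
#' @return The perturbed one-row record data frame.
#' @export
perturb_record <- function(r, m, new_id = NULL, dataset_id = NULL) {
  stopifnot(inherits(m, "perturbation_model"))
  if (!is.data.frame(r)) r <- normalize_record(r)
  ds <- dataset_id %||% r$dataset[1] %||% "CFID"
  if (is.na(ds) || !ds %in% FL_DATASET_IDS) ds <- "CFID"
  out <- r
  off <- sample(c(-1L, 0L, 1L), 1, prob = m$date_jitter[c("-1", "0", "1")])
  out$incident_date <- r$incident_date + off
  j <- m$latlon_view_jitter_deg
  if (!is.na(out$latitude)) out$latitude <- out$latitude + runif(1, -j, j)
  if (!is.na(out$longitude)) out$longitude <- out$longitude + runif(1, -j, j)
  if (runif(1) < m$latlon_missing_rate[[ds]]) {
    out$latitude <- NA_real_
    out$longitude <- NA_real_
  }
  if (runif(1) < m$state_missing_rate[[ds]]) out$incident_state <- NA_character_
  if (runif(1) < m$people_missing_rate) out$people_on_board <- NA_integer_
  # miles-from-shore independence between views is a generator-level
  # behavior (each dataset redraws it); a single-record perturbation
  # leaves the stored value alone
  if (!is.null(new_id)) {
    out$record_id <- new_id
    out$incident_id <- incident_id_of(new_id)
  }
  out
}

#' Write a universe to disk
#'
#' Writes the four dataset CSVs in the harmonized schema plus
#' `ground_truth.csv`
#' (`dataset_a,record_id_a,dataset_b,record_id_b,link_level,is_duplicate,close_group_id`).
#'
#' @param u An `fl_universe`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_universe <- function(u, dir) {
  stopifnot(inherits(u, "fl_universe"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ds in names(u$datasets)) {
    write_dataset(u$datasets[[ds]], file.path(dir, paste0(tolower(ds), ".csv")))
  }
  write.csv(u$truth$links, file.path(dir, "ground_truth.csv"),
            row.names = FALSE, na = "")
  invisible(dir)
}
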