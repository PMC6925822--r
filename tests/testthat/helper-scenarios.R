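# Shared fixtures: all generated in code, no stored data.

# Small, lightly loaded world for fast unit tests.
tiny_scenario <- function(als_ratio = 1, alpha = 0, beta = 0,
                          calls_per_day = 30) {
  default_scenario(als_ratio = als_ratio, alpha = alpha, beta = beta,
                   calls_per_day = calls_per_day)
}

# Construct an ems_calls data frame from explicit per-call values.
make_calls <- function(time, x, y, severity_actual, severity_classified,
                       scene_service, hospital_service,
                       scenario, warmup_days = 0, horizon_days = 1) {
  n <- length(time)
  stopifnot(n == length(x), n == length(y))
  out <- data.frame(
    id = seq_len(n), time = as.numeric(time),
    x = as.numeric(x), y = as.numeric(y),
    district = emsadp:::district_of(x, y, scenario$geometry$bbox),
    severity_actual = rep_len(severity_actual, n),
    severity_classified = rep_len(severity_classified, n),
    scene_service = rep_len(as.numeric(scene_service), n),
    hospital_service = rep_len(as.numeric(hospital_service), n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ems_calls", "data.frame")
  attr(out, "warmup_min") <- warmup_days * 1440
  attr(out, "horizon_min") <- horizon_days * 1440
  out
}

# Enumerable toy world: one ALS ambulance, two bases, two call sites,
# deterministic inter-arrival and service times, constant speed 60 km/h
# (1 km/min). Base 1 sits between the call sites (4 km from each); base 2
# is co-located with the hospital, 8.94 km from either site, beyond the
# 7-min response threshold. Redeploying to base 1 is optimal but base 2 is
# the nearest (zero travel) choice after a handover.
#
# Call timing is chosen so the toy respects the monotone-value assumption
# of the projection operator: one call per day at 10:40 puts every dispatch
# decision in time zone 2 and every redeployment decision (handover
# completes shortly after 11:00) in time zone 3, so the aggregated states
# of the two decision kinds are pairwise incomparable and the learned
# ordering between redeployment destinations is exact. A single-ambulance
# world with both kinds in one zone provably violates that assumption: the
# post-redeployment state dominates the everyone-busy post-dispatch state
# but has the higher true cost-to-go (see the methods vignette).
toy_scenario <- function() {
  ems_scenario(
    geometry = geometry(
      bbox = c(0, 0, 9, 9),
      bases = data.frame(x = c(4.5, 4.5), y = c(0.5, 8.5), capacity = 2L),
      hospitals = data.frame(x = 4.5, y = 8.5)
    ),
    fleet = fleet_config(1L, 1),
    demand = demand_model(calls_per_day = 1, hourly_profile = rep(1, 24),
                          district_weights = rep(1, 9), prior = 1),
    travel = travel_model(rep(60, 24)),
    service = service_model(),
    triage = triage_model(alpha = 0, beta = 0, prior = 0.248),
    rli = rli_params()
  )
}

toy_sites <- function() list(A = c(0.5, 0.5), B = c(8.5, 0.5))

# Deterministic alternating call trace for the toy world: one call per day
# at 10:40, sites A, B, A, B, ..., all actually and classified high-risk,
# fixed service times.
toy_calls <- function(warmup_days = 1, horizon_days = 7) {
  scn <- toy_scenario()
  sites <- toy_sites()
  days <- warmup_days + horizon_days
  times <- (seq_len(days) - 1) * 1440 + 640
  pick <- rep_len(c("A", "B"), length(times))
  make_calls(
    time = times,
    x = vapply(pick, function(s) sites[[s]][1], numeric(1)),
    y = vapply(pick, function(s) sites[[s]][2], numeric(1)),
    severity_actual = "H", severity_classified = "H",
    scene_service = 10, hospital_service = 5,
    scenario = scn, warmup_days = warmup_days, horizon_days = horizon_days
  )
}

# Random aggregated-state keys for value-table property tests.
random_keys <- function(n, max_count = 4L) {
  keys <- matrix(sample.int(max_count + 1L, n * 18L, replace = TRUE) - 1L,
                 n, 18)
  cbind(keys, sample.int(3L, n, replace = TRUE))
}

random_value_table <- function(n_states, max_count = 4L) {
  keys <- unique(random_keys(n_states * 2L, max_count))
  keys <- keys[seq_len(min(nrow(keys), n_states)), , drop = FALSE]
  vt <- value_table()
  vt$keys <- keys
  vt$value <- round(stats::runif(nrow(keys), 0, 50), 2)
  vt$count <- sample.int(20L, nrow(keys), replace = TRUE)
  vt
}

# Independent brute-force oracle for the monotone projection: literal
# pairwise repair of every stored state against the reference.
oracle_project <- function(vt, key, z_ref) {
  key <- as.integer(key)
  i <- emsadp:::vt_match(vt, key)
  if (is.na(i)) {
    vt$keys <- rbind(vt$keys, key)
    vt$value <- c(vt$value, z_ref)
    vt$count <- c(vt$count, 0L)
    i <- nrow(vt$keys)
  }
  for (j in seq_len(nrow(vt$keys))) {
    if (j == i) next
    s <- vt$keys[j, ]
    s_dom_ref <- s[19] == key[19] && all(s[1:9] >= key[1:9]) &&
      all(s[10:18] <= key[10:18])
    ref_dom_s <- s[19] == key[19] && all(key[1:9] >= s[1:9]) &&
      all(key[10:18] <= s[10:18])
    if (s_dom_ref) vt$value[j] <- min(vt$value[j], z_ref)
    else if (ref_dom_s) vt$value[j] <- max(vt$value[j], z_ref)
  }
  vt$value[i] <- z_ref
  vt
}
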