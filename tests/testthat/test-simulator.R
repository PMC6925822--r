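test_that("rt_pc applies the proper-care rule", {
  expect_equal(rt_pc(0, 6, 20, "H", "ALS"), 6)
  expect_equal(rt_pc(0, 6, 20, "H", "BLS"), 20)   # BLS + actual high: to hospital
  expect_equal(rt_pc(0, 6, NA, "L", "BLS"), 6)
  expect_equal(rt_pc(10, 16, NA, "L", "ALS"), 6)
  expect_error(rt_pc(0, NA, NA, "H", "ALS"), "scene arrival")
  expect_error(rt_pc(0, 6, NA, "H", "BLS"), "hospital arrival")
})

test_that("rli weights severity and penalises threshold breaches", {
  p <- rli_params()
  expect_equal(rli(0, "H", p), 0)
  expect_equal(rli(8, "H", p), 38)     # 1*8 + 30, strict 8 > 7
  expect_equal(rli(7, "H", p), 7)      # boundary: no penalty at exactly rtt
  expect_equal(rli(8, "L", p), 2)      # 0.25*8
  expect_equal(rli(c(8, 8), c("H", "L"), p), c(38, 2))
})

test_that("episodes are deterministic and conserve patients", {
  scn <- tiny_scenario()
  ep1 <- run_episode(scn, greedy_policy(), horizon_days = 2, warmup_days = 0,
                     seed = 11)
  ep2 <- run_episode(scn, greedy_policy(), horizon_days = 2, warmup_days = 0,
                     seed = 11)
  expect_identical(ep1$patients, ep2$patients)
  expect_identical(ep1$dispatches, ep2$dispatches)
  expect_identical(ep1$relocations, ep2$relocations)

  p <- ep1$patients
  expect_true(all(!is.na(p$rli)))                       # every call served
  expect_true(all(p$dispatch_time >= p$report))
  expect_true(all(p$scene_time >= p$dispatch_time))
  expect_true(all(p$hospital_time >= p$scene_time))
  expect_true(all(p$handover_time >= p$hospital_time))
})

test_that("zero demand yields an empty episode", {
  scn <- default_scenario(calls_per_day = 0)
  ep <- run_episode(scn, greedy_policy(), horizon_days = 1, warmup_days = 0,
                    seed = 1)
  expect_equal(nrow(ep$patients), 0)
  expect_equal(ep$metrics$total_rli, 0)
  expect_equal(nrow(ep$relocations), 0)
})

test_that("a lone call is dispatched immediately, without delay", {
  scn <- tiny_scenario()
  calls <- make_calls(time = 100, x = 3, y = 3,
                      severity_actual = "H", severity_classified = "H",
                      scene_service = 10, hospital_service = 5,
                      scenario = scn)
  ep <- run_episode(scn, greedy_policy(), calls = calls)
  expect_equal(ep$patients$dispatch_time, 100)    # no delay allowed
  expect_false(ep$patients$queued)
  expect_equal(nrow(ep$dispatches), 1)
  expect_equal(ep$dispatches$n_candidates, 6)
})

test_that("transport always goes to the nearest hospital", {
  scn <- default_scenario()
  ep <- run_episode(scn, greedy_policy(), horizon_days = 2, warmup_days = 0,
                    seed = 21)
  h <- scn$geometry$hospitals
  p <- ep$patients
  for (i in seq_len(nrow(p))) {
    d <- sqrt((h$x - p$x[i])^2 + (h$y - p$y[i])^2)
    expect_equal(p$hospital[i], which.min(d))
  }
})

test_that("classified-high patients pre-empt the queue regardless of order", {
  scn <- tiny_scenario()
  scn$fleet <- fleet_config(1L, 1)                # single ambulance
  # call 1 occupies the ambulance; calls 2 (low) and 3 (high) must queue;
  # at handover the high-risk head is served first despite arriving later.
  calls <- make_calls(
    time = c(10, 12, 14),
    x = c(3, 2, 4), y = c(3, 2, 4),
    severity_actual = c("L", "L", "H"),
    severity_classified = c("L", "L", "H"),
    scene_service = 10, hospital_service = 5,
    scenario = scn
  )
  ep <- run_episode(scn, greedy_policy(), calls = calls)
  p <- ep$patients
  expect_true(p$queued[2] && p$queued[3])
  expect_lt(p$dispatch_time[3], p$dispatch_time[2])   # high first
  # within the same class, first-come-first-served
  calls2 <- make_calls(
    time = c(10, 12, 14),
    x = c(3, 2, 4), y = c(3, 2, 4),
    severity_actual = "L", severity_classified = "L",
    scene_service = 10, hospital_service = 5,
    scenario = scn
  )
  ep2 <- run_episode(scn, greedy_policy(), calls = calls2)
  expect_lt(ep2$patients$dispatch_time[2], ep2$patients$dispatch_time[3])
})

test_that("priority discipline holds across a congested trace", {
  scn <- default_scenario(alpha = 0.2, beta = 0.2)
  ep <- run_episode(scn, greedy_policy(), horizon_days = 3, warmup_days = 0,
                    seed = 33)
  p <- ep$patients
  d <- ep$dispatches
  # for every dispatch of a queued classified-low patient, no classified-high
  # patient reported earlier was still waiting at that instant
  low_q <- which(!d$classified_high)
  for (i in low_q) {
    t <- d$time[i]
    waiting_high <- p$severity_classified == "H" & p$report < t &
      (is.na(p$dispatch_time) | p$dispatch_time > t)
    expect_equal(sum(waiting_high), 0)
  }
})

test_that("relocating ambulances are dispatchable, en-route ones are not", {
  scn <- tiny_scenario()
  scn$fleet <- fleet_config(2L, 1)
  # Call 1 engages ambulance 1; call 2 arrives while 1 is en route to the
  # patient and 2 idle: only ambulance 2 is a candidate.
  calls <- make_calls(
    time = c(10, 12),
    x = c(1, 5), y = c(1, 5),
    severity_actual = "H", severity_classified = "H",
    scene_service = 30, hospital_service = 10,
    scenario = scn
  )
  ep <- run_episode(scn, greedy_policy(), calls = calls)
  expect_equal(ep$dispatches$n_candidates, c(2, 1))
  expect_equal(ep$dispatches$chosen[2], 2)
  # A relocating ambulance counts as available: after ambulance 1's
  # handover it redeploys; a call during that leg must see it as candidate.
  reloc_t <- ep$relocations$time[1]
  calls2 <- make_calls(
    time = c(10, reloc_t + 0.2),
    x = c(1, 1), y = c(1, 1),
    severity_actual = "H", severity_classified = "H",
    scene_service = 30, hospital_service = 10,
    scenario = scn
  )
  ep2 <- run_episode(scn, greedy_policy(), calls = calls2)
  # both the relocating unit (1) and the idle unit (2) are candidates
  expect_equal(ep2$dispatches$n_candidates[2], 2)
})

test_that("base capacity limits redeployment destinations", {
  scn <- default_scenario()
  ep <- run_episode(scn, greedy_policy(), horizon_days = 3, warmup_days = 0,
                    seed = 13)
  # with 6 ambulances and 12 slots a feasible base always exists
  expect_true(all(ep$relocations$n_feasible >= 1))
  expect_true(all(ep$relocations$n_feasible <= 6))
})

test_that("with no errors, all-ALS, equal slopes and no penalty the total RLI
           reduces to the total response time", {
  scn <- default_scenario(als_ratio = 1, alpha = 0, beta = 0)
  scn$rli <- rli_params(c_high = 1, c_low = 1, penalty = 0, rtt = 7)
  ep <- run_episode(scn, greedy_policy(), horizon_days = 2, warmup_days = 0,
                    seed = 17)
  p <- ep$patients
  expect_equal(sum(p$rli), sum(p$rt), tolerance = 1e-12)
  expect_equal(p$rt_pc, p$rt)
})

test_that("warm-up patients are simulated but excluded from metrics", {
  scn <- tiny_scenario()
  ep <- run_episode(scn, greedy_policy(), horizon_days = 2, warmup_days = 1,
                    seed = 19)
  p <- ep$patients
  expect_true(any(!p$in_horizon))
  expect_true(all(!is.na(p$rli)))                 # warm-up calls still served
  expect_equal(ep$metrics$n_patients, sum(p$in_horizon))
  expect_equal(ep$metrics$total_rli, sum(p$rli[p$in_horizon]))
})
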