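test_that("aggregation counts ambulances, patients and the time zone", {
  scn <- default_scenario()
  b1 <- scn$geometry$bases[1, ]
  six_idle <- data.frame(x = rep(b1$x, 6), y = rep(b1$y, 6),
                         status = "idle", dest_base = NA)
  none <- data.frame(x = numeric(0), y = numeric(0))
  key <- aggregate_state(six_idle, none, 2 * 60, scn)
  expect_equal(sum(key[1:9]), 6)
  expect_equal(max(key[1:9]), 6)               # all in one cell
  expect_equal(key[10:18], rep(0L, 9))
  expect_equal(key[19], 1L)                    # 02:00 is zone 1

  # half-open boundaries: 08:00 belongs to zone 2, 11:00 to zone 3,
  # 01:00 to zone 1
  expect_equal(time_zone(8 * 60), 2L)
  expect_equal(time_zone(11 * 60), 3L)
  expect_equal(time_zone(60), 1L)
  expect_equal(time_zone(0), 3L)
  expect_equal(time_zone(1440 + 120), 1L)      # wraps across days

  # a waiting patient increments exactly one pending count
  one_wait <- data.frame(x = 5.5, y = 5.5)
  key2 <- aggregate_state(six_idle, one_wait, 2 * 60, scn)
  expect_equal(sum(key2[10:18]), 1)
  expect_equal(key2[1:9], key[1:9])

  # a relocating ambulance is counted at its destination base
  reloc <- data.frame(x = 3, y = 3, status = "to-base", dest_base = 6)
  key3 <- aggregate_state(reloc, none, 2 * 60, scn)
  b6 <- scn$geometry$bases[6, ]
  cell <- emsadp:::district_of(b6$x, b6$y, scn$geometry$bbox)
  expect_equal(which(key3[1:9] == 1L), cell)
  # busy statuses are not counted
  busy <- data.frame(x = 3, y = 3, status = "to-patient", dest_base = NA)
  expect_equal(sum(aggregate_state(busy, none, 120, scn)[1:9]), 0)
})

test_that("harmonic updates average the samples they see", {
  key <- c(rep(0L, 18), 1L)
  vt <- value_table()
  vt <- update_value(vt, key, 10)              # first visit: exact
  expect_equal(vt$value, 10)
  expect_equal(vt$count, 1L)
  vt <- update_value(vt, key, 4)               # second: (10 + 4) / 2
  expect_equal(vt$value, 7)
  vt <- update_value(vt, key, 1)               # third: step 1/3
  expect_equal(vt$value, (1 - 1/3) * 7 + 1/3 * 1)
  expect_equal(vt$count, 3L)
  # a constant sample is a fixed point
  vt2 <- value_table()
  for (i in 1:5) vt2 <- update_value(vt2, key, 3.5)
  expect_equal(vt2$value, 3.5)
  # running value equals the plain mean of all samples
  set.seed(12)
  xs <- runif(20, 0, 10)
  vt3 <- value_table()
  for (x in xs) vt3 <- update_value(vt3, key, x)
  expect_equal(vt3$value, mean(xs), tolerance = 1e-12)
})

test_that("the harmonic step schedule diverges in sum, converges in squares", {
  n <- 1:10000
  delta <- 1 / n
  # partial sums of 1/n track log(n) (divergence), while the squared sums
  # stay below the pi^2/6 bound
  expect_gt(sum(delta), log(10000))
  expect_lt(sum(delta^2), pi^2 / 6)
  expect_gt(sum(delta^2), pi^2 / 6 - 1e-4)
})

test_that("dominance is a partial order within a time zone", {
  base <- c(rep(1L, 9), rep(1L, 9), 2L)
  expect_true(dominates(base, base))           # reflexive
  more_idle <- base; more_idle[3] <- 2L
  expect_true(dominates(more_idle, base))
  expect_false(dominates(base, more_idle))
  # conflicting coordinates: incomparable
  mixed <- base; mixed[1] <- 2L; mixed[11] <- 2L
  expect_false(dominates(mixed, base))
  expect_false(dominates(base, mixed))
  # different zones are never comparable
  other_zone <- base; other_zone[19] <- 3L
  expect_false(dominates(base, other_zone))

  set.seed(31)
  keys <- random_keys(60)
  for (i in 1:40) {
    a <- keys[sample.int(60, 1), ]; b <- keys[sample.int(60, 1), ]
    cc <- keys[sample.int(60, 1), ]
    # antisymmetry
    if (dominates(a, b) && dominates(b, a)) expect_equal(a, b)
    # transitivity
    if (dominates(a, b) && dominates(b, cc)) expect_true(dominates(a, cc))
  }
})

test_that("monotone projection repairs exactly the dominated pairs", {
  zone <- 2L
  lo <- c(rep(0L, 9), rep(1L, 9), zone)        # fewer idle, more pending
  hi <- c(rep(2L, 9), rep(0L, 9), zone)        # dominates lo
  vt <- value_table()
  vt <- update_value(vt, lo, 5)
  vt <- update_value(vt, hi, 9)                # violates monotonicity
  # referencing lo at value 5 caps the dominating state's value
  out <- project_monotone(vt, lo, 5)
  expect_equal(out$value[emsadp:::vt_match(out, hi)], 5)
  expect_equal(out$value[emsadp:::vt_match(out, lo)], 5)
  # flooring: reference above a dominated state's value pulls it up
  vt2 <- value_table()
  vt2 <- update_value(vt2, lo, 2)
  vt2 <- update_value(vt2, hi, 1)              # already monotone
  out2 <- project_monotone(vt2, hi, 4)         # raise the better state
  expect_equal(out2$value[emsadp:::vt_match(out2, lo)], 4)
  # an already-monotone table only changes at the reference
  out3 <- project_monotone(vt2, hi, 1)
  expect_equal(out3$value, vt2$value)
  # idempotence
  once <- project_monotone(vt, lo, 5)
  twice <- project_monotone(once, lo, 5)
  expect_identical(once$value, twice$value)
})

test_that("projection agrees with the brute-force pairwise oracle", {
  set.seed(77)
  for (rep in 1:40) {
    vt <- random_value_table(sample(2:60, 1))
    i <- sample.int(nrow(vt$keys), 1)
    z <- runif(1, 0, 50)
    got <- project_monotone(vt, vt$keys[i, ], z)
    want <- oracle_project(vt, vt$keys[i, ], z)
    expect_equal(got$value, want$value)
  }
})

test_that("the C++ projection twin matches the R implementation", {
  set.seed(78)
  for (rep in 1:10) {
    vt <- random_value_table(sample(5:80, 1))
    i <- sample.int(nrow(vt$keys), 1)
    z <- runif(1, 0, 50)
    ptr <- emsadp:::cpp_vt_new()
    emsadp:::cpp_vt_import(ptr, vt$keys, vt$value, vt$count)
    emsadp:::cpp_vt_project(ptr, vt$keys[i, ], z)
    got <- emsadp:::cpp_vt_export(ptr)
    want <- project_monotone(vt, vt$keys[i, ], z)
    ord <- do.call(order, as.data.frame(want$keys))
    expect_equal(got$value, want$value[ord])
  }
})

test_that("C++ harmonic updates replay identically in R", {
  set.seed(79)
  keys <- random_keys(10)
  ptr <- emsadp:::cpp_vt_new()
  vt <- value_table()
  for (i in 1:200) {
    k <- keys[sample.int(10, 1), ]
    v <- runif(1, 0, 30)
    emsadp:::cpp_vt_update(ptr, k, v)
    vt <- update_value(vt, k, v)
  }
  got <- emsadp:::cpp_vt_export(ptr)
  ord <- do.call(order, as.data.frame(vt$keys))
  expect_equal(got$value, vt$value[ord], tolerance = 1e-12)
  expect_equal(got$count, vt$count[ord])
})

test_that("mini-batch projection leaves no violation among touched pairs", {
  set.seed(80)
  vt <- random_value_table(120)
  out <- minibatch_project(vt, 10)
  expect_equal(dim(out$keys), dim(vt$keys))
  # empty table: no-op
  expect_identical(minibatch_project(value_table()), value_table())
  # single visited state: that state is the reference, values unchanged
  one <- value_table()
  one <- update_value(one, c(rep(1L, 18), 1L), 4)
  expect_equal(minibatch_project(one)$value, 4)
})

test_that("training on the default scenario produces a usable fit", {
  scn <- tiny_scenario(als_ratio = 0.83, alpha = 0.2, beta = 0.2,
                       calls_per_day = 60)
  fit <- train_adp(scn, iterations = 5, seed = 3, horizon_days = 2,
                   warmup_days = 0)
  expect_s3_class(fit, "ems_adp_fit")
  expect_gt(nrow(fit$table$keys), 0)
  expect_equal(nrow(fit$curve), 5)
  expect_true(all(is.finite(fit$curve$mean_rli)))
  expect_true(all(fit$table$count >= 0))
  # resuming training carries visit counts forward
  fit2 <- train_adp(scn, iterations = 2, seed = 4, horizon_days = 2,
                    warmup_days = 0, table = fit$table)
  expect_gte(sum(fit2$table$count), sum(fit$table$count))
  # learning curve windows
  lc <- learning_curve(fit, window = 2)
  expect_equal(nrow(lc), 3)

  # determinism of the full training loop
  fit3 <- train_adp(scn, iterations = 5, seed = 3, horizon_days = 2,
                    warmup_days = 0)
  expect_identical(fit$table, fit3$table)
  expect_identical(fit$curve, fit3$curve)
})

test_that("with gamma = 0 the learner's decisions reduce to greedy", {
  # the Bellman sample estimate is then the bare contribution, so the value
  # table cannot influence any decision and the learning episode must
  # reproduce the greedy trajectory exactly
  scn <- tiny_scenario(als_ratio = 0.83, alpha = 0.2, beta = 0.2,
                       calls_per_day = 60)
  calls <- sample_calls(scn, 2, 0, seed = 55)
  fit <- train_adp(scn, iterations = 1, gamma = 0, seed = 1,
                   calls_fn = function(i) calls)
  ep <- run_episode(scn, greedy_policy(), calls = calls)
  expect_equal(fit$curve$mean_rli[1], ep$metrics$mean_rli, tolerance = 1e-12)
})

test_that("value tables round-trip through CSV", {
  set.seed(90)
  vt <- random_value_table(30)
  path <- tempfile(fileext = ".csv")
  write_value_table(vt, path)
  back <- read_value_table(path)
  expect_equal(back$keys, vt$keys)
  expect_equal(back$value, vt$value)
  expect_equal(back$count, vt$count)
})
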