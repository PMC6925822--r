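#' Named random-number substreams for one replication
#'
#' Six independent substreams drive one simulated episode: call occurrence
#' times, call locations, actual severities, classified severities, on-scene
#' service times and hospital handover times. Keeping each variable on its
#' own substream is what makes common-random-number (CRN) policy comparison
#' exact: two policies evaluated with the same master seed observe
#' bit-identical call streams because every stochastic input is drawn before
#' the policies act.
#'
#' @param seed Nonnegative integer master seed.
#' @return Named integer vector of substream seeds.
#' @export
make_streams <- function(seed) {
  stopifnot(length(seed) == 1L, is.finite(seed), seed >= 0)
  seed <- as.double(seed)
  names <- c("times", "locations", "actual", "classified", "scene", "hospital")
  # Distinct substream seeds via a 31-bit LCG step per substream index.
  s <- vapply(seq_along(names), function(k) {
    as.integer((seed * 48271 + k * 2654435) %% 2147483647)
  }, integer(1))
  stats::setNames(s, names)
}

with_stream <- function(stream_seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed)
  expr
}

#' Sample a replication's call stream
#'
#' Generates the full, time-ordered list of emergency calls for one episode
#' of `warmup + horizon` days from the scenario's nonhomogeneous Poisson
#' demand model, together with every per-call random quantity the simulator
#' will need: location (district, then uniform within the district cell),
#' actual severity (Bernoulli with the prior), classified severity
#' (conditional on actual via the undertriage/overtriage rates), and the
#' gamma on-scene and handover service durations.
#'
#' Arrival times are generated by thinning: a homogeneous Poisson process at
#' the profile's maximum hourly rate proposes candidate epochs, each accepted
#' with probability `rate(t) / rate_max`. Thinning is exact for piecewise
#' constant intensities and needs no day-boundary bookkeeping.
#'
#' @param scenario An [ems_scenario()].
#' @param horizon_days Post-warm-up measurement horizon in days.
#' @param warmup_days Warm-up period in days (calls simulated, excluded from
#'   metrics downstream).
#' @param seed Master seed, or a vector from [make_streams()].
#' @return Data frame of class `ems_calls`, one row per call, ordered by
#'   strictly increasing `time` (minutes since episode start), with columns
#'   `id`, `time`, `x`, `y`, `district`, `severity_actual`,
#'   `severity_classified` (`"H"`/`"L"`), `scene_service`, `hospital_service`.
#' @export
sample_calls <- function(scenario, horizon_days = 7, warmup_days = 1, seed = 1L) {
  stopifnot(inherits(scenario, "ems_scenario"), horizon_days > 0, warmup_days >= 0)
  streams <- if (length(seed) > 1L) seed else make_streams(seed)
  total_days <- warmup_days + horizon_days
  total_min <- total_days * 1440

  dem <- scenario$demand
  # Per-minute intensity by hour of day.
  lam_min <- dem$calls_per_day / 1440 * dem$hourly_profile
  lam_max <- max(lam_min)

  times <- with_stream(streams[["times"]], {
    if (lam_max == 0) {
      numeric(0)
    } else {
      m <- stats::rpois(1L, lam_max * total_min)
      cand <- sort(stats::runif(m, 0, total_min))
      acc <- stats::runif(m) < lam_min[floor((cand %% 1440) / 60) + 1L] / lam_max
      cand[acc]
    }
  })
  n <- length(times)

  loc <- with_stream(streams[["locations"]], {
    if (n == 0L) {
      list(d = integer(0), x = numeric(0), y = numeric(0))
    } else {
      d <- sample.int(9L, n, replace = TRUE, prob = dem$district_weights)
      bbox <- scenario$geometry$bbox
      w3 <- (bbox[3] - bbox[1]) / 3
      h3 <- (bbox[4] - bbox[2]) / 3
      col <- (d - 1L) %% 3L
      row <- (d - 1L) %/% 3L
      list(d = d,
           x = bbox[1] + (col + stats::runif(n)) * w3,
           y = bbox[2] + (row + stats::runif(n)) * h3)
    }
  })

  actual <- with_stream(streams[["actual"]],
                        stats::runif(n) < dem$prior)
  classified <- with_stream(streams[["classified"]], {
    u <- stats::runif(n)
    ifelse(actual, u >= scenario$triage$alpha, u < scenario$triage$beta)
  })
  scene <- with_stream(streams[["scene"]],
                       sample_service_times(n, scenario$service, "scene"))
  hosp <- with_stream(streams[["hospital"]],
                      sample_service_times(n, scenario$service, "hospital"))

  out <- data.frame(
    id = seq_len(n),
    time = times,
    x = loc$x, y = loc$y,
    district = loc$d,
    severity_actual = ifelse(actual, "H", "L"),
    severity_classified = ifelse(classified, "H", "L"),
    scene_service = scene,
    hospital_service = hosp,
    stringsAsFactors = FALSE
  )
  class(out) <- c("ems_calls", "data.frame")
  attr(out, "warmup_min") <- warmup_days * 1440
  attr(out, "horizon_min") <- horizon_days * 1440
  out
}
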