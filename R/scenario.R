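#' Posterior severity probabilities under triage classification error
#'
#' Given the undertriage rate `alpha` (probability that an actually high-risk
#' patient is classified low-risk at call time), the overtriage rate `beta`
#' (probability that an actually low-risk patient is classified high-risk),
#' and the prior probability `prior` that a call is actually high-risk,
#' returns the Bayes posteriors
#' \deqn{P(H^A \mid H^C) = \frac{(1-\alpha)p}{(1-\alpha)p + \beta(1-p)},\qquad
#'       P(L^A \mid L^C) = \frac{(1-\beta)(1-p)}{\alpha p + (1-\beta)(1-p)}.}
#'
#' These posteriors weight the expected risk-level-index contribution of a
#' dispatch, because the dispatcher only observes the classified severity.
#'
#' @param alpha Undertriage rate, in \[0, 1\].
#' @param beta Overtriage rate, in \[0, 1\].
#' @param prior Prior probability a call is actually high-risk, in \[0, 1\].
#' @return Named list with elements `p_high_given_hc` and `p_low_given_lc`.
#' @examples
#' posterior_probs(0.1, 0.2, 0.248)
#' @export
posterior_probs <- function(alpha, beta, prior) {
  stopifnot(length(alpha) == 1L, length(beta) == 1L, length(prior) == 1L)
  if (any(c(alpha, beta, prior) < 0) || any(c(alpha, beta, prior) > 1)) {
    stop("alpha, beta and prior must lie in [0, 1]")
  }
  den_h <- (1 - alpha) * prior + beta * (1 - prior)
  den_l <- alpha * prior + (1 - beta) * (1 - prior)
  if (den_h <= 0 || den_l <= 0) {
    stop("undefined posterior: a classified-severity class has probability zero")
  }
  list(
    p_high_given_hc = (1 - alpha) * prior / den_h,
    p_low_given_lc  = (1 - beta) * (1 - prior) / den_l
  )
}

#' Construct a triage classification-error model
#'
#' @param alpha Undertriage rate P(classified low | actually high).
#' @param beta Overtriage rate P(classified high | actually low).
#' @param prior Prior probability of actual high risk (default 0.248).
#' @return An object of class `ems_triage`.
#' @export
triage_model <- function(alpha = 0.2, beta = 0.2, prior = 0.248) {
  post <- posterior_probs(alpha, beta, prior)
  structure(
    list(alpha = alpha, beta = beta, prior = prior,
         p_high_given_hc = post$p_high_given_hc,
         p_low_given_lc = post$p_low_given_lc),
    class = "ems_triage"
  )
}

#' Risk-level-index parameters
#'
#' The risk level index (RLI) of a served patient is a severity-weighted
#' time-to-proper-care with a threshold penalty:
#' `c_high * rt_pc + penalty * (rt_pc > rtt)` for actually high-risk patients
#' and `c_low * rt_pc` for actually low-risk patients.
#'
#' @param c_high Slope for actually high-risk patients (per min), default 1.
#' @param c_low Slope for actually low-risk patients (per min), default 0.25.
#' @param penalty Constant added when a high-risk patient's time to proper
#'   care strictly exceeds `rtt`, default 30.
#' @param rtt Response-time threshold in minutes, default 7.
#' @return An object of class `ems_rli_params`.
#' @export
rli_params <- function(c_high = 1, c_low = 0.25, penalty = 30, rtt = 7) {
  stopifnot(c_high >= c_low, c_low >= 0, penalty >= 0, rtt > 0)
  structure(list(c_high = c_high, c_low = c_low, penalty = penalty, rtt = rtt),
            class = "ems_rli_params")
}

#' Gamma service-time model
#'
#' On-scene and hospital-handover service durations are gamma distributed.
#' Defaults give mean on-scene time 3.57 * 6.2 = 22.13 min and mean handover
#' time 5.02 * 3.0 = 15.06 min.
#'
#' @param scene_scale,scene_shape Gamma scale/shape of on-scene service
#'   (defaults 3.57 and 6.2).
#' @param hospital_scale,hospital_shape Gamma scale/shape of in-hospital
#'   handover (defaults 5.02 and 3.0).
#' @return An object of class `ems_service`.
#' @export
service_model <- function(scene_scale = 3.57, scene_shape = 6.2,
                          hospital_scale = 5.02, hospital_shape = 3.0) {
  stopifnot(scene_scale > 0, scene_shape > 0, hospital_scale > 0, hospital_shape > 0)
  structure(
    list(scene_scale = scene_scale, scene_shape = scene_shape,
         hospital_scale = hospital_scale, hospital_shape = hospital_shape),
    class = "ems_service"
  )
}

#' Piecewise-constant travel model
#'
#' Travel time between two planar points is the Euclidean distance divided by
#' the vehicle speed in effect at the departure clock time. The speed profile
#' has one value per hour of day; the speed at departure is used for the whole
#' leg (legs are short relative to the hourly speed bins).
#'
#' @param speed_kmh Numeric vector of 24 hourly speeds in km/h (hour 0..23).
#' @param metric Distance metric identifier; only `"euclidean"` is built in.
#' @return An object of class `ems_travel`.
#' @export
travel_model <- function(speed_kmh = rep(30, 24), metric = "euclidean") {
  stopifnot(length(speed_kmh) == 24L, all(speed_kmh > 0))
  metric <- match.arg(metric, "euclidean")
  structure(list(speed_kmh = as.numeric(speed_kmh), metric = metric),
            class = "ems_travel")
}

#' Travel time between two points
#'
#' @param origin,destination Numeric length-2 vectors (x, y) in km.
#' @param clock Departure time in minutes since midnight (values beyond one
#'   day wrap around).
#' @param travel An [travel_model()] object.
#' @return Travel time in minutes (0 for identical points).
#' @export
travel_time <- function(origin, destination, clock, travel) {
  d <- sqrt(sum((as.numeric(origin) - as.numeric(destination))^2))
  if (d == 0) return(0)
  hr <- floor((clock %% 1440) / 60) + 1L
  d / travel$speed_kmh[hr] * 60
}

#' Time-varying demand model
#'
#' Calls arrive by a nonhomogeneous Poisson process: a global 24-value hourly
#' rate multiplier profile modulates per-district base rates. The profile is
#' stored normalised so that the configured mean daily call volume is exact.
#'
#' @param calls_per_day Mean total calls per day (default 127.9).
#' @param hourly_profile 24 nonnegative relative weights, one per hour of day
#'   (normalised internally).
#' @param district_weights Nonnegative relative weights, one per demand
#'   district (normalised internally).
#' @param prior Prior probability a call is actually high-risk (default 0.248).
#' @return An object of class `ems_demand`.
#' @export
demand_model <- function(calls_per_day = 127.9,
                         hourly_profile = rep(1, 24),
                         district_weights = rep(1, 9),
                         prior = 0.248) {
  stopifnot(calls_per_day >= 0, length(hourly_profile) == 24L,
            all(hourly_profile >= 0), sum(hourly_profile) > 0,
            all(district_weights >= 0), sum(district_weights) > 0,
            prior >= 0, prior <= 1)
  structure(
    list(calls_per_day = calls_per_day,
         hourly_profile = hourly_profile / mean(hourly_profile),
         district_weights = district_weights / sum(district_weights),
         prior = prior),
    class = "ems_demand"
  )
}

#' Region geometry: bounding box, bases, hospitals and demand districts
#'
#' Demand districts are a 3 x 3 grid of equal cells over the bounding box;
#' calls within a district are located uniformly over its cell. The same grid
#' is used for the spatial aggregation of the value table.
#'
#' @param bbox Numeric length-4 vector `c(xmin, ymin, xmax, ymax)` in km.
#' @param bases Data frame with columns `x`, `y` and optionally `capacity`
#'   (waiting slots per base, default 2).
#' @param hospitals Data frame with columns `x`, `y`.
#' @return An object of class `ems_geometry`.
#' @export
geometry <- function(bbox, bases, hospitals) {
  stopifnot(length(bbox) == 4, bbox[3] > bbox[1], bbox[4] > bbox[2],
            nrow(bases) >= 1, nrow(hospitals) >= 1)
  if (is.null(bases$capacity)) bases$capacity <- 2L
  pts <- rbind(as.matrix(bases[, c("x", "y")]), as.matrix(hospitals[, c("x", "y")]))
  if (any(pts[, 1] < bbox[1] | pts[, 1] > bbox[3] |
          pts[, 2] < bbox[2] | pts[, 2] > bbox[4])) {
    stop("all base and hospital locations must lie inside the bounding box")
  }
  structure(
    list(bbox = as.numeric(bbox),
         bases = data.frame(x = as.numeric(bases$x), y = as.numeric(bases$y),
                            capacity = as.integer(bases$capacity)),
         hospitals = data.frame(x = as.numeric(hospitals$x),
                                y = as.numeric(hospitals$y))),
    class = "ems_geometry"
  )
}

#' Fleet configuration
#'
#' ALS (advanced life support) units carry paramedics and advanced equipment;
#' BLS (basic life support) units provide basic care only. The number of ALS
#' units is `round(als_ratio * n_ambulances)`; ambulances are listed ALS
#' first. Initial placement is round-robin over the bases.
#'
#' @param n_ambulances Total fleet size (default 6).
#' @param als_ratio Fraction of the fleet that is ALS (default 0.83).
#' @return An object of class `ems_fleet` with a logical `is_als` vector.
#' @export
fleet_config <- function(n_ambulances = 6L, als_ratio = 0.83) {
  stopifnot(n_ambulances >= 1, als_ratio >= 0, als_ratio <= 1)
  n_als <- as.integer(round(als_ratio * n_ambulances))
  structure(
    list(n_ambulances = as.integer(n_ambulances), als_ratio = als_ratio,
         n_als = n_als,
         is_als = c(rep(TRUE, n_als), rep(FALSE, n_ambulances - n_als))),
    class = "ems_fleet"
  )
}

#' Assemble a simulation scenario
#'
#' A scenario is the immutable world description consumed by [run_episode()]
#' and [train_adp()]: geometry, fleet, demand, travel, service, triage-error
#' and RLI parameters.
#'
#' @param geometry An [geometry()] object.
#' @param fleet A [fleet_config()] object.
#' @param demand A [demand_model()] object.
#' @param travel A [travel_model()] object.
#' @param service A [service_model()] object.
#' @param triage A [triage_model()] object.
#' @param rli An [rli_params()] object.
#' @return An object of class `ems_scenario`.
#' @export
ems_scenario <- function(geometry, fleet, demand, travel, service, triage, rli) {
  stopifnot(inherits(geometry, "ems_geometry"), inherits(fleet, "ems_fleet"),
            inherits(demand, "ems_demand"), inherits(travel, "ems_travel"),
            inherits(service, "ems_service"), inherits(triage, "ems_triage"),
            inherits(rli, "ems_rli_params"))
  ndist <- length(demand$district_weights)
  if (ndist != 9L) {
    stop("demand must have 9 district weights (3 x 3 grid over the bounding box)")
  }
  if (sum(geometry$bases$capacity) < fleet$n_ambulances) {
    stop("total base capacity must be at least the fleet size")
  }
  structure(
    list(geometry = geometry, fleet = fleet, demand = demand, travel = travel,
         service = service, triage = triage, rli = rli),
    class = "ems_scenario"
  )
}

#' @export
print.ems_scenario <- function(x, ...) {
  cat("<ems_scenario>\n")
  cat(sprintf("  region: %.1f x %.1f km, %d bases, %d hospitals\n",
              x$geometry$bbox[3] - x$geometry$bbox[1],
              x$geometry$bbox[4] - x$geometry$bbox[2],
              nrow(x$geometry$bases), nrow(x$geometry$hospitals)))
  cat(sprintf("  fleet: %d ambulances (%d ALS, %d BLS)\n",
              x$fleet$n_ambulances, x$fleet$n_als,
              x$fleet$n_ambulances - x$fleet$n_als))
  cat(sprintf("  demand: %.1f calls/day, P(high risk) = %.3f\n",
              x$demand$calls_per_day, x$demand$prior))
  cat(sprintf("  triage: alpha = %.2f, beta = %.2f\n",
              x$triage$alpha, x$triage$beta))
  cat(sprintf("  RLI: c_high = %g, c_low = %g, penalty = %g, rtt = %g min\n",
              x$rli$c_high, x$rli$c_low, x$rli$penalty, x$rli$rtt))
  invisible(x)
}

#' Default metropolitan scenario
#'
#' A synthetic stand-in for a dense urban EMS district: a 6 x 6 km bounding
#' box, six waiting bases (two slots each), three hospitals, six ambulances,
#' a mean of 127.9 calls per day with a diurnal rate profile (night trough,
#' late-morning and late-afternoon peaks), a diurnal vehicle-speed profile
#' (fast at night, slow in rush hours), gamma on-scene and handover service
#' times, and a centre-heavy 3 x 3 district demand surface. All components
#' are deterministic; randomness enters only through [sample_calls()].
#'
#' @param als_ratio Fraction of the 6-ambulance fleet that is ALS
#'   (default 0.83, i.e. 5 ALS + 1 BLS).
#' @param alpha Undertriage rate (default 0.2).
#' @param beta Overtriage rate (default 0.2).
#' @param calls_per_day Mean daily call volume (default 127.9).
#' @return An `ems_scenario` object.
#' @examples
#' scn <- default_scenario()
#' scn
#' @export
default_scenario <- function(als_ratio = 0.83, alpha = 0.2, beta = 0.2,
                             calls_per_day = 127.9) {
  bbox <- c(0, 0, 6, 6)
  bases <- data.frame(
    x = c(1.0, 3.0, 5.0, 1.0, 3.0, 5.0),
    y = c(1.5, 1.5, 1.5, 4.5, 4.5, 4.5),
    capacity = 2L
  )
  hospitals <- data.frame(
    x = c(1.5, 4.5, 3.0),
    y = c(3.0, 3.0, 5.2)
  )
  # Diurnal call profile: trough 03:00-05:00, peaks late morning and
  # late afternoon/evening (relative weights, normalised in demand_model).
  hourly <- c(0.60, 0.50, 0.45, 0.40, 0.40, 0.50,
              0.70, 0.90, 1.05, 1.15, 1.20, 1.25,
              1.20, 1.15, 1.15, 1.15, 1.20, 1.25,
              1.25, 1.20, 1.10, 1.00, 0.85, 0.70)
  # Centre-heavy demand surface over the 3 x 3 district grid.
  districts <- c(0.8, 1.0, 0.8,
                 1.0, 1.8, 1.0,
                 0.8, 1.0, 0.8)
  # Urban speed profile (km/h): free-flowing at night, congested at rush.
  speed <- c(38, 40, 42, 42, 42, 40,
             34, 26, 22, 24, 26, 26,
             25, 25, 26, 25, 23, 21,
             22, 25, 28, 31, 34, 36)
  ems_scenario(
    geometry = geometry(bbox, bases, hospitals),
    fleet = fleet_config(6L, als_ratio),
    demand = demand_model(calls_per_day, hourly, districts, prior = 0.248),
    travel = travel_model(speed),
    service = service_model(),
    triage = triage_model(alpha, beta),
    rli = rli_params()
  )
}

#' Sample gamma service times from a scenario's service model
#'
#' @param n Number of draws.
#' @param service An [service_model()] object.
#' @param which `"scene"` or `"hospital"`.
#' @return Numeric vector of durations in minutes.
#' @export
sample_service_times <- function(n, service, which = c("scene", "hospital")) {
  which <- match.arg(which)
  if (which == "scene") {
    stats::rgamma(n, shape = service$scene_shape, scale = service$scene_scale)
  } else {
    stats::rgamma(n, shape = service$hospital_shape, scale = service$hospital_scale)
  }
}

# District (3x3 grid cell) index of planar points; row-major from the
# south-west corner: cell = 3 * row + col + 1 with col/row in 0..2.
district_of <- function(x, y, bbox) {
  cx <- pmin(2L, pmax(0L, floor(3 * (x - bbox[1]) / (bbox[3] - bbox[1]))))
  cy <- pmin(2L, pmax(0L, floor(3 * (y - bbox[2]) / (bbox[4] - bbox[2]))))
  as.integer(3L * cy + cx + 1L)
}
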