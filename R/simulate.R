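# Flatten an ems_scenario into the plain list the C++ engine consumes.
scenario_cpp <- function(scenario) {
  g <- scenario$geometry
  list(
    bbox = g$bbox,
    base_x = g$bases$x, base_y = g$bases$y, base_cap = g$bases$capacity,
    hosp_x = g$hospitals$x, hosp_y = g$hospitals$y,
    speed = scenario$travel$speed_kmh,
    is_als = as.integer(scenario$fleet$is_als),
    c_high = scenario$rli$c_high, c_low = scenario$rli$c_low,
    penalty = scenario$rli$penalty, rtt = scenario$rli$rtt,
    p_high_given_hc = scenario$triage$p_high_given_hc,
    p_low_given_lc = scenario$triage$p_low_given_lc,
    mean_scene = scenario$service$scene_scale * scenario$service$scene_shape
  )
}

#' Risk level index of a served patient
#'
#' `c_high * rt_pc + penalty * 1(rt_pc > rtt)` for actually high-risk
#' patients; `c_low * rt_pc` for actually low-risk patients. The penalty
#' indicator is strict.
#'
#' @param rt_pc Time to proper care in minutes (vectorised).
#' @param severity_actual `"H"` or `"L"` (recycled).
#' @param params An [rli_params()] object.
#' @return Numeric risk values.
#' @examples
#' rli(8, "H", rli_params()) # 1 * 8 + 30
#' rli(8, "L", rli_params()) # 0.25 * 8
#' @export
rli <- function(rt_pc, severity_actual, params = rli_params()) {
  stopifnot(all(rt_pc >= 0))
  high <- severity_actual == "H"
  ifelse(high,
         params$c_high * rt_pc + params$penalty * (rt_pc > params$rtt),
         params$c_low * rt_pc)
}

#' Time to proper care
#'
#' The response time (report to scene arrival), except that an actually
#' high-risk patient transported by a BLS unit only begins proper care at the
#' hospital, so the interval extends to hospital arrival.
#'
#' @param report,scene_arrival,hospital_arrival Event times in minutes;
#'   `hospital_arrival` may be `NA` unless required by the rule.
#' @param severity_actual `"H"` or `"L"`.
#' @param ambulance_type `"ALS"` or `"BLS"`.
#' @return Minutes to proper care.
#' @examples
#' rt_pc(0, 6, 20, "H", "ALS") # 6
#' rt_pc(0, 6, 20, "H", "BLS") # 20
#' @export
rt_pc <- function(report, scene_arrival, hospital_arrival = NA,
                  severity_actual, ambulance_type) {
  stopifnot(severity_actual %in% c("H", "L"), ambulance_type %in% c("ALS", "BLS"))
  if (is.na(scene_arrival) || scene_arrival < report) {
    stop("scene arrival must be realized and not precede the report time")
  }
  if (ambulance_type == "BLS" && severity_actual == "H") {
    if (is.na(hospital_arrival) || hospital_arrival < scene_arrival) {
      stop("hospital arrival required for a BLS transport of a high-risk patient")
    }
    hospital_arrival - report
  } else {
    scene_arrival - report
  }
}

#' Simulate one episode under a policy
#'
#' Runs the discrete-event semi-MDP simulation: calls arrive by the
#' scenario's nonhomogeneous Poisson process, the policy picks a feasible
#' ambulance at every dispatch decision (dispatch is mandatory whenever an
#' idle or relocating ambulance exists) and a feasible base at every
#' redeployment decision, patients are transported to the nearest hospital,
#' and classified-high patients queue with priority over classified-low ones.
#' Identical scenario, policy and seed give bit-identical logs.
#'
#' @param scenario An [ems_scenario()].
#' @param policy A policy object from [greedy_policy()], [myopic_policy()] or
#'   [adp_policy()].
#' @param horizon_days Measurement horizon in days (default 7).
#' @param warmup_days Warm-up days simulated but excluded from metrics
#'   (default 1).
#' @param seed Master seed for the call stream (ignored when `calls` given).
#' @param calls Optional pre-sampled [sample_calls()] data frame, for
#'   common-random-number comparisons or constructed test traces.
#' @return An `ems_episode` list with elements `patients`, `dispatches`,
#'   `relocations` (data frames) and `metrics` (mean/total RLI, mean response
#'   time, counts, mean relocation time) over the post-warm-up horizon.
#' @examples
#' scn <- default_scenario()
#' ep <- run_episode(scn, greedy_policy(), horizon_days = 1, seed = 7)
#' ep$metrics$mean_rli
#' @export
run_episode <- function(scenario, policy, horizon_days = 7, warmup_days = 1,
                        seed = 1L, calls = NULL) {
  stopifnot(inherits(scenario, "ems_scenario"), inherits(policy, "ems_policy"),
            horizon_days > 0, warmup_days >= 0)
  if (is.null(calls)) {
    calls <- sample_calls(scenario, horizon_days, warmup_days, seed)
  } else {
    horizon_days <- attr(calls, "horizon_min") / 1440
    warmup_days <- attr(calls, "warmup_min") / 1440
  }
  mode <- switch(policy$kind, greedy = 0L, myopic = 1L, adp = 2L)
  keys <- NULL; vals <- NULL
  if (policy$kind == "adp") {
    keys <- policy$table$keys
    vals <- policy$table$value
  }
  res <- cpp_run_episode(scenario_cpp(scenario), calls, mode, keys, vals,
                         policy$gamma %||% 0.9,
                         warmup_days * 1440, horizon_days * 1440)
  res$metrics <- episode_metrics(res)
  res$policy <- policy$name
  class(res) <- "ems_episode"
  res
}

episode_metrics <- function(res) {
  p <- res$patients[res$patients$in_horizon, , drop = FALSE]
  r <- res$relocations[res$relocations$in_horizon, , drop = FALSE]
  list(
    n_patients = nrow(p),
    mean_rli = if (nrow(p)) mean(p$rli) else NA_real_,
    total_rli = sum(p$rli),
    mean_rt = if (nrow(p)) mean(p$rt) else NA_real_,
    mean_rt_pc = if (nrow(p)) mean(p$rt_pc) else NA_real_,
    frac_queued = if (nrow(p)) mean(p$queued) else NA_real_,
    mean_relocation_min = if (nrow(r)) mean(r$travel_min) else NA_real_,
    n_relocations = nrow(r)
  )
}

#' @export
print.ems_episode <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<ems_episode> policy = %s\n", x$policy))
  cat(sprintf("  %d patients in horizon, mean RLI %.3f, mean RT %.2f min\n",
              m$n_patients, m$mean_rli, m$mean_rt))
  cat(sprintf("  %.1f%% queued; %d relocations, mean %.2f min\n",
              100 * m$frac_queued, m$n_relocations, m$mean_relocation_min))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
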