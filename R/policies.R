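#' Dispatch and redeployment policies
#'
#' Three policies are built in:
#' * `greedy_policy()` minimises the expected immediate RLI contribution of
#'   each dispatch (posterior-weighted over the true severity given the
#'   classified severity) and redeploys to the nearest feasible base.
#' * `myopic_policy()` dispatches the nearest available ambulance and
#'   redeploys to the nearest feasible base, ignoring severity and type.
#' * `adp_policy(table)` minimises the expected contribution plus
#'   `gamma` times the learned value of the post-decision aggregated state.
#'
#' All ties are broken by shorter travel time, then lower ambulance/base id,
#' so runs are reproducible under common random numbers.
#'
#' @param table An `ems_value_table` (see [train_adp()], [value_table()]).
#' @param gamma Discount factor per decision epoch (default 0.9).
#' @param name Optional display name.
#' @return An object of class `ems_policy`.
#' @examples
#' greedy_policy()
#' @export
greedy_policy <- function(name = "greedy") {
  structure(list(kind = "greedy", name = name, gamma = 0), class = "ems_policy")
}

#' @rdname greedy_policy
#' @export
myopic_policy <- function(name = "myopic") {
  structure(list(kind = "myopic", name = name, gamma = 0), class = "ems_policy")
}

#' @rdname greedy_policy
#' @export
adp_policy <- function(table, gamma = 0.9, name = "adp") {
  stopifnot(inherits(table, "ems_value_table"), gamma >= 0, gamma <= 1)
  structure(list(kind = "adp", name = name, table = table, gamma = gamma),
            class = "ems_policy")
}

#' @export
print.ems_policy <- function(x, ...) {
  cat(sprintf("<ems_policy> %s (%s)\n", x$name, x$kind))
  if (x$kind == "adp") {
    cat(sprintf("  value table: %d states, gamma = %g\n",
                nrow(x$table$keys), x$gamma))
  }
  invisible(x)
}

#' Expected immediate RLI contribution of a dispatch
#'
#' The dispatcher knows the classified severity only, so the contribution of
#' sending an ambulance to a patient is the posterior-weighted expected RLI:
#' for a patient classified high-risk,
#' `P(H^A|H^C) f(RT, H) + P(L^A|H^C) f(RT, L)` (analogously for classified
#' low-risk), where `RT` is the deterministic expected response time (any
#' accrued waiting plus the travel time for the ambulance-patient distance).
#' When the ambulance is a BLS unit, the high-risk branch is measured to
#' hospital arrival: expected response time plus the mean on-scene service
#' time plus the travel time from the patient to the nearest hospital.
#' Redeployment actions have contribution 0.
#'
#' @param travel_min Expected ambulance-to-patient travel time, minutes.
#' @param classified `"H"` or `"L"` classified severity.
#' @param ambulance_type `"ALS"` or `"BLS"`.
#' @param scenario An [ems_scenario()] (provides posteriors, RLI parameters
#'   and the mean on-scene service time).
#' @param hospital_travel_min Travel time from patient to nearest hospital,
#'   minutes; required for BLS dispatches.
#' @param wait_min Time the patient has already waited, minutes (default 0).
#' @return Expected RLI contribution (scalar).
#' @export
expected_contribution <- function(travel_min, classified, ambulance_type,
                                  scenario, hospital_travel_min = NA,
                                  wait_min = 0) {
  stopifnot(classified %in% c("H", "L"), ambulance_type %in% c("ALS", "BLS"),
            travel_min >= 0, wait_min >= 0)
  rt_hat <- wait_min + travel_min
  w_high <- if (classified == "H") scenario$triage$p_high_given_hc
            else 1 - scenario$triage$p_low_given_lc
  rt_high <- rt_hat
  if (ambulance_type == "BLS") {
    if (is.na(hospital_travel_min)) {
      stop("hospital_travel_min is required for BLS dispatches")
    }
    mean_scene <- scenario$service$scene_scale * scenario$service$scene_shape
    rt_high <- rt_hat + mean_scene + hospital_travel_min
  }
  p <- scenario$rli
  f_high <- p$c_high * rt_high + p$penalty * (rt_high > p$rtt)
  f_low <- p$c_low * rt_hat
  w_high * f_high + (1 - w_high) * f_low
}
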