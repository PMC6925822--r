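#' Read or write a scenario configuration file
#'
#' Scenarios serialise to a YAML (or JSON) document with sections
#' `geometry` (bbox, bases, hospitals), `fleet`, `demand`, `travel`,
#' `service`, `triage` and `rli`. All distances are km, all durations
#' minutes, speeds km/h.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @param scenario An [ems_scenario()].
#' @return `read_scenario()` returns an `ems_scenario`; `write_scenario()`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  cfg <- yaml::read_yaml(path)
  required <- c("geometry", "fleet", "demand", "travel", "service",
                "triage", "rli")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop("scenario config lacks section(s): ", paste(missing, collapse = ", "))
  }
  g <- cfg$geometry
  ems_scenario(
    geometry = geometry(
      bbox = as.numeric(g$bbox),
      bases = data.frame(x = vapply(g$bases, `[[`, 0, "x"),
                         y = vapply(g$bases, `[[`, 0, "y"),
                         capacity = vapply(g$bases, function(b) {
                           as.integer(b$capacity %||% 2L)
                         }, 0L)),
      hospitals = data.frame(x = vapply(g$hospitals, `[[`, 0, "x"),
                             y = vapply(g$hospitals, `[[`, 0, "y"))
    ),
    fleet = fleet_config(as.integer(cfg$fleet$n_ambulances),
                         cfg$fleet$als_ratio),
    demand = demand_model(cfg$demand$calls_per_day,
                          as.numeric(cfg$demand$hourly_profile),
                          as.numeric(cfg$demand$district_weights),
                          cfg$demand$prior),
    travel = travel_model(as.numeric(cfg$travel$speed_kmh)),
    service = service_model(cfg$service$scene_scale, cfg$service$scene_shape,
                            cfg$service$hospital_scale,
                            cfg$service$hospital_shape),
    triage = triage_model(cfg$triage$alpha, cfg$triage$beta,
                          cfg$triage$prior),
    rli = rli_params(cfg$rli$c_high, cfg$rli$c_low, cfg$rli$penalty,
                     cfg$rli$rtt)
  )
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "ems_scenario"))
  g <- scenario$geometry
  cfg <- list(
    geometry = list(
      bbox = g$bbox,
      bases = lapply(seq_len(nrow(g$bases)), function(i) {
        list(x = g$bases$x[i], y = g$bases$y[i],
             capacity = g$bases$capacity[i])
      }),
      hospitals = lapply(seq_len(nrow(g$hospitals)), function(i) {
        list(x = g$hospitals$x[i], y = g$hospitals$y[i])
      })
    ),
    fleet = list(n_ambulances = scenario$fleet$n_ambulances,
                 als_ratio = scenario$fleet$als_ratio),
    demand = list(calls_per_day = scenario$demand$calls_per_day,
                  hourly_profile = scenario$demand$hourly_profile,
                  district_weights = scenario$demand$district_weights,
                  prior = scenario$demand$prior),
    travel = list(speed_kmh = scenario$travel$speed_kmh),
    service = list(scene_scale = scenario$service$scene_scale,
                   scene_shape = scenario$service$scene_shape,
                   hospital_scale = scenario$service$hospital_scale,
                   hospital_shape = scenario$service$hospital_shape),
    triage = list(alpha = scenario$triage$alpha,
                  beta = scenario$triage$beta,
                  prior = scenario$triage$prior),
    rli = list(c_high = scenario$rli$c_high, c_low = scenario$rli$c_low,
               penalty = scenario$rli$penalty, rtt = scenario$rli$rtt)
  )
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Write episode logs to CSV files
#'
#' Writes the per-patient log, the dispatch decision log and the relocation
#' log of an episode as three CSV files under `dir`.
#'
#' @param episode An `ems_episode`.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix (default the policy name).
#' @return Character vector of the written paths, invisibly.
#' @export
write_episode <- function(episode, dir, prefix = NULL) {
  stopifnot(inherits(episode, "ems_episode"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prefix <- prefix %||% episode$policy
  paths <- c(
    patients = file.path(dir, paste0(prefix, "_patients.csv")),
    dispatches = file.path(dir, paste0(prefix, "_dispatches.csv")),
    relocations = file.path(dir, paste0(prefix, "_relocations.csv"))
  )
  utils::write.csv(episode$patients, paths["patients"], row.names = FALSE)
  utils::write.csv(episode$dispatches, paths["dispatches"], row.names = FALSE)
  utils::write.csv(episode$relocations, paths["relocations"], row.names = FALSE)
  invisible(paths)
}
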