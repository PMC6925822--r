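#' Train the mini-batch monotone-ADP value table
#'
#' Runs the forward ADP learning loop. Each iteration simulates one
#' warm-up-plus-horizon episode with a fresh call stream. At every decision
#' point the learner evaluates each feasible action's expected immediate
#' contribution plus `gamma` times the stored value of the action's
#' post-decision aggregated state, takes the minimising action, and uses the
#' minimum as the sample estimate that updates the previous decision's
#' post-decision state (harmonic step `1/n` over cumulative visits). At the
#' end of each iteration the monotone projection operator is applied to a
#' visit-weighted sample of up to ten reference states per time zone. The
#' table starts at zero everywhere, which is optimistic for a minimisation
#' problem and drives early exploration.
#'
#' @param scenario An [ems_scenario()].
#' @param iterations Number of learning iterations (episodes).
#' @param gamma Discount factor per decision epoch (default 0.9).
#' @param seed Master seed; iteration `i` uses substreams derived from
#'   `seed` and `i`.
#' @param horizon_days,warmup_days Episode length (defaults 7 + 1, as in
#'   the evaluation runs).
#' @param n_per_zone Mini-batch size per time zone for the projection
#'   (default 10).
#' @param table Optional `ems_value_table` to resume training from.
#' @param calls_fn Optional function `(iteration) -> ems_calls` supplying
#'   each iteration's call stream (e.g. a deterministic trace); by default
#'   calls are sampled from the scenario's demand model.
#' @return A list of class `ems_adp_fit`: `table` (the learned
#'   `ems_value_table`), `curve` (data frame iteration / mean RLI /
#'   table size), `gamma`, `iterations`.
#' @examples
#' \donttest{
#' scn <- default_scenario()
#' fit <- train_adp(scn, iterations = 50, seed = 1)
#' plot(fit$curve$iteration, fit$curve$mean_rli, type = "l")
#' }
#' @export
train_adp <- function(scenario, iterations, gamma = 0.9, seed = 1L,
                      horizon_days = 7, warmup_days = 1, n_per_zone = 10L,
                      table = NULL, calls_fn = NULL) {
  stopifnot(inherits(scenario, "ems_scenario"), iterations >= 1,
            gamma >= 0, gamma <= 1)
  ptr <- cpp_vt_new()
  if (!is.null(table)) {
    stopifnot(inherits(table, "ems_value_table"))
    cpp_vt_import(ptr, table$keys, table$value, table$count)
  }
  scn <- scenario_cpp(scenario)
  curve <- data.frame(iteration = seq_len(iterations), mean_rli = NA_real_,
                      n_patients = NA_integer_, table_size = NA_integer_)
  set.seed(as.integer(seed %% 2147483647))
  for (i in seq_len(iterations)) {
    iter_seed <- (as.double(seed) * 7919 + i) %% 2147483647
    calls <- if (is.null(calls_fn)) {
      sample_calls(scenario, horizon_days, warmup_days, iter_seed)
    } else {
      calls_fn(i)
    }
    wu <- attr(calls, "warmup_min") %||% (warmup_days * 1440)
    hz <- attr(calls, "horizon_min") %||% (horizon_days * 1440)
    res <- cpp_learn_episode(scn, calls, ptr, gamma, wu, hz, FALSE)
    cpp_vt_minibatch(ptr, as.integer(n_per_zone))
    curve$mean_rli[i] <- res$mean_rli
    curve$n_patients[i] <- res$n_patients
    curve$table_size[i] <- res$table_size
  }
  tab <- cpp_vt_export(ptr)
  out <- value_table()
  out$keys <- tab$keys
  out$value <- tab$value
  out$count <- tab$count
  structure(list(table = out, curve = curve, gamma = gamma,
                 iterations = iterations),
            class = "ems_adp_fit")
}

#' @export
print.ems_adp_fit <- function(x, ...) {
  cat(sprintf("<ems_adp_fit> %d iterations, gamma = %g\n",
              x$iterations, x$gamma))
  print(x$table)
  last <- utils::tail(stats::na.omit(x$curve$mean_rli), 100)
  if (length(last)) {
    cat(sprintf("  mean RLI over last %d iterations: %.3f\n",
                length(last), mean(last)))
  }
  invisible(x)
}

#' Smoothed learning curve
#'
#' Averages the per-iteration mean RLI over consecutive windows, mirroring
#' how learning progress is usually reported (one point per 100 iterations).
#'
#' @param fit An `ems_adp_fit`.
#' @param window Window width in iterations (default 100).
#' @return Data frame with `iteration` (window end) and `mean_rli`.
#' @export
learning_curve <- function(fit, window = 100L) {
  stopifnot(inherits(fit, "ems_adp_fit"))
  n <- nrow(fit$curve)
  grp <- ceiling(seq_len(n) / window)
  data.frame(
    iteration = vapply(split(fit$curve$iteration, grp), max, numeric(1)),
    mean_rli = vapply(split(fit$curve$mean_rli, grp),
                      function(v) mean(v, na.rm = TRUE), numeric(1)),
    row.names = NULL
  )
}
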