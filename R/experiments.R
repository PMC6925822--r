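#' Common-random-number paired policy comparison
#'
#' Evaluates two or more policies on identical call streams: in every
#' replication all policies see the same call times, locations, actual and
#' classified severities and service durations, so the only difference
#' between their episode outcomes is the decisions. The function verifies
#' the synchronisation (a checksum of the shared call stream per policy run)
#' and returns per-replication mean RLI together with paired t-tests of
#' every policy against the first.
#'
#' @param scenario An [ems_scenario()].
#' @param policies Named list of `ems_policy` objects (>= 2 entries, or 1 to
#'   compare a policy with itself).
#' @param replications Number of CRN-paired replications (default 30).
#' @param seed Master seed; replication `r` uses substreams derived from
#'   `seed` and `r`.
#' @param horizon_days,warmup_days Episode length per replication.
#' @return A list of class `ems_crn` with `results` (long data frame:
#'   replication, policy, mean RLI, mean relocation time, ...), `paired`
#'   (comparisons vs the first policy: mean difference, t, p two-sided),
#'   and `episodes` (the last replication's episodes, for inspection).
#' @export
crn_compare <- function(scenario, policies, replications = 30, seed = 1L,
                        horizon_days = 7, warmup_days = 1) {
  stopifnot(inherits(scenario, "ems_scenario"), length(policies) >= 1,
            replications >= 1)
  if (is.null(names(policies)) || any(!nzchar(names(policies)))) {
    names(policies) <- vapply(policies, function(p) p$name, character(1))
  }
  rows <- list()
  episodes <- NULL
  for (r in seq_len(replications)) {
    rep_seed <- (as.double(seed) * 131071 + r) %% 2147483647
    calls <- sample_calls(scenario, horizon_days, warmup_days, rep_seed)
    checksum <- NULL
    episodes <- list()
    for (nm in names(policies)) {
      ep <- run_episode(scenario, policies[[nm]], calls = calls)
      cs <- sum(ep$patients$report) + sum(ep$patients$x) +
        sum(ep$patients$severity_actual == "H") +
        sum(ep$patients$severity_classified == "H")
      if (is.null(checksum)) checksum <- cs
      else if (!identical(checksum, cs)) {
        stop("CRN breach: call streams diverged between policies")
      }
      episodes[[nm]] <- ep
      m <- ep$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        replication = r, policy = nm, seed = rep_seed,
        mean_rli = m$mean_rli, mean_rt = m$mean_rt,
        mean_rt_pc = m$mean_rt_pc, frac_queued = m$frac_queued,
        mean_relocation_min = m$mean_relocation_min,
        n_patients = m$n_patients,
        fhi = fhi(ep), pli = pli(ep), iai = iai(ep),
        stringsAsFactors = FALSE
      )
    }
  }
  results <- do.call(rbind, rows)
  base_nm <- names(policies)[1]
  paired <- NULL
  if (length(policies) >= 2) {
    base <- results$mean_rli[results$policy == base_nm]
    paired <- do.call(rbind, lapply(names(policies)[-1], function(nm) {
      other <- results$mean_rli[results$policy == nm]
      tt <- if (replications >= 2) {
        stats::t.test(other, base, paired = TRUE)
      } else NULL
      data.frame(policy = nm, reference = base_nm,
                 mean_diff = mean(other - base),
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 p_value = if (is.null(tt)) NA_real_ else tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(results = results, paired = paired, episodes = episodes,
                 replications = replications),
            class = "ems_crn")
}

#' @export
print.ems_crn <- function(x, ...) {
  cat(sprintf("<ems_crn> %d CRN-paired replications\n", x$replications))
  agg <- stats::aggregate(mean_rli ~ policy, x$results, mean)
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-10s mean RLI %.3f\n", agg$policy[i], agg$mean_rli[i]))
  }
  if (!is.null(x$paired)) {
    for (i in seq_len(nrow(x$paired))) {
      cat(sprintf("  %s - %s: diff %.3f (paired t = %.2f, p = %.3g)\n",
                  x$paired$policy[i], x$paired$reference[i],
                  x$paired$mean_diff[i], x$paired$t[i], x$paired$p_value[i]))
    }
  }
  invisible(x)
}

#' Operational dispatch indices
#'
#' Computed from an episode's dispatch decision log (post-warm-up decisions
#' only):
#' * `fhi()` — future orientation for classified-high patients: among
#'   dispatches to classified-high patients with at least two available
#'   ambulances of which at least one is an ALS, the fraction where neither
#'   the nearest ALS nor the nearest ambulance was chosen.
#' * `pli()` — present orientation for classified-low patients: among
#'   dispatches to classified-low patients where the nearest available
#'   ambulance is an ALS and alternatives exist, the fraction where that
#'   nearest ALS was chosen.
#' * `iai()` — ALS oversupply: the fraction of classified-low dispatches
#'   served by an ALS.
#'
#' "Nearest" is resolved by expected travel time at the decision instant,
#' ties to the lower ambulance id. When no decision qualifies for an index's
#' denominator the index is undefined and `NA` is returned.
#'
#' @param dispatches A dispatch decision log (the `dispatches` element of an
#'   `ems_episode`, or any data frame with the same columns).
#' @return A single ratio in \[0, 1\], or `NA` if undefined.
#' @export
fhi <- function(dispatches) {
  d <- eligible_decisions(dispatches)
  elig <- d$classified_high & d$n_candidates >= 2L & d$n_als_candidates >= 1L
  if (!any(elig)) return(NA_real_)
  dev <- d$chosen[elig] != d$nearest_als[elig] & d$chosen[elig] != d$nearest[elig]
  mean(dev)
}

#' @rdname fhi
#' @export
pli <- function(dispatches) {
  d <- eligible_decisions(dispatches)
  elig <- !d$classified_high & d$n_candidates >= 2L & d$nearest_is_als
  if (!any(elig)) return(NA_real_)
  mean(d$chosen[elig] == d$nearest[elig])
}

#' @rdname fhi
#' @export
iai <- function(dispatches) {
  d <- eligible_decisions(dispatches)
  elig <- !d$classified_high
  if (!any(elig)) return(NA_real_)
  mean(d$chosen_als[elig])
}

eligible_decisions <- function(dispatches) {
  if (inherits(dispatches, "ems_episode")) dispatches <- dispatches$dispatches
  if (!is.null(dispatches$in_horizon)) {
    dispatches <- dispatches[dispatches$in_horizon, , drop = FALSE]
  }
  dispatches
}

#' Mean relocation time of an episode
#'
#' Mean travel time (base arrival minus handover completion) over the
#' post-warm-up redeployments of an episode.
#'
#' @param episode An `ems_episode` or its `relocations` data frame.
#' @return Minutes, or `NA` if there were no redeployments.
#' @export
relocation_time <- function(episode) {
  r <- if (inherits(episode, "ems_episode")) episode$relocations else episode
  if (!is.null(r$in_horizon)) r <- r[r$in_horizon, , drop = FALSE]
  if (!nrow(r)) return(NA_real_)
  mean(r$travel_min)
}

#' Full-factorial experiment over fleet composition and triage errors
#'
#' Crosses ALS ratio, undertriage rate and overtriage rate; for each cell,
#' trains an ADP value table when an ADP policy is requested (training is
#' per cell, since the optimal table depends on the cell's scenario), then
#' evaluates every policy with CRN-paired replications.
#'
#' @param scenario_fn Function `(als_ratio, alpha, beta) -> ems_scenario`;
#'   default wires the factors into [default_scenario()].
#' @param als_ratios,alphas,betas Factor levels.
#' @param policies Character vector naming the policies to evaluate, among
#'   `"greedy"`, `"myopic"`, `"adp"`.
#' @param replications CRN replications per cell.
#' @param train_iterations ADP training iterations per cell (used only when
#'   `"adp"` is requested).
#' @param seed Master seed.
#' @param horizon_days,warmup_days Episode length.
#' @param gamma Discount factor for ADP.
#' @return A list of class `ems_factorial` with `results` (long data frame:
#'   cell factors x policy x replication with mean RLI, FHI, PLI, IAI and
#'   mean relocation time) and `cells` (per-cell paired summaries).
#' @export
factorial_run <- function(scenario_fn = NULL,
                          als_ratios = c(0.5, 0.67, 0.83, 1.0),
                          alphas = seq(0, 0.4, 0.1),
                          betas = seq(0, 0.4, 0.1),
                          policies = c("greedy", "adp"),
                          replications = 100,
                          train_iterations = 1000,
                          seed = 1L, horizon_days = 7, warmup_days = 1,
                          gamma = 0.9) {
  if (is.null(scenario_fn)) {
    scenario_fn <- function(als_ratio, alpha, beta) {
      default_scenario(als_ratio = als_ratio, alpha = alpha, beta = beta)
    }
  }
  stopifnot(all(als_ratios >= 0 & als_ratios <= 1),
            all(alphas >= 0 & alphas <= 1), all(betas >= 0 & betas <= 1),
            replications >= 2)
  grid <- expand.grid(als_ratio = als_ratios, alpha = alphas, beta = betas,
                      KEEP.OUT.ATTRS = FALSE)
  res <- list(); cells <- list()
  for (g in seq_len(nrow(grid))) {
    scn <- scenario_fn(grid$als_ratio[g], grid$alpha[g], grid$beta[g])
    cell_seed <- (as.double(seed) * 524287 + g) %% 2147483647
    pol <- list()
    for (nm in policies) {
      pol[[nm]] <- switch(
        nm,
        greedy = greedy_policy(),
        myopic = myopic_policy(),
        adp = {
          fit <- train_adp(scn, train_iterations, gamma = gamma,
                           seed = cell_seed, horizon_days = horizon_days,
                           warmup_days = warmup_days)
          adp_policy(fit$table, gamma)
        },
        stop("unknown policy name: ", nm)
      )
    }
    cmp <- crn_compare(scn, pol, replications, cell_seed,
                       horizon_days, warmup_days)
    r <- cmp$results
    r$als_ratio <- grid$als_ratio[g]
    r$alpha <- grid$alpha[g]
    r$beta <- grid$beta[g]
    res[[g]] <- r
    if (!is.null(cmp$paired)) {
      pc <- cmp$paired
      pc$als_ratio <- grid$als_ratio[g]
      pc$alpha <- grid$alpha[g]
      pc$beta <- grid$beta[g]
      cells[[g]] <- pc
    }
  }
  structure(list(results = do.call(rbind, res),
                 cells = if (length(cells)) do.call(rbind, cells) else NULL,
                 grid = grid),
            class = "ems_factorial")
}

#' Main-effect summary of a factorial experiment
#'
#' Cell-mean summaries of mean RLI by each factor level and policy, the
#' simple replacement for a formal multiway ANOVA.
#'
#' @param x An `ems_factorial`.
#' @return Named list of data frames, one per factor.
#' @export
main_effects <- function(x) {
  stopifnot(inherits(x, "ems_factorial"))
  lapply(
    stats::setNames(c("als_ratio", "alpha", "beta"),
                    c("als_ratio", "alpha", "beta")),
    function(f) {
      stats::aggregate(stats::as.formula(paste("mean_rli ~ policy +", f)),
                       x$results, mean)
    }
  )
}
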