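#' Create an empty value table
#'
#' The value table maps a 19-dimensional aggregated state (idle-or-relocating
#' ambulance count and pending patient count in each of the nine spatial
#' cells, plus the time-zone index) to an approximate value and a visit
#' count. Unseen states have value 0.
#'
#' @return An object of class `ems_value_table`.
#' @export
value_table <- function() {
  structure(
    list(keys = matrix(integer(0), 0, 19), value = numeric(0),
         count = integer(0)),
    class = "ems_value_table"
  )
}

#' @export
print.ems_value_table <- function(x, ...) {
  cat(sprintf("<ems_value_table> %d aggregated states, %s visits\n",
              nrow(x$keys), format(sum(x$count), big.mark = ",")))
  if (nrow(x$keys)) {
    cat(sprintf("  value range [%.3f, %.3f]; states per zone: %s\n",
                min(x$value), max(x$value),
                paste(tabulate(x$keys[, 19], 3), collapse = "/")))
  }
  invisible(x)
}

vt_match <- function(table, key) {
  key <- as.integer(key)
  stopifnot(length(key) == 19L)
  hit <- which(colSums(t(table$keys) != key) == 0L)
  if (length(hit)) hit[1] else NA_integer_
}

#' Aggregate a system snapshot into a value-table key
#'
#' Spatial aggregation uses the 3 x 3 grid over the scenario's bounding box;
#' temporal aggregation uses three time zones: 1 = \[01:00, 08:00),
#' 2 = \[08:00, 11:00), 3 = the remainder of the day (intervals are
#' half-open). Idle ambulances are counted in the cell of their current
#' position; relocating (to-base) ambulances in the cell of their
#' destination base, so that alternative redeployment destinations map to
#' distinct post-decision keys; ambulances in any other status are not
#' counted. Waiting patients are counted in the cell of their location.
#'
#' @param ambulances Data frame with columns `x`, `y`, `status` (one of
#'   `"idle"`, `"to-patient"`, `"on-scene"`, `"to-hospital"`,
#'   `"at-hospital"`, `"to-base"`) and, for `"to-base"` rows, `dest_base`
#'   (base index).
#' @param waiting Data frame of waiting-patient locations (`x`, `y`); may
#'   have zero rows.
#' @param clock Time in minutes since midnight (wraps daily).
#' @param scenario An [ems_scenario()].
#' @return Integer vector of length 19 (9 idle counts, 9 pending counts,
#'   zone index in 1..3).
#' @export
aggregate_state <- function(ambulances, waiting, clock, scenario) {
  bbox <- scenario$geometry$bbox
  idle <- integer(9)
  for (i in seq_len(nrow(ambulances))) {
    st <- ambulances$status[i]
    if (st == "idle") {
      cell <- district_of(ambulances$x[i], ambulances$y[i], bbox)
    } else if (st == "to-base") {
      b <- ambulances$dest_base[i]
      cell <- district_of(scenario$geometry$bases$x[b],
                          scenario$geometry$bases$y[b], bbox)
    } else next
    idle[cell] <- idle[cell] + 1L
  }
  pend <- integer(9)
  for (i in seq_len(nrow(waiting))) {
    cell <- district_of(waiting$x[i], waiting$y[i], bbox)
    pend[cell] <- pend[cell] + 1L
  }
  c(idle, pend, time_zone(clock))
}

#' Time zone index of a clock time
#'
#' @param clock Minutes since midnight (wraps daily).
#' @return 1 for \[01:00, 08:00), 2 for \[08:00, 11:00), 3 otherwise.
#' @export
time_zone <- function(clock) {
  m <- clock %% 1440
  ifelse(m >= 60 & m < 480, 1L, ifelse(m >= 480 & m < 660, 2L, 3L))
}

#' Harmonic value update
#'
#' Increments the state's visit count `n` and moves its value toward the
#' sampled estimate with step size `1/n`: the first visit stores the sample
#' exactly, and a constant sample is a fixed point. The harmonic schedule
#' satisfies the stochastic-approximation conditions (divergent step sum,
#' convergent squared sum).
#'
#' @param table An `ems_value_table`.
#' @param key Integer aggregated-state key of length 19.
#' @param v_hat Sampled value estimate (finite).
#' @return The updated table.
#' @export
update_value <- function(table, key, v_hat) {
  stopifnot(inherits(table, "ems_value_table"), is.finite(v_hat))
  i <- vt_match(table, key)
  if (is.na(i)) {
    table$keys <- rbind(table$keys, as.integer(key))
    table$value <- c(table$value, v_hat)
    table$count <- c(table$count, 1L)
  } else {
    n <- table$count[i] + 1L
    table$count[i] <- n
    table$value[i] <- (1 - 1 / n) * table$value[i] + v_hat / n
  }
  table
}

#' Dominance relation between aggregated states
#'
#' State `s` dominates `s2` when both lie in the same time zone, `s` has at
#' least as many idle-or-relocating ambulances in every cell, and at most as
#' many pending patients in every cell. A dominating state can serve any
#' realisation at least as well, so under the minimised RLI objective its
#' value should not exceed the dominated state's. States in different time
#' zones are incomparable.
#'
#' @param s,s2 Integer keys of length 19.
#' @return `TRUE` if `s` dominates `s2`.
#' @export
dominates <- function(s, s2) {
  s <- as.integer(s); s2 <- as.integer(s2)
  stopifnot(length(s) == 19L, length(s2) == 19L)
  s[19] == s2[19] && all(s[1:9] >= s2[1:9]) && all(s[10:18] <= s2[10:18])
}

#' Monotonicity-preserving projection
#'
#' Given a reference state and value `(s_r, z_r)`, sets the reference
#' state's value to `z_r`, caps at `z_r` the value of every stored state
#' that dominates `s_r`, and floors at `z_r` the value of every stored state
#' dominated by `s_r`. Incomparable states are untouched. Applying the
#' operator twice with the same reference is idempotent.
#'
#' @param table An `ems_value_table`.
#' @param key Reference aggregated-state key (length 19).
#' @param z_ref Reference value; defaults to the state's current stored
#'   value (0 if unseen).
#' @return The projected table.
#' @export
project_monotone <- function(table, key, z_ref = NULL) {
  stopifnot(inherits(table, "ems_value_table"))
  key <- as.integer(key)
  i <- vt_match(table, key)
  if (is.null(z_ref)) z_ref <- if (is.na(i)) 0 else table$value[i]
  if (is.na(i)) {
    table$keys <- rbind(table$keys, key)
    table$value <- c(table$value, z_ref)
    table$count <- c(table$count, 0L)
    i <- nrow(table$keys)
  }
  n <- nrow(table$keys)
  if (n > 1L) {
    K <- table$keys
    same_zone <- K[, 19] == key[19]
    idle_ge <- rowSums(K[, 1:9, drop = FALSE] >=
                         matrix(key[1:9], n, 9, byrow = TRUE)) == 9L
    idle_le <- rowSums(K[, 1:9, drop = FALSE] <=
                         matrix(key[1:9], n, 9, byrow = TRUE)) == 9L
    pend_le <- rowSums(K[, 10:18, drop = FALSE] <=
                         matrix(key[10:18], n, 9, byrow = TRUE)) == 9L
    pend_ge <- rowSums(K[, 10:18, drop = FALSE] >=
                         matrix(key[10:18], n, 9, byrow = TRUE)) == 9L
    dom_over_ref <- same_zone & idle_ge & pend_le   # s dominates reference
    dom_under_ref <- same_zone & idle_le & pend_ge  # reference dominates s
    dom_over_ref[i] <- dom_under_ref[i] <- FALSE
    table$value[dom_over_ref] <- pmin(table$value[dom_over_ref], z_ref)
    table$value[dom_under_ref] <- pmax(table$value[dom_under_ref], z_ref)
  }
  table$value[i] <- z_ref
  table
}

#' Stochastic mini-batch monotone projection
#'
#' At the end of a learning iteration, samples up to `n_per_zone` distinct
#' visited states per time zone with probability proportional to their visit
#' counts (without replacement) and applies [project_monotone()] with each
#' sampled state as the reference, in sampled order, re-reading the
#' reference value after each projection.
#'
#' @param table An `ems_value_table`.
#' @param n_per_zone Maximum reference states per zone (default 10).
#' @return The projected table.
#' @export
minibatch_project <- function(table, n_per_zone = 10L) {
  stopifnot(inherits(table, "ems_value_table"))
  if (!nrow(table$keys)) return(table)
  refs <- list()
  for (zone in 1:3) {
    idx <- which(table$keys[, 19] == zone & table$count > 0L)
    if (!length(idx)) next
    take <- min(length(idx), n_per_zone)
    picked <- if (length(idx) == 1L) idx else {
      sample(idx, take, replace = FALSE, prob = table$count[idx])
    }
    refs <- c(refs, as.list(picked))
  }
  for (i in refs) {
    table <- project_monotone(table, table$keys[i, ], table$value[i])
  }
  table
}

#' Read or write a value table as a flat CSV
#'
#' The CSV has 19 key columns (`idle1..idle9`, `pending1..pending9`,
#' `zone`), then `value` and `count`.
#'
#' @param table An `ems_value_table`.
#' @param path File path.
#' @return `read_value_table()` returns an `ems_value_table`;
#'   `write_value_table()` returns `path` invisibly.
#' @export
write_value_table <- function(table, path) {
  stopifnot(inherits(table, "ems_value_table"))
  df <- as.data.frame(table$keys)
  names(df) <- c(paste0("idle", 1:9), paste0("pending", 1:9), "zone")
  df$value <- table$value
  df$count <- table$count
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_value_table
#' @export
read_value_table <- function(path) {
  df <- utils::read.csv(path)
  out <- value_table()
  out$keys <- as.matrix(df[, 1:19])
  dimnames(out$keys) <- NULL
  storage.mode(out$keys) <- "integer"
  out$value <- as.numeric(df$value)
  out$count <- as.integer(df$count)
  out
}
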