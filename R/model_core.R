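#' Time grid for the cohort simulation
#'
#' The model advances a cohort in fixed monthly cycles over a finite horizon.
#' The default grid is 72 monthly cycles (6 years).
#'
#' @param horizon_years Model horizon in years.
#' @param cycle_length_months Cycle length in months; must divide 12.
#'
#' @return An object of class `time_grid` with fields `cycle_length_months`,
#'   `horizon_years`, `cycles_per_year` and `n_cycles`.
#' @export
#' @examples
#' time_grid() # 72 monthly cycles
time_grid <- function(horizon_years = 6, cycle_length_months = 1) {
  if (cycle_length_months < 1) {
    stop("cycle_length_months must be >= 1", call. = FALSE)
  }
  if (horizon_years <= 0) {
    stop("horizon_years must be positive", call. = FALSE)
  }
  cycles_per_year <- 12 / cycle_length_months
  n_cycles <- horizon_years * cycles_per_year
  if (abs(n_cycles - round(n_cycles)) > 1e-9) {
    stop("horizon does not contain a whole number of cycles", call. = FALSE)
  }
  structure(
    list(
      cycle_length_months = cycle_length_months,
      horizon_years = horizon_years,
      cycles_per_year = cycles_per_year,
      n_cycles = as.integer(round(n_cycles))
    ),
    class = "time_grid"
  )
}

# Absolute tolerance for row-stochasticity checks.
STOCHASTIC_TOL <- 1e-9

#' Construct a validated per-cycle transition matrix
#'
#' Wraps a square numeric matrix of per-cycle transition probabilities.
#' Validation enforces row-stochasticity (each row sums to 1 within 1e-9),
#' entries in [0, 1], and an absorbing death row.
#'
#' @param probs Square numeric matrix; `probs[i, j]` is the per-cycle
#'   probability of moving from state `i` to state `j`.
#' @param states Character vector of state names, in matrix order.
#' @param death_state Name of the absorbing death state.
#'
#' @return An object of class `transition_matrix`.
#' @export
transition_matrix <- function(probs, states = rownames(probs),
                              death_state = "death") {
  if (is.null(states)) {
    stop("state names are required", call. = FALSE)
  }
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs) || nrow(probs) != length(states)) {
    stop("probs must be square with one row per state", call. = FALSE)
  }
  dimnames(probs) <- list(states, states)
  out <- structure(
    list(probs = probs, states = states, death_state = death_state),
    class = "transition_matrix"
  )
  validate_transition_matrix(out)
  out
}

validate_transition_matrix <- function(tm) {
  p <- tm$probs
  if (any(p < -STOCHASTIC_TOL) || any(p > 1 + STOCHASTIC_TOL)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(p)
  if (any(abs(rs - 1) > STOCHASTIC_TOL)) {
    bad <- tm$states[which.max(abs(rs - 1))]
    stop(sprintf("row '%s' sums to %.12f, not 1", bad, rs[which.max(abs(rs - 1))]),
         call. = FALSE)
  }
  if (tm$death_state %in% tm$states) {
    d <- tm$death_state
    if (abs(p[d, d] - 1) > STOCHASTIC_TOL ||
        any(abs(p[d, setdiff(tm$states, d)]) > STOCHASTIC_TOL)) {
      stop("death row must be absorbing", call. = FALSE)
    }
  }
  invisible(tm)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("Per-cycle transition matrix: %d states (absorbing: %s)\n",
              length(x$states), x$death_state))
  print(round(x$probs, 4))
  invisible(x)
}

#' Build a transition matrix from sparse entries with diagonal closure
#'
#' Off-diagonal transition probabilities are given as `(from, to, prob)`
#' entries; each row's remaining mass is closed onto the diagonal ("remain in
#' state"), so a perturbed entry never breaks row-stochasticity. The death row
#' is forced absorbing.
#'
#' @param entries A data.frame with columns `from`, `to`, `prob` (off-diagonal
#'   moves only), or an empty data.frame / NULL for a no-event model.
#' @param states Ordered character vector of state names.
#' @param adjacency Optional logical matrix (states x states) of structurally
#'   allowed moves; entries outside it are rejected.
#' @param death_state Name of the absorbing state.
#'
#' @return A `transition_matrix`.
#' @export
#' @examples
#' sts <- c("alive", "death")
#' build_transition_matrix(
#'   data.frame(from = "alive", to = "death", prob = 0.1), sts
#' )
build_transition_matrix <- function(entries, states, adjacency = NULL,
                                    death_state = "death") {
  n <- length(states)
  p <- diag(n)
  dimnames(p) <- list(states, states)
  if (!is.null(entries) && nrow(entries) > 0) {
    entries <- as.data.frame(entries)
    if (!all(c("from", "to", "prob") %in% names(entries))) {
      stop("entries must have columns from, to, prob", call. = FALSE)
    }
    if (!all(entries$from %in% states) || !all(entries$to %in% states)) {
      stop("entries reference unknown states", call. = FALSE)
    }
    if (anyDuplicated(entries[, c("from", "to")])) {
      stop("duplicate (from, to) entries", call. = FALSE)
    }
    if (any(entries$from == entries$to)) {
      stop("diagonal entries are implied by closure; specify off-diagonal moves only",
           call. = FALSE)
    }
    if (any(entries$prob < 0 | entries$prob > 1)) {
      stop("entry probabilities must lie in [0, 1]", call. = FALSE)
    }
    if (any(entries$from == death_state)) {
      stop("the death state is absorbing and has no outgoing entries",
           call. = FALSE)
    }
    if (!is.null(adjacency)) {
      ok <- mapply(function(f, t) isTRUE(adjacency[f, t]),
                   entries$from, entries$to)
      if (!all(ok)) {
        bad <- entries[!ok, , drop = FALSE]
        stop(sprintf("entries violate structural adjacency: %s",
                     paste(sprintf("%s -> %s", bad$from, bad$to),
                           collapse = ", ")),
             call. = FALSE)
      }
    }
    for (i in seq_len(nrow(entries))) {
      p[entries$from[i], entries$to[i]] <- entries$prob[i]
    }
    # close each live row onto its diagonal
    for (s in setdiff(states, death_state)) {
      off <- sum(p[s, setdiff(states, s)])
      if (off > 1 + STOCHASTIC_TOL) {
        stop(sprintf("row '%s' is over-specified: off-diagonal sum %.6f > 1",
                     s, off), call. = FALSE)
      }
      p[s, s] <- max(0, 1 - off)
    }
  }
  if (death_state %in% states) {
    p[death_state, ] <- 0
    p[death_state, death_state] <- 1
  }
  transition_matrix(p, states, death_state = death_state)
}

#' Propagate a cohort through the model
#'
#' Computes the state-occupancy trace `occupancy[t] = occupancy[t-1] %*% P`
#' for `t = 1..n_cycles`; row 0 is the initial distribution.
#'
#' @param tm A `transition_matrix`.
#' @param initial Numeric occupancy vector summing to 1 (named or in state
#'   order).
#' @param grid A `time_grid`.
#'
#' @return An object of class `cohort_trace`: a `(n_cycles + 1) x n_states`
#'   matrix with a `cycle` attribute `0:n_cycles`.
#' @export
run_cohort <- function(tm, initial, grid = time_grid()) {
  stopifnot(inherits(tm, "transition_matrix"), inherits(grid, "time_grid"))
  n <- length(tm$states)
  if (!is.null(names(initial))) {
    if (!setequal(names(initial), tm$states)) {
      stop("initial occupancy names do not match model states", call. = FALSE)
    }
    initial <- initial[tm$states]
  }
  if (length(initial) != n) {
    stop("initial occupancy has wrong length", call. = FALSE)
  }
  if (any(initial < 0) || abs(sum(initial) - 1) > STOCHASTIC_TOL) {
    stop("initial occupancy must be a probability distribution", call. = FALSE)
  }
  occ <- matrix(0, nrow = grid$n_cycles + 1L, ncol = n,
                dimnames = list(NULL, tm$states))
  occ[1L, ] <- initial
  for (t in seq_len(grid$n_cycles)) {
    occ[t + 1L, ] <- occ[t, ] %*% tm$probs
  }
  structure(occ, class = c("cohort_trace", "matrix"),
            cycle = 0:grid$n_cycles, death_state = tm$death_state)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("Cohort trace: %d cycles, %d states\n", nrow(x) - 1L, ncol(x)))
  idx <- unique(c(1L, min(7L, nrow(x)), nrow(x)))
  print(round(unclass(x)[idx, , drop = FALSE], 4))
  invisible(x)
}

#' Per-cycle discount factors
#'
#' Factors are evaluated at cycle end: cycle `t` is discounted by
#' `(1 + annual_rate)^(-t / cycles_per_year)`.
#'
#' @param annual_rate Annual discount rate as a fraction (default 0.05).
#' @param grid A `time_grid`.
#'
#' @return Numeric vector of length `n_cycles`.
#' @export
#' @examples
#' discount_factors(0.05)[12] # one year out: 1 / 1.05
discount_factors <- function(annual_rate = 0.05, grid = time_grid()) {
  if (annual_rate < 0) stop("annual_rate must be >= 0", call. = FALSE)
  t <- seq_len(grid$n_cycles)
  (1 + annual_rate)^(-t / grid$cycles_per_year)
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' With the half-cycle correction on (the default), the effective membership
#' for cycle `t` is the trapezoidal mean of the cycle-start and cycle-end
#' occupancy rows. Costs are per state per cycle; utilities are annual weights
#' so each cycle accrues `utility * cycle_length / 12` QALYs.
#'
#' @param trace A `cohort_trace`.
#' @param state_cost Named numeric vector: cost per state per cycle (currency).
#' @param state_utility Named numeric vector: utility weight per state in
#'   [0, 1]; death must be 0.
#' @param annual_rate Annual discount rate.
#' @param grid A `time_grid`.
#' @param half_cycle Apply the trapezoidal half-cycle correction (to both
#'   costs and effects).
#' @param weighting Occupancy weighting within a cycle; overrides `half_cycle`
#'   when supplied. One of "half" (trapezoidal), "end", "start".
#'
#' @return A list with elements `cost` and `qalys` (discounted totals).
#' @export
accumulate_outcomes <- function(trace, state_cost, state_utility,
                                annual_rate = 0.05, grid = time_grid(),
                                half_cycle = TRUE,
                                weighting = if (half_cycle) "half" else "end") {
  stopifnot(inherits(trace, "cohort_trace"))
  weighting <- match.arg(weighting, c("half", "end", "start"))
  states <- colnames(trace)
  if (nrow(trace) != grid$n_cycles + 1L) {
    stop("trace and grid disagree on the number of cycles", call. = FALSE)
  }
  state_cost <- reorder_named(state_cost, states, "state_cost")
  state_utility <- reorder_named(state_utility, states, "state_utility")
  if (any(state_cost < 0)) stop("state costs must be >= 0", call. = FALSE)
  if (any(state_utility < 0 | state_utility > 1)) {
    stop("state utilities must lie in [0, 1]", call. = FALSE)
  }
  occ <- unclass(trace)
  n <- grid$n_cycles
  eff <- switch(weighting,
    half  = (occ[1:n, , drop = FALSE] + occ[2:(n + 1), , drop = FALSE]) / 2,
    end   = occ[2:(n + 1), , drop = FALSE],
    start = occ[1:n, , drop = FALSE]
  )
  d <- discount_factors(annual_rate, grid)
  year_frac <- grid$cycle_length_months / 12
  list(
    cost  = sum(d * (eff %*% state_cost)),
    qalys = sum(d * (eff %*% state_utility)) * year_frac
  )
}

reorder_named <- function(x, states, what) {
  if (!is.null(names(x))) {
    if (!setequal(names(x), states)) {
      stop(sprintf("%s names do not match model states", what), call. = FALSE)
    }
    x <- x[states]
  }
  if (length(x) != length(states)) {
    stop(sprintf("%s has wrong length", what), call. = FALSE)
  }
  x
}

#' Export a cohort trace as CSV
#'
#' Writes one row per cycle boundary (0..n_cycles) with header
#' `cycle,<state names...>`, occupancies as decimal fractions at full
#' precision.
#'
#' @param trace A `cohort_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  df <- data.frame(cycle = attr(trace, "cycle"), unclass(trace),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
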