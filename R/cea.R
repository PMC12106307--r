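#' Incremental cost-effectiveness result for two strategies
#'
#' Computes incremental cost, incremental QALYs, the ICER (incremental cost
#' divided by incremental QALYs) and a dominance flag for the combination arm
#' against monotherapy. When the sign of the incremental cost and incremental
#' QALYs differ, one strategy dominates and the ICER is not reported as a
#' number.
#'
#' @param cost_mono,qalys_mono Discounted totals for the monotherapy arm.
#' @param cost_combo,qalys_combo Discounted totals for the combination arm.
#'
#' @return An object of class `cea_result`: a list with `arms` (a data.frame
#'   of per-arm totals), `incr_cost`, `incr_qalys`, `icer` (NA when incremental
#'   QALYs are zero), and `dominance` (one of "none", "intervention_dominant",
#'   "intervention_dominated").
#' @export
#' @examples
#' compute_icer(529928.56, 1.48, 650629.56, 2.02)
compute_icer <- function(cost_mono, qalys_mono, cost_combo, qalys_combo) {
  vals <- c(cost_mono, qalys_mono, cost_combo, qalys_combo)
  if (any(!is.finite(vals))) stop("inputs must be finite", call. = FALSE)
  if (qalys_mono < 0 || qalys_combo < 0) {
    stop("QALY totals must be >= 0", call. = FALSE)
  }
  incr_cost <- cost_combo - cost_mono
  incr_qalys <- qalys_combo - qalys_mono
  dominance <- "none"
  if (incr_qalys > 0 && incr_cost < 0) dominance <- "intervention_dominant"
  if (incr_qalys < 0 && incr_cost > 0) dominance <- "intervention_dominated"
  icer <- if (incr_qalys != 0) incr_cost / incr_qalys else NA_real_
  structure(
    list(
      arms = data.frame(
        arm = arm_names(),
        cost = c(cost_mono, cost_combo),
        qalys = c(qalys_mono, qalys_combo)
      ),
      incr_cost = incr_cost,
      incr_qalys = incr_qalys,
      icer = icer,
      dominance = dominance
    ),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness result (combination vs monotherapy)\n")
  arms <- x$arms
  arms$cost <- sprintf("%.2f", arms$cost)
  arms$qalys <- sprintf("%.2f", arms$qalys)
  print(arms, row.names = FALSE)
  cat(sprintf("  incremental cost:  %.2f CNY\n", x$incr_cost))
  cat(sprintf("  incremental QALYs: %.2f\n", x$incr_qalys))
  if (x$dominance != "none") {
    cat(sprintf("  dominance: %s (ICER not reported)\n", x$dominance))
  } else if (is.na(x$icer)) {
    cat("  ICER: undefined (equal QALYs)\n")
  } else {
    cat(sprintf("  ICER: %.2f CNY/QALY\n", x$icer))
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' `nmb = wtp x qalys - cost`. For two strategies with positive incremental
#' QALYs, the intervention has the larger NMB exactly when its ICER lies below
#' the willingness-to-pay threshold.
#'
#' @param cost Discounted cost.
#' @param qalys Discounted QALYs.
#' @param wtp Willingness-to-pay threshold (currency per QALY), `>= 0`.
#'
#' @return Net monetary benefit in currency units (vectorized over inputs).
#' @export
net_monetary_benefit <- function(cost, qalys, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * qalys - cost
}

#' Run the deterministic base case
#'
#' Builds both strategies from a parameter set, propagates the cohort from
#' all-mass-in-the-complication-free state over the model horizon, accumulates
#' discounted costs and QALYs (with half-cycle correction by default), and
#' assembles the incremental comparison.
#'
#' @param params A `gd_params` with per-arm transitions.
#' @param half_cycle Apply the half-cycle correction; defaults to the value in
#'   `params$economics`.
#'
#' @return A `cea_result`.
#' @export
run_base_case <- function(params, half_cycle = params$economics$half_cycle) {
  grid <- params_grid(params)
  init <- initial_occupancy(params)
  totals <- lapply(arm_names(), function(arm) {
    st <- build_strategy(arm, params)
    trace <- run_cohort(st$matrix, init, grid)
    accumulate_outcomes(trace, st$state_cost, st$state_utility,
                        annual_rate = params$economics$discount_rate,
                        grid = grid, half_cycle = half_cycle)
  })
  compute_icer(totals[[1]]$cost, totals[[1]]$qalys,
               totals[[2]]$cost, totals[[2]]$qalys)
}

#' Export a base-case result as CSV
#'
#' One row per arm with columns `arm,cost,incr_cost,qalys,incr_qalys,icer`
#' (incremental columns empty on the reference row), full precision.
#'
#' @param result A `cea_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_base_case_csv <- function(result, path) {
  stopifnot(inherits(result, "cea_result"))
  df <- data.frame(
    arm = result$arms$arm,
    cost = result$arms$cost,
    incr_cost = c(NA, result$incr_cost),
    qalys = result$arms$qalys,
    incr_qalys = c(NA, result$incr_qalys),
    icer = c(NA, result$icer)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
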