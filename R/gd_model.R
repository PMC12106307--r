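#' Health states of the Gaucher disease model
#'
#' Eight states: a complication-free state, six complication states reflecting
#' the visceral, pulmonary, neurological and haematological burden of
#' neuronopathic Gaucher disease, and absorbing death. All patients enter the
#' model without complications.
#'
#' @return Character vector of the eight state names in model order.
#' @export
gd_states <- function() {
  c("state_without_complications",
    "state_with_multiple_complications",
    "necessary_tracheostomy",
    "necessary_enteral_feeding",
    "epilepsy",
    "interstitial_lung_disease",
    "major_bleeding",
    "death")
}

#' Structural adjacency of the Gaucher disease model
#'
#' Allowed moves: every state may remain where it is; the complication-free
#' state may move to any other state; every live state may move to death;
#' death is absorbing. Transitions among complication states are disallowed by
#' default but can be enabled.
#'
#' @param states Ordered state names.
#' @param death_state Name of the absorbing state.
#' @param inter_complication Allow moves between complication states.
#'
#' @return Logical matrix `allowed[from, to]`.
#' @export
gd_adjacency <- function(states = gd_states(), death_state = "death",
                         inter_complication = FALSE) {
  n <- length(states)
  allowed <- matrix(FALSE, n, n, dimnames = list(states, states))
  diag(allowed) <- TRUE
  live <- setdiff(states, death_state)
  allowed[states[1L], ] <- TRUE           # entry state reaches everything
  allowed[live, death_state] <- TRUE      # all live states reach death
  if (inter_complication) {
    comp <- setdiff(live, states[1L])
    allowed[comp, comp] <- TRUE
    diag(allowed) <- TRUE
  }
  allowed[death_state, ] <- FALSE
  allowed[death_state, death_state] <- TRUE
  allowed
}

#' Check a transition matrix against a structural adjacency
#'
#' Reports every nonzero entry that falls outside the allowed move set; the
#' matrix is structurally valid iff the report is empty.
#'
#' @param tm A `transition_matrix`.
#' @param adjacency Logical matrix of allowed moves, as from [gd_adjacency()].
#'
#' @return A data.frame with columns `from`, `to`, `prob`, one row per
#'   violation (zero rows when valid).
#' @export
validate_structure <- function(tm, adjacency = gd_adjacency(tm$states)) {
  stopifnot(inherits(tm, "transition_matrix"))
  bad <- which(!adjacency & abs(tm$probs) > STOCHASTIC_TOL, arr.ind = TRUE)
  data.frame(
    from = tm$states[bad[, 1L]],
    to = tm$states[bad[, 2L]],
    prob = tm$probs[bad],
    row.names = NULL
  )
}

#' Drug dosing schedules
#'
#' Describes how a drug is dosed and priced. Weekly-dosed drugs specify
#' `dose_per_admin` (per kg) and `admins_per_week`; daily-dosed drugs specify
#' `daily_dose_per_kg`. The priced pack links dose units to currency.
#'
#' @param drug_name Drug label.
#' @param pack_size Units (U or mg) per priced pack.
#' @param pack_price Price per pack (CNY).
#' @param dose_per_admin Dose per administration per kg (weekly schedule).
#' @param admins_per_week Administrations per week (weekly schedule).
#' @param daily_dose_per_kg Daily dose per kg (daily schedule).
#'
#' @return An object of class `dose_schedule`.
#' @export
#' @examples
#' dose_schedule("imiglucerase", 400, 21870,
#'               dose_per_admin = 2.5, admins_per_week = 3)
dose_schedule <- function(drug_name, pack_size, pack_price,
                          dose_per_admin = NULL, admins_per_week = NULL,
                          daily_dose_per_kg = NULL) {
  weekly <- !is.null(dose_per_admin) || !is.null(admins_per_week)
  daily <- !is.null(daily_dose_per_kg)
  if (weekly == daily) {
    stop("specify either a weekly or a daily schedule", call. = FALSE)
  }
  qty <- c(pack_size, pack_price,
           if (weekly) c(dose_per_admin, admins_per_week) else daily_dose_per_kg)
  if (any(qty <= 0)) stop("all dosing quantities must be > 0", call. = FALSE)
  structure(
    list(drug_name = drug_name, pack_size = pack_size, pack_price = pack_price,
         dose_per_admin = dose_per_admin, admins_per_week = admins_per_week,
         daily_dose_per_kg = daily_dose_per_kg),
    class = "dose_schedule"
  )
}

# Month length follows the astronomical year: 365.25 / 12 days.
DAYS_PER_YEAR <- 365.25

#' Expected drug cost per monthly cycle
#'
#' Cohort-level expected cost: fractional packs are allowed (no pack
#' rounding). A month is 365.25/12 days, so a weekly schedule delivers
#' 365.25/7/12 administrations per week-month.
#'
#' @param schedule A `dose_schedule`.
#' @param weight_kg Patient weight in kg.
#'
#' @return Cost in CNY per monthly cycle.
#' @export
#' @examples
#' imi <- dose_schedule("imiglucerase", 400, 21870,
#'                      dose_per_admin = 2.5, admins_per_week = 3)
#' monthly_drug_cost(imi, 20) # ~ 35,660.80
monthly_drug_cost <- function(schedule, weight_kg) {
  stopifnot(inherits(schedule, "dose_schedule"))
  if (weight_kg <= 0) stop("weight_kg must be > 0", call. = FALSE)
  price_per_unit <- schedule$pack_price / schedule$pack_size
  if (!is.null(schedule$daily_dose_per_kg)) {
    units_per_month <- schedule$daily_dose_per_kg * weight_kg *
      (DAYS_PER_YEAR / 12)
  } else {
    units_per_month <- schedule$dose_per_admin * weight_kg *
      schedule$admins_per_week * (DAYS_PER_YEAR / 7 / 12)
  }
  units_per_month * price_per_unit
}

#' Default model parameters
#'
#' Returns the full model parameterization used in the analysis: the eight
#' states and structural adjacency, published state utilities, drug pack
#' prices and dosing rules, 20 kg mean patient weight, a 6-year horizon of
#' monthly cycles with half-cycle correction, 5% annual discounting, a WTP
#' range of 1-3x China's 2023 GDP per capita (CNY 89,358), and the sensitivity
#' analysis settings (OWSA perturbation 10%; PSA with 1,000 draws and
#' SE = 10% of the mean).
#'
#' Transition probabilities are not part of the defaults: they are supplied
#' via config or produced by [calibrate_to_targets()] / [random_parameter_set()].
#'
#' @return An object of class `gd_params`.
#' @export
default_parameters <- function() {
  states <- gd_states()
  live <- states[states != "death"]
  utilities <- c(
    state_without_complications = 0.86,
    state_with_multiple_complications = 0.44,
    necessary_tracheostomy = 0.68,
    necessary_enteral_feeding = 0.50,
    epilepsy = 0.55,
    interstitial_lung_disease = 0.55,
    major_bleeding = 0.52,
    death = 0
  )[states]
  params <- list(
    states = states,
    adjacency = gd_adjacency(states),
    utilities = utilities,
    drugs = list(
      imiglucerase = dose_schedule("imiglucerase", pack_size = 400,
                                   pack_price = 21870,
                                   dose_per_admin = 2.5, admins_per_week = 3),
      ambroxol = dose_schedule("ambroxol", pack_size = 600, pack_price = 5.25,
                               daily_dose_per_kg = 25)
    ),
    weight_kg = 20,
    cost_multiplier = c(imiglucerase_mono = 1, imiglucerase_plus_ambroxol = 1),
    transitions = list(mono = empty_entries(), combo = empty_entries()),
    economics = list(
      discount_rate = 0.05,
      horizon_years = 6,
      cycle_length_months = 1,
      gdp_per_capita = 89358,
      wtp_multipliers = c(1, 2, 3),
      half_cycle = TRUE
    ),
    psa = list(
      n_draws = 1000,
      se_fraction = 0.1,
      sample_transitions = FALSE,
      wtp_points = 21
    ),
    owsa = list(
      fraction = 0.1,
      parameters = c("imiglucerase_price", "ambroxol_price",
                     paste0("utility.", live), "discount_rate")
    )
  )
  structure(params, class = "gd_params")
}

empty_entries <- function() {
  data.frame(from = character(), to = character(), prob = numeric(),
             stringsAsFactors = FALSE)
}

#' @export
print.gd_params <- function(x, ...) {
  cat("Gaucher disease model parameters\n")
  cat(sprintf("  states: %d (absorbing death), transitions: mono %d / combo %d entries\n",
              length(x$states), nrow(x$transitions$mono),
              nrow(x$transitions$combo)))
  cat(sprintf("  horizon %g y, cycle %g mo, discount %.1f%%, weight %g kg\n",
              x$economics$horizon_years, x$economics$cycle_length_months,
              100 * x$economics$discount_rate, x$weight_kg))
  cat(sprintf("  WTP: %s (GDP per capita x %s)\n",
              paste(wtp_thresholds(x), collapse = ", "),
              paste(x$economics$wtp_multipliers, collapse = ", ")))
  invisible(x)
}

#' Willingness-to-pay thresholds
#'
#' @param params A `gd_params` object.
#' @return Numeric vector of WTP thresholds (CNY per QALY), the GDP per capita
#'   times each multiplier.
#' @export
wtp_thresholds <- function(params = default_parameters()) {
  params$economics$gdp_per_capita * params$economics$wtp_multipliers
}

arm_names <- function() c("imiglucerase_mono", "imiglucerase_plus_ambroxol")

#' Assemble a strategy: transition matrix plus per-state rewards
#'
#' The monotherapy arm accrues the monthly imiglucerase cost in every live
#' state; the combination arm adds the monthly ambroxol cost. Utilities are
#' identical across arms; death accrues zero cost and zero utility. The arm's
#' `cost_multiplier` (default 1) scales its per-state drug cost.
#'
#' @param arm One of `"imiglucerase_mono"`, `"imiglucerase_plus_ambroxol"`.
#' @param params A `gd_params` with transitions for this arm.
#'
#' @return An object of class `gd_strategy` with fields `arm`, `matrix`,
#'   `state_cost`, `state_utility`.
#' @export
build_strategy <- function(arm, params) {
  arm <- match.arg(arm, arm_names())
  key <- if (arm == "imiglucerase_mono") "mono" else "combo"
  tm <- build_transition_matrix(params$transitions[[key]], params$states,
                                adjacency = params$adjacency)
  viol <- validate_structure(tm, params$adjacency)
  if (nrow(viol) > 0) {
    stop("transition matrix violates structural adjacency", call. = FALSE)
  }
  monthly <- monthly_drug_cost(params$drugs$imiglucerase, params$weight_kg)
  if (key == "combo") {
    monthly <- monthly + monthly_drug_cost(params$drugs$ambroxol,
                                           params$weight_kg)
  }
  monthly <- monthly * params$cost_multiplier[[arm]]
  cost <- stats::setNames(rep(monthly, length(params$states)), params$states)
  cost["death"] <- 0
  structure(
    list(arm = arm, matrix = tm, state_cost = cost,
         state_utility = params$utilities),
    class = "gd_strategy"
  )
}

#' @export
print.gd_strategy <- function(x, ...) {
  cat(sprintf("Strategy '%s': monthly drug cost %.2f CNY/live state\n",
              x$arm, max(x$state_cost)))
  invisible(x)
}

params_grid <- function(params) {
  time_grid(params$economics$horizon_years,
            params$economics$cycle_length_months)
}

initial_occupancy <- function(params) {
  stats::setNames(c(1, rep(0, length(params$states) - 1L)), params$states)
}
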