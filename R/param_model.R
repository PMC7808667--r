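# Parameter model: health-state space, probability/rate conversions,
# parameter-set construction, YAML loading and validation.

#' Internal and reported health-state spaces
#'
#' The model tracks eight internal states. The two `Recovered` sub-states
#' (with and without amputation history) carry the patient's amputation
#' history so that utilities and costs may differ by history while each
#' state remains memoryless; they are summed to a single `Recovered` column
#' for reporting, giving the familiar seven-state presentation.
#'
#' @return Character vector of state names, in canonical order (the
#'   absorbing `Dead` state last).
#' @export
#' @examples
#' pad_states()
#' pad_reported_states()
pad_states <- function() {
  c("Mild", "Progressive", "Severe", "MinorAmputation", "MajorAmputation",
    "RecoveredNoAmp", "RecoveredPostAmp", "Dead")
}

#' @rdname pad_states
#' @export
pad_reported_states <- function() {
  c("Mild", "Progressive", "Severe", "MinorAmputation", "MajorAmputation",
    "Recovered", "Dead")
}

#' Map an internal state to its reported label
#' @param state Character vector of internal state names.
#' @return Character vector of reported labels (`Recovered` for both
#'   recovered sub-states).
#' @export
reported_label <- function(state) {
  bad <- setdiff(state, pad_states())
  if (length(bad) > 0L) {
    stop("unknown health state(s): ", paste(bad, collapse = ", "))
  }
  ifelse(state %in% c("RecoveredNoAmp", "RecoveredPostAmp"), "Recovered", state)
}

#' Convert between annual and per-cycle probabilities
#'
#' Transition evidence in the PAD literature is quoted per year (for
#' example a 25% one-year mortality under critical limb ischaemia), while
#' the model steps in three-month cycles. Under a constant hazard the
#' per-cycle probability is `1 - (1 - p_annual)^(1/cycles_per_year)`;
#' `cycle_to_annual_prob()` is its exact inverse.
#'
#' @param p_annual Annual probability in `[0, 1]`.
#' @param p_cycle Per-cycle probability in `[0, 1]`.
#' @param cycles_per_year Number of model cycles per year (>= 1; 4 for a
#'   three-month cycle).
#' @return A probability on the requested time base.
#' @export
#' @examples
#' annual_to_cycle_prob(0.25, 4)
#' cycle_to_annual_prob(annual_to_cycle_prob(0.35, 4), 4)
annual_to_cycle_prob <- function(p_annual, cycles_per_year = 4) {
  check_probability(p_annual, "p_annual")
  if (any(cycles_per_year < 1)) {
    stop("cycles_per_year must be >= 1, got ", min(cycles_per_year))
  }
  1 - (1 - p_annual)^(1 / cycles_per_year)
}

#' @rdname annual_to_cycle_prob
#' @export
cycle_to_annual_prob <- function(p_cycle, cycles_per_year = 4) {
  check_probability(p_cycle, "p_cycle")
  if (any(cycles_per_year < 1)) {
    stop("cycles_per_year must be >= 1, got ", min(cycles_per_year))
  }
  1 - (1 - p_cycle)^cycles_per_year
}

check_probability <- function(p, name) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop(name, " must lie in [0, 1], got ",
         paste(format(p[!is.finite(p) | p < 0 | p > 1]), collapse = ", "))
  }
  invisible(p)
}

# Care cost per three-month cycle (GBP, 2017/18 NHS reference costs) by
# severity. Recovered states carry no PAD treatment cost; Dead costs nothing.
default_state_costs <- function() {
  c(Mild = 143.09, Progressive = 828.43, Severe = 1767.33,
    MinorAmputation = 2254.98, MajorAmputation = 4913.19,
    RecoveredNoAmp = 0, RecoveredPostAmp = 0, Dead = 0)
}

# Health-state utility weights (EQ-5D index scale; 1 = full health,
# 0 = dead, negative = worse than dead). Ordered strictly by severity;
# recovered-after-amputation sits below recovery without amputation
# because of residual disability.
default_state_utilities <- function() {
  c(Mild = 0.80, Progressive = 0.62, Severe = 0.41,
    MinorAmputation = 0.22, MajorAmputation = -0.087,
    RecoveredNoAmp = 0.75, RecoveredPostAmp = 0.55, Dead = 0)
}

#' Age-group utility multipliers
#'
#' Age enters the model as a multiplicative adjustment on state utilities
#' only; costs are age-invariant. The default multipliers reproduce the
#' ordering of five-year QALY outcomes across age bands (younger groups
#' identical, then a small decline from age 70).
#'
#' @param age_group One of `"50-59"`, `"60-69"`, `"70-79"`, `">=80"`.
#' @return A single multiplier in `(0, 1]`.
#' @export
age_utility_multiplier <- function(age_group = c("50-59", "60-69", "70-79", ">=80")) {
  age_group <- match.arg(age_group)
  c("50-59" = 1.0, "60-69" = 1.0, "70-79" = 0.96, ">=80" = 0.95)[[age_group]]
}

#' Scenario specifications
#'
#' Four strategies are modelled: standard care alone (`SC`), and the
#' negative-pressure device combined with nominal care (`S0`), no
#' additional care (`S1`), or full standard care (`S2`). The care package
#' scales per-state care costs (1 for standard, `nominal_fraction` for
#' nominal, 0 for none); device rental accrues only when the device is
#' active.
#'
#' @param id Scenario identifier: `"SC"`, `"S0"`, `"S1"` or `"S2"`.
#' @param nominal_fraction Fraction of standard care cost charged per state
#'   under nominal care (default 0.5).
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec("S0")
scenario_spec <- function(id = c("SC", "S0", "S1", "S2"), nominal_fraction = 0.5) {
  id <- match.arg(id)
  if (!is.numeric(nominal_fraction) || nominal_fraction < 0 || nominal_fraction > 1) {
    stop("nominal_fraction must lie in [0, 1]")
  }
  spec <- switch(id,
    SC = list(device_active = FALSE, care_package = "standard"),
    S0 = list(device_active = TRUE,  care_package = "nominal"),
    S1 = list(device_active = TRUE,  care_package = "none"),
    S2 = list(device_active = TRUE,  care_package = "standard"))
  structure(
    list(id = id, device_active = spec$device_active,
         care_package = spec$care_package,
         nominal_fraction = nominal_fraction),
    class = "scenario_spec")
}

#' Device dose regimens
#'
#' A `single_annual` regimen activates the device for the first cycle of
#' each model year (one three-month dose per annum); `continuous` activates
#' every cycle.
#'
#' @param mode `"single_annual"` or `"continuous"`.
#' @param horizon_cycles Number of model cycles.
#' @param cycles_per_year Cycles per year (default 4).
#' @return An object of class `dose_regimen` with 0-based `active_cycles`.
#' @export
#' @examples
#' dose_regimen("single_annual", 20)$active_cycles
dose_regimen <- function(mode = c("single_annual", "continuous"),
                         horizon_cycles, cycles_per_year = 4) {
  mode <- match.arg(mode)
  if (horizon_cycles < 0) stop("horizon_cycles must be >= 0")
  all_cycles <- seq_len(horizon_cycles) - 1L
  active <- switch(mode,
    single_annual = all_cycles[all_cycles %% cycles_per_year == 0L],
    continuous = all_cycles)
  structure(list(mode = mode, active_cycles = active,
                 horizon_cycles = as.integer(horizon_cycles),
                 cycles_per_year = as.integer(cycles_per_year)),
            class = "dose_regimen")
}

#' Assemble a model parameter set
#'
#' Collects every input the pipeline needs: per-cycle care costs and
#' utilities per state, the transition models for standard care and for
#' the device arm, device rental pricing, discount rates, cohort and
#' timing settings. Defaults give the base-case configuration: a cohort of
#' 1000 patients starting in the `Progressive` (symptomatic) state, a
#' three-month cycle, a five-year horizon, 3.5%/year discounting on both
#' costs and effects, and £15/day device rental.
#'
#' @param state_costs Named numeric, care cost (GBP) per cycle per internal
#'   state.
#' @param utilities Named numeric, utility weight per internal state.
#' @param transitions List with components `sc` and `flowox`, each a
#'   [transition_model()]; `sc` drives the standard-care arm and `flowox`
#'   is shared by all device scenarios.
#' @param device_rental_rate Device rental price, GBP per day.
#' @param nominal_fraction Fraction of standard care cost under nominal care.
#' @param discount_rate_cost,discount_rate_effect Annual discount rates.
#' @param cycle_length Cycle length in years (default 0.25).
#' @param horizon_cycles Number of cycles modelled (default 20 = 5 years).
#' @param cohort_size Closed-cohort size (default 1000).
#' @param initial_state State holding the whole cohort at cycle 0.
#' @param age_group Age band used for the utility multiplier.
#' @param provenance Free-text note recording which values are published
#'   point estimates and which are synthetic.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(state_costs = default_state_costs(),
                          utilities = default_state_utilities(),
                          transitions,
                          device_rental_rate = 15,
                          nominal_fraction = 0.5,
                          discount_rate_cost = 0.035,
                          discount_rate_effect = 0.035,
                          cycle_length = 0.25,
                          horizon_cycles = 20L,
                          cohort_size = 1000,
                          initial_state = "Progressive",
                          age_group = "50-59",
                          provenance = "unspecified") {
  states <- pad_states()
  state_costs <- complete_named(state_costs, states, "state_costs")
  utilities <- complete_named(utilities, states, "utilities")
  if (missing(transitions) || is.null(transitions)) {
    stop("transitions must be supplied (list with components 'sc' and 'flowox')")
  }
  if (!all(c("sc", "flowox") %in% names(transitions))) {
    stop("transitions must contain components 'sc' and 'flowox'")
  }
  ps <- structure(
    list(state_costs = state_costs,
         utilities = utilities,
         transitions = transitions,
         device_rental_rate = device_rental_rate,
         nominal_fraction = nominal_fraction,
         discount_rate_cost = discount_rate_cost,
         discount_rate_effect = discount_rate_effect,
         cycle_length = cycle_length,
         horizon_cycles = as.integer(horizon_cycles),
         cohort_size = cohort_size,
         initial_state = initial_state,
         age_group = age_group,
         age_utility_multiplier = age_utility_multiplier(age_group),
         provenance = provenance),
    class = "parameter_set")
  violations <- validate_parameter_set(ps)
  if (length(violations) > 0L) {
    stop("invalid parameter set:\n  - ", paste(violations, collapse = "\n  - "))
  }
  ps
}

complete_named <- function(x, states, what) {
  if (is.null(names(x))) stop(what, " must be a named numeric vector")
  bad <- setdiff(names(x), states)
  if (length(bad) > 0L) stop(what, ": unknown state(s) ", paste(bad, collapse = ", "))
  out <- setNames(numeric(length(states)), states)
  out[names(x)] <- as.numeric(x)
  out
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs and reports the
#' violations as a character vector (empty when valid). Never raises and
#' never mutates the input. Checked: non-negative costs and rental rate;
#' care-cost ordering by severity with zero cost for recovered and dead
#' states; strict utility ordering by severity with `Dead = 0`; discount
#' rates in `[0, 1]`; timing/cohort sanity; and full transition-matrix
#' validation for both scenario families.
#'
#' @param ps A `parameter_set` (or a structurally similar list).
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_parameter_set <- function(ps) {
  v <- character(0)
  costs <- ps$state_costs
  u <- ps$utilities
  if (any(costs < 0)) {
    v <- c(v, paste0("negative care cost for state(s): ",
                     paste(names(costs)[costs < 0], collapse = ", ")))
  }
  if (ps$device_rental_rate < 0) v <- c(v, "device_rental_rate must be >= 0")
  sev <- c("Mild", "Progressive", "Severe", "MinorAmputation", "MajorAmputation")
  if (!all(diff(costs[sev]) > 0)) {
    v <- c(v, "care costs must increase strictly with severity (Mild < Progressive < Severe < MinorAmputation < MajorAmputation)")
  }
  if (costs[["Dead"]] != 0) v <- c(v, "Dead state must carry zero cost")
  if (costs[["RecoveredNoAmp"]] != 0 || costs[["RecoveredPostAmp"]] != 0) {
    v <- c(v, "recovered states carry no PAD treatment cost")
  }
  if (!all(diff(u[sev]) < 0)) {
    v <- c(v, "utilities must decrease strictly with severity (Mild > Progressive > Severe > MinorAmputation > MajorAmputation)")
  }
  if (u[["RecoveredNoAmp"]] >= u[["Mild"]]) {
    v <- c(v, "RecoveredNoAmp utility must be below Mild (residual disability)")
  }
  if (u[["Dead"]] != 0) v <- c(v, "absorbing state must carry zero utility")
  if (any(u > 1)) v <- c(v, "utilities cannot exceed 1")
  for (r in c("discount_rate_cost", "discount_rate_effect")) {
    if (ps[[r]] < 0 || ps[[r]] > 1) v <- c(v, paste0(r, " must lie in [0, 1]"))
  }
  if (ps$cycle_length <= 0) v <- c(v, "cycle_length must be positive")
  if (ps$horizon_cycles < 0) v <- c(v, "horizon_cycles must be >= 0")
  if (ps$cohort_size <= 0) v <- c(v, "cohort_size must be positive")
  if (!ps$initial_state %in% pad_states()) {
    v <- c(v, paste0("unknown initial_state: ", ps$initial_state))
  }
  for (fam in names(ps$transitions)) {
    tm <- ps$transitions[[fam]]
    mv <- validate_matrix(tm$base_matrix)
    if (length(mv) > 0L) v <- c(v, paste0("transitions[", fam, "]: ", mv))
    for (rule in tm$time_varying) {
      if (!rule$state %in% pad_states()) {
        v <- c(v, paste0("transitions[", fam, "]: time-varying rule references unknown state ", rule$state))
      }
    }
  }
  v
}

#' Load a parameter set from a YAML configuration
#'
#' Reads the YAML schema (top-level keys `costs`, `utilities`,
#' `transitions`, `device`, `discounting`, `cohort`, `scenario`, `regimen`,
#' `age_group`, `seed`), applies defaults for omitted optional keys, and
#' returns a validated [parameter_set()]. Money is in GBP; probabilities in
#' `transitions` are per cycle (annual literature rates should be converted
#' with [annual_to_cycle_prob()] before entering the file, or supplied via
#' the `_annual` convenience suffix on row entries).
#'
#' Transition matrices are given as named maps of named maps
#' (`from: {to: p, ...}`); omitted entries are structural zeros and the
#' diagonal may be left implicit (filled so rows sum to one). The device
#' arm may be specified either as a full matrix or as
#' `relative_progression: r`, which scales every progression entry of the
#' standard-care matrix by `r` (see [apply_relative_progression()]).
#'
#' @param config Path to a YAML file, or a YAML string, or an already
#'   parsed list.
#' @return A validated `parameter_set` with `provenance` describing the
#'   source of each block.
#' @export
load_parameter_set <- function(config) {
  doc <- parse_config(config)
  required <- "transitions"
  missing_keys <- setdiff(required, names(doc))
  if (length(missing_keys) > 0L) {
    stop("config missing required key(s): ", paste(missing_keys, collapse = ", "))
  }
  costs <- default_state_costs()
  if (!is.null(doc$costs)) {
    num <- vapply(doc$costs, function(x) {
      if (!is.numeric(x)) stop("malformed number under key 'costs'")
      as.numeric(x)
    }, numeric(1))
    costs[names(num)] <- num
  }
  utilities <- default_state_utilities()
  if (!is.null(doc$utilities)) {
    num <- vapply(doc$utilities, function(x) {
      if (!is.numeric(x)) stop("malformed number under key 'utilities'")
      as.numeric(x)
    }, numeric(1))
    utilities[names(num)] <- num
  }
  device_rate <- doc$device$rental_rate_per_day %||% 15
  disc_cost <- doc$discounting$cost %||% 0.035
  disc_eff <- doc$discounting$effect %||% 0.035
  cohort <- doc$cohort %||% list()
  transitions <- parse_transitions(doc$transitions)
  ps <- parameter_set(
    state_costs = costs,
    utilities = utilities,
    transitions = transitions,
    device_rental_rate = device_rate,
    nominal_fraction = doc$scenario$nominal_fraction %||% 0.5,
    discount_rate_cost = disc_cost,
    discount_rate_effect = disc_eff,
    cycle_length = cohort$cycle_length_years %||% 0.25,
    horizon_cycles = cohort$horizon_cycles %||% 20L,
    cohort_size = cohort$size %||% 1000,
    initial_state = cohort$initial_state %||% "Progressive",
    age_group = doc$age_group %||% "50-59",
    provenance = doc$provenance %||%
      "costs: published point estimates; transitions/utilities: user-supplied")
  ps
}

parse_config <- function(config) {
  if (is.list(config)) return(config)
  if (!is.character(config) || length(config) != 1L) {
    stop("config must be a file path, a YAML string, or a list")
  }
  if (file.exists(config)) yaml::read_yaml(config) else yaml::yaml.load(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_transitions <- function(tr) {
  if (is.null(tr$sc)) stop("config missing required key: transitions.sc")
  sc_tm <- parse_one_transition_model(tr$sc)
  flowox_tm <- if (!is.null(tr$flowox$relative_progression)) {
    rr <- tr$flowox$relative_progression
    transition_model(
      apply_relative_progression(sc_tm$base_matrix, rr),
      time_varying = sc_tm$time_varying)
  } else if (!is.null(tr$flowox)) {
    parse_one_transition_model(tr$flowox)
  } else {
    sc_tm
  }
  list(sc = sc_tm, flowox = flowox_tm)
}

parse_one_transition_model <- function(node) {
  if (is.null(node$matrix)) stop("transition model needs a 'matrix' key")
  M <- rows_to_matrix(node$matrix)
  rules <- lapply(node$time_varying %||% list(), function(rule) {
    list(state = rule$state,
         cycles = seq.int(rule$from_cycle %||% 0L, rule$to_cycle),
         row = unlist(rule$row))
  })
  transition_model(M, time_varying = rules)
}

rows_to_matrix <- function(rows) {
  states <- pad_states()
  M <- matrix(0, length(states), length(states), dimnames = list(states, states))
  for (from in names(rows)) {
    if (!from %in% states) stop("unknown state in transition matrix: ", from)
    row <- rows[[from]]
    for (to in names(row)) {
      p <- row[[to]]
      to_state <- sub("_annual$", "", to)
      if (!to_state %in% states) stop("unknown state in transition matrix: ", to)
      if (!is.numeric(p)) stop("malformed number in transitions row ", from)
      if (endsWith(to, "_annual")) p <- annual_to_cycle_prob(p, 4)
      M[from, to_state] <- M[from, to_state] + p
    }
  }
  # implicit diagonal: remaining mass stays in state
  resid <- 1 - rowSums(M) + diag(M)
  diag(M) <- pmax(resid, 0)
  M["Dead", ] <- 0
  M["Dead", "Dead"] <- 1
  M
}

#' Serialise a parameter set to the YAML configuration schema
#'
#' Inverse of [load_parameter_set()]: writing then re-loading reproduces
#' the parameter set (round-trip stability).
#'
#' @param ps A `parameter_set`.
#' @param path Optional file path; if `NULL` the YAML text is returned.
#' @return The YAML text, invisibly when written to `path`.
#' @export
serialise_parameter_set <- function(ps, path = NULL) {
  matrix_to_rows <- function(M) {
    rows <- lapply(rownames(M), function(from) {
      nz <- M[from, M[from, ] > 0, drop = TRUE]
      as.list(nz)
    })
    names(rows) <- rownames(M)
    rows[vapply(rows, length, 1L) > 0]
  }
  tm_to_list <- function(tm) {
    out <- list(matrix = matrix_to_rows(tm$base_matrix))
    if (length(tm$time_varying) > 0L) {
      out$time_varying <- lapply(tm$time_varying, function(rule) {
        list(state = rule$state,
             from_cycle = min(rule$cycles),
             to_cycle = max(rule$cycles),
             row = as.list(rule$row[rule$row != 0]))
      })
    }
    out
  }
  doc <- list(
    costs = as.list(ps$state_costs),
    utilities = as.list(ps$utilities),
    transitions = list(sc = tm_to_list(ps$transitions$sc),
                       flowox = tm_to_list(ps$transitions$flowox)),
    device = list(rental_rate_per_day = ps$device_rental_rate),
    discounting = list(cost = ps$discount_rate_cost, effect = ps$discount_rate_effect),
    cohort = list(size = ps$cohort_size,
                  initial_state = ps$initial_state,
                  cycle_length_years = ps$cycle_length,
                  horizon_cycles = ps$horizon_cycles),
    scenario = list(nominal_fraction = ps$nominal_fraction),
    age_group = ps$age_group,
    provenance = ps$provenance)
  txt <- yaml::as.yaml(doc, precision = 15)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat("  cohort:", x$cohort_size, "patients starting in", x$initial_state, "\n")
  cat("  horizon:", x$horizon_cycles, "cycles of", x$cycle_length, "years\n")
  cat("  discounting: cost", x$discount_rate_cost, "/yr, effect",
      x$discount_rate_effect, "/yr\n")
  cat("  device rental:", x$device_rental_rate, "GBP/day\n")
  cat("  age group:", x$age_group,
      "(utility multiplier", x$age_utility_multiplier, ")\n")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}
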