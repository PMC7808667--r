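# Markov engine: transition-model construction, matrix validation,
# cohort propagation and aggregation to the reported state space.

#' Construct a transition model
#'
#' A transition model is a base row-stochastic matrix over the eight
#' internal states plus a list of time-varying rules. Each rule replaces
#' one state's outgoing row over a window of cycle indices; the default
#' model uses a single rule that lowers post-major-amputation mortality
#' after the first model year (35%/year in the first year after
#' amputation, 19%/year thereafter). Rules are keyed on time in the model,
#' not time in state — a deliberate approximation, since a true
#' sojourn-time tunnel would require expanded states; a full per-cycle
#' matrix override is available through [build_transition_sequence()]'s
#' `override` argument.
#'
#' @param base_matrix Square numeric matrix with rows and columns named by
#'   [pad_states()]; each row a probability distribution.
#' @param time_varying List of rules, each `list(state =, cycles =, row =)`
#'   with `cycles` a vector of 0-based cycle indices and `row` a named
#'   numeric replacement row (omitted entries are zero).
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(base_matrix, time_varying = list()) {
  states <- pad_states()
  if (!is.matrix(base_matrix) || !identical(dim(base_matrix), c(8L, 8L))) {
    stop("base_matrix must be an 8 x 8 matrix over the internal states")
  }
  if (is.null(rownames(base_matrix))) {
    dimnames(base_matrix) <- list(states, states)
  }
  if (!identical(rownames(base_matrix), states) ||
      !identical(colnames(base_matrix), states)) {
    stop("base_matrix rows/columns must be named by pad_states() in order")
  }
  for (rule in time_varying) {
    if (!is.list(rule) || is.null(rule$state) || is.null(rule$cycles) || is.null(rule$row)) {
      stop("each time-varying rule needs components state, cycles and row")
    }
    if (!rule$state %in% states) {
      stop("time-varying rule references unknown state: ", rule$state)
    }
  }
  structure(list(base_matrix = base_matrix, time_varying = time_varying),
            class = "transition_model")
}

#' Validate a transition matrix
#'
#' Reports (never raises) violations of: row sums equal to one (tolerance
#' 1e-9), entries in `[0, 1]`, `Dead` absorbing (unit row, no entries out),
#' and the structural rules of the state space — `RecoveredPostAmp` can
#' only be entered from an amputation state (or itself), and
#' `RecoveredNoAmp` never from an amputation state.
#'
#' @param M Square numeric matrix; if unnamed, [pad_states()] order is
#'   assumed.
#' @return Character vector of violations; `character(0)` if valid.
#' @export
validate_matrix <- function(M) {
  v <- character(0)
  states <- pad_states()
  if (!is.matrix(M) || nrow(M) != ncol(M)) return("matrix must be square")
  if (is.null(rownames(M)) && nrow(M) == length(states)) {
    dimnames(M) <- list(states, states)
  }
  nm <- rownames(M)
  rs <- rowSums(M)
  bad <- which(abs(rs - 1) > 1e-9)
  for (i in bad) {
    v <- c(v, sprintf("row %s sums to %.6f, expected 1", nm[i], rs[i]))
  }
  if (any(M < 0) || any(M > 1)) {
    ij <- which(M < 0 | M > 1, arr.ind = TRUE)[1, ]
    v <- c(v, sprintf("entry %s -> %s = %.6f outside [0, 1]",
                      nm[ij[1]], nm[ij[2]], M[ij[1], ij[2]]))
  }
  if (all(states %in% nm)) {
    if (M["Dead", "Dead"] != 1 || any(M["Dead", setdiff(states, "Dead")] != 0)) {
      v <- c(v, "Dead must be absorbing (unit row on Dead)")
    }
    allowed_into_recpost <- c("MinorAmputation", "MajorAmputation", "RecoveredPostAmp")
    offenders <- setdiff(nm[M[, "RecoveredPostAmp"] > 0], allowed_into_recpost)
    if (length(offenders) > 0L) {
      v <- c(v, paste0("RecoveredPostAmp may only be entered from amputation states; found entry from ",
                       paste(offenders, collapse = ", ")))
    }
    amp <- c("MinorAmputation", "MajorAmputation")
    if (any(M[amp, "RecoveredNoAmp"] > 0)) {
      v <- c(v, "amputation states cannot transition to RecoveredNoAmp")
    }
  }
  v
}

#' Expand a parameter set into the per-cycle transition matrix sequence
#'
#' Selects the transition family for the scenario (standard care for `SC`,
#' the shared device-arm model otherwise) and materialises one matrix per
#' cycle, applying any time-varying rule whose window covers the cycle.
#' Every emitted matrix is validated.
#'
#' @param ps A validated `parameter_set`.
#' @param scenario A [scenario_spec()] (or scenario id string).
#' @param n_cycles Number of cycles.
#' @param override Optional list of full matrices (one per cycle) taking
#'   precedence over the rule mechanism.
#' @return List of `n_cycles` row-stochastic matrices.
#' @export
build_transition_sequence <- function(ps, scenario, n_cycles, override = NULL) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  if (!is.null(override)) {
    if (length(override) < n_cycles) stop("override must supply one matrix per cycle")
    mats <- override[seq_len(n_cycles)]
  } else {
    family <- if (identical(scenario$id, "SC")) "sc" else "flowox"
    tm <- ps$transitions[[family]]
    mats <- expand_transition_model(tm, n_cycles)
  }
  for (i in seq_along(mats)) {
    viol <- validate_matrix(mats[[i]])
    if (length(viol) > 0L) {
      stop("invalid transition matrix at cycle ", i - 1L, ":\n  - ",
           paste(viol, collapse = "\n  - "))
    }
  }
  mats
}

# Materialise a transition_model over n cycles (0-based cycle indices).
expand_transition_model <- function(tm, n_cycles) {
  if (n_cycles == 0L) return(list())
  states <- pad_states()
  lapply(seq_len(n_cycles) - 1L, function(t) {
    M <- tm$base_matrix
    for (rule in tm$time_varying) {
      if (t %in% rule$cycles) {
        if (!rule$state %in% states) {
          stop("time-varying rule references unknown state: ", rule$state)
        }
        row <- setNames(numeric(length(states)), states)
        row[names(rule$row)] <- rule$row
        M[rule$state, ] <- row
      }
    }
    M
  })
}

#' Propagate a closed cohort through the transition sequence
#'
#' Computes the expected state occupancy `occupancy[t + 1] = occupancy[t] %*%
#' matrices[[t + 1]]` for `t = 0, ..., n_cycles - 1`. The trace conserves
#' the cohort (each row sums to the cohort size) and the absorbing `Dead`
#' column is non-decreasing.
#'
#' @param matrices List of row-stochastic matrices, one per cycle.
#' @param initial Named occupancy vector at cycle 0 (sums to the cohort
#'   size), or a single state name meaning the whole cohort starts there.
#' @param n_cycles Number of cycles to run (default: all supplied
#'   matrices).
#' @param cohort_size Cohort size; default `sum(initial)`.
#' @param cycle_length Cycle length in years (metadata on the trace).
#' @return An object of class `cohort_trace` with an
#'   `(n_cycles + 1) x n_states` `occupancy` matrix.
#' @export
#' @examples
#' p <- annual_to_cycle_prob(0.25, 4)
#' M <- matrix(c(1 - p, p, 0, 1), 2, 2, byrow = TRUE,
#'             dimnames = list(c("Alive", "Dead"), c("Alive", "Dead")))
#' tr <- run_cohort(rep(list(M), 4), c(Alive = 1000, Dead = 0))
#' tr$occupancy["cycle4", "Dead"]  # ~250: the 25%/year anchor
run_cohort <- function(matrices, initial, n_cycles = length(matrices),
                       cohort_size = NULL, cycle_length = 0.25) {
  if (length(matrices) < n_cycles) {
    stop("need at least n_cycles transition matrices (have ",
         length(matrices), ", need ", n_cycles, ")")
  }
  if (is.character(initial)) {
    states <- pad_states()
    if (!initial %in% states) stop("unknown initial state: ", initial)
    init <- setNames(numeric(length(states)), states)
    init[initial] <- if (is.null(cohort_size)) 1000 else cohort_size
    initial <- init
  }
  if (is.null(cohort_size)) cohort_size <- sum(initial)
  if (abs(sum(initial) - cohort_size) > 1e-6) {
    stop("initial occupancy must sum to cohort_size")
  }
  n_states <- length(initial)
  occ <- matrix(0, n_cycles + 1L, n_states,
                dimnames = list(paste0("cycle", 0:n_cycles), names(initial)))
  occ[1L, ] <- initial
  for (t in seq_len(n_cycles)) {
    M <- matrices[[t]]
    if (!identical(dim(M), c(n_states, n_states))) {
      stop("transition matrix at cycle ", t - 1L,
           " does not match the state space (", n_states, " states)")
    }
    occ[t + 1L, ] <- occ[t, , drop = FALSE] %*% M
  }
  structure(list(occupancy = occ, cohort_size = cohort_size,
                 cycle_length = cycle_length, n_cycles = as.integer(n_cycles)),
            class = "cohort_trace")
}

#' Aggregate an internal trace to the reported seven-state space
#'
#' Sums the two recovered sub-states into a single `Recovered` column;
#' every other column is unchanged, so cohort conservation is preserved.
#'
#' @param trace A `cohort_trace` over the internal states.
#' @return A `cohort_trace` over [pad_reported_states()].
#' @export
aggregate_trace <- function(trace) {
  occ <- trace$occupancy
  if (!all(c("RecoveredNoAmp", "RecoveredPostAmp") %in% colnames(occ))) {
    return(trace)
  }
  rep_states <- pad_reported_states()
  out <- matrix(0, nrow(occ), length(rep_states),
                dimnames = list(rownames(occ), rep_states))
  keep <- setdiff(rep_states, "Recovered")
  out[, keep] <- occ[, keep]
  out[, "Recovered"] <- occ[, "RecoveredNoAmp"] + occ[, "RecoveredPostAmp"]
  structure(list(occupancy = out, cohort_size = trace$cohort_size,
                 cycle_length = trace$cycle_length, n_cycles = trace$n_cycles),
            class = "cohort_trace")
}

#' Convert a cohort trace to a data frame
#'
#' One row per cycle with the cycle index and calendar time in years,
#' suitable for CSV export.
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  cycles <- 0:x$n_cycles
  data.frame(cycle = cycles, years = cycles * x$cycle_length,
             as.data.frame(x$occupancy, row.names = FALSE),
             check.names = FALSE)
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace>", x$cohort_size, "patients,", x$n_cycles,
      "cycles of", x$cycle_length, "years\n")
  print(utils::head(round(x$occupancy, 2)))
  if (x$n_cycles > 5) cat("...\n")
  invisible(x)
}

#' Scale progression probabilities by a relative risk
#'
#' Builds the device-arm transition matrix from the standard-care matrix by
#' multiplying every progression entry — a transition to a more severe
#' disease state (`Mild -> Progressive`, `Progressive -> Severe`,
#' `Severe -> MinorAmputation/MajorAmputation`,
#' `MinorAmputation -> MajorAmputation`) — by the relative risk `rr`, and
#' returning the freed probability mass to the diagonal (patients who do
#' not progress remain in their current state). Rows remain stochastic by
#' construction.
#'
#' @param M Standard-care base matrix over [pad_states()].
#' @param rr Relative risk of progression, in `[0, 1]`.
#' @return The scaled matrix.
#' @export
apply_relative_progression <- function(M, rr) {
  if (rr < 0 || rr > 1) stop("relative_progression must lie in [0, 1]")
  prog_edges <- list(
    c("Mild", "Progressive"),
    c("Progressive", "Severe"),
    c("Severe", "MinorAmputation"),
    c("Severe", "MajorAmputation"),
    c("MinorAmputation", "MajorAmputation"))
  out <- M
  for (e in prog_edges) {
    freed <- out[e[1], e[2]] * (1 - rr)
    out[e[1], e[2]] <- out[e[1], e[2]] * rr
    out[e[1], e[1]] <- out[e[1], e[1]] + freed
  }
  out
}
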