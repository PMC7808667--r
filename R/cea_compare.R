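# Incremental cost-effectiveness analysis: deltas, ICER/dominance
# classification, net monetary benefit, scenario grids.

#' Classify an incremental comparison
#'
#' Standard cost-effectiveness plane logic against a fixed comparator:
#' cheaper and more effective is `dominant`; dearer and less effective is
#' `dominated`; both deltas exactly zero is `equivalent`; any other sign
#' combination gets a numeric ICER. A single exact-zero delta with the
#' other nonzero is labelled `ICER` (the ratio degenerates to 0 or a
#' signed infinity) and flagged via the `tie` attribute.
#'
#' @param delta_cost Incremental cost (GBP per patient).
#' @param delta_qalys Incremental effect (QALYs per patient).
#' @return Character label, one of `"dominant"`, `"dominated"`,
#'   `"equivalent"`, `"ICER"`, with attribute `tie` when a delta is
#'   exactly zero.
#' @export
#' @examples
#' classify(-960.23, 0.06)   # cheaper, more effective
#' classify(1314.54, 0.06)   # trade-off: numeric ICER
classify <- function(delta_cost, delta_qalys) {
  if (delta_cost == 0 && delta_qalys == 0) return("equivalent")
  if (delta_cost < 0 && delta_qalys > 0) return("dominant")
  if (delta_cost > 0 && delta_qalys < 0) return("dominated")
  out <- "ICER"
  if (delta_cost == 0 || delta_qalys == 0) attr(out, "tie") <- TRUE
  out
}

#' Incremental comparison of two scenario results
#'
#' Deltas are computed at full internal precision; the ICER
#' `delta_cost / delta_qalys` is reported only when the comparison is a
#' genuine trade-off (label `ICER`), never for dominant or dominated
#' pairs. Swapping result and comparator negates both deltas.
#'
#' @param result,comparator `scenario_result` objects (or lists with
#'   `discounted_cost` and `discounted_qalys`) sharing horizon and
#'   discount settings.
#' @return An object of class `incremental_result`.
#' @export
incremental <- function(result, comparator) {
  for (f in c("horizon_years", "discount_rate_cost", "discount_rate_effect")) {
    if (!is.null(result[[f]]) && !is.null(comparator[[f]]) &&
        !isTRUE(all.equal(result[[f]], comparator[[f]]))) {
      stop("cannot compare results with different ", f)
    }
  }
  dc <- result$discounted_cost - comparator$discounted_cost
  de <- result$discounted_qalys - comparator$discounted_qalys
  label <- classify(dc, de)
  icer <- if (identical(as.character(label), "ICER") && de != 0) dc / de else NA_real_
  if (identical(as.character(label), "ICER") && de == 0) {
    icer <- sign(dc) * Inf
  }
  structure(
    list(scenario_id = result$scenario_id %||% "result",
         comparator_id = comparator$scenario_id %||% "comparator",
         delta_cost = dc, delta_qalys = de,
         icer = icer, label = as.character(label),
         tie = isTRUE(attr(label, "tie"))),
    class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental_result> %s vs %s\n", x$scenario_id, x$comparator_id))
  cat(sprintf("  Δcost %.2f GBP, ΔQALYs %.4f -> %s",
              x$delta_cost, x$delta_qalys, x$label))
  if (x$label == "ICER") cat(sprintf(" (%.2f GBP/QALY)", x$icer))
  cat("\n")
  invisible(x)
}

#' Incremental monetary net benefit
#'
#' `imnb = lambda * delta_qalys - delta_cost`: the money value of the
#' health gained at willingness-to-pay `lambda`, net of the extra cost.
#' Positive values favour the intervention; `imnb` is affine in `lambda`
#' with slope `delta_qalys`.
#'
#' @param lambda Willingness-to-pay threshold, GBP per QALY (>= 0;
#'   vectorised).
#' @param delta_cost,delta_qalys Incremental cost and effect.
#' @return Net benefit in GBP (vectorised over `lambda`).
#' @export
#' @examples
#' imnb(c(20000, 30000), 1314.54, 0.06)
imnb <- function(lambda, delta_cost, delta_qalys) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  lambda * delta_qalys - delta_cost
}

#' Run a grid of scenarios with incremental analysis against standard care
#'
#' Evaluates every combination of scenario, horizon, regimen, effect
#' discount rate and age group, and appends incremental columns versus the
#' `SC` arm of the same combination. `SC` rows carry `NA` incremental
#' cells. Deterministic given the parameter set.
#'
#' @param ps A validated `parameter_set`.
#' @param scenarios Character vector of scenario ids (default all four).
#' @param horizons Horizons in years (default `ps` horizon).
#' @param regimens Regimen modes (default `"single_annual"`).
#' @param effect_discounts Annual effect discount rates (default the
#'   parameter set's rate).
#' @param age_groups Age bands (default the parameter set's band).
#' @return A data frame, one row per combination, with columns `scenario`,
#'   `horizon_years`, `regimen`, `effect_discount`, `age_group`, `cost`,
#'   `qalys`, `delta_cost`, `delta_qalys`, `icer`, `label`.
#' @export
run_scenarios <- function(ps,
                          scenarios = c("S0", "S1", "S2", "SC"),
                          horizons = NULL,
                          regimens = "single_annual",
                          effect_discounts = NULL,
                          age_groups = NULL) {
  if (length(scenarios) == 0L) {
    return(data.frame(scenario = character(), horizon_years = numeric(),
                      regimen = character(), effect_discount = numeric(),
                      age_group = character(), cost = numeric(),
                      qalys = numeric(), delta_cost = numeric(),
                      delta_qalys = numeric(), icer = numeric(),
                      label = character()))
  }
  unknown <- setdiff(scenarios, c("SC", "S0", "S1", "S2"))
  if (length(unknown) > 0L) {
    stop("unknown scenario id(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(horizons)) horizons <- ps$horizon_cycles * ps$cycle_length
  if (is.null(effect_discounts)) effect_discounts <- ps$discount_rate_effect
  if (is.null(age_groups)) age_groups <- ps$age_group
  cycles_per_year <- round(1 / ps$cycle_length)

  rows <- list()
  for (h in horizons) for (reg in regimens) for (ed in effect_discounts) for (ag in age_groups) {
    ps_i <- ps
    ps_i$discount_rate_effect <- ed
    ps_i$age_group <- ag
    ps_i$age_utility_multiplier <- age_utility_multiplier(ag)
    n_cycles <- round(h * cycles_per_year)
    sc_res <- evaluate_scenario(ps_i, "SC", regimen = reg, horizon_cycles = n_cycles)
    for (sid in scenarios) {
      res <- if (sid == "SC") sc_res else {
        evaluate_scenario(ps_i, sid, regimen = reg, horizon_cycles = n_cycles)
      }
      if (sid == "SC") {
        inc <- list(delta_cost = NA_real_, delta_qalys = NA_real_,
                    icer = NA_real_, label = NA_character_)
      } else {
        inc <- incremental(res, sc_res)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sid, horizon_years = h, regimen = reg,
        effect_discount = ed, age_group = ag,
        cost = res$discounted_cost, qalys = res$discounted_qalys,
        delta_cost = inc$delta_cost, delta_qalys = inc$delta_qalys,
        icer = inc$icer, label = inc$label,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
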