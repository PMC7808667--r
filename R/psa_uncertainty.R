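# Probabilistic sensitivity analysis: parameter distributions, Monte-Carlo
# propagation, CE plane, CEAC, net-benefit intervals.

#' Specify the PSA sampling scheme
#'
#' Distribution families follow standard health-technology-assessment
#' practice: gamma for costs (mean at the base case, dispersion given as a
#' coefficient of variation), beta for per-cycle transition probabilities
#' (mean at the base case, dispersion given as an effective sample size),
#' and a rescaled beta on the interval `[utility_lower, 1]` for utilities,
#' which may be negative (worse than dead). Setting `cost_cv = 0` and the
#' effective sample sizes to `Inf` makes every distribution degenerate at
#' the base case.
#'
#' @param n_draws Number of Monte-Carlo draws (default 1000).
#' @param cost_cv Coefficient of variation for care costs (default 0.2).
#' @param prob_ess Effective sample size for probability draws (default
#'   100).
#' @param utility_ess Effective sample size for utility draws (default
#'   100).
#' @param utility_lower Lower bound of the utility support (default
#'   -0.594, the floor of the EQ-5D index scale).
#' @param seed Integer seed controlling all PSA randomness.
#' @param max_retries Rejection budget for re-drawing blocks that violate
#'   ordering constraints (default 100).
#' @return An object of class `psa_spec`.
#' @export
psa_spec <- function(n_draws = 1000L, cost_cv = 0.2, prob_ess = 100,
                     utility_ess = 100, utility_lower = -0.594,
                     seed = 1L, max_retries = 100L) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (cost_cv < 0) stop("cost_cv must be >= 0")
  if (prob_ess <= 0 || utility_ess <= 0) stop("effective sample sizes must be positive")
  if (utility_lower >= 1) stop("utility_lower must be below 1")
  structure(list(n_draws = as.integer(n_draws), cost_cv = cost_cv,
                 prob_ess = prob_ess, utility_ess = utility_ess,
                 utility_lower = utility_lower, seed = as.integer(seed),
                 max_retries = as.integer(max_retries)),
            class = "psa_spec")
}

draw_gamma_mean_cv <- function(mean, cv) {
  if (cv == 0 || mean == 0) return(mean)
  shape <- 1 / cv^2
  rgamma(length(mean), shape = shape, rate = shape / mean)
}

draw_beta_mean_ess <- function(p, ess) {
  if (is.infinite(ess)) return(p)
  out <- p
  inner <- p > 0 & p < 1  # degenerate at the bounds
  out[inner] <- rbeta(sum(inner), p[inner] * ess, (1 - p[inner]) * ess)
  out
}

draw_row <- function(row, state, ess) {
  others <- setdiff(names(row), state)
  nz <- others[row[others] > 0]
  if (length(nz) == 0L || is.infinite(ess)) return(row)
  row[nz] <- draw_beta_mean_ess(row[nz], ess)
  # keep the base relative stay mass, then renormalise the full row
  row[state] <- max(row[state], 0)
  row / sum(row)
}

draw_transition_model <- function(tm, ess) {
  if (is.infinite(ess)) return(tm)
  M <- tm$base_matrix
  for (s in setdiff(rownames(M), "Dead")) {
    M[s, ] <- draw_row(M[s, ], s, ess)
  }
  rules <- lapply(tm$time_varying, function(rule) {
    full <- setNames(numeric(ncol(M)), colnames(M))
    full[names(rule$row)] <- rule$row
    full <- draw_row(full, rule$state, ess)
    rule$row <- full[full != 0]
    rule
  })
  transition_model(M, time_varying = rules)
}

#' Draw one parameter set from the PSA distributions
#'
#' Returns a new parameter set with care costs, utilities and transition
#' rows resampled around the base case. Ordering constraints (costs and
#' utilities strictly monotone in severity) are enforced by rejection:
#' the violating block is redrawn up to `spec$max_retries` times. Draws
#' are taken from R's current random stream — seed it (or use
#' [run_psa()], which seeds from `spec$seed`) for reproducibility.
#'
#' @param ps Base-case `parameter_set`.
#' @param spec A [psa_spec()].
#' @return A validated `parameter_set`.
#' @export
draw_parameters <- function(ps, spec) {
  sev <- c("Mild", "Progressive", "Severe", "MinorAmputation", "MajorAmputation")

  costs <- ps$state_costs
  for (i in seq_len(spec$max_retries)) {
    cand <- costs
    cand[sev] <- vapply(costs[sev], draw_gamma_mean_cv, numeric(1), cv = spec$cost_cv)
    if (all(diff(cand[sev]) > 0)) { costs <- cand; break }
    if (i == spec$max_retries) {
      stop("PSA cost draw failed the severity-ordering constraint after ",
           spec$max_retries, " retries")
    }
  }

  lb <- spec$utility_lower
  u <- ps$utilities
  draw_u <- function(base) {
    y <- (base - lb) / (1 - lb)
    lb + (1 - lb) * draw_beta_mean_ess(y, spec$utility_ess)
  }
  for (i in seq_len(spec$max_retries)) {
    cand <- u
    for (s in setdiff(names(u), "Dead")) cand[s] <- draw_u(u[s])
    ok <- all(diff(cand[sev]) < 0) && cand["RecoveredNoAmp"] < cand["Mild"]
    if (ok) { u <- cand; break }
    if (i == spec$max_retries) {
      stop("PSA utility draw failed the severity-ordering constraint after ",
           spec$max_retries, " retries")
    }
  }

  transitions <- lapply(ps$transitions, draw_transition_model, ess = spec$prob_ess)

  out <- ps
  out$state_costs <- costs
  out$utilities <- u
  out$transitions <- transitions
  viol <- validate_parameter_set(out)
  if (length(viol) > 0L) {
    stop("PSA draw produced an invalid parameter set:\n  - ",
         paste(viol, collapse = "\n  - "))
  }
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `spec$n_draws` parameter sets, reruns the full pipeline for
#' standard care and each requested scenario under every draw, and stores
#' the per-draw incremental cost and QALYs versus standard care. All
#' randomness is seeded from `spec$seed`, so identical specs reproduce the
#' result exactly.
#'
#' @param ps Base-case `parameter_set`.
#' @param spec A [psa_spec()].
#' @param scenarios Device scenarios to compare against `SC` (default
#'   `"S0"`).
#' @param horizon_cycles Horizon override (default from `ps`).
#' @param regimen Dose regimen mode (default `"single_annual"`).
#' @return An object of class `psa_result` with a `draws` data frame
#'   (`draw`, `scenario`, `cost`, `qalys`, `delta_cost`, `delta_qalys`)
#'   and the deterministic base-case incrementals.
#' @export
run_psa <- function(ps, spec, scenarios = "S0", horizon_cycles = NULL,
                    regimen = "single_annual") {
  scenarios <- setdiff(scenarios, "SC")
  if (length(scenarios) == 0L) stop("need at least one non-SC scenario")
  set.seed(spec$seed)
  n_cycles <- if (is.null(horizon_cycles)) ps$horizon_cycles else as.integer(horizon_cycles)

  base_rows <- lapply(scenarios, function(sid) {
    inc <- incremental(evaluate_scenario(ps, sid, regimen, n_cycles),
                       evaluate_scenario(ps, "SC", regimen, n_cycles))
    data.frame(scenario = sid, delta_cost = inc$delta_cost,
               delta_qalys = inc$delta_qalys, stringsAsFactors = FALSE)
  })

  rows <- vector("list", spec$n_draws * length(scenarios))
  k <- 0L
  for (d in seq_len(spec$n_draws)) {
    ps_d <- tryCatch(draw_parameters(ps, spec),
                     error = function(e) stop("PSA draw ", d, ": ", conditionMessage(e)))
    sc_res <- evaluate_scenario(ps_d, "SC", regimen, n_cycles)
    for (sid in scenarios) {
      res <- evaluate_scenario(ps_d, sid, regimen, n_cycles)
      k <- k + 1L
      rows[[k]] <- data.frame(
        draw = d, scenario = sid,
        cost = res$discounted_cost, qalys = res$discounted_qalys,
        sc_cost = sc_res$discounted_cost, sc_qalys = sc_res$discounted_qalys,
        delta_cost = res$discounted_cost - sc_res$discounted_cost,
        delta_qalys = res$discounted_qalys - sc_res$discounted_qalys,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(draws = do.call(rbind, rows),
                 base = do.call(rbind, base_rows),
                 spec = spec, scenarios = scenarios,
                 horizon_years = n_cycles * ps$cycle_length,
                 regimen = regimen),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$spec$n_draws, "draws,",
      paste(x$scenarios, collapse = "/"), "vs SC over",
      x$horizon_years, "years\n")
  agg <- aggregate(cbind(delta_cost, delta_qalys) ~ scenario, x$draws, mean)
  print(agg)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability of
#' cost-effectiveness is the fraction of PSA draws with positive
#' incremental monetary net benefit. At `lambda = 0` this is the fraction
#' of cost-saving draws; as `lambda` grows it tends to the fraction of
#' draws with a QALY gain.
#'
#' @param psa A `psa_result`.
#' @param lambdas Numeric vector of thresholds (GBP/QALY).
#' @param scenario Scenario to summarise (default: all in the result).
#' @return Data frame with `scenario`, `lambda`, `probability`.
#' @export
ceac <- function(psa, lambdas = seq(0, 50000, by = 500), scenario = NULL) {
  draws <- psa$draws
  if (!is.null(scenario)) draws <- draws[draws$scenario %in% scenario, ]
  if (nrow(draws) == 0L) stop("no PSA draws to summarise")
  out <- lapply(unique(draws$scenario), function(sid) {
    d <- draws[draws$scenario == sid, ]
    prob <- vapply(lambdas, function(l) {
      mean(imnb(l, d$delta_cost, d$delta_qalys) > 0)
    }, numeric(1))
    data.frame(scenario = sid, lambda = lambdas, probability = prob,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bootstrap confidence interval for a CEAC probability
#'
#' Percentile bootstrap over the PSA draws of the probability of positive
#' incremental net benefit at one threshold. Degenerates to `[0, 0]` or
#' `[1, 1]` when no or every resample is cost-effective.
#'
#' @param psa A `psa_result`.
#' @param lambda Single threshold (GBP/QALY).
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param scenario Scenario id (default: the first in the result).
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(lower, upper)` with attribute `probability`.
#' @export
ceac_ci <- function(psa, lambda, n_boot = 1000L, scenario = NULL, level = 0.95) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  sid <- scenario %||% psa$scenarios[1]
  d <- psa$draws[psa$draws$scenario == sid, ]
  if (nrow(d) == 0L) stop("no PSA draws for scenario ", sid)
  acc <- imnb(lambda, d$delta_cost, d$delta_qalys) > 0
  n <- length(acc)
  boots <- vapply(seq_len(n_boot), function(b) {
    mean(acc[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- unname(quantile(boots, c(alpha, 1 - alpha), names = FALSE))
  structure(c(lower = ci[1], upper = ci[2]), probability = mean(acc))
}

#' Bootstrap-free interval for incremental monetary net benefit
#'
#' Percentile interval of the per-draw IMNB distribution at each
#' threshold.
#'
#' @param psa A `psa_result`.
#' @param lambdas Thresholds (GBP/QALY).
#' @param scenario Scenario id (default: the first in the result).
#' @param level Confidence level (default 0.95).
#' @return Data frame with `lambda`, `mean_imnb`, `lower`, `upper`.
#' @export
imnb_ci <- function(psa, lambdas, scenario = NULL, level = 0.95) {
  sid <- scenario %||% psa$scenarios[1]
  d <- psa$draws[psa$draws$scenario == sid, ]
  alpha <- (1 - level) / 2
  rows <- lapply(lambdas, function(l) {
    v <- imnb(l, d$delta_cost, d$delta_qalys)
    q <- quantile(v, c(alpha, 1 - alpha), names = FALSE)
    data.frame(lambda = l, mean_imnb = mean(v), lower = q[1], upper = q[2])
  })
  do.call(rbind, rows)
}

#' Cost-effectiveness plane points with quadrant labels
#'
#' Labels each PSA draw by the signs of (incremental QALYs, incremental
#' cost): `NE` dearer/more effective, `SE` cheaper/more effective
#' (dominant), `NW` dearer/less effective (dominated), `SW` cheaper/less
#' effective. A draw exactly at the origin is labelled `origin` and
#' flagged.
#'
#' @param psa A `psa_result`.
#' @return The draws data frame with added `quadrant` and `flagged`
#'   columns.
#' @export
ce_plane <- function(psa) {
  d <- psa$draws
  quadrant <- ifelse(d$delta_qalys > 0,
                     ifelse(d$delta_cost > 0, "NE", "SE"),
                     ifelse(d$delta_cost > 0, "NW", "SW"))
  on_axis <- d$delta_qalys == 0 | d$delta_cost == 0
  quadrant[d$delta_qalys == 0 & d$delta_cost == 0] <- "origin"
  d$quadrant <- quadrant
  d$flagged <- on_axis
  d
}

#' Plot the cost-effectiveness plane
#'
#' @param psa A `psa_result`.
#' @param lambda Optional threshold; when given, the line
#'   `delta_cost = lambda * delta_qalys` is drawn.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, lambda = NULL) {
  d <- ce_plane(psa)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = delta_qalys, y = delta_cost,
                                       colour = scenario)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)",
                  title = "Cost-effectiveness plane vs standard care") +
    ggplot2::theme_minimal()
  if (!is.null(lambda)) {
    p <- p + ggplot2::geom_abline(slope = lambda, intercept = 0, linetype = 2)
  }
  p
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param curve Output of [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = lambda, y = probability,
                                      colour = scenario)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}
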