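#' Assemble and validate a simulation scenario
#'
#' A scenario bundles everything a lifecycle simulation needs: the
#' Cobb-Douglas elasticities of the financial and physical domains, the
#' physical decay/investment parameters, span functions, economy, the
#' financial-index map, initial state and horizon. All component invariants
#' are enforced here, including the cross-field span-shape checks
#' (`H <= T`, `h' > g' >= 0` above the threshold) that no single parameter
#' can guarantee alone.
#'
#' @param elasticities Named numeric vector `c(F = , P = )` passed to
#'   [validate_elasticities()].
#' @param physical An [physical_params()] object.
#' @param spans An [span_params()] object.
#' @param economy An [economy_params()] object.
#' @param fin_index An [financial_index_params()] object.
#' @param initial_P Initial physical index in `[0, 1]`.
#' @param initial_OF Initial objective wealth, currency >= 0.
#' @param initial_SF Subjective financial index in `[0, 1]`, held constant
#'   over the simulation (the model gives it no dynamics).
#' @param start_age First simulated age, periods (years).
#' @param horizon Number of periods to simulate, >= 1.
#' @param name Optional scenario label.
#' @param static_oracle Optional list describing a static allocation
#'   problem (`R`, `theta`, `slopes`, `levels`, `delta`) carried by oracle
#'   fixtures; not used by the simulator.
#' @return A list with class `"iwb_scenario"`.
#' @export
scenario <- function(elasticities, physical, spans, economy, fin_index,
                     initial_P, initial_OF, initial_SF = 0.7,
                     start_age = 25, horizon = 60, name = NULL,
                     static_oracle = NULL) {
  elasticities <- validate_elasticities(elasticities)
  stopifnot(inherits(physical, "iwb_physical_params"),
            inherits(spans, "iwb_span_params"),
            inherits(economy, "iwb_economy_params"),
            inherits(fin_index, "iwb_fin_params"))
  if (length(elasticities) != 2L ||
      !identical(names(unclass(elasticities)), c("F", "P"))) {
    stop("invalid scenario: elasticities must be named c(F = , P = )",
         call. = FALSE)
  }
  if (!is.numeric(initial_P) || initial_P < 0 || initial_P > 1) {
    stop("invalid scenario: initial_P must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(initial_OF) || initial_OF < 0) {
    stop("invalid scenario: initial_OF must be >= 0 (no-borrowing)",
         call. = FALSE)
  }
  if (!is.numeric(initial_SF) || initial_SF < 0 || initial_SF > 1) {
    stop("invalid scenario: initial_SF must lie in [0, 1]", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) {
    stop("invalid scenario: horizon must be >= 1", call. = FALSE)
  }
  validate_spans(spans, physical$P_bar_H)
  structure(list(name = name, elasticities = elasticities,
                 physical = physical, spans = spans, economy = economy,
                 fin_index = fin_index, initial_P = initial_P,
                 initial_OF = initial_OF, initial_SF = initial_SF,
                 start_age = start_age, horizon = horizon,
                 static_oracle = static_oracle),
            class = "iwb_scenario")
}

#' Allocation policies
#'
#' A policy maps the per-period state to requested health spending; the
#' simulator clips requests to the available budget (with a warning) so
#' every emitted allocation is feasible. `policy_constant_fraction(phi)`
#' spends the fraction `phi` of available resources on health each period;
#' `policy_fixed_amount(amount)` requests a constant currency amount;
#' `policy_zero_spend()` never spends on health.
#'
#' @param phi Health-spend fraction in `[0, 1]`.
#' @param amount Requested health spending per period, currency >= 0.
#' @return A policy object of class `"iwb_policy"`.
#' @export
policy_constant_fraction <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1L || phi < 0 || phi > 1) {
    stop("phi must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = sprintf("constant_fraction(phi=%g)", phi),
                 request = function(state, age) phi * state$available),
            class = "iwb_policy")
}

#' @rdname policy_constant_fraction
#' @export
policy_fixed_amount <- function(amount) {
  if (!is.numeric(amount) || length(amount) != 1L || amount < 0) {
    stop("amount must be >= 0", call. = FALSE)
  }
  structure(list(name = sprintf("fixed_amount(%g)", amount),
                 request = function(state, age) amount),
            class = "iwb_policy")
}

#' @rdname policy_constant_fraction
#' @export
policy_zero_spend <- function() {
  p <- policy_fixed_amount(0)
  p$name <- "zero_spend"
  p
}

#' Simulate a full lifecycle trajectory
#'
#' Runs the coupled physical-financial system forward one period (year) at
#' a time. Within each period, in order: the age-dependent decay rate is
#' evaluated; labour income and interest are earned on the previous
#' period's state (income only while the previous health span was open);
#' the policy's requested health spending is clipped to the available
#' budget; physical wellbeing decays and absorbs the investment; spans,
#' wealth, the financial index and integrated wellbeing are updated. The
#' subjective financial index is held constant.
#'
#' @param scn An [scenario()] object.
#' @param policy An allocation policy (see [policy_constant_fraction()]).
#'   Default: zero health spending.
#' @param stop_at_lifespan If `TRUE`, stop early once the remaining-lifespan
#'   estimate `g(P)` falls below one period; default simulates the fixed
#'   horizon.
#' @param quiet Suppress the policy-clipping warning.
#' @return A data frame of class `"iwb_trajectory"` with one row per
#'   simulated period and columns `age, P, alpha, H, T, Y, r, OF, SF, F,
#'   IW, C_OF, I_OF`; the generating scenario and policy name are attached
#'   as attributes.
#' @examples
#' scn <- baseline_scenarios()[["steady-midlife"]]
#' traj <- simulate_lifecycle(scn, policy_constant_fraction(0.05))
#' trajectory_summary(traj)
#' @export
simulate_lifecycle <- function(scn, policy = policy_zero_spend(),
                               stop_at_lifespan = FALSE, quiet = FALSE) {
  stopifnot(inherits(scn, "iwb_scenario"), inherits(policy, "iwb_policy"))
  n <- scn$horizon
  r_path <- rep_len(scn$economy$r_path, n)
  theta <- scn$elasticities
  SF <- scn$initial_SF

  P_prev <- scn$initial_P
  OF_prev <- scn$initial_OF
  H_prev <- health_span(P_prev, scn$spans, scn$physical$P_bar_H)

  out <- vector("list", n)
  clipped <- 0L
  for (k in seq_len(n)) {
    age <- scn$start_age + k - 1
    alpha <- decay_rate(age, scn$physical)
    r <- r_path[k]
    Y <- labour_income(P_prev, scn$economy, H_prev)
    GR <- Y + r * OF_prev
    available <- OF_prev + GR

    C_req <- policy$request(list(P = P_prev, OF = OF_prev, H = H_prev,
                                 available = available), age)
    C_OF <- min(max(C_req, 0), available)
    if (C_req > available) clipped <- clipped + 1L
    I_OF <- available - C_OF

    P <- step_physical(P_prev, C_OF, age, scn$physical)
    H <- health_span(P, scn$spans, scn$physical$P_bar_H)
    Tt <- lifespan(P, scn$spans)
    OF <- step_wealth(OF_prev, r, Y, C_OF, H_prev > 0)
    Ft <- financial_index(OF, SF, scn$fin_index)
    IW <- integrated_wellbeing(c(F = Ft, P = P), theta)

    out[[k]] <- c(age = age, P = P, alpha = alpha, H = H, T = Tt, Y = Y,
                  r = r, OF = OF, SF = SF, F = Ft, IW = IW, C_OF = C_OF,
                  I_OF = I_OF)
    P_prev <- P; OF_prev <- OF; H_prev <- H
    if (stop_at_lifespan && Tt < 1) {
      out <- out[seq_len(k)]
      break
    }
  }
  if (clipped > 0L && !quiet) {
    warning("policy request clipped to the available budget in ", clipped,
            " period(s)", call. = FALSE)
  }
  traj <- as.data.frame(do.call(rbind, out))
  attr(traj, "scenario") <- scn
  attr(traj, "policy") <- policy$name
  class(traj) <- c("iwb_trajectory", "data.frame")
  traj
}

#' Summarise a trajectory
#'
#' @param traj An `iwb_trajectory` from [simulate_lifecycle()].
#' @return A list: `years_in_healthspan` (periods with `H > 0`),
#'   `terminal_OF`, `terminal_F`, `mean_IW`, `min_IW`.
#' @export
trajectory_summary <- function(traj) {
  stopifnot(inherits(traj, "iwb_trajectory"))
  if (nrow(traj) == 0L) stop("empty trajectory", call. = FALSE)
  n <- nrow(traj)
  list(years_in_healthspan = sum(traj$H > 0),
       terminal_OF = traj$OF[n],
       terminal_F = traj$F[n],
       mean_IW = mean(traj$IW),
       min_IW = min(traj$IW))
}

#' @export
print.iwb_trajectory <- function(x, ...) {
  scn <- attr(x, "scenario")
  cat("<iwb_trajectory> ", nrow(x), " periods",
      if (!is.null(scn$name)) paste0(", scenario '", scn$name, "'"),
      ", policy ", attr(x, "policy"), "\n", sep = "")
  s <- trajectory_summary(x)
  cat(sprintf("  years in health span: %d | terminal OF: %.2f | mean IW: %.4f\n",
              s$years_in_healthspan, s$terminal_OF, s$mean_IW))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ... ", nrow(x) - 5, " more periods\n", sep = "")
  invisible(x)
}
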