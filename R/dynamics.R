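#' Physical-wellbeing parameters
#'
#' Parameters governing physical decay, the health-span threshold, and the
#' health-investment response. The per-period decay rate follows a bounded
#' logistic in age, rising from `alpha_min` (early adulthood) to `alpha_max`
#' (late-life accelerated ageing) with transition speed `tau` and inflexion
#' age `t0`.
#'
#' @param alpha_min Lowest natural decay rate per period, in (0, 1).
#' @param alpha_max Highest natural decay rate per period, in (0, 1); must
#'   exceed `alpha_min`.
#' @param tau Transition speed, 1/period; > 0.
#' @param t0 Inflexion age (period at which decay accelerates fastest).
#' @param P_bar_H Health-span threshold on the physical index, in (0, 1):
#'   at or below it the remaining health span is zero and labour income
#'   stops.
#' @param kappa Maximum per-period wellbeing gain from health spending
#'   (index units); > 0.
#' @param c0 Spending scale (currency) at which the investment response has
#'   decayed by `1/e`; > 0.
#' @return A list with class `"iwb_physical_params"`.
#' @export
physical_params <- function(alpha_min, alpha_max, tau, t0, P_bar_H,
                            kappa, c0) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("invalid physical params: ", nm, " must be a finite number",
           call. = FALSE)
    }
    x
  }
  for (nm in c("alpha_min", "alpha_max", "tau", "t0", "P_bar_H", "kappa",
               "c0")) num1(get(nm), nm)
  if (!(0 < alpha_min && alpha_min < alpha_max && alpha_max < 1)) {
    stop("invalid physical params: decay bounds must satisfy ",
         "0 < alpha_min < alpha_max < 1 (got alpha_min = ", alpha_min,
         ", alpha_max = ", alpha_max, ")", call. = FALSE)
  }
  if (tau <= 0) stop("invalid physical params: tau must be > 0", call. = FALSE)
  if (kappa <= 0) stop("invalid physical params: kappa must be > 0",
                       call. = FALSE)
  if (c0 <= 0) stop("invalid physical params: c0 must be > 0", call. = FALSE)
  if (P_bar_H <= 0 || P_bar_H >= 1) {
    stop("invalid physical params: P_bar_H must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max, tau = tau,
                 t0 = t0, P_bar_H = P_bar_H, kappa = kappa, c0 = c0),
            class = "iwb_physical_params")
}

#' Health-span and lifespan parameters
#'
#' Parameterises the two span functions of the physical index:
#' health span `H = H_max * ((P - P_bar_H)/(1 - P_bar_H))^a` above the
#' threshold (0 at or below it) and lifespan
#' `T = T_min + (T_max - T_min) * P^b`. The model requires `H <= T`
#' everywhere and `h'(P) > g'(P) >= 0` on the supra-threshold interval:
#' physical wellbeing moves health span harder than lifespan. Both are
#' checked numerically on a grid when a scenario is assembled, since they
#' constrain parameter combinations, not single fields.
#'
#' @param H_max Health span at perfect physical wellbeing, periods.
#' @param a Curvature of the health-span response, >= 1.
#' @param T_min Lifespan floor at `P = 0`, periods, >= 0.
#' @param T_max Lifespan at `P = 1`, periods; must be >= `H_max`.
#' @param b Curvature of the lifespan response, > 0.
#' @return A list with class `"iwb_span_params"`.
#' @export
span_params <- function(H_max, a, T_min, T_max, b) {
  vals <- c(H_max = H_max, a = a, T_min = T_min, T_max = T_max, b = b)
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    stop("invalid span params: all fields must be finite numbers",
         call. = FALSE)
  }
  if (T_min < 0) stop("invalid span params: T_min must be >= 0", call. = FALSE)
  if (H_max <= 0) stop("invalid span params: H_max must be > 0", call. = FALSE)
  if (H_max > T_max) {
    stop("invalid span params: H_max must be <= T_max (health span cannot ",
         "exceed lifespan)", call. = FALSE)
  }
  if (a < 1) stop("invalid span params: curvature a must be >= 1",
                  call. = FALSE)
  if (b <= 0) stop("invalid span params: curvature b must be > 0",
                   call. = FALSE)
  if (T_max < T_min) stop("invalid span params: T_max must be >= T_min",
                          call. = FALSE)
  structure(as.list(vals), class = "iwb_span_params")
}

#' Economy parameters
#'
#' Labour income is `Y(P) = y_max * P^eta` while the health span is open,
#' and zero otherwise; `eta < 1` gives the concave (diminishing-returns)
#' income response the required-return convexity result relies on. The
#' interest-rate path is exogenous; a scalar is recycled over the horizon.
#'
#' @param y_max Labour income at `P = 1`, currency/period, >= 0.
#' @param eta Income curvature, > 0.
#' @param r_path Per-period interest rate(s); scalar or vector, recycled.
#' @return A list with class `"iwb_economy_params"`.
#' @export
economy_params <- function(y_max, eta, r_path = 0.03) {
  if (!is.numeric(y_max) || length(y_max) != 1L || !is.finite(y_max) ||
      y_max < 0) {
    stop("invalid economy params: y_max must be a finite number >= 0",
         call. = FALSE)
  }
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0) {
    stop("invalid economy params: eta must be > 0", call. = FALSE)
  }
  if (!is.numeric(r_path) || length(r_path) < 1L || any(!is.finite(r_path))) {
    stop("invalid economy params: r_path must be finite numeric",
         call. = FALSE)
  }
  structure(list(y_max = y_max, eta = eta, r_path = r_path),
            class = "iwb_economy_params")
}

#' Per-period allocation of financial resources
#'
#' Splits the resources available in a period between health spending
#' `C_OF` and retained financial investment `I_OF`. Both components are
#' nonnegative; feasibility against the budget is checked separately by
#' [budget_feasible()].
#'
#' @param C_OF Health spending, currency, >= 0.
#' @param I_OF Financial investment (retained wealth), currency, >= 0.
#' @return A list with class `"iwb_allocation"`.
#' @export
allocation <- function(C_OF, I_OF = 0) {
  if (!is.numeric(C_OF) || !is.numeric(I_OF) || length(C_OF) != 1L ||
      length(I_OF) != 1L || !is.finite(C_OF) || !is.finite(I_OF) ||
      C_OF < 0 || I_OF < 0) {
    stop("invalid allocation: C_OF and I_OF must be finite and >= 0",
         call. = FALSE)
  }
  structure(list(C_OF = C_OF, I_OF = I_OF), class = "iwb_allocation")
}

#' Age-dependent physical decay rate
#'
#' Bounded logistic transition
#' `alpha(t) = alpha_min + (alpha_max - alpha_min) / (1 + exp(-tau*(t - t0)))`.
#' Strictly increasing in age, with asymptotes at the two bounds and the
#' midpoint value at the inflexion age `t0`.
#'
#' @param t Age (period); vectorised.
#' @param params An [physical_params()] object.
#' @return Decay rate(s) strictly inside `(alpha_min, alpha_max)`.
#' @export
decay_rate <- function(t, params) {
  stopifnot(inherits(params, "iwb_physical_params"))
  params$alpha_min + (params$alpha_max - params$alpha_min) /
    (1 + exp(-params$tau * (t - params$t0)))
}

#' Wellbeing gain from health spending
#'
#' Concave, saturating investment response
#' `I_P(C) = kappa * (1 - exp(-C / c0))`: zero at zero spending, strictly
#' increasing, strictly concave, bounded above by `kappa`.
#'
#' @param C Health spending, currency, >= 0; vectorised.
#' @param params An [physical_params()] object.
#' @return Physical-index increment(s) in `[0, kappa)`.
#' @export
physical_investment <- function(C, params) {
  stopifnot(inherits(params, "iwb_physical_params"))
  if (any(!is.finite(C)) || any(C < 0)) {
    stop("invalid allocation: health spending C must be >= 0", call. = FALSE)
  }
  params$kappa * (1 - exp(-C / params$c0))
}

#' One-period update of physical wellbeing
#'
#' `P' = min(1, max(0, (1 - alpha(t)) * P + I_P(C)))`. The upper cap is the
#' model's unit bound on the index; the zero floor keeps the state in its
#' declared type (decay alone cannot undershoot, but a floor makes the
#' invariant unconditional).
#'
#' @param P Current physical index in `[0, 1]`.
#' @param C Health spending this period, currency >= 0.
#' @param t Current age (period), used to evaluate the decay rate.
#' @param params An [physical_params()] object.
#' @return Next-period physical index in `[0, 1]`.
#' @export
step_physical <- function(P, C, t, params) {
  stopifnot(inherits(params, "iwb_physical_params"))
  if (any(P < 0) || any(P > 1) || any(!is.finite(P))) {
    stop("physical index P must lie in [0, 1]", call. = FALSE)
  }
  a <- decay_rate(t, params)
  pmin(1, pmax(0, (1 - a) * P + physical_investment(C, params)))
}

#' One-period update of a generic wellbeing domain
#'
#' The n-domain progress rule `x' = min(1, (1 - delta) * x + I(C))` with a
#' constant decay rate `delta` and a caller-supplied investment function.
#'
#' @param x Current domain index in `[0, 1]`.
#' @param C Spending on the domain, currency >= 0.
#' @param delta Constant per-period decay rate in `[0, 1]`.
#' @param invest Function mapping spending to an index increment
#'   (increasing, concave, `invest(0) = 0`).
#' @return Next-period domain index in `[0, 1]`.
#' @export
step_domain <- function(x, C, delta, invest) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta < 0 || delta > 1) {
    stop("invalid scenario: decay rate delta must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(x < 0) || any(x > 1)) stop("domain index must lie in [0, 1]",
                                     call. = FALSE)
  if (any(C < 0)) stop("invalid allocation: spending must be >= 0",
                       call. = FALSE)
  pmin(1, pmax(0, (1 - delta) * x + invest(C)))
}

#' Remaining health span
#'
#' `H(P) = H_max * ((P - P_bar_H)/(1 - P_bar_H))^a` above the threshold,
#' and exactly 0 for `P <= P_bar_H`: the regime in which labour income can
#' no longer be earned. Continuous and strictly increasing above the
#' threshold.
#'
#' @param P Physical index in `[0, 1]`; vectorised.
#' @param spans An [span_params()] object.
#' @param P_bar_H Health-span threshold in (0, 1).
#' @return Remaining productive years, >= 0.
#' @export
health_span <- function(P, spans, P_bar_H) {
  stopifnot(inherits(spans, "iwb_span_params"))
  if (any(P < 0) || any(P > 1)) stop("physical index P must lie in [0, 1]",
                                     call. = FALSE)
  u <- pmax(0, (P - P_bar_H) / (1 - P_bar_H))
  spans$H_max * u^spans$a
}

#' Remaining lifespan
#'
#' `T(P) = T_min + (T_max - T_min) * P^b`: weakly increasing in physical
#' wellbeing, never below the health span for a validly parameterised
#' scenario (enforced numerically at scenario assembly).
#'
#' @inheritParams health_span
#' @return Remaining living years, >= 0.
#' @export
lifespan <- function(P, spans) {
  stopifnot(inherits(spans, "iwb_span_params"))
  if (any(P < 0) || any(P > 1)) stop("physical index P must lie in [0, 1]",
                                     call. = FALSE)
  spans$T_min + (spans$T_max - spans$T_min) * P^spans$b
}

#' Labour income
#'
#' `Y = y_max * P_prev^eta` while the previous-period health span was open
#' (`H_prev > 0`), else 0: productive capacity exists only inside the
#' health span, and income is earned with last period's physical state.
#'
#' @param P_prev Previous-period physical index in `[0, 1]`.
#' @param params An [economy_params()] object.
#' @param H_prev Previous-period remaining health span, periods.
#' @return Labour income, currency/period.
#' @export
labour_income <- function(P_prev, params, H_prev) {
  stopifnot(inherits(params, "iwb_economy_params"))
  if (any(P_prev < 0) || any(P_prev > 1)) {
    stop("physical index P must lie in [0, 1]", call. = FALSE)
  }
  ifelse(H_prev > 0, params$y_max * P_prev^params$eta, 0)
}

#' Per-period resource flow
#'
#' Total new resources entering the budget: labour income earned with the
#' previous period's physical state plus interest on the previous period's
#' wealth, `GR = Y(P_prev) + r_prev * OF_prev`.
#'
#' @param P_prev Previous-period physical index.
#' @param OF_prev Previous-period objective wealth, currency >= 0.
#' @param r_prev Previous-period interest rate.
#' @param economy An [economy_params()] object.
#' @param H_prev Previous-period remaining health span.
#' @return Resource inflow, currency.
#' @export
resource_flow <- function(P_prev, OF_prev, r_prev, economy, H_prev) {
  if (any(OF_prev < 0)) stop("OF must be >= 0 (no-borrowing)", call. = FALSE)
  labour_income(P_prev, economy, H_prev) + r_prev * OF_prev
}

#' Budget feasibility of an allocation
#'
#' The no-borrowing constraint: within a period, health spending plus
#' financial investment may not exceed start-of-period wealth plus the
#' period's resource flow, `C_OF + I_OF <= OF_prev + GR`.
#'
#' @param alloc An [allocation()] object.
#' @param OF_prev Start-of-period wealth, currency >= 0.
#' @param GR Period resource flow, currency.
#' @return `TRUE` iff the allocation is affordable.
#' @export
budget_feasible <- function(alloc, OF_prev, GR) {
  stopifnot(inherits(alloc, "iwb_allocation"))
  alloc$C_OF + alloc$I_OF <= OF_prev + GR
}

#' One-period update of objective wealth
#'
#' Accounting identity
#' `OF' = OF_prev + r_prev * OF_prev + Y * [in health span] - C_OF`.
#' Labour income enters only while the previous period's health span was
#' open. With a feasible allocation the result is nonnegative; a negative
#' result signals an infeasible allocation and aborts the period.
#'
#' @param OF_prev Start-of-period wealth, currency >= 0.
#' @param r_prev Interest rate earned on it.
#' @param Y Labour income this period (already regime-adjusted or not —
#'   see `in_healthspan`).
#' @param C_OF Health spending this period.
#' @param in_healthspan Logical: was the previous-period health span open?
#' @return Next-period wealth, currency >= 0.
#' @export
step_wealth <- function(OF_prev, r_prev, Y, C_OF, in_healthspan) {
  OF_new <- OF_prev + r_prev * OF_prev + Y * as.numeric(in_healthspan) - C_OF
  if (any(OF_new < 0)) {
    stop("infeasible allocation slipped through: wealth would fall below 0",
         call. = FALSE)
  }
  OF_new
}

#' One-period update of the generic resource stock
#'
#' The n-domain resource law `R' = R + Y(x) - sum(C_i)` under no-borrowing.
#'
#' @param R Current resource stock, currency.
#' @param levels Current domain levels, passed to `income_fn`.
#' @param total_spend Total spending across domains this period, >= 0.
#' @param income_fn Function of the domain levels returning period income.
#' @return Next-period resource stock, currency >= 0.
#' @export
step_resources_general <- function(R, levels, total_spend, income_fn) {
  Y <- income_fn(levels)
  if (total_spend > R + Y) {
    stop("infeasible: total spending ", total_spend, " exceeds resources ",
         R + Y, call. = FALSE)
  }
  R + Y - total_spend
}

# Cross-field span validation: the model's qualitative shape requirements
# (h <= g and h' > g' >= 0 above the threshold) constrain parameter
# combinations, so they are enforced numerically here rather than trusted.
validate_spans <- function(spans, P_bar_H, n_grid = 100L) {
  Pg <- seq(P_bar_H + 1e-6, 1, length.out = n_grid)
  h <- health_span(Pg, spans, P_bar_H)
  g <- lifespan(Pg, spans)
  if (any(h > g + 1e-12)) {
    stop("invalid scenario: health span exceeds lifespan (H <= T violated) ",
         "for P near ", signif(Pg[which.max(h - g)], 4), call. = FALSE)
  }
  dh <- diff(h) / diff(Pg)
  dg <- diff(g) / diff(Pg)
  if (any(dg < -1e-12) || any(dh <= dg)) {
    stop("invalid scenario: span slopes must satisfy h'(P) > g'(P) >= 0 on ",
         "(P_bar_H, 1]", call. = FALSE)
  }
  invisible(TRUE)
}
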