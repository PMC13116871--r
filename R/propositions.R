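#' Required rate of return for a wealth target
#'
#' Rearranges the wealth accounting identity to the interest rate needed
#' to move wealth from `OF_prev` to `OF_target` in one period, given
#' labour income `Y`, financial investment `I_OF` and health spending
#' `C_OF`:
#' `r = (OF_target - OF_prev - Y - I_OF + C_OF) / OF_prev`.
#' Labour income substitutes one-for-one for investment return, which is
#' the mechanism behind the required-return gradient in physical
#' wellbeing.
#'
#' @param OF_target Target end-of-period wealth, currency.
#' @param OF_prev Start-of-period wealth, currency, strictly > 0.
#' @param Y Labour income, currency.
#' @param I_OF Financial investment, currency (default 0).
#' @param C_OF Health spending, currency (default 0).
#' @return The required per-period rate of return (dimensionless).
#' @examples
#' required_return(110, 100, Y = 5, C_OF = 2)  # 0.07
#' @export
required_return <- function(OF_target, OF_prev, Y, I_OF = 0, C_OF = 0) {
  if (any(OF_prev <= 0)) {
    stop("required return undefined: OF_prev must be > 0", call. = FALSE)
  }
  (OF_target - OF_prev - Y - I_OF + C_OF) / OF_prev
}

#' Required return as a function of physical wellbeing
#'
#' Evaluates [required_return()] along a grid of physical-wellbeing
#' levels, with labour income supplied by the scenario's income function
#' `Y(P) = y_max * P^eta`. Within the labour-income regime the curve is
#' strictly decreasing in `P` (income substitutes for return) and convex
#' when income is concave (`eta < 1`). Grid points at or below the
#' health-span threshold earn no labour income; they are flagged in the
#' output (`in_regime = FALSE`) and trigger a warning rather than being
#' silently included.
#'
#' @param P_grid Physical-wellbeing levels in (0, 1].
#' @param OF_target Target end-of-period wealth, currency.
#' @param scn An [scenario()] supplying the income function and threshold.
#' @param OF_prev Start-of-period wealth, > 0; defaults to the scenario's
#'   initial wealth.
#' @param I_OF,C_OF Investment and health spending entering the identity.
#' @return A data frame of class `"iwb_rr_curve"` with columns
#'   `P, Y, r, in_regime`.
#' @export
required_return_curve <- function(P_grid, OF_target, scn,
                                  OF_prev = scn$initial_OF,
                                  I_OF = 0, C_OF = 0) {
  stopifnot(inherits(scn, "iwb_scenario"))
  if (any(P_grid <= 0) || any(P_grid > 1)) {
    stop("P_grid must lie in (0, 1]", call. = FALSE)
  }
  in_regime <- P_grid > scn$physical$P_bar_H
  if (any(!in_regime)) {
    warning(sum(!in_regime), " grid point(s) at or below the health-span ",
            "threshold earn no labour income; flagged in_regime = FALSE",
            call. = FALSE)
  }
  Y <- ifelse(in_regime, scn$economy$y_max * P_grid^scn$economy$eta, 0)
  r <- required_return(OF_target, OF_prev, Y, I_OF, C_OF)
  structure(data.frame(P = P_grid, Y = Y, r = r, in_regime = in_regime),
            class = c("iwb_rr_curve", "data.frame"),
            OF_prev = OF_prev, OF_target = OF_target)
}

#' @export
plot.iwb_rr_curve <- function(x, ...) {
  graphics::plot(x$P[x$in_regime], x$r[x$in_regime], type = "l",
                 xlab = "Physical wellbeing P",
                 ylab = "Required rate of return r",
                 main = "Required return falls as physical wellbeing rises",
                 ...)
  invisible(x)
}

new_prop_report <- function(id, checks, narrative, inconclusive = FALSE) {
  pass <- if (inconclusive) NA else all(vapply(checks, `[[`, logical(1),
                                               "pass"))
  structure(list(id = id, pass = pass, checks = checks,
                 narrative = narrative),
            class = "iwb_prop_report")
}

#' @export
print.iwb_prop_report <- function(x, ...) {
  status <- if (isTRUE(x$pass)) "PASS" else if (is.na(x$pass)) "INCONCLUSIVE"
            else "FAIL"
  cat("<proposition check> ", x$id, ": ", status, "\n", sep = "")
  for (ck in x$checks) {
    cat(sprintf("  [%s] %s\n", if (ck$pass) "ok" else "FAIL", ck$name))
  }
  cat("  ", x$narrative, "\n", sep = "")
  invisible(x)
}

#' Verify the option value of health spending
#'
#' Certifies, by simulation, the causal chain through which health
#' spending carries an intertemporal option value: higher spending raises
#' the physical-wellbeing path, which delays or prevents the crossing
#' below the health-span threshold, which preserves labour income, which
#' raises the wealth path and hence the financial index. The scenario is
#' expected to straddle the threshold: its lowest spend level must let
#' physical wellbeing cross below the threshold within the horizon while
#' its highest keeps it above throughout — otherwise the report is
#' inconclusive (`pass = NA`), not a failure. In this deterministic model
#' the "higher likelihood" of remaining in the income regime is certified
#' as a threshold-crossing statement: more spending weakly delays or
#' prevents the zero-income regime.
#'
#' @param scn An [scenario()], typically the shipped
#'   `"threshold-straddling"` fixture.
#' @param spend_levels Ordered (ascending) per-period health-spend
#'   amounts; at least two.
#' @return An `"iwb_prop_report"`.
#' @export
check_prop1 <- function(scn, spend_levels = c(0, 3, 7)) {
  stopifnot(inherits(scn, "iwb_scenario"), length(spend_levels) >= 2L)
  spend_levels <- sort(spend_levels)
  trajs <- lapply(spend_levels, function(a) {
    simulate_lifecycle(scn, policy_fixed_amount(a), quiet = TRUE)
  })
  m <- length(trajs)
  lo <- trajs[[1L]]; hi <- trajs[[m]]
  straddles <- any(lo$H == 0) && all(hi$H > 0)
  if (!straddles) {
    return(new_prop_report(
      "proposition 1", list(),
      paste("inconclusive: the scenario does not straddle the health-span",
            "threshold across the given spend levels, so the option-value",
            "mechanism cannot be exhibited"),
      inconclusive = TRUE))
  }
  income_periods <- vapply(trajs, function(tr) sum(tr$Y > 0), numeric(1))
  cum_income <- vapply(trajs, function(tr) sum(tr$Y), numeric(1))
  term_OF <- vapply(trajs, function(tr) tr$OF[nrow(tr)], numeric(1))
  term_F <- vapply(trajs, function(tr) tr$F[nrow(tr)], numeric(1))
  weakly_up <- function(v) all(diff(v) >= -1e-9)
  checks <- list(
    list(name = "higher spending => pointwise higher P path",
         pass = all(vapply(seq_len(m - 1), function(i) {
           all(trajs[[i + 1]]$P - trajs[[i]]$P >= -1e-12)
         }, logical(1))),
         detail = lapply(trajs, `[[`, "P")),
    list(name = "periods with open health span weakly increasing in spend",
         pass = weakly_up(income_periods), detail = income_periods),
    list(name = "cumulative labour income weakly increasing in spend",
         pass = weakly_up(cum_income), detail = cum_income),
    list(name = "terminal wealth weakly increasing in spend",
         pass = weakly_up(term_OF), detail = term_OF),
    list(name = "terminal financial index weakly increasing in spend",
         pass = weakly_up(term_F), detail = term_F),
    list(name = "strict gain, lowest vs highest spend (income periods, cumulative income, terminal OF, terminal F)",
         pass = income_periods[m] > income_periods[1] &&
           cum_income[m] > cum_income[1] && term_OF[m] > term_OF[1] &&
           term_F[m] > term_F[1],
         detail = rbind(low = c(income_periods[1], cum_income[1],
                                term_OF[1], term_F[1]),
                        high = c(income_periods[m], cum_income[m],
                                 term_OF[m], term_F[m])))
  )
  new_prop_report(
    "proposition 1", checks,
    paste("health spending raises the physical path, keeps the health span",
          "open for longer, preserves labour income, and thereby raises",
          "terminal wealth and the financial index: an intertemporal option",
          "value. (Wealth accounting treats retained wealth as the financial",
          "investment, so no inflow is double-counted.)"))
}

#' Verify dominance of joint domain improvement
#'
#' A pure algebraic consequence of the Cobb-Douglas form with positive
#' exponents: whenever one state weakly dominates another in both the
#' financial and the physical index, its integrated wellbeing weakly
#' dominates too. Checked exactly (no tolerance) period by period on the
#' supplied pair.
#'
#' @param A,B Either two `iwb_trajectory` objects of equal length sharing
#'   elasticities, or two data frames / lists with numeric fields `F` and
#'   `P` of equal length.
#' @param theta Elasticities `c(F = , P = )`; taken from `A`'s scenario
#'   when trajectories are supplied.
#' @return An `"iwb_prop_report"`. Periods where neither state dominates
#'   the other in both coordinates are outside the proposition's premise
#'   and are skipped.
#' @export
check_prop2 <- function(A, B, theta = NULL) {
  if (inherits(A, "iwb_trajectory") && is.null(theta)) {
    theta <- attr(A, "scenario")$elasticities
  }
  theta <- validate_elasticities(unclass(theta))
  FA <- A$F; PA <- A$P; FB <- B$F; PB <- B$P
  if (length(FA) != length(FB)) {
    stop("mismatched trajectory lengths", call. = FALSE)
  }
  thF <- unclass(theta)[["F"]]; thP <- unclass(theta)[["P"]]
  IWA <- FA^thF * PA^thP
  IWB <- FB^thF * PB^thP
  dom_AB <- FA >= FB & PA >= PB
  dom_BA <- FB >= FA & PB >= PA
  ok <- all(IWA[dom_AB] >= IWB[dom_AB]) && all(IWB[dom_BA] >= IWA[dom_BA])
  checks <- list(list(
    name = sprintf("IW dominance at all %d period(s) with joint domination (exact, no tolerance)",
                   sum(dom_AB | dom_BA)),
    pass = ok,
    detail = data.frame(F_A = FA, P_A = PA, IW_A = IWA, F_B = FB, P_B = PB,
                        IW_B = IWB)))
  new_prop_report(
    "proposition 2", checks,
    paste("with positive elasticities the Cobb-Douglas composite is",
          "monotone in each domain, so joint weak improvement in the",
          "financial and physical indices can never lower integrated",
          "wellbeing"))
}

#' Verify the required-return gradient in physical wellbeing
#'
#' Within the health span the required return satisfies
#' `dr/dP = -Y'(P) / OF_prev < 0`: better physical wellbeing lowers the
#' return needed to hit a wealth target, with diminishing impact (positive
#' second derivative) when labour income is concave in `P`. The analytic
#' derivative of the default income form is compared against central
#' finite differences of [required_return_curve()] at every grid point,
#' and the sign structure of first and second differences along the grid
#' is asserted.
#'
#' @param scn An [scenario()]; its `eta` should be below 1 for the
#'   convexity assertion to have content.
#' @param P_grid Grid in the labour-income regime (all points above the
#'   scenario threshold). Default: 50 points spanning it.
#' @param OF_target,OF_prev Wealth target and base, `OF_prev > 0`.
#' @param fd_step Central-difference step on the `P` axis.
#' @param rel_tol Relative agreement tolerance between analytic and
#'   finite-difference derivatives (absolute floor `1e-12`).
#' @return An `"iwb_prop_report"`.
#' @export
check_prop3 <- function(scn, P_grid = NULL, OF_target = NULL,
                        OF_prev = NULL, fd_step = 1e-5, rel_tol = 1e-6) {
  stopifnot(inherits(scn, "iwb_scenario"))
  if (is.null(OF_prev)) OF_prev <- max(scn$initial_OF, 1)
  if (is.null(OF_target)) OF_target <- OF_prev * 1.2
  if (is.null(P_grid)) {
    P_grid <- seq(scn$physical$P_bar_H + 0.05, 0.99, length.out = 50)
  }
  if (any(P_grid <= scn$physical$P_bar_H) || any(P_grid > 1)) {
    stop("P_grid must lie in the labour-income regime (P_bar_H, 1]",
         call. = FALSE)
  }
  if (OF_prev <= 0) stop("OF_prev must be > 0", call. = FALSE)
  y_max <- scn$economy$y_max; eta <- scn$economy$eta
  rr <- function(P) {
    required_return(OF_target, OF_prev, y_max * P^eta)
  }
  analytic <- -y_max * eta * P_grid^(eta - 1) / OF_prev
  fd <- (rr(P_grid + fd_step) - rr(P_grid - fd_step)) / (2 * fd_step)
  err <- abs(analytic - fd) / pmax(abs(analytic), 1e-12)
  r_vals <- rr(P_grid)
  d1 <- diff(r_vals)
  d2 <- diff(d1)
  checks <- list(
    list(name = "analytic dr/dP = -Y'(P)/OF_prev matches central differences",
         pass = max(err) < rel_tol, detail = max(err)),
    list(name = "dr/dP < 0 throughout the health span",
         pass = all(analytic < 0) && all(d1 < 0), detail = range(analytic)),
    list(name = "second differences positive (diminishing impact, concave Y)",
         pass = if (eta < 1) all(d2 > 0) else all(d2 > -1e-12),
         detail = range(d2)))
  new_prop_report(
    "proposition 3", checks,
    paste("labour income substitutes for investment return: each unit of",
          "income lowers the required return by 1/OF_prev, so the curve",
          "r(P) falls in P and flattens as P rises when income is concave",
          "(the shape of the required-return figure)"))
}
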