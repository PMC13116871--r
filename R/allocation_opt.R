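#' Intertemporal objective for policy search
#'
#' The model itself prescribes no intertemporal aggregate, so the objective
#' is an explicit choice: the terminal-period integrated wellbeing, the
#' mean over the horizon (the default, with no discounting), or a
#' discounted sum with rate `rho`.
#'
#' @param kind One of `"terminal_IW"`, `"mean_IW"`, `"discounted_IW"`.
#' @param rho Discount rate, >= 0; used only by `"discounted_IW"`.
#' @return An objective object of class `"iwb_objective"`.
#' @export
objective <- function(kind = c("mean_IW", "terminal_IW", "discounted_IW"),
                      rho = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(rho) || rho < 0) stop("rho must be >= 0", call. = FALSE)
  structure(list(kind = kind, rho = rho), class = "iwb_objective")
}

eval_objective <- function(obj, traj) {
  switch(obj$kind,
         terminal_IW = traj$IW[nrow(traj)],
         mean_IW = mean(traj$IW),
         discounted_IW = sum(traj$IW / (1 + obj$rho)^(seq_len(nrow(traj)) - 1)))
}

#' Optimal single-period allocation across wellbeing domains
#'
#' Maximises the Cobb-Douglas composite `prod(x_i'^theta_i)` over spending
#' vectors `C >= 0` with `sum(C) <= R`, where each post-investment level is
#' `x_i' = min(1, (1 - delta_i) * x_i + I_i(C_i))` for increasing, concave
#' investment functions `I_i`. Solved from the first-order condition: at an
#' interior optimum the marginal log-wellbeing per unit of spending,
#' `theta_i * I_i'(C_i) / x_i'(C_i)`, is equalised across all domains not
#' at their cap; the common multiplier is found by bracketed bisection
#' until the budget residual is below `tol`. The budget is exhausted
#' whenever some domain remains below its cap (the objective is strictly
#' increasing); if every domain can be capped within budget, only the
#' capping amounts are spent.
#'
#' @param R Available resources, currency > 0.
#' @param theta Elasticities as for [validate_elasticities()].
#' @param invest_fns List of investment functions `I_i(C)`, one per domain,
#'   each increasing and concave with `I_i(0) = 0`.
#' @param levels Carried-over domain levels in `[0, 1]` (default all 0).
#' @param delta Per-domain decay rates in `[0, 1]` applied to the
#'   carryover (default all 0).
#' @param tol Budget-residual tolerance, default `1e-10`.
#' @return A list with class `"iwb_static_allocation"`: `C` (optimal
#'   spending), `levels_new` (post-investment levels), `objective` (the
#'   achieved integrated wellbeing), `spent` (total outlay).
#' @examples
#' sol <- optimal_static_allocation(100, c(0.7, 0.3),
#'   list(function(C) 0.002 * C, function(C) 0.002 * C))
#' sol$C  # 70, 30
#' @export
optimal_static_allocation <- function(R, theta, invest_fns,
                                      levels = NULL, delta = NULL,
                                      tol = 1e-10) {
  theta <- validate_elasticities(unclass(theta))
  n <- length(theta)
  if (!is.numeric(R) || length(R) != 1L || R <= 0) {
    stop("resources R must be > 0", call. = FALSE)
  }
  if (!is.list(invest_fns) || length(invest_fns) != n ||
      !all(vapply(invest_fns, is.function, logical(1)))) {
    stop("invest_fns must be a list of ", n, " functions", call. = FALSE)
  }
  if (is.null(levels)) levels <- rep(0, n)
  if (is.null(delta)) delta <- rep(0, n)
  stopifnot(length(levels) == n, length(delta) == n)
  carried <- (1 - delta) * levels

  post <- function(i, C) min(1, carried[i] + invest_fns[[i]](C))
  dinvest <- function(i, C) {
    h <- 1e-6 * max(1, abs(C))
    if (C - h < 0) (invest_fns[[i]](C + h) - invest_fns[[i]](C)) / h
    else (invest_fns[[i]](C + h) - invest_fns[[i]](C - h)) / (2 * h)
  }
  # marginal log-objective per unit spend; decreasing in C
  phi <- function(i, C) {
    x <- carried[i] + invest_fns[[i]](C)
    if (x >= 1) return(0)
    if (x <= 0) return(Inf)
    unclass(theta)[i] * dinvest(i, C) / x
  }
  # spending at which the domain caps at 1 (Inf if unreachable within R)
  cap_spend <- vapply(seq_len(n), function(i) {
    if (carried[i] >= 1) return(0)
    if (post(i, R) < 1) return(Inf)
    stats::uniroot(function(C) carried[i] + invest_fns[[i]](C) - 1,
                   c(0, R), tol = min(tol, 1e-12))$root
  }, numeric(1))

  finite_caps <- pmin(cap_spend, R)
  if (all(cap_spend <= R)) {
    # everything can be capped: nothing left to optimise beyond the caps
    C <- cap_spend
  } else {
    spend_at <- function(mu) {
      vapply(seq_len(n), function(i) {
        hi <- min(cap_spend[i], R)
        if (hi <= 0) return(0)
        if (phi(i, 0) <= mu) return(0)        # corner: not worth the first unit
        if (phi(i, hi) >= mu) return(hi)       # cap or budget binds first
        stats::uniroot(function(C) phi(i, C) - mu, c(0, hi),
                       tol = min(tol, 1e-12))$root
      }, numeric(1))
    }
    # bracket the multiplier: S(mu) is decreasing
    mu_hi <- max(vapply(seq_len(n), function(i) phi(i, 0), numeric(1))[
      is.finite(vapply(seq_len(n), function(i) phi(i, 0), numeric(1)))],
      1, na.rm = TRUE)
    while (sum(spend_at(mu_hi)) > R) mu_hi <- mu_hi * 10
    mu_lo <- mu_hi
    while (sum(spend_at(mu_lo)) < R && mu_lo > 1e-300) mu_lo <- mu_lo / 10
    for (it in seq_len(200)) {
      mu <- sqrt(mu_lo * mu_hi)
      S <- sum(spend_at(mu))
      if (S > R) mu_lo <- mu else mu_hi <- mu
      if (abs(S - R) <= tol * max(1, R)) break
    }
    C <- spend_at(mu_hi)
    # distribute any residual over interior domains, preserving caps
    resid <- R - sum(C)
    interior <- which(C < pmin(cap_spend, R) - tol)
    if (length(interior) > 0L && resid > 0) {
      w <- unclass(theta)[interior] / sum(unclass(theta)[interior])
      C[interior] <- C[interior] + resid * w
    }
  }
  x_new <- vapply(seq_len(n), function(i) post(i, C[i]), numeric(1))
  structure(list(C = unname(C),
                 levels_new = unname(x_new),
                 objective = integrated_wellbeing(x_new, theta),
                 spent = sum(C)),
            class = "iwb_static_allocation")
}

#' Search constant-fraction health-spending policies on a grid
#'
#' Simulates the scenario under each constant-fraction policy
#' `phi in phi_grid` (spend `phi` of available resources on health each
#' period), evaluates the chosen intertemporal objective on every
#' trajectory, and returns the maximiser together with the full objective
#' surface. Ties are broken toward the smaller health-spend fraction.
#'
#' @param scn An [scenario()] object.
#' @param phi_grid Numeric vector of fractions in `[0, 1]`, non-empty.
#' @param obj An [objective()]; default mean integrated wellbeing.
#' @return A list with class `"iwb_policy_search"`: `best_phi`,
#'   `best_value`, and `table` — a data frame with one row per `phi`
#'   holding the objective and terminal/mean diagnostics.
#' @export
grid_policy_search <- function(scn, phi_grid, obj = objective("mean_IW")) {
  stopifnot(inherits(scn, "iwb_scenario"), inherits(obj, "iwb_objective"))
  if (!is.numeric(phi_grid) || length(phi_grid) < 1L ||
      any(phi_grid < 0) || any(phi_grid > 1)) {
    stop("phi_grid must be a non-empty subset of [0, 1]", call. = FALSE)
  }
  phi_grid <- sort(phi_grid)
  rows <- lapply(phi_grid, function(phi) {
    traj <- simulate_lifecycle(scn, policy_constant_fraction(phi),
                               quiet = TRUE)
    s <- trajectory_summary(traj)
    data.frame(phi = phi, objective = eval_objective(obj, traj),
               terminal_P = traj$P[nrow(traj)], terminal_OF = s$terminal_OF,
               terminal_F = s$terminal_F, mean_IW = s$mean_IW)
  })
  tab <- do.call(rbind, rows)
  best <- which.max(tab$objective)  # first max: ties go to smaller phi
  structure(list(best_phi = tab$phi[best], best_value = tab$objective[best],
                 objective = obj, table = tab),
            class = "iwb_policy_search")
}

#' Trade-off frontier across health-spending policies
#'
#' One `(terminal F, terminal P, mean IW)` triple per constant-fraction
#' policy: the surface on which spending more on health trades terminal
#' wealth against physical wellbeing and the integrated composite.
#'
#' @inheritParams grid_policy_search
#' @return A data frame with columns `phi, terminal_F, terminal_P,
#'   mean_IW`, one row per grid point.
#' @export
wellbeing_frontier <- function(scn, phi_grid) {
  res <- grid_policy_search(scn, phi_grid)
  data.frame(phi = res$table$phi, terminal_F = res$table$terminal_F,
             terminal_P = res$table$terminal_P, mean_IW = res$table$mean_IW)
}

#' @export
print.iwb_policy_search <- function(x, ...) {
  cat("<iwb_policy_search> objective:", x$objective$kind,
      "| best phi:", x$best_phi,
      sprintf("(value %.6f)\n", x$best_value))
  print(x$table, row.names = FALSE)
  invisible(x)
}
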