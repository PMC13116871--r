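#' Validate a vector of domain elasticities
#'
#' Elasticities are the exponents of the Cobb-Douglas integrated-wellbeing
#' aggregator. Each must be strictly positive and they must sum to one
#' (constant returns to scale), so that integrated wellbeing is itself a
#' bounded index on `[0, 1]`.
#'
#' @param theta Numeric vector of per-domain elasticities. Names, if present,
#'   identify the domains and are preserved.
#' @param normalise If `TRUE`, rescale `theta` to sum to exactly one before
#'   validating. Off by default: silent coercion of a mis-specified scenario
#'   is worse than an error.
#' @param tol Absolute tolerance on `sum(theta) == 1`. Default `1e-12`.
#' @return `theta`, unchanged (or normalised), with class
#'   `"iwb_elasticities"`.
#' @examples
#' validate_elasticities(c(F = 0.5, P = 0.5))
#' validate_elasticities(c(0.7, 0.3))
#' @export
validate_elasticities <- function(theta, normalise = FALSE, tol = 1e-12) {
  if (!is.numeric(theta) || length(theta) < 1L || anyNA(theta) ||
      any(!is.finite(theta))) {
    stop("elasticities must be a finite numeric vector", call. = FALSE)
  }
  if (normalise) theta <- theta / sum(theta)
  if (any(theta <= 0)) {
    stop("invalid elasticities: every theta_i must be > 0 (got ",
         paste(signif(theta, 6), collapse = ", "), ")", call. = FALSE)
  }
  if (abs(sum(theta) - 1) > tol) {
    stop("invalid elasticities: sum(theta) = ", format(sum(theta), digits = 15),
         " but constant returns to scale requires sum(theta_i) = 1",
         call. = FALSE)
  }
  structure(theta, class = "iwb_elasticities")
}

#' Cobb-Douglas integrated wellbeing
#'
#' Aggregates per-domain wellbeing indices `x_i` in `[0, 1]` into the
#' integrated-wellbeing index `IW = prod(x_i ^ theta_i)`. The multiplicative
#' form encodes complementarity: a zero in any domain annihilates the
#' composite regardless of the others, and each domain exhibits diminishing
#' marginal contribution when its exponent is below one.
#'
#' The `0^0` convention: a zero level with a positive exponent contributes a
#' factor of 0, never 1.
#'
#' @param levels Numeric vector of domain indices, each in `[0, 1]`, same
#'   length (and names, if any) as `theta`.
#' @param theta Elasticities as accepted by [validate_elasticities()].
#' @return The integrated wellbeing index, a scalar in `[0, 1]`.
#' @examples
#' integrated_wellbeing(c(1, 1), c(0.5, 0.5))          # 1
#' integrated_wellbeing(c(0.49, 0.81), c(0.5, 0.5))    # 0.63
#' @export
integrated_wellbeing <- function(levels, theta) {
  theta <- validate_elasticities(unclass(theta))
  check_levels(levels, theta)
  if (any(levels == 0)) return(0)
  # exp/log form is exact enough and avoids 0^0 pitfalls for interior x
  exp(sum(unclass(theta) * log(levels)))
}

#' Marginal contribution of one domain to integrated wellbeing
#'
#' The partial derivative of the Cobb-Douglas composite with respect to a
#' single domain level: `dIW/dx_d = theta_d * IW / x_d`. Strictly positive,
#' and strictly decreasing in `x_d` whenever `theta_d < 1` (diminishing
#' marginal returns of any single domain).
#'
#' @inheritParams integrated_wellbeing
#' @param domain Index or name of the domain to differentiate with respect
#'   to. Its level must be strictly positive.
#' @return The marginal contribution, a positive scalar.
#' @export
marginal_iw <- function(levels, theta, domain) {
  theta <- validate_elasticities(unclass(theta))
  check_levels(levels, theta)
  d <- resolve_domain(domain, levels, theta)
  if (levels[d] == 0) {
    stop("marginal undefined at boundary: level of domain ", domain,
         " is 0", call. = FALSE)
  }
  unname(unclass(theta)[d] * integrated_wellbeing(levels, theta) / levels[d])
}

#' Parameters of the financial-wellbeing index map
#'
#' The model constrains the financial index only to be bounded on `[0, 1]`
#' and strictly increasing in both objective wealth and the subjective
#' index; this package adopts the saturating form
#' `F = (OF / (OF + s))^lambda * SF^(1 - lambda)`.
#'
#' @param s Wealth half-saturation scale, in currency units; the wealth at
#'   which the objective component reaches one half. Must be > 0.
#' @param lambda Weight on the objective component, strictly inside (0, 1).
#' @return A list with class `"iwb_fin_params"`.
#' @export
financial_index_params <- function(s, lambda) {
  stopifnot(is.numeric(s), length(s) == 1L, is.numeric(lambda),
            length(lambda) == 1L)
  if (!is.finite(s) || s <= 0) {
    stop("invalid financial index params: wealth scale s must be > 0",
         call. = FALSE)
  }
  if (!is.finite(lambda) || lambda <= 0 || lambda >= 1) {
    stop("invalid financial index params: objective weight lambda must lie ",
         "strictly inside (0, 1)", call. = FALSE)
  }
  structure(list(s = s, lambda = lambda), class = "iwb_fin_params")
}

#' Financial wellbeing index
#'
#' Maps an objective wealth stock `OF >= 0` (currency) and a subjective
#' financial-wellbeing index `SF` in `[0, 1]` to the composite financial
#' index `F = (OF/(OF + s))^lambda * SF^(1-lambda)`. Strictly increasing in
#' both arguments, 0 when either is 0, and approaching 1 as wealth grows
#' without bound with `SF = 1`.
#'
#' @param OF Objective financial wealth, a nonnegative currency stock.
#' @param SF Subjective financial wellbeing index in `[0, 1]`.
#' @param params A [financial_index_params()] object.
#' @return The financial wellbeing index in `[0, 1]`. Vectorised over `OF`
#'   and `SF`.
#' @examples
#' p <- financial_index_params(s = 500, lambda = 0.5)
#' financial_index(500, 1, p)   # sqrt(0.5)
#' @export
financial_index <- function(OF, SF, params) {
  stopifnot(inherits(params, "iwb_fin_params"))
  if (any(!is.finite(OF)) || any(OF < 0)) {
    stop("invalid financial state: OF must be finite and >= 0 (no-borrowing)",
         call. = FALSE)
  }
  if (any(!is.finite(SF)) || any(SF < 0) || any(SF > 1)) {
    stop("invalid financial state: SF must lie in [0, 1]", call. = FALSE)
  }
  obj <- OF / (OF + params$s)
  obj^params$lambda * SF^(1 - params$lambda)
}

# -- internal helpers ---------------------------------------------------------

check_levels <- function(levels, theta) {
  if (!is.numeric(levels) || anyNA(levels) || any(!is.finite(levels))) {
    stop("domain levels must be finite numeric", call. = FALSE)
  }
  if (length(levels) != length(theta)) {
    stop("invalid scenario: ", length(levels), " domain levels but ",
         length(theta), " elasticities", call. = FALSE)
  }
  tn <- names(unclass(theta)); ln <- names(levels)
  if (!is.null(tn) && !is.null(ln) && !identical(tn, ln)) {
    stop("invalid scenario: domain names of levels and elasticities differ",
         call. = FALSE)
  }
  if (any(levels < 0) || any(levels > 1)) {
    stop("domain levels must lie in [0, 1]", call. = FALSE)
  }
  invisible(levels)
}

resolve_domain <- function(domain, levels, theta) {
  if (is.character(domain)) {
    nm <- names(levels)
    if (is.null(nm)) nm <- names(unclass(theta))
    d <- match(domain, nm)
    if (is.na(d)) stop("unknown domain '", domain, "'", call. = FALSE)
    return(d)
  }
  d <- as.integer(domain)
  if (is.na(d) || d < 1L || d > length(levels)) {
    stop("domain index out of range", call. = FALSE)
  }
  d
}
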