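# Shared fixtures and independent oracles, built in code.

# A scenario whose decay rate is effectively a chosen constant: the age grid
# sits far below the inflexion, so alpha(t) == alpha_min to machine precision.
const_alpha_physical <- function(alpha, P_bar_H = 0.3, kappa = 0.1,
                                 c0 = 10) {
  physical_params(alpha_min = alpha, alpha_max = min(0.99, alpha + 0.1),
                  tau = 0.1, t0 = 1e6, P_bar_H = P_bar_H, kappa = kappa,
                  c0 = c0)
}

default_spans <- function() span_params(H_max = 60, a = 1, T_min = 70,
                                        T_max = 85, b = 1)

mini_scenario <- function(alpha = 0.05, P0 = 0.8, OF0 = 100, SF = 0.7,
                          y_max = 50, eta = 0.5, r = 0.03, horizon = 10,
                          start_age = 25, P_bar_H = 0.3, kappa = 0.1,
                          c0 = 10, theta = c(F = 0.5, P = 0.5)) {
  scenario(
    elasticities = theta,
    physical = const_alpha_physical(alpha, P_bar_H, kappa, c0),
    spans = default_spans(),
    economy = economy_params(y_max, eta, r),
    fin_index = financial_index_params(s = 500, lambda = 0.5),
    initial_P = P0, initial_OF = OF0, initial_SF = SF,
    start_age = start_age, horizon = horizon)
}

# Random valid (levels, theta) draws for the Cobb-Douglas property suite.
rand_theta <- function(n_dom) {
  w <- stats::runif(n_dom, 0.05, 1)
  w / sum(w)
}

# Independent brute-force oracle for the static allocator: exhaustive search
# over an n-point discretisation of the budget simplex. Deliberately knows
# nothing about first-order conditions.
static_grid_best <- function(R, theta, invest_fns, levels = NULL,
                             delta = NULL, n = 200) {
  k <- length(theta)
  if (is.null(levels)) levels <- rep(0, k)
  if (is.null(delta)) delta <- rep(0, k)
  post_iw <- function(C) {
    x <- vapply(seq_len(k), function(i) {
      min(1, (1 - delta[i]) * levels[i] + invest_fns[[i]](C[i]))
    }, numeric(1))
    prod(x^theta)
  }
  if (k == 2) {
    shares <- seq(0, 1, length.out = n)
    vals <- vapply(shares, function(s) post_iw(c(s, 1 - s) * R), numeric(1))
    best <- which.max(vals)
    list(C = c(shares[best], 1 - shares[best]) * R, value = vals[best])
  } else if (k == 3) {
    m <- ceiling(sqrt(2 * n))        # triangular grid with >= n points
    pts <- list(); vals <- c()
    for (i in 0:m) for (j in 0:(m - i)) {
      C <- c(i, j, m - i - j) / m * R
      pts[[length(pts) + 1L]] <- C
      vals <- c(vals, post_iw(C))
    }
    best <- which.max(vals)
    list(C = pts[[best]], value = vals[best])
  } else {
    stop("oracle supports 2 or 3 domains")
  }
}

# Draws of (F, P) pairs where state A weakly dominates state B.
rand_dominating_pairs <- function(n) {
  FB <- stats::runif(n); PB <- stats::runif(n)
  FA <- FB + (1 - FB) * stats::runif(n)
  PA <- PB + (1 - PB) * stats::runif(n)
  list(A = data.frame(F = FA, P = PA), B = data.frame(F = FB, P = PB))
}
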