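SCHEMA_VERSION <- 1L

scenario_schema <- list(
  top = c("schema_version", "name", "elasticities", "physical", "spans",
          "economy", "fin_index", "initial", "start_age", "horizon",
          "static_oracle"),
  elasticities = c("F", "P"),
  physical = c("alpha_min", "alpha_max", "tau", "t0", "P_bar_H", "kappa",
               "c0"),
  spans = c("H_max", "a", "T_min", "T_max", "b"),
  economy = c("y_max", "eta", "r_path"),
  fin_index = c("s", "lambda"),
  initial = c("P", "OF", "SF")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0L) {
    stop("invalid scenario config: unknown key(s) ",
         paste0("'", extra, "'", collapse = ", "), " in ", where,
         call. = FALSE)
  }
  miss <- setdiff(setdiff(allowed, c("name", "static_oracle")), names(x))
  if (length(miss) > 0L) {
    stop("invalid scenario config: missing key(s) ",
         paste0("'", miss, "'", collapse = ", "), " in ", where,
         call. = FALSE)
  }
  invisible(x)
}

#' Load and validate a scenario configuration
#'
#' Reads a JSON scenario document (or an already-parsed list of the same
#' shape), checks it against the versioned schema — unknown keys are
#' rejected, every numeric invariant of the constituent parameter sets is
#' enforced with an error naming the offending field — and assembles a
#' validated [scenario()].
#'
#' @param x Path to a JSON file, a JSON string, or a named list.
#' @return An `"iwb_scenario"`.
#' @seealso [write_scenario()] for the inverse; round-trips are lossless.
#' @export
load_scenario <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    doc <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  } else if (is.list(x)) {
    doc <- x
  } else {
    stop("expected a file path, JSON string, or list", call. = FALSE)
  }
  check_keys(doc, scenario_schema$top, "document root")
  if (!identical(as.integer(doc$schema_version), SCHEMA_VERSION)) {
    stop("invalid scenario config: schema_version must be ", SCHEMA_VERSION,
         call. = FALSE)
  }
  for (blk in c("elasticities", "physical", "spans", "economy", "fin_index",
                "initial")) {
    check_keys(doc[[blk]], scenario_schema[[blk]], paste0("'", blk, "'"))
  }
  ph <- doc$physical; sp <- doc$spans; ec <- doc$economy
  scenario(
    elasticities = c(F = doc$elasticities$F, P = doc$elasticities$P),
    physical = physical_params(ph$alpha_min, ph$alpha_max, ph$tau, ph$t0,
                               ph$P_bar_H, ph$kappa, ph$c0),
    spans = span_params(sp$H_max, sp$a, sp$T_min, sp$T_max, sp$b),
    economy = economy_params(ec$y_max, ec$eta, ec$r_path),
    fin_index = financial_index_params(doc$fin_index$s,
                                       doc$fin_index$lambda),
    initial_P = doc$initial$P, initial_OF = doc$initial$OF,
    initial_SF = doc$initial$SF, start_age = doc$start_age,
    horizon = doc$horizon, name = doc$name,
    static_oracle = doc$static_oracle)
}

#' Serialise a scenario to its JSON configuration
#'
#' @param scn An [scenario()] object.
#' @param path Optional file path; if omitted, the JSON string is
#'   returned. Serialisation is lossless (full double precision), so
#'   `load_scenario(write_scenario(scn))` reproduces `scn`.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_scenario <- function(scn, path = NULL) {
  stopifnot(inherits(scn, "iwb_scenario"))
  doc <- list(
    schema_version = SCHEMA_VERSION,
    name = scn$name,
    elasticities = list(F = unclass(scn$elasticities)[["F"]],
                        P = unclass(scn$elasticities)[["P"]]),
    physical = unclass(scn$physical),
    spans = unclass(scn$spans),
    economy = unclass(scn$economy),
    fin_index = unclass(scn$fin_index),
    initial = list(P = scn$initial_P, OF = scn$initial_OF,
                   SF = scn$initial_SF),
    start_age = scn$start_age,
    horizon = scn$horizon,
    static_oracle = scn$static_oracle)
  doc <- doc[!vapply(doc, is.null, logical(1))]
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' Named baseline scenarios
#'
#' Fixtures realising the model's qualitative regimes, built in code so
#' every test runs offline:
#' \describe{
#'   \item{steady-midlife}{Physical wellbeing stays comfortably above the
#'     health-span threshold for the whole horizon even without health
#'     spending.}
#'   \item{threshold-straddling}{Under zero health spending, physical
#'     wellbeing crosses below the threshold mid-horizon; moderate
#'     spending keeps it above throughout. The option-value fixture.}
#'   \item{post-healthspan}{Starts below the threshold: the health span is
#'     closed from the outset and income is interest only.}
#'   \item{symmetric-static}{Carries a `static_oracle` block (linear
#'     symmetric investment, zero carryover) for which the optimal static
#'     allocation is the budget split in elasticity proportions.}
#' }
#'
#' @return A named list of `"iwb_scenario"` objects.
#' @export
baseline_scenarios <- function() {
  fin <- financial_index_params(s = 500, lambda = 0.5)
  phys <- physical_params(alpha_min = 0.01, alpha_max = 0.21, tau = 0.1,
                          t0 = 65, P_bar_H = 0.3, kappa = 0.1, c0 = 10)
  spans <- span_params(H_max = 60, a = 1, T_min = 70, T_max = 85, b = 1)
  econ <- economy_params(y_max = 50, eta = 0.5, r_path = 0.03)
  th <- c(F = 0.5, P = 0.5)

  list(
    "steady-midlife" = scenario(
      elasticities = th,
      physical = physical_params(0.01, 0.21, 0.1, 65, 0.25, 0.1, 10),
      spans = spans, economy = econ, fin_index = fin,
      initial_P = 0.95, initial_OF = 50, initial_SF = 0.7,
      start_age = 25, horizon = 30, name = "steady-midlife"),
    "threshold-straddling" = scenario(
      elasticities = th, physical = phys, spans = spans, economy = econ,
      fin_index = fin, initial_P = 0.9, initial_OF = 50, initial_SF = 0.7,
      start_age = 25, horizon = 60, name = "threshold-straddling"),
    "post-healthspan" = scenario(
      elasticities = th, physical = phys, spans = spans, economy = econ,
      fin_index = fin, initial_P = 0.2, initial_OF = 200, initial_SF = 0.6,
      start_age = 65, horizon = 30, name = "post-healthspan"),
    "symmetric-static" = scenario(
      elasticities = th, physical = phys, spans = spans, economy = econ,
      fin_index = fin, initial_P = 0.9, initial_OF = 50, initial_SF = 0.7,
      start_age = 25, horizon = 10, name = "symmetric-static",
      static_oracle = list(R = 100, theta = c(0.5, 0.5),
                           slope = 0.002, levels = c(0, 0),
                           delta = c(0, 0)))
  )
}

#' Write a trajectory to comma-separated text
#'
#' One row per period, header row naming every field, stable column order,
#' numbers serialised with 12 significant digits. The generating scenario
#' is echoed to a JSON sidecar (`<path>.scenario.json`) for
#' reproducibility.
#'
#' @param traj A non-empty `iwb_trajectory`.
#' @param path Output file path.
#' @param sidecar Write the scenario sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "iwb_trajectory"))
  if (nrow(traj) == 0L) stop("empty trajectory", call. = FALSE)
  cols <- c("age", "P", "alpha", "H", "T", "Y", "r", "OF", "SF", "F", "IW",
            "C_OF", "I_OF")
  df <- as.data.frame(traj)[, cols]
  fmt <- vapply(df, function(col) sprintf("%.12g", col), character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1)
  lines <- c(paste(cols, collapse = ","),
             apply(fmt, 1, paste, collapse = ","))
  writeLines(lines, path)
  scn <- attr(traj, "scenario")
  if (sidecar && !is.null(scn)) {
    write_scenario(scn, paste0(path, ".scenario.json"))
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path File path.
#' @return A plain data frame with the trajectory columns.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Write a proposition report as structured text
#'
#' @param report An `"iwb_prop_report"`.
#' @param path Output file path (JSON).
#' @return `path`, invisibly.
#' @export
write_prop_report <- function(report, path) {
  stopifnot(inherits(report, "iwb_prop_report"))
  doc <- list(id = report$id, pass = report$pass,
              checks = lapply(report$checks, function(ck) {
                list(name = ck$name, pass = ck$pass)
              }),
              narrative = report$narrative)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}
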