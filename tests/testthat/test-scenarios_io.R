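test_that("every shipped fixture loads and survives a lossless round trip", {
  scns <- baseline_scenarios()
  expect_named(scns, c("steady-midlife", "threshold-straddling",
                       "post-healthspan", "symmetric-static"))
  for (scn in scns) {
    json1 <- write_scenario(scn)
    reloaded <- load_scenario(json1)
    # byte-identical re-serialisation certifies the lossless round trip
    expect_identical(write_scenario(reloaded), json1)
    expect_equal(reloaded$initial_P, scn$initial_P)
    expect_equal(unclass(reloaded$physical), unclass(scn$physical))
  }
  # file-based round trip too
  f <- tempfile(fileext = ".json")
  write_scenario(scns[[1]], f)
  expect_identical(write_scenario(load_scenario(f)),
                   write_scenario(scns[[1]]))
})

test_that("fixtures realise their stated regimes", {
  scns <- baseline_scenarios()
  # threshold-straddling: zero spending closes the health span mid-horizon
  tr0 <- simulate_lifecycle(scns[["threshold-straddling"]])
  expect_true(any(tr0$H == 0))
  expect_true(any(tr0$H > 0))
  # post-healthspan: income is interest only, at every period
  trp <- simulate_lifecycle(scns[["post-healthspan"]])
  expect_true(all(trp$Y == 0))
  # steady-midlife: never leaves the health span even unspent
  trs <- simulate_lifecycle(scns[["steady-midlife"]])
  expect_true(all(trs$H > 0))
  # symmetric-static carries its oracle block
  expect_equal(scns[["symmetric-static"]]$static_oracle$theta, c(0.5, 0.5))
})

test_that("schema violations are rejected with messages naming the constraint", {
  doc <- jsonlite::fromJSON(write_scenario(baseline_scenarios()[[1]]))
  bad <- doc; bad$physical$alpha_min <- bad$physical$alpha_max
  expect_error(load_scenario(bad), "0 < alpha_min < alpha_max < 1")
  bad <- doc; bad$spurious <- 1
  expect_error(load_scenario(bad), "unknown key.*spurious")
  bad <- doc; bad$physical$extra <- 1
  expect_error(load_scenario(bad), "unknown key.*extra")
  bad <- doc; bad$economy$y_max <- NULL
  expect_error(load_scenario(bad), "missing key.*y_max")
  bad <- doc; bad$schema_version <- 99
  expect_error(load_scenario(bad), "schema_version")
  bad <- doc; bad$initial$P <- 1.4
  expect_error(load_scenario(bad), "initial_P")
  bad <- doc; bad$fin_index$lambda <- 1
  expect_error(load_scenario(bad), "lambda")
})

test_that("trajectory writer round-trips values and keeps a stable column order", {
  scn <- baseline_scenarios()[["steady-midlife"]]
  traj <- simulate_lifecycle(scn, policy_constant_fraction(0.05),
                             quiet = TRUE)
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_identical(names(back),
                   c("age", "P", "alpha", "H", "T", "Y", "r", "OF", "SF",
                     "F", "IW", "C_OF", "I_OF"))
  for (col in names(back)) {
    expect_lt(max(abs(back[[col]] - traj[[col]]) /
                    pmax(1, abs(traj[[col]]))), 1e-9)
  }
  # scenario sidecar reproduces the generating configuration
  side <- load_scenario(paste0(f, ".scenario.json"))
  expect_identical(write_scenario(side), write_scenario(scn))
  # repeated writes are byte-identical
  f2 <- tempfile(fileext = ".csv")
  write_trajectory(traj, f2, sidecar = FALSE)
  expect_identical(readLines(f), readLines(f2))
  expect_error(write_trajectory(traj[0, ], tempfile(), sidecar = FALSE),
               "empty")
})

test_that("proposition reports serialise to structured text", {
  scn <- baseline_scenarios()[["threshold-straddling"]]
  rep3 <- check_prop3(scn)
  f <- tempfile(fileext = ".json")
  write_prop_report(rep3, f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  expect_identical(doc$id, "proposition 3")
  expect_true(doc$pass)
  expect_length(doc$checks, length(rep3$checks))
})

test_that("the CLI drives simulate, optimize, frontier and verify", {
  out <- tempfile(); dir.create(out)
  cfg <- file.path(out, "scenario.json")
  write_scenario(baseline_scenarios()[["threshold-straddling"]], cfg)

  expect_identical(suppressMessages(
    iwb_cli(c("simulate", "--config", cfg, "--phi", "0.05",
              "--out", out))), 0L)
  expect_true(file.exists(file.path(out, "trajectory.csv")))

  expect_identical(suppressMessages(
    iwb_cli(c("optimize", "--config", cfg, "--phi-grid", "0:0.2:5",
              "--out", out))), 0L)
  tab <- utils::read.csv(file.path(out, "policy_search.csv"))
  expect_equal(nrow(tab), 5L)

  expect_identical(suppressMessages(
    iwb_cli(c("frontier", "--config", cfg, "--phi-grid", "0:0.2:3",
              "--out", out))), 0L)

  verify_out <- utils::capture.output(status <- suppressMessages(
    iwb_cli(c("verify", "--fixtures", "--out", out))))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out, "proposition_1.json")))

  # repeated invocations are byte-identical
  out2 <- tempfile(); dir.create(out2)
  suppressMessages(iwb_cli(c("simulate", "--config", cfg, "--phi", "0.05",
                             "--out", out2)))
  expect_identical(readLines(file.path(out, "trajectory.csv")),
                   readLines(file.path(out2, "trajectory.csv")))

  # validation failures surface as a non-zero exit status
  expect_identical(suppressMessages(iwb_cli(c("simulate"))), 1L)
  expect_identical(suppressMessages(iwb_cli(c("nonsense"))), 2L)
})
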