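write_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}

test_that("delimited matrix and vector files round-trip with either delimiter", {
  d <- tempfile(); dir.create(d)
  A <- matrix(c(-1, 2, 2, -1), 2, 2)

  csv <- write_lines(c("-1,2", "2,-1"), file.path(d, "A.csv"))
  expect_equal(read_interaction_matrix(csv), A)

  tsv <- write_lines(c("-1\t2", "2\t-1"), file.path(d, "A.tsv"))
  expect_equal(read_interaction_matrix(tsv), A)

  with_header <- write_lines(c("sp1,sp2", "-1,2", "2,-1"), file.path(d, "Ah.csv"))
  expect_equal(read_interaction_matrix(with_header), A)

  vec <- write_lines(c("1", "1.5"), file.path(d, "n.csv"))
  expect_equal(read_abundance_vector(vec), c(1, 1.5))
})

test_that("malformed numeric tables are rejected with the offending file named", {
  d <- tempfile(); dir.create(d)
  notsquare <- write_lines(c("-1,2,0", "2,-1,0"), file.path(d, "bad.csv"))
  expect_error(read_interaction_matrix(notsquare), "square")
  zero <- write_lines(c("1", "0"), file.path(d, "zero.csv"))
  expect_error(read_abundance_vector(zero), "strictly positive")
  expect_error(read_abundance_vector(file.path(d, "missing.csv")), "not found")
})

test_that("scenario config files parse, override, and reject unknown keys", {
  f <- tempfile(fileext = ".yml")
  writeLines(c("connectance: 0.5", "sigma: 0.3", "n_reps: 4", "seed: 9"), f)
  cfg <- read_scenario_config(f, overrides = list(S = 12, sigma = 0.25))
  expect_equal(cfg$connectance, 0.5)
  expect_equal(cfg$sigma, 0.25) # override wins
  expect_equal(cfg$S, 12L)

  writeLines(c("S: 10", "not_a_field: 1"), f)
  expect_error(read_scenario_config(f), "unknown config keys")

  cfg2 <- scenario_config(S = 8, n_reps = 2)
  f2 <- tempfile(fileext = ".yml")
  write_scenario_config(cfg2, f2)
  expect_equal(read_scenario_config(f2), cfg2)
})

test_that("sweep results round-trip losslessly through CSV", {
  d <- tempfile()
  cfg <- tiny_config(bounded = TRUE)
  sw <- run_richness_sweep(cfg, S_grid = 10, n_reps = 3)
  paths <- write_sweep_results(sw, d)
  rec <- readr::read_csv(paths[["records"]], show_col_types = FALSE)
  expect_equal(as.data.frame(rec), as.data.frame(sw$records))
  manifest <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(manifest$config$seed, cfg$seed)
  expect_equal(manifest$package, "glvsim")
})

test_that("the sweep subcommand writes deterministic tables", {
  d1 <- tempfile(); d2 <- tempfile()
  args <- c("--s-grid", "10,20", "--n-reps", "5", "--seed", "1", "--quiet")
  suppressMessages(cli_sweep(c(args, "--out-dir", d1)))
  suppressMessages(cli_sweep(c(args, "--out-dir", d2)))
  rec <- readr::read_csv(file.path(d1, "sweep_records.csv"), show_col_types = FALSE)
  expect_equal(nrow(rec), 10)
  expect_identical(readLines(file.path(d1, "sweep_records.csv")),
                   readLines(file.path(d2, "sweep_records.csv")))
})

test_that("the scenario subcommand produces outcome-classification summaries", {
  d <- tempfile()
  suppressMessages(cli_sweep(c("--s-grid", "10", "--n-reps", "4", "--seed", "2",
                               "--sign-mode", "all_positive", "--quiet",
                               "--out-dir", d, "--prefix", "pos"),
                             scenario = TRUE))
  s <- readr::read_csv(file.path(d, "pos_summary.csv"), show_col_types = FALSE)
  expect_true(all(c("prop_no_extinction", "prop_near_total_extinction",
                    "mean_n_at_ceiling") %in% names(s)))
  expect_error(cli_sweep(c("--s-grid", "10"), scenario = TRUE), "sign-mode")
})

test_that("simulate-one reports the saddle and dumps a trajectory starting at N0", {
  d <- tempfile(); dir.create(d)
  write_lines(c("-1,2", "2,-1"), file.path(d, "A.csv"))
  write_lines(c("1", "1"), file.path(d, "n.csv"))
  traj_path <- file.path(d, "traj.csv")
  out <- capture.output(
    cli_simulate_one(c("--matrix", file.path(d, "A.csv"),
                       "--equilibrium", file.path(d, "n.csv"),
                       "--seed", "4", "--trajectory", traj_path))
  )
  expect_true(any(grepl("unstable \\(saddle\\)", out)))
  traj <- readr::read_csv(traj_path, show_col_types = FALSE)
  set.seed(4)
  expect_equal(unlist(traj[1, c("N1", "N2")], use.names = FALSE),
               perturb_equilibrium(c(1, 1), 0.02))

  write_lines(c("1", "0"), file.path(d, "n0.csv"))
  expect_error(cli_simulate_one(c("--matrix", file.path(d, "A.csv"),
                                  "--equilibrium", file.path(d, "n0.csv"))),
               "strictly positive")
  write_lines(c("1", "1", "1"), file.path(d, "n3.csv"))
  expect_error(cli_simulate_one(c("--matrix", file.path(d, "A.csv"),
                                  "--equilibrium", file.path(d, "n3.csv"))),
               "mismatch")
})

test_that("phase-plane tables contain the saddle geometry", {
  d <- tempfile()
  cli_phase_plane(c("--params", "r1=-1,r2=-1,a11=-1,a12=2,a21=2,a22=-1",
                    "--nmax", "10", "--resolution", "12", "--out-dir", d))
  eq <- readr::read_csv(file.path(d, "equilibria.csv"), show_col_types = FALSE)
  expect_true(any(eq$N1 == 0 & eq$N2 == 0))
  expect_true(any(eq$N1 == 1 & eq$N2 == 1 & eq$kind == "interior"))
  expect_true(any(eq$N1 == 10 & eq$N2 == 10 & eq$kind == "ceiling"))
  vf <- readr::read_csv(file.path(d, "vector_field.csv"), show_col_types = FALSE)
  expect_equal(nrow(vf), 144)
  expect_error(cli_phase_plane(c("--params", "r1=-1,junk")), "malformed")
})

test_that("the dispatcher routes subcommands and rejects unknown ones", {
  expect_error(glv_cli("frobnicate"), "unknown subcommand")
  expect_message(glv_cli(character(0)), "usage")
})
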