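minimal_config_yaml <- function(extra = "") {
  paste0(
"n: 200
n_sim: 4
seed: 9
unmeasured_confounders:
  - kind: normal
    mean: 0
    variance: 1
exposure:
  family: normal
  gamma_u: [1.0]
mediator:
  family: normal
  alpha_a: 0.5
  alpha_u: [1.0]
outcome:
  family: normal
  beta_a: 0.3
  beta_m: 0.8
  beta_u: [1.0]
", extra)
}

write_tmp_config <- function(text) {
  f <- tempfile(fileext = ".yaml")
  writeLines(text, f)
  f
}

test_that("a minimal config loads with all documented defaults", {
  cfg <- load_config(write_tmp_config(minimal_config_yaml()))
  expect_s3_class(cfg, "umed_config")
  expect_equal(cfg$n, 200L)
  expect_equal(cfg$master_seed, 9L)
  expect_equal(cfg$options$n_draws, 1000L)
  expect_equal(cfg$options$alpha, 0.05)
  expect_equal(cfg$options$treat, 1)
  expect_equal(cfg$options$control, 0)
  expect_false(cfg$options$interaction)
  expect_equal(cfg$scenario$mediator$sigma, 1)
  expect_null(cfg$sweep_grid)
})

test_that("config validation names the offending key", {
  no_n <- sub("n: 200\n", "", minimal_config_yaml())
  expect_error(load_config(write_tmp_config(no_n)), "'n'")
  bad_key <- paste0(minimal_config_yaml(), "bogus_key: 1\n")
  expect_error(load_config(write_tmp_config(bad_key)), "bogus_key")
  bad_nested <- sub("alpha_a: 0.5", "alpha_x: 0.5", minimal_config_yaml())
  expect_error(load_config(write_tmp_config(bad_nested)), "alpha_x")
  bad_len <- sub("gamma_u: \\[1.0\\]", "gamma_u: [1.0, 2.0]",
                 minimal_config_yaml())
  expect_error(load_config(write_tmp_config(bad_len)), "gamma_u")
  expect_error(load_config(tempfile()), "not found")
})

test_that("configurations round-trip through write_config", {
  cfg <- load_config(write_tmp_config(paste0(minimal_config_yaml(),
                                             "sweep_grid: [0, 1, 2]\n")))
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  expect_equal(load_config(f), cfg)
})

test_that("study reports are complete, exact and deterministic", {
  sc <- linear_scenario(u_effect = 1)
  st <- run_umediation(sc, 120, 4, master_seed = 2,
                       options = mediation_options(n_draws = 120))
  prefix <- file.path(tempfile("report"), "study")
  files <- write_report(st, prefix)
  expect_true(all(file.exists(files)))

  j <- jsonlite::read_json(paste0(prefix, "_summary.json"))
  expect_equal(as.numeric(j$prop_match_mediated),
               st$summary$prop_match_mediated)
  expect_equal(as.numeric(j$avg_abs_diff_acme), st$summary$avg_abs_diff_acme,
               tolerance = 1e-14)

  # byte-identical on rewrite
  before <- lapply(files, readLines)
  write_report(st, prefix)
  expect_identical(lapply(files, readLines), before)

  # the CSV is a complete audit trail: summarising the read-back records
  # reproduces every summary number
  recs <- read_records(paste0(prefix, "_records.csv"))
  s2 <- summarize_records(recs)
  for (f in setdiff(names(st$summary), "avg_correlations"))
    expect_equal(s2[[f]], st$summary[[f]], info = f)
  expect_equal(s2$avg_correlations, st$summary$avg_correlations)
})

test_that("sweep reports round-trip and drive the plot", {
  sc <- linear_scenario(u_effect = 1)
  sw <- sweep_confounder_effect(sc, grid = c(0, 1, 2), n = 120, n_sim = 3,
                                master_seed = 8,
                                options = mediation_options(n_draws = 120))
  prefix <- file.path(tempfile("sweep"), "copd")
  files <- write_report(sw, prefix)
  expect_true(all(file.exists(files)))
  csv <- read.csv(paste0(prefix, "_sweep.csv"))
  expect_equal(nrow(csv), 3)
  expect_equal(csv$effect, c(0, 1, 2))
  expect_equal(csv$prop_match_mediated,
               vapply(sw$summaries, `[[`, 0, "prop_match_mediated"))

  back <- read_sweep_json(paste0(prefix, "_sweep.json"))
  expect_equal(back$grid, sw$grid)
  expect_equal(
    vapply(back$summaries, function(s) as.numeric(s$prop_match_direct), 0),
    vapply(sw$summaries, `[[`, 0, "prop_match_direct"))

  p <- plot_sweep(back)
  expect_s3_class(p, "ggplot")
  expect_equal(sort(unique(p$data$effect)), c(0, 1, 2))
  # the plotted series are a pure view of the summary fields
  med <- p$data[p$data$series == "mediated effect", ]
  expect_equal(med$proportion[order(med$effect)],
               vapply(sw$summaries, `[[`, 0, "prop_match_mediated"))

  png_path <- file.path(tempfile("plots"), "sweep.png")
  plot_sweep(list(`1 U` = sw, `2 U` = sw), path = png_path)
  expect_true(file.exists(png_path))
})

test_that("single-point sweeps are refused by the plot with guidance", {
  sc <- linear_scenario(u_effect = 1)
  sw1 <- sweep_confounder_effect(sc, grid = 1, n = 120, n_sim = 2,
                                 master_seed = 4,
                                 options = mediation_options(n_draws = 120))
  expect_error(plot_sweep(sw1), "write_report")
})

test_that("the command-line interface runs, partitions and merges studies", {
  cli <- system.file("cli", "umediate.R", package = "umediate")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  cfg <- write_tmp_config(paste0(minimal_config_yaml(),
                                 "options:\n  n_draws: 120\n"))
  dir <- tempfile("cli")
  dir.create(dir)
  run_cli <- function(...) {
    out <- system2(rscript, c(cli, ...), stdout = TRUE, stderr = TRUE)
    expect_null(attr(out, "status"))
    out
  }
  run_cli("run", "--config", cfg, "--out", file.path(dir, "full"))
  expect_true(file.exists(file.path(dir, "full_summary.json")))

  # split the same study across two "nodes" and merge the record files
  run_cli("run", "--config", cfg, "--out", file.path(dir, "a"),
          "--iterations", "1:2")
  run_cli("run", "--config", cfg, "--out", file.path(dir, "b"),
          "--iterations", "3:4")
  run_cli("merge", "--out", file.path(dir, "merged"),
          file.path(dir, "a_records.csv"), file.path(dir, "b_records.csv"))
  expect_identical(readLines(file.path(dir, "merged_summary.json")),
                   readLines(file.path(dir, "full_summary.json")))
})
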