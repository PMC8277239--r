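test_that("configs validate and presets are complete", {
  expect_error(validate_config(list(kind = "nope", seed = 1)), "kind")
  expect_error(validate_config(list(kind = "fmprc")), "seed")
  ok <- validate_config(list(kind = "fmprc", seed = 3))
  expect_invisible(validate_config(list(kind = "fmprc", seed = 3)))
  for (nm in c("table1_ing", "table1_ping", "table2_ing", "table2_ping")) {
    expect_true(length(network_preset(nm)) > 5)
  }
  expect_equal(network_preset("table2_ing")$eta_i, 20)
  expect_equal(network_preset("table1_ing")$W, 3e-2)
})

test_that("yaml round trip preserves an experiment config", {
  cfg <- list(kind = "fmprc", seed = 11, cv = 0.1, amplitude = -800)
  path <- tempfile(fileext = ".yml")
  yaml::write_yaml(cfg, path)
  back <- read_experiment_config(path)
  expect_equal(back[names(cfg)], cfg)
})

test_that("experiments are deterministic and write their outputs", {
  cfg <- list(kind = "fmprc", seed = 5, cv = 0.15, n = 150, W = 0.1,
              n_phases = 8, out_dir = tempfile())
  a <- run_experiment(cfg)
  b <- run_experiment(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(file.exists(file.path(cfg$out_dir, "fmprc.csv")))
  expect_true(file.exists(file.path(cfg$out_dir, "fmprc_meta.yml")))
  tab <- read.csv(file.path(cfg$out_dir, "fmprc.csv"))
  expect_equal(nrow(tab), 8)
  # rerun is idempotent on disk
  run_experiment(cfg)
  expect_identical(read.csv(file.path(cfg$out_dir, "fmprc.csv")), tab)
})

test_that("bias vectors export to csv in the documented layout", {
  b <- gaussian_bias_quantiles(20.4, 0.1, 10)
  path <- tempfile(fileext = ".csv")
  write_bias_csv(b, path)
  tab <- read.csv(path)
  expect_equal(names(tab), c("index", "value"))
  expect_equal(tab$value, b)
})

test_that("the shipped example config validates", {
  path <- system.file("extdata", "fmprc_desk.yml", package = "gammaprc")
  cfg <- read_experiment_config(path)
  expect_equal(cfg$kind, "fmprc")
  expect_equal(cfg$amplitude, -1600)
})
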