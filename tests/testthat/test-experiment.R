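test_that("experiment configs parse, validate and hash stably", {
  path <- withr::local_tempfile(lines = c(
    "# demo config",
    "task = linear",
    "n_bins = 80   # inline comment",
    "seed = 3"))
  cfg <- read_experiment_config(path)
  expect_equal(cfg$task, "linear")
  expect_equal(cfg$n_bins, "80")
  expect_equal(cfg$seed, "3")
  expect_identical(config_hash(cfg), config_hash(cfg))
  expect_false(identical(config_hash(cfg),
                         config_hash(c(cfg, list(lr = "0.1")))))
  expect_error(read_experiment_config(withr::local_tempfile(
    lines = c("task = gcn", "bogus_key = 1"))), "unknown config key")
  expect_error(read_experiment_config(withr::local_tempfile(
    lines = c("task = gcn", "task = linear"))), "duplicate")
  expect_error(read_experiment_config(withr::local_tempfile(
    lines = "just some words")), "malformed")
  expect_error(read_experiment_config(withr::local_tempfile(
    lines = "n_bins = 50")), "task")
  expect_error(read_experiment_config("/nonexistent/x.cfg"), "no such config")
})

test_that("the simulate task writes matrix and label artifacts", {
  out <- withr::local_tempdir()
  cfg <- list(task = "simulate", n_bins = "60", n_segments = "2",
              min_len = "5", max_len = "8", seed = "2")
  run_experiment(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "matrix.tsv")))
  expect_true(file.exists(file.path(out, "labels.bed")))
  expect_true(file.exists(file.path(out, "run_info.json")))
  expect_true(file.exists(file.path(out, "run.log")))
  m <- read_contact_matrix(file.path(out, "matrix.tsv"))
  expect_equal(m$n_bins, 60)
  info <- jsonlite::read_json(file.path(out, "run_info.json"))
  expect_equal(info$package, "cnvhic")
  expect_match(info$config_hash, "^[0-9a-f]{8}$")
})

test_that("identical configs produce byte-identical metrics", {
  cfg <- list(task = "linear", n_bins = "80", n_segments = "3",
              min_len = "6", max_len = "10", seed = "5",
              linear_epochs = "200")
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  run_experiment(cfg, out_dir = out1)
  run_experiment(cfg, out_dir = out2)
  expect_identical(readLines(file.path(out1, "metrics.json")),
                   readLines(file.path(out2, "metrics.json")))
  expect_true(file.exists(file.path(out1, "linear_model.json")))
  expect_true(file.exists(file.path(out1, "loss.tsv")))
})

test_that("the packaged demo config reproduces its documented task", {
  demo <- system.file("extdata", "gcn-demo.cfg", package = "cnvhic")
  expect_true(nzchar(demo))
  cfg <- read_experiment_config(demo)
  expect_equal(cfg$task, "gcn")
  out <- withr::local_tempdir()
  run_experiment(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_true(file.exists(file.path(out, "embedding.tsv")))
  m <- jsonlite::read_json(file.path(out, "metrics.json"))
  expect_gt(m$accuracy, 0.5)
})

test_that("the perturbation-suite task emits five reports plus a baseline", {
  suite_cfg <- system.file("extdata", "perturbation-suite.cfg",
                           package = "cnvhic")
  cfg <- read_experiment_config(suite_cfg)
  ## shrink to a smoke-test size; artifact contract is what matters here
  cfg$n_bins <- "80"; cfg$n_segments <- "3"; cfg$min_len <- "6"
  cfg$max_len <- "10"; cfg$embed_epochs <- "1"; cfg$gcn_epochs <- "30"
  cfg$perturb_seeds <- "1"
  out <- withr::local_tempdir()
  run_experiment(cfg, out_dir = out)
  reports <- list.files(out, pattern = "^report_.*\\.json$")
  expect_length(reports, 6)  # 5 perturbations + 1 baseline
  expect_true("report_none.json" %in% reports)
  expect_setequal(reports, paste0("report_",
                                  c("none", "label_reconstruction",
                                    "label_shuffle", "row_shuffle",
                                    "value_shuffle", "value_noise"), ".json"))
  res <- utils::read.table(file.path(out, "perturbation_results.tsv"),
                           header = TRUE)
  expect_equal(nrow(res), 6)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
})

test_that("unknown tasks fail with a clear message", {
  expect_error(run_experiment(list(task = "frobnicate"),
                              out_dir = withr::local_tempdir()),
               "unknown task")
})
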