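test_that("manifest round-trips and validates", {
  expect_error(study_manifest(list(list(id = "a")), "out"), "exam1")
  cfg <- analysis_config(registration_mode = "surface",
                         bone_threshold_hu = c(550, 600))
  man <- study_manifest(
    pairs = list(list(id = "p1", exam1 = "a.mha", exam2 = "b.mha"),
                 list(id = "p2", exam1 = "c.mha", exam2 = "d.mha",
                      config = list(bone_threshold_hu = 400))),
    output_dir = "out", seed = 9L, config = cfg,
    dlp_mgy_cm = c(15.5, 14.2))
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(man, path)
  back <- read_manifest(path)
  expect_identical(back$seed, 9L)
  expect_identical(back$config$registration_mode, "surface")
  expect_identical(back$config$bone_threshold_hu, c(550, 600))
  expect_identical(back$dlp_mgy_cm, c(15.5, 14.2))
  expect_identical(back$pairs[[2]]$config$bone_threshold_hu, 400L)
})

test_that("run_study analyses pairs, isolates failures and is reproducible", {
  dir <- withr::local_tempdir()
  # two good pairs plus one with an unreadable exam
  pairs <- list()
  for (i in 1:2) {
    spec <- small_spec(60L + i)
    repo <- sample_repositioning(2, 1.5, seed = 70L + i)
    pair <- generate_phantom_pair(spec, repositioning = repo)
    e1 <- file.path(dir, sprintf("p%d_e1.mha", i))
    e2 <- file.path(dir, sprintf("p%d_e2.mha", i))
    write_volume(pair$exam1, e1)
    write_volume(pair$exam2, e2)
    pairs[[i]] <- list(id = sprintf("p%d", i), exam1 = e1, exam2 = e2)
  }
  pairs[[3]] <- list(id = "broken", exam1 = file.path(dir, "missing.mha"),
                     exam2 = pairs[[1]]$exam2)
  out1 <- file.path(dir, "run1")
  man <- study_manifest(pairs, out1, seed = 5L,
                        config = analysis_config(
                          registration_mode = "surface"),
                        dlp_mgy_cm = c(15, 16, 15, 16))
  res <- run_study(man)
  expect_identical(length(res$migrations), 2L)
  expect_identical(names(res$excluded), "broken")
  expect_true(file.exists(file.path(out1, "migrations.csv")))
  expect_true(file.exists(file.path(out1, "precision.csv")))
  expect_true(file.exists(file.path(out1, "doses.csv")))
  expect_true(file.exists(file.path(out1, "study.log")))
  expect_identical(nrow(utils::read.csv(file.path(out1, "precision.csv"))),
                   6L)
  doses <- utils::read.csv(file.path(out1, "doses.csv"))
  expect_identical(doses$effective_dose_msv, c(15, 16, 15, 16) * 0.0129)
  # near-zero migration on zero-motion doubles
  expect_lt(max(abs(res$precision$surface$mean[1:3])), 0.1)

  # re-running the same manifest reproduces the migration table verbatim
  out2 <- file.path(dir, "run2")
  man2 <- study_manifest(pairs, out2, seed = 5L,
                         config = analysis_config(
                           registration_mode = "surface"),
                         dlp_mgy_cm = c(15, 16, 15, 16))
  run_study(man2)
  expect_identical(readLines(file.path(out1, "migrations.csv")),
                   readLines(file.path(out2, "migrations.csv")))
})

test_that("the CLI dispatches dose and precision subcommands", {
  out <- utils::capture.output(ctmotion_cli(c("dose", "--dlp", "100,200")))
  expect_true(any(grepl("1.29", out)))
  expect_identical(ctmotion_cli(character(0)), 0L)
  expect_error(ctmotion_cli("frobnicate"), "unknown subcommand")

  mig <- list(
    migration_result(c(0.1, 0, 0), c(0, 0, 0.2), c(0, 0, 0), id = "a",
                     mode = "beads"),
    migration_result(c(-0.1, 0, 0), c(0, 0, -0.2), c(0, 0, 0), id = "b",
                     mode = "beads"))
  tab <- withr::local_tempfile(fileext = ".csv")
  write_migration_table(mig, tab)
  pout <- withr::local_tempfile(fileext = ".csv")
  txt <- utils::capture.output(
    ctmotion_cli(c("precision", "--table", tab, "--out", pout)))
  expect_true(file.exists(pout))
  prec <- utils::read.csv(pout)
  expect_equal(prec$sd[1], stats::sd(c(0.1, -0.1)), tolerance = 1e-6)
})
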