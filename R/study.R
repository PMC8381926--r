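#' Study manifest
#'
#' Describes a double-examination study: a list of examination pairs (paths
#' to CT volumes on disk), optional per-pair configuration overrides, an
#' output directory and a global seed from which all per-stage seeds are
#' derived.
#'
#' @param pairs a list; each element is a list with fields `id`, `exam1`,
#'   `exam2` (volume paths) and optionally `config` (a named list of
#'   [analysis_config()] overrides, e.g. a per-patient bone threshold).
#' @param output_dir directory for `migrations.csv`, `precision.csv`,
#'   `doses.csv` and `study.log`.
#' @param seed global integer seed.
#' @param config base [analysis_config()] applied to every pair before the
#'   per-pair overrides.
#' @param dlp_mgy_cm optional numeric vector of per-examination dose-length
#'   products; summarised into `doses.csv`.
#' @return An object of class `study_manifest`.
#' @export
study_manifest <- function(pairs, output_dir, seed = 1L,
                           config = analysis_config(),
                           dlp_mgy_cm = NULL) {
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  for (p in pairs) {
    if (is.null(p$id) || is.null(p$exam1) || is.null(p$exam2))
      stop("each pair needs fields id, exam1, exam2", call. = FALSE)
  }
  structure(list(pairs = pairs, output_dir = output_dir,
                 seed = as.integer(seed), config = config,
                 dlp_mgy_cm = dlp_mgy_cm),
            class = "study_manifest")
}

#' Read / write a study manifest
#'
#' @param manifest a [study_manifest()].
#' @param path JSON file path.
#' @return `write_manifest()`: `path` invisibly; `read_manifest()`: a
#'   `study_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "study_manifest"))
  x <- unclass(manifest)
  x$config <- unclass(x$config)
  x$config$anatomical_basis <- as.numeric(t(x$config$anatomical_basis))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg_args <- x$config
  if (!is.null(cfg_args$anatomical_basis))
    cfg_args$anatomical_basis <-
      matrix(as.numeric(unlist(cfg_args$anatomical_basis)), 3, 3,
             byrow = TRUE)
  for (nm in c("bone_threshold_hu", "bead_volume_range_mm3",
               "rotation_signs"))
    if (!is.null(cfg_args[[nm]]))
      cfg_args[[nm]] <- as.numeric(unlist(cfg_args[[nm]]))
  config <- do.call(analysis_config, cfg_args)
  study_manifest(pairs = x$pairs, output_dir = x$output_dir,
                 seed = x$seed, config = config,
                 dlp_mgy_cm = if (is.null(x$dlp_mgy_cm)) NULL
                 else as.numeric(unlist(x$dlp_mgy_cm)))
}

apply_config_overrides <- function(config, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(config)
  args <- unclass(config)
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (nm == "anatomical_basis" && !is.matrix(v))
      v <- matrix(as.numeric(unlist(v)), 3, 3, byrow = TRUE)
    if (is.list(v)) v <- unlist(v)
    args[[nm]] <- v
  }
  do.call(analysis_config, args)
}

#' Run a double-examination study
#'
#' Runs [run_ctma()] for every pair in the manifest, isolating per-pair
#' failures (a failing pair is excluded and reported, and the study
#' continues — the analogue of excluding a patient for marker occlusion),
#' aggregates the double-examination precision per registration mode, and
#' summarises effective doses when dose-length products are provided.
#' Outputs (`migrations.csv`, `precision.csv`, `doses.csv`, `study.log`)
#' are written to the manifest's output directory; re-running the same
#' manifest reproduces them.
#'
#' @param manifest a [study_manifest()] (or path to a manifest JSON).
#' @return A list with `migrations` (list of [migration_result()]),
#'   `excluded` (named character vector of failure messages), `precision`
#'   (list of `precision_report` per mode) and `doses` (a `dose_record` or
#'   `NULL`), invisibly.
#' @export
run_study <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "study_manifest"))
  out_dir <- manifest$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- c(sprintf("ctmotion study, seed = %d", manifest$seed),
                 sprintf("pairs: %d", length(manifest$pairs)))

  results <- list()
  excluded <- character(0)
  for (i in seq_along(manifest$pairs)) {
    p <- manifest$pairs[[i]]
    cfg <- apply_config_overrides(manifest$config, p$config)
    cfg$seed <- as.integer((as.double(manifest$seed) * 131071 + i) %%
                             2147483647)
    res <- tryCatch({
      e1 <- read_volume(p$exam1)
      e2 <- read_volume(p$exam2)
      run_ctma(e1, e2, cfg, id = p$id)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excluded[p$id] <- conditionMessage(res)
      log_lines <- c(log_lines,
                     sprintf("pair %s EXCLUDED: %s", p$id,
                             conditionMessage(res)))
    } else {
      results[[length(results) + 1L]] <- res
      log_lines <- c(log_lines,
                     sprintf("pair %s: ok (%s mode, gate %s)", p$id,
                             res$mode,
                             if (isTRUE(res$gate$pass)) "pass" else "FAIL"))
    }
  }

  if (length(results) > 0L)
    write_migration_table(results, file.path(out_dir, "migrations.csv"))

  modes <- unique(vapply(results, function(r) as.character(r$mode), ""))
  precision <- list()
  prec_rows <- list()
  for (m in modes) {
    in_mode <- Filter(function(r) identical(as.character(r$mode), m),
                      results)
    if (length(in_mode) >= 2L) {
      rep_m <- precision_from_doubles(in_mode)
      precision[[m]] <- rep_m
      df <- as.data.frame(rep_m)
      df$method <- attr(rep_m, "method_label")
      prec_rows[[m]] <- df
    }
  }
  if (length(prec_rows) > 0L)
    utils::write.csv(do.call(rbind, prec_rows),
                     file.path(out_dir, "precision.csv"),
                     row.names = FALSE)

  doses <- NULL
  if (!is.null(manifest$dlp_mgy_cm)) {
    doses <- effective_dose_from_dlp(
      manifest$dlp_mgy_cm,
      manifest$config$dose_factor_msv_per_mgy_cm)
    utils::write.csv(as.data.frame(doses),
                     file.path(out_dir, "doses.csv"), row.names = FALSE)
    log_lines <- c(log_lines,
                   sprintf("mean effective dose: %.4f mSv",
                           mean(doses$effective_dose_msv)))
  }
  writeLines(log_lines, file.path(out_dir, "study.log"))
  invisible(list(migrations = results, excluded = excluded,
                 precision = precision, doses = doses))
}

#' Simulate and analyse a reproducible demonstration study
#'
#' Generates `n_pairs` double examinations of the digital phantom with
#' identity migration and random repositioning, writes them to disk, runs
#' the study in the requested mode, and returns the study outputs. Serves
#' both as an end-to-end smoke test and as the `demo` CLI subcommand.
#'
#' @param out_dir output directory (volumes, manifest and result tables).
#' @param seed global seed.
#' @param n_pairs number of double examinations (default 10).
#' @param mode registration mode.
#' @param spec phantom specification; a desk-scale phantom by default.
#' @param max_translation_mm,max_rotation_deg repositioning bounds.
#' @return The [run_study()] output, invisibly.
#' @export
run_demo_study <- function(out_dir, seed = 1L, n_pairs = 10L,
                           mode = c("surface", "beads"),
                           spec = NULL,
                           max_translation_mm = 4, max_rotation_deg = 3) {
  mode <- match.arg(mode)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    pair_seed <- as.integer((as.double(seed) * 65537 + i) %% 2147483647)
    if (is.null(spec)) {
      sp <- phantom_spec(volume_shape = c(104L, 104L, 104L),
                         cup_outer_radius_mm = 14, seed = pair_seed)
    } else {
      sp <- spec
      sp$seed <- pair_seed
    }
    repo <- sample_repositioning(max_translation_mm, max_rotation_deg,
                                 seed = pair_seed + 1L)
    pair <- generate_phantom_pair(sp, repositioning = repo)
    d1 <- file.path(out_dir, sprintf("pair%02d_exam1.mha", i))
    d2 <- file.path(out_dir, sprintf("pair%02d_exam2.mha", i))
    write_volume(pair$exam1, d1)
    write_volume(pair$exam2, d2)
    pairs[[i]] <- list(id = sprintf("pair%02d", i), exam1 = d1, exam2 = d2)
  }
  manifest <- study_manifest(
    pairs, output_dir = out_dir, seed = seed,
    config = analysis_config(registration_mode = mode),
    dlp_mgy_cm = rep(15.5, 2L * n_pairs))
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  run_study(manifest)
}
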