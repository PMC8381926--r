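#' Small-sample coverage factor
#'
#' Two-sided Student-t quantile with `n - 1` degrees of freedom, used in
#' place of the asymptotic 1.96 when estimating double-examination
#' precision from a small number of patients: with few double examinations
#' a z-score would understate the margin of error. As `n` grows the factor
#' decreases monotonically towards the familiar 1.96 (at 95% confidence).
#'
#' @param n number of double examinations (>= 2).
#' @param level two-sided confidence level in (0, 1), default 0.95.
#' @return The coverage factor (scalar).
#' @examples
#' t_factor(10)   # 2.262
#' t_factor(1e6)  # ~1.96
#' @export
t_factor <- function(n, level = 0.95) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("t_factor requires n >= 2", call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  stats::qt(1 - (1 - level) / 2, df = n - 1)
}

#' Double-examination precision report
#'
#' Implements the repeatability analysis of the double-examination
#' protocol: each patient is examined twice in immediate succession with
#' repositioning, so the true migration is zero and the spread of the
#' measured migrations estimates the precision of the method. Per degree of
#' freedom the report gives the mean of the signed measured values (a bias
#' check), their standard deviation (n - 1 denominator), and the precision
#' bound `t_factor(n, level) * SD` — the small-sample analogue of the
#' 1.96 x SD 95% interval.
#'
#' @param migrations list of [migration_result()]s from double
#'   examinations; all must share the same frame and mode. At least 2.
#' @param level confidence level (default 0.95).
#' @param method_label label stored in the report (defaults to
#'   `"ctma_<mode>"`).
#' @return An object of class `precision_report`: a data.frame with one row
#'   per degree of freedom (`dof`, `n`, `mean`, `sd`, `precision_bound`)
#'   and attributes `confidence_level` and `method_label`.
#' @export
precision_from_doubles <- function(migrations, level = 0.95,
                                   method_label = NULL) {
  if (inherits(migrations, "migration_result"))
    migrations <- list(migrations)
  n <- length(migrations)
  if (n < 2L)
    stop("precision requires at least 2 double examinations", call. = FALSE)
  frames <- vapply(migrations, `[[`, "", "frame")
  modes <- vapply(migrations, function(m) as.character(m$mode), "")
  if (length(unique(frames)) > 1L)
    stop("all migrations must share the same frame", call. = FALSE)
  if (length(unique(modes)) > 1L)
    stop("all migrations must share the same mode", call. = FALSE)
  values <- t(vapply(migrations, function(m)
    c(m$translations_mm, m$rotations_deg), numeric(6)))
  dof_labels <- c("tx_mm", "ty_mm", "tz_mm", "rx_deg", "ry_deg", "rz_deg")
  tf <- t_factor(n, level)
  report <- data.frame(
    dof = dof_labels,
    n = n,
    mean = colMeans(values),
    sd = apply(values, 2L, stats::sd),
    stringsAsFactors = FALSE)
  report$precision_bound <- tf * report$sd
  if (is.null(method_label))
    method_label <- paste0("ctma_", modes[1])
  structure(report, class = c("precision_report", "data.frame"),
            confidence_level = level, method_label = method_label,
            t_factor = tf)
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf(
    "Double-examination precision (%s, %d%% level, coverage factor %.3f)\n",
    attr(x, "method_label"), round(100 * attr(x, "confidence_level")),
    attr(x, "t_factor")))
  df <- as.data.frame(x)
  df[c("mean", "sd", "precision_bound")] <-
    lapply(df[c("mean", "sd", "precision_bound")], round, digits = 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Effective dose from the dose-length product
#'
#' The standard clinical estimate: effective dose (mSv) is the CT
#' dose-length product (mGy cm) multiplied by a body-region conversion
#' factor. The default factor 0.0129 mSv/(mGy cm) is the pelvic
#' coefficient; pass another factor for other regions.
#'
#' @param dlp_mgy_cm dose-length product, >= 0 (vectorised).
#' @param factor conversion factor in mSv per mGy cm (default 0.0129).
#' @return An object of class `dose_record`: a data.frame with columns
#'   `dlp_mgy_cm`, `conversion_factor_msv_per_mgy_cm`,
#'   `effective_dose_msv`.
#' @examples
#' effective_dose_from_dlp(100)  # 1.29 mSv
#' @export
effective_dose_from_dlp <- function(dlp_mgy_cm, factor = 0.0129) {
  if (any(!is.finite(dlp_mgy_cm)) || any(dlp_mgy_cm < 0))
    stop("dlp_mgy_cm must be finite and >= 0", call. = FALSE)
  if (factor <= 0)
    stop("conversion factor must be positive", call. = FALSE)
  structure(data.frame(
    dlp_mgy_cm = dlp_mgy_cm,
    conversion_factor_msv_per_mgy_cm = factor,
    effective_dose_msv = dlp_mgy_cm * factor),
    class = c("dose_record", "data.frame"))
}
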