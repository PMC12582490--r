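# Validation-report assembly.
#
# Ties calibration, lack-of-fit, LOD/LOQ and recovery statistics into the
# two standard method-validation tables: a linearity table (regression
# equation, R2, range, lack-of-fit verdict) and a recovery/precision table
# (mean measured, recovery %, RSD % per spike level), with CSV and JSON
# writers that record the configuration used.

#' Assemble a method-validation report
#'
#' @param calibration Data frame with columns `name`, `conc_ugl`,
#'   `area_analyte`, `area_is`, `conc_is` (e.g. from
#'   [generate_calibration_set()] or a transcribed instrument export).
#' @param recovery Optional data frame with columns `name`, `spike_ngl`,
#'   `measured_ngl` and optionally `background` (e.g. from
#'   [generate_recovery_set()]).
#' @param alpha Significance level for the lack-of-fit test.
#' @param weighting Calibration weighting, see [fit_calibration()].
#' @return A list of class `pfas_validation`: `linearity` (per-compound
#'   slope, intercept, R2, range, F, F critical, verdict), `recovery`
#'   (per compound and spike level), `curves` (named list of `pfas_cal`),
#'   `settings`.
#' @export
validate_method <- function(calibration, recovery = NULL, alpha = 0.05,
                            weighting = "none") {
  need <- c("name", "conc_ugl", "area_analyte", "area_is", "conc_is")
  missing <- setdiff(need, names(calibration))
  if (length(missing))
    stop("calibration table missing column(s): ", paste(missing, collapse = ", "))
  if (!nrow(calibration)) stop("empty calibration table")
  curves <- list()
  lin <- lapply(split(calibration, calibration$name), function(d) {
    y <- is_response(d$area_analyte, d$area_is, d$conc_is)
    cal <- fit_calibration(d$conc_ugl, y, weighting = weighting)
    curves[[d$name[1]]] <<- cal
    lof <- tryCatch(lack_of_fit_test(d$conc_ugl, y, alpha = alpha),
                    error = function(e) NULL)
    data.frame(name = d$name[1], slope = cal$slope, intercept = cal$intercept,
               r2 = cal$r2, range_min = cal$range[1], range_max = cal$range[2],
               n_levels = cal$n_levels,
               F = if (is.null(lof)) NA_real_ else lof$F,
               F_crit = if (is.null(lof)) NA_real_ else lof$F_crit,
               verdict = if (is.null(lof)) "unreplicated"
                         else if (lof$linear) "linear" else "lack-of-fit",
               stringsAsFactors = FALSE)
  })
  linearity <- do.call(rbind, lin)
  rownames(linearity) <- NULL

  rec <- NULL
  if (!is.null(recovery) && nrow(recovery)) {
    groups <- split(recovery, list(recovery$name, recovery$spike_ngl), drop = TRUE)
    rec <- do.call(rbind, lapply(groups, function(d) {
      bg <- if ("background" %in% names(d)) d$background[1] else 0
      r <- recovery_precision(d$measured_ngl, d$spike_ngl[1], bg)
      data.frame(name = d$name[1], spike_ngl = d$spike_ngl[1], n = r$n,
                 mean_ngl = r$mean, recovery_pct = r$recovery, rsd_pct = r$rsd,
                 stringsAsFactors = FALSE)
    }))
    rec <- rec[order(rec$name, rec$spike_ngl), ]
    rownames(rec) <- NULL
  }
  structure(list(linearity = linearity, recovery = rec, curves = curves,
                 settings = list(alpha = alpha, weighting = weighting)),
            class = "pfas_validation")
}

#' @export
print.pfas_validation <- function(x, ...) {
  cat("<validation report> ", nrow(x$linearity), " compounds; ",
      sum(x$linearity$verdict == "linear"), " linear at alpha = ",
      x$settings$alpha, "\n", sep = "")
  invisible(x)
}

#' Write a validation report to disk
#'
#' Writes the linearity and recovery tables as CSV plus a combined JSON
#' document that records the settings and seed for reproducibility.
#'
#' @param report A `pfas_validation` from [validate_method()].
#' @param dir Output directory (created if needed).
#' @param seed Optional seed to record alongside the settings.
#' @return Invisibly, the paths written.
#' @export
write_validation_report <- function(report, dir, seed = NULL) {
  stopifnot(inherits(report, "pfas_validation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(linearity = file.path(dir, "linearity.csv"),
             json = file.path(dir, "validation_report.json"))
  utils::write.csv(report$linearity, paths["linearity"], row.names = FALSE)
  if (!is.null(report$recovery)) {
    paths["recovery"] <- file.path(dir, "recovery.csv")
    utils::write.csv(report$recovery, paths["recovery"], row.names = FALSE)
  }
  jsonlite::write_json(
    list(schema = "pfasprm-validation/1",
         settings = c(report$settings, list(seed = seed)),
         linearity = report$linearity, recovery = report$recovery),
    paths["json"], auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

#' Export predicted fragments for one or all compounds
#'
#' @param names Compound names, or `NULL` for the full registry.
#' @param registry A `pfas_registry`.
#' @return A data frame of predicted fragments with a `compound` column,
#'   m/z rounded half-up to 4 decimals in `mz_4dp` alongside the full-
#'   precision `mz`.
#' @export
fragment_table <- function(names = NULL, registry = pfas_registry()) {
  if (is.null(names)) names <- registry$name
  out <- do.call(rbind, lapply(names, function(nm) {
    f <- predict_fragments(nm, registry)
    cbind(compound = nm, f, mz_4dp = round_half_up(f$mz, 4))
  }))
  rownames(out) <- NULL
  out
}
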