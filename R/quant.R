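# Internal-standard calibration and method validation.
#
# The calibration response is y = (analyte area / IS area) x C_IS, plotted
# against the nominal analyte concentration x; the curve is an unweighted
# ordinary least-squares line. Linearity is judged by the lack-of-fit
# F-test: the residual sum of squares about the line decomposes into pure
# error (replicate scatter within concentration levels) and lack of fit
# (level means about the line), compared via F with (I-2, IJ-I) degrees of
# freedom at the 95% level. Detection and quantification limits follow the
# signal-to-noise convention with multipliers 3 and 10.

#' Internal-standard-normalized calibration response
#'
#' `y = (analyte area / IS area) * C_IS`, which carries concentration units
#' so the calibration slope is dimensionless recovery of response per unit
#' concentration.
#'
#' @param area_analyte,area_is Peak areas (IS area must be positive).
#' @param conc_is Internal-standard concentration (ug/L), default 5.0.
#' @return Numeric response vector (ug/L scale).
#' @export
is_response <- function(area_analyte, area_is, conc_is = 5.0) {
  if (any(area_is <= 0))
    stop("internal-standard area is zero or negative: IS failure for this injection")
  if (any(conc_is <= 0)) stop("conc_is must be positive")
  (area_analyte / area_is) * conc_is
}

#' Fit an internal-standard calibration curve
#'
#' Unweighted ordinary least squares of the IS-normalized response on the
#' nominal concentration. A 1/x-weighted fit is available behind
#' `weighting = "1/x"` but is off by default.
#'
#' @param conc Nominal concentrations (ug/L); at least 3 distinct levels.
#' @param response Responses from [is_response()], same length.
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return A list of class `pfas_cal`: `slope`, `intercept`, `r2` (squared
#'   Pearson correlation of fitted vs observed response), `residuals`,
#'   `range` (min/max concentration), `n_levels`, `fit` (the `lm` object).
#' @export
fit_calibration <- function(conc, response, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  stopifnot(length(conc) == length(response))
  if (length(unique(conc)) < 3)
    stop("calibration needs at least 3 distinct concentration levels")
  if (stats::var(conc) == 0) stop("zero variance in concentration")
  if (stats::var(response) == 0)
    stop("response is constant across levels (zero slope)")
  w <- if (weighting == "1/x") 1 / conc else NULL
  fit <- stats::lm(response ~ conc, weights = w)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = stats::cor(stats::fitted(fit), response)^2,
    residuals = unname(stats::residuals(fit)),
    range = range(conc),
    n_levels = length(unique(conc)),
    weighting = weighting,
    fit = fit
  ), class = "pfas_cal")
}

#' @export
print.pfas_cal <- function(x, ...) {
  cat(sprintf("<calibration> y = %.6g x %s %.6g, R2 = %.4f, range %g-%g ug/L (%d levels)\n",
              x$slope, ifelse(x$intercept < 0, "-", "+"), abs(x$intercept),
              x$r2, x$range[1], x$range[2], x$n_levels))
  invisible(x)
}

#' Inverse prediction from a calibration curve
#'
#' @param cal A `pfas_cal` object.
#' @param response Observed response(s).
#' @return Predicted concentration(s), `(y - intercept) / slope`.
#' @export
predict_conc <- function(cal, response) {
  stopifnot(inherits(cal, "pfas_cal"))
  (response - cal$intercept) / cal$slope
}

#' Lack-of-fit F-test for calibration linearity
#'
#' Decomposes the residual sum of squares about the fitted line (`SS_r`)
#' into pure error (`SS_eps`, replicate scatter within levels) and lack of
#' fit (`SS_lof`, level means about the line), and compares
#' `F = (SS_lof / (I-2)) / (SS_eps / (IJ-I))` with the upper-alpha F
#' quantile on (I-2, IJ-I) degrees of freedom. The line is accepted as
#' linear when F is below the critical value.
#'
#' @param conc,response Calibration data; a balanced design with I >= 3
#'   levels and J >= 2 replicates per level is required.
#' @param alpha Significance level (default 0.05, i.e. 95% confidence).
#' @return A list of class `pfas_lof`: `I`, `J`, `ss_r`, `ss_eps`,
#'   `ss_lof`, `df` (numerator, denominator), `F`, `F_crit`, `p_value`,
#'   `linear` (logical verdict).
#' @export
lack_of_fit_test <- function(conc, response, alpha = 0.05) {
  stopifnot(length(conc) == length(response))
  levels_ <- sort(unique(conc))
  I <- length(levels_)
  if (I < 3) stop("lack-of-fit test needs at least 3 concentration levels")
  counts <- table(conc)
  if (any(counts < 2))
    stop("lack-of-fit test requires replicated levels (J >= 2 at every level)")
  if (length(unique(counts)) != 1)
    stop("lack-of-fit test requires a balanced design (equal replicates per level)")
  J <- unname(counts[1])
  fit <- stats::lm(response ~ conc)
  ss_r <- sum(stats::residuals(fit)^2)
  level_means <- tapply(response, conc, mean)[as.character(conc)]
  ss_eps <- sum((response - level_means)^2)
  ss_lof <- ss_r - ss_eps
  df1 <- I - 2
  df2 <- I * J - I
  # numerically exact data: both components vanish and the ratio is taken as 0
  tiny <- 1e-12 * (sum(response^2) + 1)
  Fstat <- if (ss_eps <= tiny && ss_lof <= tiny) 0
           else (ss_lof / df1) / (ss_eps / df2)
  Fcrit <- stats::qf(1 - alpha, df1, df2)
  structure(list(I = I, J = J, ss_r = ss_r, ss_eps = ss_eps,
                 ss_lof = max(ss_lof, 0), df = c(df1, df2), F = Fstat,
                 F_crit = Fcrit, p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
                 alpha = alpha, linear = Fstat < Fcrit), class = "pfas_lof")
}

#' @export
print.pfas_lof <- function(x, ...) {
  cat(sprintf("<lack-of-fit> I = %d, J = %d: F(%d,%d) = %.3f vs critical %.2f -> %s\n",
              x$I, x$J, x$df[1], x$df[2], x$F, x$F_crit,
              if (x$linear) "linear" else "lack of fit"))
  invisible(x)
}

#' Signal-to-noise based LOD and LOQ
#'
#' From the signal-to-noise ratio observed at a known spike level:
#' `LOD = 3 * spike / SN`, `LOQ = 10 * spike / SN` (multipliers
#' configurable). When an XIC is supplied, S/N is its peak height over its
#' baseline noise SD.
#'
#' @param spike Spike concentration (same units as the returned limits,
#'   typically ng/L).
#' @param sn Signal-to-noise ratio; alternatively supply `xic`.
#' @param xic Optional `pfas_xic` from a spiked blank.
#' @param multipliers Length-2 numeric, S/N multipliers for LOD and LOQ.
#' @return A list of class `pfas_lod`: `lod`, `loq`, `sn`, `spike`,
#'   `flag` (`"ok"`, `"not-detected"` — limits reported as above the spike
#'   level — or `"below-noise-floor"` for a noiseless trace).
#' @export
lod_loq <- function(spike, sn = NULL, xic = NULL, multipliers = c(3, 10)) {
  stopifnot(spike > 0, length(multipliers) == 2)
  flag <- "ok"
  if (is.null(sn)) {
    stopifnot(inherits(xic, "pfas_xic"))
    if (!xic$found) {
      return(structure(list(lod = NA_real_, loq = NA_real_, sn = NA_real_,
                            spike = spike, flag = "not-detected"),
                       class = "pfas_lod"))
    }
    if (xic$noise_sd <= 1e-8 * max(xic$height, 1)) {
      # numerically noiseless trace: the S/N definition has no floor here
      sn <- Inf
      flag <- "below-noise-floor"
    } else sn <- xic$height / xic$noise_sd
  }
  if (sn <= 0) stop("signal-to-noise ratio must be positive")
  structure(list(lod = multipliers[1] * spike / sn,
                 loq = multipliers[2] * spike / sn,
                 sn = sn, spike = spike, flag = flag), class = "pfas_lod")
}

#' @export
print.pfas_lod <- function(x, ...) {
  if (x$flag == "not-detected")
    cat("<lod/loq> no detectable peak: LOD > ", x$spike, "\n", sep = "")
  else
    cat(sprintf("<lod/loq> S/N = %.3g at spike %g: LOD = %.3g, LOQ = %.3g (%s)\n",
                x$sn, x$spike, x$lod, x$loq, x$flag))
  invisible(x)
}

#' Recovery and precision from replicate spiked measurements
#'
#' @param measured Replicate measured concentrations (n >= 2).
#' @param spike Spiked concentration (> 0), same units.
#' @param background Matrix background; `"n.d."` (or `NA`) counts as 0.
#' @return A list of class `pfas_recovery`: `n`, `mean`, `recovery`
#'   (percent, `(mean - background) / spike * 100`), `rsd` (percent,
#'   `100 * sd / mean`), `spike`, `background`.
#' @examples
#' recovery_precision(c(4.6, 4.7, 4.72), spike = 5)
#' @export
recovery_precision <- function(measured, spike, background = 0) {
  if (spike <= 0) stop("spike level must be positive")
  if (length(measured) < 2) stop("need at least 2 replicate measurements")
  if (is.character(background) || is.na(background)) {
    bg <- suppressWarnings(as.numeric(background))
    background <- if (is.na(bg)) 0 else bg
  }
  m <- mean(measured)
  structure(list(n = length(measured), mean = m,
                 recovery = (m - background) / spike * 100,
                 rsd = 100 * stats::sd(measured) / m,
                 spike = spike, background = background),
            class = "pfas_recovery")
}

#' @export
print.pfas_recovery <- function(x, ...) {
  cat(sprintf("<recovery> spike %g: mean %.3g, recovery %.1f%%, RSD %.1f%% (n = %d)\n",
              x$spike, x$mean, x$recovery, x$rsd, x$n))
  invisible(x)
}

#' Quantify a PRM run against fitted calibration curves
#'
#' For each registry compound: extracts the quantifier-transition XIC and
#' the assigned internal standard's XIC from the run, forms the
#' IS-normalized response, inverse-predicts the extract concentration from
#' the compound's calibration curve, and converts to a water concentration.
#' With the default 1000-fold solid-phase-extraction preconcentration
#' (200 mL water into 200 uL extract), 1 ug/L in the extract corresponds to
#' 1 ng/L in water.
#'
#' Values below the LOD report `"n.d."`, between LOD and LOQ `"<LOQ"`, and
#' responses above the calibration range `"over range"` (no extrapolated
#' value).
#'
#' @param run A `prm_run` whose schedule includes `IS:<name>` channels.
#' @param curves Named list of `pfas_cal` objects (names = compounds).
#' @param registry A `pfas_registry`.
#' @param lod_table Optional data frame (`name`, `lod_ngl`, `loq_ngl`); by
#'   default the registry's columns are used.
#' @param conc_is Internal-standard concentration in the extract (ug/L).
#' @param preconcentration Water-to-extract volume ratio.
#' @param tol_ppm Extraction tolerance in ppm.
#' @return A data frame: `name`, `conc_ngl` (NA when flagged), `flag` in
#'   `{"ok", "n.d.", "<LOQ", "over range", "no curve", "IS failure",
#'   "not acquired"}` (the last for channels absent from the run),
#'   `response`, `area_analyte`, `area_is`.
#' @export
quantify_sample <- function(run, curves, registry = pfas_registry(),
                            lod_table = NULL, conc_is = 5.0,
                            preconcentration = 1000, tol_ppm = 5) {
  stopifnot(inherits(run, "prm_run"))
  iss <- internal_standards(registry)
  rows <- lapply(registry$name, function(nm) {
    row <- registry_compound(nm, registry)
    out <- data.frame(name = nm, conc_ngl = NA_real_, flag = "no curve",
                      response = NA_real_, area_analyte = NA_real_,
                      area_is = NA_real_, stringsAsFactors = FALSE)
    tr <- diagnostic_transition(nm, registry)
    win <- c(row$rt_min - 0.5, row$rt_min + 0.5)
    xic <- extract_xic(run, row$precursor_mz_theo, tr$product_mz_theo,
                       tol_ppm = tol_ppm, rt_range = win)
    out$area_analyte <- xic$area
    if (xic$empty) {
      out$flag <- "not acquired"
      return(out)
    }
    isrow <- iss[iss$is_name == row$internal_standard, ]
    is_win <- c(isrow$rt_min - 0.5, isrow$rt_min + 0.5)
    is_xic <- extract_xic(run, isrow$precursor_mz, isrow$product_mz,
                          tol_ppm = tol_ppm, rt_range = is_win)
    out$area_is <- is_xic$area
    if (!is_xic$found || is_xic$area <= 0) {
      out$flag <- "IS failure"
      return(out)
    }
    cal <- curves[[nm]]
    if (is.null(cal)) return(out)
    y <- is_response(xic$area, is_xic$area, conc_is)
    out$response <- y
    x_ugl <- predict_conc(cal, y)
    if (x_ugl > cal$range[2]) {
      out$flag <- "over range"
      return(out)
    }
    # extract ug/L -> water ng/L: x(ng/L water) = x(ug/L extract) * 1000 / preconcentration
    ngl <- x_ugl * 1000 / preconcentration
    lim <- if (is.null(lod_table)) row else
      lod_table[lod_table$name == nm, , drop = FALSE]
    if (!xic$found || ngl < lim$lod_ngl) {
      out$flag <- "n.d."
    } else if (ngl < lim$loq_ngl) {
      out$flag <- "<LOQ"
    } else {
      out$flag <- "ok"
      out$conc_ngl <- ngl
    }
    out
  })
  do.call(rbind, rows)
}
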