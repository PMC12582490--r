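# Synthetic PRM data with recorded ground truth.
#
# The generator emulates the acquisition design of the targeted method:
# segmented PRM scanning in +/-0.5 min windows around each compound's
# retention time, Gaussian chromatographic peaks (default sigma 3 s), a
# cycle time chosen so that at least eight data points fall across a peak,
# internal standards co-generated at 5.0 ug/L, and analyte response
# following the registry's internal-standard calibration line
# y = slope * x + intercept. Fragment spectra are built from the
# rule-engine predictions with a fixed, purely conventional relative
# intensity profile. All randomness flows from one seed; planted values are
# returned as machine-readable ground truth.

#' Configuration for the synthetic PRM generator
#'
#' @param conc_ugl Named numeric vector: extract-scale concentration (ug/L)
#'   per compound (names must exist in the registry; zero is allowed and
#'   yields a signal-free channel). With the method's 1000-fold SPE
#'   preconcentration, 1 ug/L extract corresponds to 1 ng/L water.
#' @param sigma_s Chromatographic peak SD in seconds.
#' @param cycle_s PRM cycle time in seconds; must give >= 8 points across
#'   the peak width at 1% of apex height (6.07 sigma).
#' @param rt_half_width Acquisition window half width in minutes.
#' @param baseline_mean,baseline_sd Additive baseline noise (counts) applied
#'   to every trace point.
#' @param area_cv Multiplicative relative SD applied per injection to each
#'   planted peak area.
#' @param mz_jitter_ppm Gaussian mass-error SD applied to observed peak m/z.
#' @param conc_is Internal-standard concentration (ug/L).
#' @param is_area Nominal internal-standard peak area (arbitrary counts x
#'   minutes).
#' @param rel_profile Relative fragment intensity profile: quantifier,
#'   precursor, base and geometric decay for the remaining fragments. A
#'   fixed convention with no physical claim.
#' @param seed Integer seed; fixed seed implies identical output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(conc_ugl = numeric(0), sigma_s = 3, cycle_s = 1.5,
                         rt_half_width = 0.5, baseline_mean = 0,
                         baseline_sd = 0, area_cv = 0, mz_jitter_ppm = 0,
                         conc_is = 5.0, is_area = 5e5,
                         rel_profile = c(quantifier = 1, precursor = 0.45,
                                         other = 0.3, decay = 0.6),
                         seed = NULL) {
  stopifnot(sigma_s > 0, cycle_s > 0, rt_half_width > 0, conc_is > 0,
            is_area > 0, area_cv >= 0, baseline_sd >= 0)
  if (length(conc_ugl) && is.null(names(conc_ugl)))
    stop("conc_ugl must be a named vector of compound concentrations")
  if (any(conc_ugl < 0)) stop("concentrations must be non-negative")
  ppp <- 6.07 * sigma_s / cycle_s
  if (ppp < 8)
    stop(sprintf("cycle time %g s gives only %.1f points per peak (need >= 8); shorten the cycle or widen sigma",
                 cycle_s, ppp))
  structure(list(conc_ugl = conc_ugl, sigma_s = sigma_s, cycle_s = cycle_s,
                 rt_half_width = rt_half_width, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, area_cv = area_cv,
                 mz_jitter_ppm = mz_jitter_ppm, conc_is = conc_is,
                 is_area = is_area, rel_profile = rel_profile, seed = seed),
            class = "synth_config")
}

.mult_noise <- function(n, cv) {
  if (cv <= 0) rep(1, n) else pmax(1 + stats::rnorm(n, 0, cv), 0.05)
}

.gauss_trace <- function(t, rt, sigma_min, area) {
  area * stats::dnorm(t, mean = rt, sd = sigma_min)
}

#' Generate a synthetic PRM run
#'
#' Builds a PRM run containing, for every compound named in the
#' configuration, spectra at cycle-time intervals across its scheduled
#' window; each spectrum holds the compound's predicted fragment ions with
#' the configured intensity profile scaled by a Gaussian chromatographic
#' envelope at the registry retention time, plus baseline noise. The
#' quantifier-fragment trace integrates to the planted area, which is
#' derived from the registry calibration line so that the full pipeline
#' (extraction, IS normalization, inverse prediction) recovers the planted
#' concentration. Internal standards of the selected compounds are
#' co-generated at fixed concentration on mass-shifted channels.
#'
#' @param cfg A [synth_config()].
#' @param registry A `pfas_registry`.
#' @return A list: `run` (a `prm_run`) and `truth` (planted concentrations,
#'   pre- and post-noise areas, apex RTs, per-injection area multipliers,
#'   IS areas, seed and configuration).
#' @export
generate_run <- function(cfg, registry = pfas_registry()) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  compounds <- names(cfg$conc_ugl)
  missing <- setdiff(compounds, registry$name)
  if (length(missing))
    stop("compounds absent from registry: ", paste(missing, collapse = ", "))
  sigma_min <- cfg$sigma_s / 60
  spectra <- list()
  sched <- list()
  truth_area <- truth_area_true <- truth_mult <- setNames(numeric(length(compounds)), compounds)

  for (nm in compounds) {
    row <- registry_compound(nm, registry)
    frags <- predict_fragments(nm, registry)
    tr <- diagnostic_transition(nm, registry)
    rel <- .relative_profile(frags, tr$match_label, cfg$rel_profile)
    x <- cfg$conc_ugl[[nm]]
    y <- max(row$slope * x + row$intercept, 0)
    if (x == 0) y <- 0
    area_true <- y / cfg$conc_is * cfg$is_area
    mult <- .mult_noise(1, cfg$area_cv)
    area <- area_true * mult
    truth_area_true[nm] <- area_true
    truth_area[nm] <- area
    truth_mult[nm] <- mult
    ch <- nm
    times <- .cycle_times(row$rt_min, cfg$rt_half_width, cfg$cycle_s)
    for (t in times) {
      env <- .gauss_trace(t, row$rt_min, sigma_min, area)
      spectra[[length(spectra) + 1]] <- .synth_spectrum(
        t, row$precursor_mz_theo, ch, frags$mz, rel * env, cfg)
    }
    sched[[length(sched) + 1]] <- data.frame(
      channel = ch, precursor_mz = row$precursor_mz_theo,
      rt_center = row$rt_min, rt_half_width = cfg$rt_half_width,
      stringsAsFactors = FALSE)
  }

  iss <- internal_standards(registry)
  iss <- iss[iss$is_name %in% registry$internal_standard[registry$name %in% compounds], ]
  is_area <- setNames(numeric(nrow(iss)), iss$is_name)
  for (i in seq_len(nrow(iss))) {
    isr <- iss[i, ]
    mult <- .mult_noise(1, cfg$area_cv)
    area <- cfg$is_area * mult
    is_area[isr$is_name] <- area
    ch <- paste0("IS:", isr$is_name)
    times <- .cycle_times(isr$rt_min, cfg$rt_half_width, cfg$cycle_s)
    mzv <- sort(c(isr$product_mz, isr$precursor_mz))
    relv <- ifelse(mzv == isr$product_mz, 1, 0.5)
    for (t in times) {
      env <- .gauss_trace(t, isr$rt_min, sigma_min, area)
      spectra[[length(spectra) + 1]] <- .synth_spectrum(
        t, isr$precursor_mz, ch, mzv, relv * env, cfg)
    }
    sched[[length(sched) + 1]] <- data.frame(
      channel = ch, precursor_mz = isr$precursor_mz,
      rt_center = isr$rt_min, rt_half_width = cfg$rt_half_width,
      stringsAsFactors = FALSE)
  }

  schedule <- if (length(sched)) do.call(rbind, sched) else
    data.frame(channel = character(0), precursor_mz = numeric(0),
               rt_center = numeric(0), rt_half_width = numeric(0))
  ord <- order(vapply(spectra, `[[`, numeric(1), "rt"))
  run <- prm_run(spectra[ord], schedule,
                 metadata = list(resolution = 35000, agc_target = 1e5,
                                 max_it_ms = 100, generator = "pfasprm-synth"))
  truth <- list(conc_ugl = cfg$conc_ugl, area = truth_area,
                area_true = truth_area_true, area_mult = truth_mult,
                apex_rt = setNames(registry$rt_min[match(compounds, registry$name)], compounds),
                is_area = is_area, seed = cfg$seed, config = cfg)
  list(run = run, truth = truth)
}

.cycle_times <- function(rt, half_width, cycle_s) {
  t <- seq(rt - half_width, rt + half_width, by = cycle_s / 60)
  t[t < rt + half_width]  # half-open [rt - w, rt + w)
}

.relative_profile <- function(frags, quant_label, prof) {
  rel <- numeric(nrow(frags))
  others <- which(!(frags$label %in% c(quant_label, "[M-H]-")))
  rel[match(quant_label, frags$label)] <- prof[["quantifier"]]
  if ("[M-H]-" %in% frags$label && quant_label != "[M-H]-")
    rel[match("[M-H]-", frags$label)] <- prof[["precursor"]]
  if (length(others))
    rel[others] <- prof[["other"]] * prof[["decay"]]^(seq_along(others) - 1)
  rel
}

.synth_spectrum <- function(t, precursor, channel, mz, intensity, cfg) {
  if (cfg$mz_jitter_ppm > 0)
    mz <- mz * (1 + stats::rnorm(length(mz), 0, cfg$mz_jitter_ppm * 1e-6))
  if (cfg$baseline_sd > 0 || cfg$baseline_mean > 0)
    intensity <- intensity +
      pmax(stats::rnorm(length(mz), cfg$baseline_mean, cfg$baseline_sd), 0)
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  keep <- !duplicated(mz)
  prm_spectrum(t, precursor, mz[keep], intensity[keep], channel)
}

#' Generate a synthetic calibration series
#'
#' Emits replicated (concentration, analyte area, IS area) points per
#' compound, consistent with the registry calibration line under the
#' IS-normalized response definition: the planted response at level x is
#' `slope * x + intercept`, perturbed multiplicatively by `area_cv`, and
#' converted to an analyte area against the (optionally noisy) IS area.
#' Levels outside a compound's registry linear range are dropped.
#'
#' @param compounds Character vector of registry compound names.
#' @param levels Concentration levels (ug/L); default the method's
#'   five-point series 0.2, 1.0, 5.0, 10.0, 20.0.
#' @param J Replicates per level.
#' @param area_cv Multiplicative response noise (relative SD).
#' @param is_area_cv Multiplicative IS-area noise (relative SD).
#' @param registry A `pfas_registry`.
#' @param conc_is,is_area IS concentration (ug/L) and nominal area.
#' @param seed Integer seed.
#' @return A list: `data` (data frame `name`, `conc_ugl`, `replicate`,
#'   `area_analyte`, `area_is`, `conc_is`) and `truth` (planted slopes and
#'   intercepts, seed, settings).
#' @export
generate_calibration_set <- function(compounds, levels = c(0.2, 1, 5, 10, 20),
                                     J = 3, area_cv = 0, is_area_cv = 0,
                                     registry = pfas_registry(),
                                     conc_is = 5.0, is_area = 5e5,
                                     seed = NULL) {
  if (!length(levels)) stop("empty level list")
  stopifnot(J >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (nm in compounds) {
    row <- registry_compound(nm, registry)
    lv <- levels[levels >= row$linear_min_ugl & levels <= row$linear_max_ugl]
    for (x in lv) for (j in seq_len(J)) {
      a_is <- is_area * .mult_noise(1, is_area_cv)
      y <- (row$slope * x + row$intercept) * .mult_noise(1, area_cv)
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, conc_ugl = x, replicate = j,
        area_analyte = y / conc_is * a_is, area_is = a_is,
        conc_is = conc_is, stringsAsFactors = FALSE)
    }
  }
  data <- do.call(rbind, rows)
  truth <- list(
    slope = setNames(registry$slope[match(compounds, registry$name)], compounds),
    intercept = setNames(registry$intercept[match(compounds, registry$name)], compounds),
    levels = levels, J = J, area_cv = area_cv, is_area_cv = is_area_cv,
    conc_is = conc_is, seed = seed)
  list(data = data, truth = truth)
}

#' Generate a synthetic spike-recovery dataset
#'
#' Replicate measured concentrations at each spike level, planted as
#' `spike * recovery_factor` with lognormal noise of the given CV.
#'
#' @param compounds Registry compound names.
#' @param spikes Spike levels (ng/L); default 1.0, 5.0, 10.0.
#' @param n Replicates per level (>= 2).
#' @param recovery_factor Planted recovery as a fraction; scalar or named
#'   per-compound vector.
#' @param cv Lognormal coefficient of variation of the measurements.
#' @param seed Integer seed.
#' @return A list: `data` (data frame `name`, `spike_ngl`, `replicate`,
#'   `measured_ngl`, `background`) and `truth`.
#' @export
generate_recovery_set <- function(compounds, spikes = c(1, 5, 10), n = 6,
                                  recovery_factor = 1, cv = 0, seed = NULL) {
  if (any(spikes <= 0)) stop("spike levels must be positive")
  stopifnot(n >= 2, cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  fac <- if (length(recovery_factor) == 1)
    setNames(rep(recovery_factor, length(compounds)), compounds)
  else recovery_factor[compounds]
  rows <- list()
  for (nm in compounds) for (s in spikes) {
    noise <- if (cv > 0) exp(stats::rnorm(n, -cv^2 / 2, cv)) else rep(1, n)
    rows[[length(rows) + 1]] <- data.frame(
      name = nm, spike_ngl = s, replicate = seq_len(n),
      measured_ngl = s * fac[[nm]] * noise, background = "n.d.",
      stringsAsFactors = FALSE)
  }
  list(data = do.call(rbind, rows),
       truth = list(recovery_factor = fac, cv = cv, spikes = spikes,
                    n = n, seed = seed))
}
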