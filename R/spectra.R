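# PRM runs, extracted ion chromatograms and spectrum annotation.
#
# A PRM run is an ordered list of product-ion spectra, each tied to a
# precursor isolation target, plus the acquisition schedule (per-channel
# retention-time window, +/-0.5 min by default). The canonical on-disk form
# is a JSON dialect written/read losslessly by this module; mzML files are
# read through an adapter (mzR) into the same structure.

#' Construct a PRM product-ion spectrum
#'
#' @param rt Retention time in minutes.
#' @param precursor_mz Precursor isolation target (Th).
#' @param mz,intensity Peak arrays: `mz` strictly increasing, `intensity`
#'   non-negative, equal length.
#' @param channel Optional schedule channel name.
#' @param isolation_width Isolation window full width (Th).
#' @return A list of class `prm_spectrum`.
#' @export
prm_spectrum <- function(rt, precursor_mz, mz, intensity, channel = NA_character_,
                         isolation_width = 1.5) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) > 1 && is.unsorted(mz, strictly = TRUE))
    stop("mz array must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(rt = rt, precursor_mz = precursor_mz, channel = channel,
                 isolation_width = isolation_width,
                 mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "prm_spectrum")
}

#' Construct a PRM run
#'
#' @param spectra A list of [prm_spectrum()] objects, sorted by retention
#'   time (an error lists offending indices otherwise).
#' @param schedule A data frame with columns `channel`, `precursor_mz`,
#'   `rt_center`, `rt_half_width` (minutes); every spectrum's precursor
#'   target must appear in it.
#' @param metadata Free-form instrument metadata list (resolution, AGC
#'   target, etc.), carried opaquely.
#' @return A list of class `prm_run`.
#' @export
prm_run <- function(spectra, schedule, metadata = list()) {
  stopifnot(is.list(spectra), is.data.frame(schedule))
  need <- c("channel", "precursor_mz", "rt_center", "rt_half_width")
  if (length(setdiff(need, names(schedule))))
    stop("schedule must have columns: ", paste(need, collapse = ", "))
  rts <- vapply(spectra, `[[`, numeric(1), "rt")
  if (is.unsorted(rts)) {
    bad <- which(diff(rts) < 0) + 1L
    stop("spectra not sorted by retention time; offending indices: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  chans <- vapply(spectra, function(s) s$channel %||% NA_character_, character(1))
  known <- is.na(chans) | chans %in% schedule$channel
  if (!all(known))
    stop("spectra reference unknown channel(s): ",
         paste(unique(chans[!known]), collapse = ", "))
  structure(list(spectra = spectra, schedule = schedule, metadata = metadata),
            class = "prm_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.prm_run <- function(x, ...) {
  rng <- if (length(x$spectra))
    range(vapply(x$spectra, `[[`, numeric(1), "rt")) else c(NA, NA)
  cat("<prm_run> ", length(x$spectra), " spectra, ",
      nrow(x$schedule), " scheduled channels, RT ",
      sprintf("%.2f-%.2f", rng[1], rng[2]), " min\n", sep = "")
  invisible(x)
}

#' Write / read a PRM run in the fixture-JSON dialect
#'
#' The JSON schema (`pfasprm-run/1`) stores the schedule, metadata, and each
#' spectrum's retention time, precursor target, channel and peak arrays at
#' full double precision, so that a write/read cycle is lossless.
#'
#' @param run A `prm_run`.
#' @param path File path.
#' @return `read_prm_run()` returns a `prm_run`; `write_prm_run()` returns
#'   `path` invisibly.
#' @export
write_prm_run <- function(run, path) {
  stopifnot(inherits(run, "prm_run"))
  obj <- list(
    schema = "pfasprm-run/1",
    metadata = run$metadata,
    schedule = run$schedule,
    spectra = lapply(run$spectra, function(s)
      list(rt = s$rt, precursor_mz = s$precursor_mz, channel = s$channel,
           isolation_width = s$isolation_width, mz = s$mz,
           intensity = s$intensity))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_prm_run
#' @param dialect `"json"` for the fixture dialect, `"mzML"` for mzML input
#'   (requires the mzR package).
#' @export
read_prm_run <- function(path, dialect = c("json", "mzML")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "mzML") return(.read_mzml(path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(obj$schema, "pfasprm-run/1"))
    stop("not a pfasprm run file (schema: ", obj$schema %||% "missing", ")")
  sp <- obj$spectra
  spectra <- if (is.data.frame(sp)) {
    lapply(seq_len(nrow(sp)), function(i)
      prm_spectrum(sp$rt[i], sp$precursor_mz[i], unlist(sp$mz[i]),
                   unlist(sp$intensity[i]), sp$channel[i],
                   sp$isolation_width[i]))
  } else {
    lapply(sp, function(s)
      prm_spectrum(s$rt, s$precursor_mz, unlist(s$mz), unlist(s$intensity),
                   s$channel %||% NA_character_, s$isolation_width %||% 1.5))
  }
  sched <- as.data.frame(obj$schedule, stringsAsFactors = FALSE)
  prm_run(spectra, sched, as.list(obj$metadata))
}

# mzML adapter: precursor targets become channels; the schedule is
# reconstructed from the observed RT span of each target.
.read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  hdr <- mzR::header(ms)
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  prec <- hdr$precursorMZ
  rt_min <- hdr$retentionTime / 60
  chan <- sprintf("prec_%.4f", prec)
  spectra <- lapply(order(rt_min), function(i) {
    m <- pk[[i]]
    o <- order(m[, 1])
    keep <- !duplicated(m[o, 1])
    prm_spectrum(rt_min[i], prec[i], m[o, 1][keep], m[o, 2][keep], chan[i])
  })
  sched <- do.call(rbind, lapply(split(seq_along(chan), chan), function(ix) {
    data.frame(channel = chan[ix[1]], precursor_mz = prec[ix[1]],
               rt_center = mean(range(rt_min[ix])),
               rt_half_width = max(diff(range(rt_min[ix])) / 2, 0.5),
               stringsAsFactors = FALSE)
  }))
  rownames(sched) <- NULL
  prm_run(spectra, sched)
}

#' Extract an ion chromatogram and integrate its peak
#'
#' Builds the intensity-versus-time trace for a product ion within a
#' precursor channel and retention-time window, then integrates the largest
#' chromatographic peak. Per spectrum, intensities of all peaks within
#' `tol_ppm` of `target_mz` are summed. The peak apex is the trace maximum
#' (ties resolved to the earlier time); boundaries extend outward from the
#' apex until the trace falls below `max(baseline + 3 * noise SD, 1%% of
#' apex)`; the baseline level and noise SD are the median and scaled median
#' absolute deviation of the trace outside the peak; the area is the
#' trapezoidal integral of the baseline-subtracted peak (intensity x
#' minutes).
#'
#' @param run A `prm_run`.
#' @param precursor_mz Precursor channel to read (matched within half the
#'   isolation width).
#' @param target_mz Product ion m/z (Th).
#' @param tol_ppm Extraction tolerance in ppm.
#' @param rt_range Length-2 numeric window in minutes, or `NULL` for the
#'   full trace.
#' @return A list of class `pfas_xic`: `time`, `intensity`, `found`,
#'   `apex_rt`, `height`, `area`, `left`, `right` (boundary times),
#'   `baseline`, `noise_sd`, `n_points` (points across the peak).
#' @export
extract_xic <- function(run, precursor_mz, target_mz, tol_ppm = 5,
                        rt_range = NULL) {
  stopifnot(inherits(run, "prm_run"), tol_ppm > 0)
  sel <- vapply(run$spectra, function(s)
    abs(s$precursor_mz - precursor_mz) <= (s$isolation_width %||% 1.5) / 2 &&
      (is.null(rt_range) || (s$rt >= rt_range[1] && s$rt < rt_range[2])),
    logical(1))
  spectra <- run$spectra[sel]
  if (!length(spectra)) {
    return(structure(list(time = numeric(0), intensity = numeric(0),
                          target_mz = target_mz, found = FALSE, area = 0,
                          apex_rt = NA_real_, height = 0, left = NA_real_,
                          right = NA_real_, baseline = 0, noise_sd = 0,
                          n_points = 0L, empty = TRUE), class = "pfas_xic"))
  }
  tol <- tol_ppm * 1e-6 * target_mz
  trace <- vapply(spectra, function(s)
    sum(s$intensity[abs(s$mz - target_mz) <= tol]), numeric(1))
  times <- vapply(spectra, `[[`, numeric(1), "rt")
  pk <- .integrate_peak(times, trace)
  structure(c(list(time = times, intensity = trace, target_mz = target_mz,
                   empty = FALSE), pk), class = "pfas_xic")
}

# Apex-outward peak integration with robust baseline estimation.
.integrate_peak <- function(time, y) {
  if (!any(y > 0)) {
    return(list(found = FALSE, area = 0, apex_rt = NA_real_, height = 0,
                left = NA_real_, right = NA_real_, baseline = 0,
                noise_sd = 0, n_points = 0L))
  }
  apex <- which.max(y)
  h <- y[apex]
  expand <- function(threshold) {
    l <- apex
    while (l > 1 && y[l - 1] > threshold) l <- l - 1
    r <- apex
    while (r < length(y) && y[r + 1] > threshold) r <- r + 1
    c(l, r)
  }
  prov <- expand(0.01 * h)
  outside <- setdiff(seq_along(y), seq(prov[1], prov[2]))
  baseline <- if (length(outside) >= 4) stats::median(y[outside]) else 0
  noise_sd <- if (length(outside) >= 4) stats::mad(y[outside]) else 0
  thr <- max(baseline + 3 * noise_sd, 0.01 * h)
  b <- expand(thr)
  idx <- seq(b[1], b[2])
  area <- if (length(idx) > 1)
    pracma::trapz(time[idx], pmax(y[idx] - baseline, 0)) else 0
  list(found = h > thr, area = max(area, 0), apex_rt = time[apex],
       height = h - baseline, left = time[b[1]], right = time[b[2]],
       baseline = baseline, noise_sd = noise_sd, n_points = length(idx))
}

#' @export
print.pfas_xic <- function(x, ...) {
  cat("<xic> target m/z ", sprintf("%.4f", x$target_mz), ": ", sep = "")
  if (!x$found) cat("no peak detected (", length(x$time), " points)\n", sep = "")
  else cat("apex ", sprintf("%.2f", x$apex_rt), " min, height ",
           signif(x$height, 4), ", area ", signif(x$area, 4), ", ",
           x$n_points, " points across peak\n", sep = "")
  invisible(x)
}

#' Annotate a spectrum against predicted fragment ions
#'
#' Matches observed peaks to predicted fragments within a ppm tolerance.
#' Peaks are processed in decreasing intensity order and each takes the
#' unassigned prediction with the smallest absolute mass error; each
#' prediction annotates at most one peak, so the result is independent of
#' the input peak order.
#'
#' @param spectrum A `prm_spectrum`.
#' @param predicted A fragment table from [predict_fragments()] (columns
#'   `label`, `formula`, `mz`).
#' @param tol_ppm Match tolerance in ppm.
#' @return A data frame: `label`, `formula`, `mz_theo`, `mz_obs`,
#'   `intensity`, `delta_ppm`; zero rows if nothing matches.
#' @export
annotate_spectrum <- function(spectrum, predicted, tol_ppm = 5) {
  stopifnot(tol_ppm > 0)
  empty <- data.frame(label = character(0), formula = character(0),
                      mz_theo = numeric(0), mz_obs = numeric(0),
                      intensity = numeric(0), delta_ppm = numeric(0))
  if (!length(spectrum$mz) || !nrow(predicted)) return(empty)
  ord <- order(-spectrum$intensity, spectrum$mz)
  used <- logical(nrow(predicted))
  hits <- list()
  for (i in ord) {
    dppm <- ppm_error(spectrum$mz[i], predicted$mz)
    cand <- which(!used & abs(dppm) <= tol_ppm)
    if (!length(cand)) next
    j <- cand[which.min(abs(dppm[cand]))]
    used[j] <- TRUE
    hits[[length(hits) + 1]] <- data.frame(
      label = predicted$label[j], formula = predicted$formula[j],
      mz_theo = predicted$mz[j], mz_obs = spectrum$mz[i],
      intensity = spectrum$intensity[i], delta_ppm = dppm[j])
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out[order(-out$mz_theo), , drop = FALSE]
}

#' Identify registry compounds in a PRM run
#'
#' A compound is reported as detected when (a) the extracted quantifier
#' transition yields an integrated peak with apex inside the compound's
#' scheduled retention window, and (b) at least one additional predicted
#' fragment is annotated in the apex spectrum. Compounds whose quantifier
#' peak is found but lack a confirming fragment are flagged
#' `quantifier_only`.
#'
#' @param run A `prm_run`.
#' @param registry A `pfas_registry`.
#' @param tol_ppm Annotation/extraction tolerance in ppm.
#' @return A data frame with one row per registry compound: `name`,
#'   `detected`, `quantifier_only`, `apex_rt`, `area`, `n_fragments`
#'   (annotated fragments in the apex spectrum, quantifier included),
#'   `mean_abs_ppm`.
#' @export
identify_compounds <- function(run, registry = pfas_registry(), tol_ppm = 5) {
  stopifnot(inherits(run, "prm_run"))
  if (!length(run$spectra)) stop("run contains no spectra")
  rows <- lapply(registry$name, function(nm) {
    row <- registry_compound(nm, registry)
    tr <- diagnostic_transition(nm, registry)
    win <- c(row$rt_min - 0.5, row$rt_min + 0.5)
    xic <- extract_xic(run, row$precursor_mz_theo, tr$product_mz_theo,
                       tol_ppm = tol_ppm, rt_range = win)
    base <- data.frame(name = nm, detected = FALSE, quantifier_only = FALSE,
                       apex_rt = NA_real_, area = 0, n_fragments = 0L,
                       mean_abs_ppm = NA_real_, stringsAsFactors = FALSE)
    if (!xic$found || is.na(xic$apex_rt) ||
        xic$apex_rt < win[1] || xic$apex_rt >= win[2]) return(base)
    frags <- predict_fragments(nm, registry)
    apex_spec <- .apex_spectrum(run, row$precursor_mz_theo, xic$apex_rt)
    ann <- annotate_spectrum(apex_spec, frags, tol_ppm = tol_ppm)
    n_other <- sum(abs(ppm_error(ann$mz_theo, tr$product_mz_theo)) > tol_ppm)
    base$apex_rt <- xic$apex_rt
    base$area <- xic$area
    base$n_fragments <- nrow(ann)
    base$mean_abs_ppm <- if (nrow(ann)) mean(abs(ann$delta_ppm)) else NA_real_
    base$detected <- n_other >= 1L
    base$quantifier_only <- !base$detected
    base
  })
  do.call(rbind, rows)
}

.apex_spectrum <- function(run, precursor_mz, rt) {
  sel <- which(vapply(run$spectra, function(s)
    abs(s$precursor_mz - precursor_mz) <= (s$isolation_width %||% 1.5) / 2,
    logical(1)))
  rts <- vapply(run$spectra[sel], `[[`, numeric(1), "rt")
  run$spectra[[sel[which.min(abs(rts - rt))]]]
}
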