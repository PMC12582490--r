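# Shared fixtures: the packaged registry, and a hand-built PRM run with one
# Gaussian peak of known area (the closed-form oracle for XIC integration).

REG <- pfas_registry()

# A single-channel run: Gaussian peak of area `area` (intensity x minutes)
# at `rt` on the trace of `target_mz`, sampled every `cycle_s` seconds over
# rt +/- 0.5 min. Optional flat baseline.
gaussian_run <- function(target_mz = 468.970210, precursor_mz = 512.960039,
                         rt = 9.05, sigma_s = 3, area = 1e5, cycle_s = 1.5,
                         baseline = 0, extra_mz = numeric(0),
                         extra_rel = numeric(0)) {
  times <- seq(rt - 0.5, rt + 0.5 - 1e-9, by = cycle_s / 60)
  spectra <- lapply(times, function(t) {
    h <- area * dnorm(t, rt, sigma_s / 60)
    mz <- c(target_mz, extra_mz)
    int <- c(h, extra_rel * h) + baseline
    o <- order(mz)
    prm_spectrum(t, precursor_mz, mz[o], int[o], channel = "chan")
  })
  prm_run(spectra,
          data.frame(channel = "chan", precursor_mz = precursor_mz,
                     rt_center = rt, rt_half_width = 0.5))
}

# Random small molecular formula over the supported elements.
random_formula <- function() {
  els <- names(mass_constants()$elements)
  k <- sample(1:4, 1)
  pick <- sample(els, k)
  as_mol_formula(setNames(sample(1:9, k, replace = TRUE), pick))
}
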