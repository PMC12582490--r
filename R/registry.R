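# Compound/transition registry.
#
# The packaged registry holds the 26-compound PRM transition list: free-acid
# neutral formulas, structural class, perfluoroalkyl chain length, ether-arm
# compositions, retention times, the instrument's printed precursor/product
# m/z and collision energies, assigned internal standards, and default
# internal-standard calibration response factors (slope/intercept) with
# linear ranges. Rows whose printed product m/z deviates from theory by more
# than ~2 ppm carry `mz_flag = TRUE`; for those, matching and synthesis use
# the theoretical value.

.PFAS_CLASSES <- c("PFCA", "PFSA", "PFSAmide", "FTSA", "EtherPFCA", "ClPFESA")

#' Load the PFAS compound registry
#'
#' Reads the packaged transition registry (or a user CSV with the same
#' columns), validates class and chain-length invariants, and appends the
#' theoretical precursor m/z (`precursor_mz_theo`) computed from the
#' free-acid formula under the deprotonated-anion convention.
#'
#' @param path Optional path to a registry CSV; defaults to the packaged one.
#' @return A data frame of class `pfas_registry`, one row per compound.
#' @examples
#' reg <- pfas_registry()
#' reg[reg$name == "PFOA", c("formula", "precursor_mz", "precursor_mz_theo")]
#' @export
pfas_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pfas_registry.csv", package = "pfasprm", mustWork = TRUE)
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "cas", "formula", "class", "chain_n", "ether_r", "rt_min",
              "precursor_mz", "product_mz", "ce_ev", "internal_standard", "mz_flag")
  missing <- setdiff(needed, names(reg))
  if (length(missing))
    stop("registry is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(reg$name)) stop("duplicate compound names in registry")
  bad <- setdiff(reg$class, .PFAS_CLASSES)
  if (length(bad)) stop("unknown compound class(es): ", paste(bad, collapse = ", "))
  if (any(reg$rt_min <= 0)) stop("retention times must be positive")
  reg$mz_flag <- as.logical(reg$mz_flag)
  reg$precursor_mz_theo <- vapply(reg$formula, function(f) mz_deprotonated(f), numeric(1))
  for (i in seq_len(nrow(reg))) .check_chain(reg[i, ])
  class(reg) <- c("pfas_registry", "data.frame")
  reg
}

# Chain-length consistency: PFCA CnF2n+1-COOH has C = n+1, F = 2n+1;
# PFSA CnF2n+1-SO3H has C = n, F = 2n+1.
.check_chain <- function(row) {
  f <- parse_formula(row$formula)
  n <- row$chain_n
  ok <- switch(row$class,
    PFCA = identical(unname(f["C"]), as.integer(n + 1)) &&
           identical(unname(f["F"]), as.integer(2 * n + 1)),
    PFSA = identical(unname(f["C"]), as.integer(n)) &&
           identical(unname(f["F"]), as.integer(2 * n + 1)),
    TRUE)
  if (!isTRUE(ok))
    stop("chain length ", n, " inconsistent with formula ", row$formula,
         " for ", row$name)
  invisible(TRUE)
}

#' Look up one registry compound
#'
#' @param name Compound name as listed in the registry.
#' @param registry A `pfas_registry` data frame.
#' @return The matching single-row data frame.
#' @export
registry_compound <- function(name, registry = pfas_registry()) {
  i <- match(name, registry$name)
  if (is.na(i))
    stop("unknown compound '", name, "'; valid names: ",
         paste(registry$name, collapse = ", "))
  registry[i, , drop = FALSE]
}

#' Internal standards table
#'
#' Derives the isotope-labeled internal standard table from the registry:
#' one row per distinct standard, with the number of 13C labels parsed from
#' the name, the unlabeled analogue compound, and (where the analogue is in
#' the registry) its retention time and mass-shifted PRM transition. The 13C
#' label shift is 1.003355 Da per position.
#'
#' @param registry A `pfas_registry` data frame.
#' @return A data frame with columns `is_name`, `n_label`, `analogue`,
#'   `rt_min`, `precursor_mz`, `product_mz`.
#' @export
internal_standards <- function(registry = pfas_registry()) {
  nm <- unique(registry$internal_standard)
  n_label <- as.integer(sub("^13C(\\d+)-.*$", "\\1", nm))
  analogue <- sub("^13C\\d+-\\s*", "", nm)
  shift <- 1.003355 * n_label
  i <- match(analogue, registry$name)
  # product ion of the labeled analogue: the analyte's theoretical quantifier
  # fragment, shifted by as many 13C labels as the fragment can retain
  prod <- vapply(seq_along(nm), function(k) {
    tr <- diagnostic_transition(analogue[k], registry)
    frags <- predict_fragments(analogue[k], registry)
    frag <- parse_formula(frags$formula[match(tr$match_label, frags$label)])
    c_frag <- if (is.na(frag["C"])) 0 else unname(frag["C"])
    tr$product_mz_theo + 1.003355 * min(n_label[k], c_frag)
  }, numeric(1))
  data.frame(
    is_name = nm,
    n_label = n_label,
    analogue = analogue,
    rt_min = registry$rt_min[i],
    precursor_mz = registry$precursor_mz_theo[i] + shift,
    product_mz = prod,
    stringsAsFactors = FALSE
  )
}

#' Printed recovery/precision table fixture
#'
#' The transcribed spike-recovery table (ultrapure-water matrix, n = 6) used
#' by the validation tests: per compound, the background and the printed
#' mean measured concentration, mean recovery and RSD at spikes of 1.0, 5.0
#' and 10.0 ng/L.
#'
#' @return A data frame, one row per compound.
#' @export
recovery_reference <- function() {
  path <- system.file("extdata", "recovery_table.csv", package = "pfasprm", mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
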