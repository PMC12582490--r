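# Exact monoisotopic mass scale used throughout the package.
#
# All m/z arithmetic is anchored to these constants so that every module
# (fragment prediction, annotation, synthetic spectra) shares a single mass
# scale. Values are standard monoisotopic atomic masses in Da.

.ELEMENT_MASSES <- c(
  C  = 12,
  H  = 1.00782503,
  F  = 18.99840322,
  O  = 15.99491462,
  N  = 14.00307401,
  S  = 31.97207117,
  Cl = 34.96885268,
  Na = 22.98976928,
  K  = 38.96370649
)

.ELECTRON_MASS <- 0.00054858
.PROTON_MASS <- 1.00727646

#' Mass constants
#'
#' Monoisotopic atomic masses (Da) for the supported elements, the electron
#' and proton masses, and the derived neutral-loss masses used by the
#' fragmentation rules (CO2, CF2, HF, SO3).
#'
#' @return A list with components `elements` (named numeric vector),
#'   `electron`, `proton`, and `losses` (named numeric vector).
#' @examples
#' mass_constants()$losses[["CF2"]]
#' @export
mass_constants <- function() {
  list(
    elements = .ELEMENT_MASSES,
    electron = .ELECTRON_MASS,
    proton   = .PROTON_MASS,
    losses   = c(
      CO2 = unname(.ELEMENT_MASSES["C"] + 2 * .ELEMENT_MASSES["O"]),
      CF2 = unname(.ELEMENT_MASSES["C"] + 2 * .ELEMENT_MASSES["F"]),
      HF  = unname(.ELEMENT_MASSES["H"] + .ELEMENT_MASSES["F"]),
      SO3 = unname(.ELEMENT_MASSES["S"] + 3 * .ELEMENT_MASSES["O"])
    )
  )
}

#' Parse a molecular formula string
#'
#' Parses element-count strings such as `"C4HF7O2"` into a named integer
#' vector of element counts. Element symbols must be among C, H, F, O, N, S,
#' Cl, Na, K; a symbol without a trailing number counts once.
#'
#' @param text A single formula string.
#' @return A named integer vector of class `mol_formula` (canonical element
#'   order: C, H, then alphabetical).
#' @examples
#' parse_formula("C4HF7O2")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  if (!nzchar(text)) stop("empty formula string")
  rx <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(rx))[[1]]
  if (sum(attr(rx, "match.length")) != nchar(text) || rx[1] != 1L) {
    covered <- rep(FALSE, nchar(text))
    for (i in seq_along(rx)) covered[seq(rx[i], length.out = attr(rx, "match.length")[i])] <- TRUE
    bad <- substr(text, which(!covered)[1], nchar(text))
    stop("malformed formula near '", bad, "' in '", text, "'")
  }
  sym <- sub("[0-9]*$", "", toks)
  num <- sub("^[A-Za-z]+", "", toks)
  unknown <- setdiff(sym, names(.ELEMENT_MASSES))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  cnt <- ifelse(nzchar(num), suppressWarnings(as.integer(num)), 1L)
  if (anyNA(cnt) || any(cnt < 1L))
    stop("malformed count in formula '", text, "'")
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  as_mol_formula(out)
}

#' @rdname parse_formula
#' @param counts A named integer vector of element counts (zeros are dropped).
#' @export
as_mol_formula <- function(counts) {
  if (is.null(names(counts)) && length(counts))
    stop("element counts must be named")
  counts <- counts[counts != 0]
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop("negative element count")
  unknown <- setdiff(names(counts), names(.ELEMENT_MASSES))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  counts <- counts[order(match(names(counts), c("C", "H"), nomatch = 3L), names(counts))]
  structure(counts, class = "mol_formula")
}

#' Format a molecular formula
#'
#' Canonical Hill-like formatting: C first, then H, then remaining elements
#' alphabetically; unit counts are omitted.
#'
#' @param f A `mol_formula` (or named count vector).
#' @return A single string; `""` for the empty formula.
#' @export
format_formula <- function(f) {
  f <- as_mol_formula(unclass(f))
  if (!length(f)) return("")
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' @export
format.mol_formula <- function(x, ...) format_formula(x)

#' @export
print.mol_formula <- function(x, ...) {
  cat("<formula> ", format_formula(x), "  (", round(monoisotopic_mass(x), 6), " Da)\n", sep = "")
  invisible(x)
}

#' Formula arithmetic
#'
#' Element-wise addition and subtraction of molecular formulas. Subtraction
#' errors if any element count would become negative.
#'
#' @param f1,f2 `mol_formula` objects (or parseable strings).
#' @return A `mol_formula`.
#' @export
formula_add <- function(f1, f2) {
  f1 <- .as_formula(f1); f2 <- .as_formula(f2)
  els <- union(names(f1), names(f2))
  out <- setNames(integer(length(els)), els)
  out[names(f1)] <- out[names(f1)] + f1
  out[names(f2)] <- out[names(f2)] + f2
  as_mol_formula(out)
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f1, f2) {
  f1 <- .as_formula(f1); f2 <- .as_formula(f2)
  els <- union(names(f1), names(f2))
  out <- setNames(integer(length(els)), els)
  out[names(f1)] <- out[names(f1)] + f1
  out[names(f2)] <- out[names(f2)] - f2
  if (any(out < 0L))
    stop("subtraction would give negative count for: ",
         paste(names(out)[out < 0L], collapse = ", "))
  as_mol_formula(out)
}

.as_formula <- function(f) {
  if (inherits(f, "mol_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  as_mol_formula(f)
}

#' Monoisotopic mass of a formula
#'
#' @param f A `mol_formula`, named count vector, or formula string.
#' @return Mass in Da (0 for the empty formula).
#' @examples
#' monoisotopic_mass("CO2")
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  if (!length(f)) return(0)
  sum(.ELEMENT_MASSES[names(f)] * as.numeric(f))
}

#' m/z of the deprotonated molecular anion [M-H]-
#'
#' Computed as the neutral monoisotopic mass minus the proton mass, i.e. the
#' electron-inclusive singly charged anion convention. The neutral must
#' contain at least one hydrogen.
#'
#' @param neutral The neutral molecule (`mol_formula` or string).
#' @return m/z in Th.
#' @examples
#' mz_deprotonated("C4HF7O2") # PFBA precursor
#' @export
mz_deprotonated <- function(neutral) {
  f <- .as_formula(neutral)
  if (is.na(f["H"]) || f["H"] < 1L)
    stop("no hydrogen available to remove from ", format_formula(f))
  monoisotopic_mass(f) - .PROTON_MASS
}

#' m/z of a singly charged anion of stated composition
#'
#' For fragment compositions given directly as the charged species (e.g.
#' `C3F7-`, `SO3-`): composition mass plus one electron mass.
#'
#' @param composition The ion composition (`mol_formula` or string).
#' @return m/z in Th.
#' @examples
#' mz_anion("C5F11") # PFHxA product ion
#' @export
mz_anion <- function(composition) {
  f <- .as_formula(composition)
  if (!length(f)) stop("empty composition")
  monoisotopic_mass(f) + .ELECTRON_MASS
}

#' Signed mass error in parts per million
#'
#' @param observed,theoretical m/z values in Th; `theoretical` must be > 0.
#' @return `1e6 * (observed - theoretical) / theoretical` (vectorized).
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Round half away from zero
#'
#' Display rounding used for reported m/z values (4 decimal places, half-up),
#' avoiding the round-half-even behaviour of [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
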