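# Class-specific fragmentation rules.
#
# Negative-mode CID of PFAS follows a small set of class-diagnostic
# pathways:
#   * PFCAs lose neutral CO2 from the carboxylate ([M-H-CO2]- = CnF2n+1-),
#     then shed CF2 units down the perfluoroalkyl series CkF2k+1-.
#   * PFSAs lose the CnF2n+1 radical to give SO3-. and the rearranged FSO3-,
#     plus the CkF2k+1- series from C-C/S-C cleavage.
#   * Ether-containing substitutes (HFPO-DA, DONA, Cl-PFESAs) cleave at the
#     ether oxygen, giving the acid-distal [R]- and [R-O]- ions.
#   * Fluorotelomer sulfonates lose HF; perfluoroalkane sulfonamides give
#     the SO2N-type sulfonamide fragment.
# The engine emits compositions and theoretical m/z only; intensities are
# assigned by the synthetic-data module.

.PATHWAYS <- c("deprotonation", "decarboxylation", "CC_cleavage",
               "radical_loss_rearrangement", "ether_cleavage", "HF_loss")

.frag_row <- function(label, comp, pathway, parent, loss) {
  data.frame(label = label, formula = format_formula(comp),
             mz = mz_anion(comp), pathway = pathway,
             parent = parent, loss = loss, stringsAsFactors = FALSE)
}

.series_label <- function(k) {
  sprintf("[%s]-", format_formula(c(C = k, F = 2L * k + 1L)))
}

.series_rows <- function(n, top_parent, top_loss) {
  if (n < 1) return(NULL)
  rows <- vector("list", n)
  for (k in seq(n, 1)) {
    comp <- as_mol_formula(c(C = k, F = 2L * k + 1L))
    parent <- if (k == n) top_parent else .series_label(k + 1L)
    loss <- if (k == n) top_loss else "CF2"
    rows[[n - k + 1]] <- .frag_row(.series_label(k), comp, "CC_cleavage",
                                   parent, loss)
  }
  do.call(rbind, rows)
}

#' Predict diagnostic fragment ions for a registry compound
#'
#' Applies the structural-class fragmentation rules to one compound and
#' returns the predicted fragment ions with theoretical m/z, the pathway
#' that generates each ion, and the parent ion plus neutral/radical loss
#' linking it into the fragmentation tree. Ions reachable by more than one
#' pathway (e.g. a PFCA's decarboxylation product, which is also the top of
#' the CkF2k+1 series) appear once with the pathway labels joined by ";".
#'
#' @param name Compound name present in the registry.
#' @param registry A `pfas_registry` data frame.
#' @return A data frame (`label`, `formula`, `mz`, `pathway`, `parent`,
#'   `loss`) sorted by descending m/z; the precursor `[M-H]-` is the root
#'   with `parent = NA`.
#' @examples
#' predict_fragments("PFDA")[, c("label", "mz", "pathway")]
#' @export
predict_fragments <- function(name, registry = pfas_registry()) {
  row <- registry_compound(name, registry)
  neutral <- parse_formula(row$formula)
  root_comp <- formula_subtract(neutral, c(H = 1L))
  root <- data.frame(label = "[M-H]-", formula = format_formula(root_comp),
                     mz = mz_deprotonated(neutral), pathway = "deprotonation",
                     parent = NA_character_, loss = NA_character_,
                     stringsAsFactors = FALSE)
  n <- row$chain_n
  ethers <- if (nzchar(row$ether_r) && !is.na(row$ether_r))
    strsplit(row$ether_r, ";", fixed = TRUE)[[1]] else character(0)

  rows <- switch(row$class,
    PFCA = rbind(
      .frag_row("[M-H-CO2]-", formula_subtract(root_comp, "CO2"),
                "decarboxylation", "[M-H]-", "CO2"),
      .series_rows(n, "[M-H]-", "CO2")
    ),
    PFSA = rbind(
      .frag_row("[SO3]-", parse_formula("SO3"), "radical_loss_rearrangement",
                "[M-H]-", format_formula(formula_subtract(root_comp, "SO3"))),
      .frag_row("[FSO3]-", parse_formula("FSO3"), "radical_loss_rearrangement",
                "[M-H]-", format_formula(formula_subtract(root_comp, "FSO3"))),
      .series_rows(n, "[M-H]-", "SO3")
    ),
    EtherPFCA = rbind(
      .frag_row("[M-H-CO2]-", formula_subtract(root_comp, "CO2"),
                "decarboxylation", "[M-H]-", "CO2"),
      .ether_rows(root_comp, ethers),
      .series_rows(n, "[M-H]-",
                   format_formula(formula_subtract(root_comp,
                     as_mol_formula(c(C = n, F = 2L * n + 1L)))))
    ),
    ClPFESA = rbind(
      .frag_row("[SO3]-", parse_formula("SO3"), "radical_loss_rearrangement",
                "[M-H]-", format_formula(formula_subtract(root_comp, "SO3"))),
      .frag_row("[FSO3]-", parse_formula("FSO3"), "radical_loss_rearrangement",
                "[M-H]-", format_formula(formula_subtract(root_comp, "FSO3"))),
      .ether_rows(root_comp, ethers)
    ),
    FTSA = rbind(
      .frag_row("[M-H-HF]-", formula_subtract(root_comp, "HF"),
                "HF_loss", "[M-H]-", "HF"),
      .frag_row("[SO3]-", parse_formula("SO3"), "radical_loss_rearrangement",
                "[M-H]-", format_formula(formula_subtract(root_comp, "SO3"))),
      .frag_row("[FSO3]-", parse_formula("FSO3"), "radical_loss_rearrangement",
                "[M-H]-", format_formula(formula_subtract(root_comp, "FSO3")))
    ),
    PFSAmide = .frag_row("[SO2N]-", parse_formula("NO2S"),
                         "radical_loss_rearrangement", "[M-H]-",
                         format_formula(formula_subtract(root_comp, "NO2S"))),
    stop("unsupported class: ", row$class)
  )

  out <- .dedupe_fragments(rbind(root, rows))
  out[order(-out$mz), , drop = FALSE]
}

# Acid-distal products of ether C-O cleavage: [R]- and [R-O]-.
.ether_rows <- function(root_comp, ethers) {
  do.call(rbind, lapply(ethers, function(rtxt) {
    r <- parse_formula(rtxt)
    ro <- formula_add(r, c(O = 1L))
    rbind(
      .frag_row(sprintf("[%s]-", format_formula(ro)), ro, "ether_cleavage",
                "[M-H]-", format_formula(formula_subtract(root_comp, ro))),
      .frag_row(sprintf("[%s]-", format_formula(r)), r, "ether_cleavage",
                "[M-H]-", format_formula(formula_subtract(root_comp, r)))
    )
  }))
}

# Collapse duplicate compositions; the first occurrence keeps its label,
# parent and loss, and accumulates the other pathway labels. Parent
# references to a collapsed label are rewritten to the kept one.
.dedupe_fragments <- function(rows) {
  keep <- !duplicated(rows$formula)
  remap <- setNames(rows$label[match(rows$formula, rows$formula)], rows$label)
  out <- rows[keep, , drop = FALSE]
  for (i in which(!keep)) {
    j <- match(rows$formula[i], out$formula)
    pw <- unique(c(strsplit(out$pathway[j], ";")[[1]], rows$pathway[i]))
    out$pathway[j] <- paste(pw, collapse = ";")
  }
  out$parent <- ifelse(is.na(out$parent), NA_character_,
                       unname(remap[out$parent]))
  rownames(out) <- NULL
  out
}

#' Quantifier transition for a compound
#'
#' Returns the registry's optimized PRM transition (printed precursor and
#' product m/z with collision energy) together with the predicted fragment
#' it corresponds to. The printed product must match a predicted ion within
#' 5 ppm, or within 25 ppm for registry rows flagged as printed-m/z
#' discrepant; the theoretical m/z of the matched fragment is returned for
#' downstream extraction.
#'
#' @param name Compound name.
#' @param registry A `pfas_registry` data frame.
#' @return A list: `precursor_mz`, `product_mz` (printed), `ce_ev`,
#'   `product_mz_theo`, `match_label`, `match_ppm`, `flagged`.
#' @export
diagnostic_transition <- function(name, registry = pfas_registry()) {
  row <- registry_compound(name, registry)
  frags <- predict_fragments(name, registry)
  dppm <- ppm_error(row$product_mz, frags$mz)
  j <- which.min(abs(dppm))
  tol <- if (row$mz_flag) 25 else 5
  if (abs(dppm[j]) > tol)
    stop("printed product ion ", row$product_mz, " for ", name,
         " matches no predicted fragment within ", tol, " ppm")
  list(precursor_mz = row$precursor_mz, product_mz = row$product_mz,
       ce_ev = row$ce_ev, product_mz_theo = frags$mz[j],
       match_label = frags$label[j], match_ppm = unname(dppm[j]),
       flagged = row$mz_flag)
}

#' Group m/z values into CF2-spaced homologue series
#'
#' Scans a sorted m/z list and groups values whose successive spacings are
#' small integer multiples of the CF2 repeat unit (49.996806 Da), the
#' characteristic spacing of perfluoroalkyl homologous series. Values that
#' do not chain to a neighbour remain singletons.
#'
#' @param mz Numeric vector of m/z values, ascending.
#' @param tol_ppm Relative tolerance on the spacing match (ppm of the larger
#'   member, scaled by the number of CF2 units spanned).
#' @param max_gap Largest multiple of CF2 allowed between series neighbours.
#' @return A list of numeric vectors, one per group, in ascending m/z order.
#' @examples
#' homologue_series(c(168.9894, 218.9862, 268.9830, 300.0))
#' @export
homologue_series <- function(mz, tol_ppm = 10, max_gap = 3) {
  if (!length(mz)) return(list())
  if (is.unsorted(mz, strictly = TRUE)) stop("mz must be sorted ascending")
  cf2 <- mass_constants()$losses[["CF2"]]
  groups <- list(mz[1])
  for (v in mz[-1]) {
    last <- tail(groups[[length(groups)]], 1)
    d <- v - last
    j <- round(d / cf2)
    if (j >= 1 && j <= max_gap && abs(d - j * cf2) <= j * tol_ppm * 1e-6 * v) {
      groups[[length(groups)]] <- c(groups[[length(groups)]], v)
    } else {
      groups[[length(groups) + 1]] <- v
    }
  }
  groups
}

#' Fragmentation pathway tree
#'
#' Arranges the predicted fragments of a compound into the rooted pathway
#' tree implied by their parent/loss links: the `[M-H]-` precursor at the
#' root, each child reachable from its parent by one neutral or radical
#' loss.
#'
#' @param name Compound name.
#' @param registry A `pfas_registry` data frame.
#' @return A nested list of class `pfas_tree`; each node has `label`,
#'   `formula`, `mz`, `pathway`, `loss`, and `children`.
#' @seealso [pathway_tree_json()] for serialization.
#' @export
pathway_tree <- function(name, registry = pfas_registry()) {
  frags <- predict_fragments(name, registry)
  build <- function(label) {
    i <- match(label, frags$label)
    kids <- frags$label[!is.na(frags$parent) & frags$parent == label]
    list(label = frags$label[i], formula = frags$formula[i],
         mz = frags$mz[i], pathway = frags$pathway[i], loss = frags$loss[i],
         children = lapply(kids, build))
  }
  structure(c(build("[M-H]-"), list(compound = name)), class = "pfas_tree")
}

#' @rdname pathway_tree
#' @param tree A `pfas_tree`.
#' @param pretty Passed to [jsonlite::toJSON()].
#' @return `pathway_tree_json()`: a JSON string.
#' @export
pathway_tree_json <- function(tree, pretty = TRUE) {
  jsonlite::toJSON(unclass(tree), auto_unbox = TRUE, digits = NA, pretty = pretty)
}

#' @export
print.pfas_tree <- function(x, ...) {
  rec <- function(node, depth) {
    cat(strrep("  ", depth), node$label, "  m/z ",
        sprintf("%.4f", round_half_up(node$mz, 4)),
        if (!is.null(node$loss) && !is.na(node$loss)) paste0("  (-", node$loss, ")") else "",
        "\n", sep = "")
    for (ch in node$children) rec(ch, depth + 1)
  }
  cat("Fragmentation pathway tree: ", x$compound, "\n", sep = "")
  rec(x, 0)
  invisible(x)
}

# Count of nodes in a pathway tree (consistency with predict_fragments).
.tree_size <- function(node) {
  1L + sum(vapply(node$children, .tree_size, integer(1)))
}
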