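#' The 18 modification attribute codes in canonical (Table-order) sequence
#'
#' The analysis represents every medicinal and formula as a vector over 18
#' histone/DNA modification attributes: cytosine methylation (DNMT), histone
#' acetylation/deacetylation (HAT/HDAC), residue-specific histone
#' (de)methylation (e.g. H3K4, H3K9; a trailing "i" marks the reverse,
#' erasing reaction such as H3K4i = H3K4 demethylation),
#' (de)phosphorylation of H3 serine 10 (H3S10/H3S10i), and ATP-dependent
#' chromatin remodeling (ATP).
#'
#' @return Character vector of the 18 attribute codes, in the fixed column
#'   order used by all potency matrices.
#' @export
attribute_codes <- function() {
  c("DNMT", "HAT", "HDAC",
    "H3K4", "H3K36", "H3K79", "H3R17", "H3K9", "H3K27", "H4K20",
    "H3K4i", "H3K36i", "H3R2i", "H4R3i", "H3K27i",
    "H3S10", "H3S10i", "ATP")
}

#' Chromatin conformation associated with each modification attribute
#'
#' Each attribute either opens chromatin (euchromatic), condenses it
#' (heterochromatic), or can do both (ambivalent; only ATP-dependent
#' remodeling). The partition is 7 euchromatic, 10 heterochromatic,
#' 1 ambivalent.
#'
#' @return Named character vector over [attribute_codes()] with values
#'   `"euchromatic"`, `"heterochromatic"` or `"ambivalent"`.
#' @export
chromatin_conformations <- function() {
  c(DNMT = "heterochromatic",
    HAT = "euchromatic",
    HDAC = "heterochromatic",
    H3K4 = "euchromatic",
    H3K36 = "euchromatic",
    H3K79 = "euchromatic",
    H3R17 = "euchromatic",
    H3K9 = "heterochromatic",
    H3K27 = "heterochromatic",
    H4K20 = "heterochromatic",
    H3K4i = "heterochromatic",
    H3K36i = "heterochromatic",
    H3R2i = "heterochromatic",
    H4R3i = "heterochromatic",
    H3K27i = "euchromatic",
    H3S10 = "euchromatic",
    H3S10i = "heterochromatic",
    ATP = "ambivalent")
}

#' Chemistry classes of the modification attributes
#'
#' Groups the attributes by the chemistry of the mark: `me` (DNA/histone
#' methylation and demethylation), `ph` (H3S10 phosphorylation and
#' dephosphorylation), `ac` (acetylation and deacetylation) and `all`
#' (every attribute with a defined conformation, i.e. all but ATP).
#'
#' @return Named list of character vectors of attribute codes.
#' @export
modification_classes <- function() {
  conf <- chromatin_conformations()
  me <- c("DNMT", "H3K4", "H3K36", "H3K79", "H3R17", "H3K9", "H3K27",
          "H4K20", "H3K4i", "H3K36i", "H3R2i", "H4R3i", "H3K27i")
  ph <- c("H3S10", "H3S10i")
  ac <- c("HAT", "HDAC")
  list(me = me, ph = ph, ac = ac,
       all = names(conf)[conf != "ambivalent"])
}

#' Construct a modification catalog
#'
#' A modification catalog binds each of the 18 attributes to its chromatin
#' conformation and to the set of enzyme (protein) identifiers whose
#' chemical interactions count toward that attribute's potency.
#'
#' @param proteins data.frame with columns `protein_id` and `attribute`.
#' @param conformations optional named vector overriding
#'   [chromatin_conformations()]; mainly for constructing pathological
#'   catalogs in tests.
#' @return Object of class `modification_catalog`: a list with elements
#'   `attributes` (data.frame `attribute`, `conformation`) and `proteins`
#'   (data.frame `protein_id`, `attribute`).
#' @export
modification_catalog <- function(proteins, conformations = chromatin_conformations()) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "attribute") %in% names(proteins)))
  codes <- attribute_codes()
  bad <- setdiff(unique(proteins$attribute), codes)
  if (length(bad) > 0L)
    stop("unknown attribute code(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(codes, unique(proteins$attribute))
  if (length(missing) > 0L)
    stop("modification catalog must cover all 18 attributes; missing: ",
         paste(missing, collapse = ", "))
  proteins <- unique(proteins[, c("protein_id", "attribute")])
  amb <- names(conformations)[conformations == "ambivalent"]
  if (!identical(amb, "ATP"))
    stop("ATP must be the only ambivalent attribute")
  out <- list(
    attributes = data.frame(attribute = codes,
                            conformation = unname(conformations[codes]),
                            stringsAsFactors = FALSE),
    proteins = proteins
  )
  class(out) <- "modification_catalog"
  out
}

#' @export
print.modification_catalog <- function(x, ...) {
  tab <- table(x$attributes$conformation)
  cat("Modification catalog: 18 attributes (",
      paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
      "), ", nrow(x$proteins), " enzyme assignments\n", sep = "")
  invisible(x)
}

# attribute -> protein_id list, in canonical order
attribute_proteins <- function(modcat) {
  split(modcat$proteins$protein_id,
        factor(modcat$proteins$attribute, levels = attribute_codes()))
}
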