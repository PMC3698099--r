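NATURE_TOKENS <- c("cold", "mild cold", "cool", "neutral", "mild warm",
                   "warm", "hot")
FLAVOR_TOKENS <- c("sweet", "mild sweet", "pungent", "mild pungent", "plain",
                   "sour", "mild sour", "bitter", "mild bitter",
                   "salty", "mild salty")
ACTION_TOKENS <- c("activation", "inhibition", "unspecified")

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c("NA", ""),
                          check.names = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  df
}

split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
}

#' Read a medicinal catalog
#'
#' Reads a tab-delimited catalog of medicinals with their taxonomy lineage,
#' TCM nature and flavor annotations and constituent chemical identifiers.
#' Columns: `medicinal_id`, `scientific_name`, `lineage` (taxa root to
#' species, `|`-separated; may be empty when a Newick tree is supplied
#' separately), `nature` (one of the seven cold-hot tokens or NA),
#' `flavors` (`;`-separated flavor tokens), `chemical_ids` (`;`-separated).
#'
#' Medicinals can appear in a source database more than once (different
#' plant parts); duplicate `medicinal_id` rows are collapsed keeping the
#' first occurrence's annotations while the chemical sets of all
#' occurrences are unioned. First-occurrence row order is preserved.
#'
#' @param path path to the TSV file.
#' @param strict if `TRUE` (default), an unknown nature or flavor token is an
#'   error; if `FALSE` the offending token is dropped with a warning.
#' @param id_map optional path to a two-column TSV (`from_id`, `to_id`)
#'   mapping chemical identifiers to a canonical namespace at load time.
#' @return A `tcm_catalog`: data.frame with columns `medicinal_id`,
#'   `scientific_name`, `nature`, and list columns `lineage`, `flavors`,
#'   `chemical_ids`.
#' @export
read_medicinal_catalog <- function(path, strict = TRUE, id_map = NULL) {
  df <- read_tsv_checked(path, c("medicinal_id", "scientific_name",
                                 "lineage", "nature", "flavors",
                                 "chemical_ids"))
  if (nrow(df) == 0L) return(new_tcm_catalog(df[0, , drop = FALSE]))
  if (anyNA(df$medicinal_id)) stop("medicinal_id may not be missing")

  mapper <- identity
  if (!is.null(id_map)) {
    m <- read_tsv_checked(id_map, c("from_id", "to_id"))
    lut <- stats::setNames(m$to_id, m$from_id)
    mapper <- function(x) ifelse(x %in% names(lut), unname(lut[x]), x)
  }

  for (i in seq_len(nrow(df))) {
    nt <- df$nature[i]
    if (!is.na(nt) && !(nt %in% NATURE_TOKENS)) {
      if (strict)
        stop(sprintf("row %d: unknown nature token '%s'", i, nt))
      warning(sprintf("row %d: dropping unknown nature token '%s'", i, nt))
      df$nature[i] <- NA_character_
    }
  }

  flavors <- lapply(seq_len(nrow(df)), function(i) {
    toks <- split_tokens(df$flavors[i])
    bad <- setdiff(toks, FLAVOR_TOKENS)
    if (length(bad) > 0L) {
      if (strict)
        stop(sprintf("row %d: unknown flavor token(s): %s", i,
                     paste(bad, collapse = ", ")))
      warning(sprintf("row %d: dropping unknown flavor token(s): %s", i,
                      paste(bad, collapse = ", ")))
      toks <- setdiff(toks, bad)
    }
    unique(toks)
  })
  chems <- lapply(df$chemical_ids, function(x) unique(mapper(split_tokens(x))))
  lineages <- lapply(df$lineage, function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else trimws(strsplit(x, "|", fixed = TRUE)[[1L]])
  })

  # first-occurrence rule: annotations from the first row; chemicals unioned
  first <- !duplicated(df$medicinal_id)
  idx <- which(first)
  chem_union <- lapply(df$medicinal_id[idx], function(id) {
    sort(unique(unlist(chems[df$medicinal_id == id])))
  })
  out <- data.frame(medicinal_id = df$medicinal_id[idx],
                    scientific_name = df$scientific_name[idx],
                    nature = df$nature[idx],
                    stringsAsFactors = FALSE)
  out$lineage <- lineages[idx]
  out$flavors <- flavors[idx]
  out$chemical_ids <- chem_union
  new_tcm_catalog(out)
}

new_tcm_catalog <- function(df) {
  if (nrow(df) > 0L) rownames(df) <- NULL
  class(df) <- c("tcm_catalog", "data.frame")
  df
}

#' @export
print.tcm_catalog <- function(x, ...) {
  cat("TCM medicinal catalog:", nrow(x), "medicinals;",
      sum(is.na(x$nature)), "without a cold-hot nature\n")
  invisible(x)
}

#' Write a medicinal catalog back to TSV
#'
#' Inverse of [read_medicinal_catalog()]; re-reading the written file yields
#' an identical catalog.
#'
#' @param catalog a `tcm_catalog`.
#' @param path output path.
#' @export
write_medicinal_catalog <- function(catalog, path) {
  df <- data.frame(
    medicinal_id = catalog$medicinal_id,
    scientific_name = catalog$scientific_name,
    lineage = vapply(catalog$lineage, paste, "", collapse = "|"),
    nature = ifelse(is.na(catalog$nature), "NA", catalog$nature),
    flavors = vapply(catalog$flavors, paste, "", collapse = ";"),
    chemical_ids = vapply(catalog$chemical_ids, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a chemical-protein interaction table
#'
#' TSV with columns `chemical_id`, `protein_id`, `action`; action is one of
#' `activation`, `inhibition`, `unspecified`. A blank or missing action is
#' stored as `unspecified` (interpretation as inhibition happens at potency
#' time, not at load time). Exact duplicate triples are collapsed.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `chemical_id`, `protein_id`, `action`.
#' @export
read_interaction_table <- function(path) {
  df <- read_tsv_checked(path, c("chemical_id", "protein_id", "action"))
  df$action[is.na(df$action)] <- "unspecified"
  bad <- setdiff(unique(df$action), ACTION_TOKENS)
  if (length(bad) > 0L)
    stop("unknown action token(s): ", paste(bad, collapse = ", "))
  unique(df[, c("chemical_id", "protein_id", "action")])
}

#' Write an interaction table
#' @param interactions data.frame as returned by [read_interaction_table()].
#' @param path output path.
#' @export
write_interaction_table <- function(interactions, path) {
  utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a modification catalog from TSV
#'
#' TSV with columns `attribute_code`, `conformation`, `protein_id`, one row
#' per enzyme. All 18 attributes must be present, the conformation of an
#' attribute must be consistent across its rows, and ATP must be the only
#' ambivalent attribute.
#'
#' @param path path to the TSV file.
#' @return A [modification_catalog()].
#' @export
read_modification_catalog <- function(path) {
  df <- read_tsv_checked(path, c("attribute_code", "conformation",
                                 "protein_id"))
  codes <- attribute_codes()
  bad <- setdiff(unique(df$attribute_code), codes)
  if (length(bad) > 0L)
    stop("unknown attribute code(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(codes, unique(df$attribute_code))
  if (length(missing) > 0L)
    stop("expected 18 attributes; missing: ", paste(missing, collapse = ", "))
  conf_ok <- c("euchromatic", "heterochromatic", "ambivalent")
  if (!all(df$conformation %in% conf_ok))
    stop("conformation must be one of: ", paste(conf_ok, collapse = ", "))
  confs <- tapply(df$conformation, df$attribute_code, unique)
  multi <- names(confs)[lengths(confs) > 1L]
  if (length(multi) > 0L)
    stop("conflicting conformations for attribute(s): ",
         paste(multi, collapse = ", "))
  conf_vec <- vapply(confs, `[`, "", 1L)[codes]
  names(conf_vec) <- codes
  modification_catalog(
    data.frame(protein_id = df$protein_id, attribute = df$attribute_code,
               stringsAsFactors = FALSE),
    conformations = conf_vec)
}

#' Write a modification catalog to TSV
#' @param modcat a `modification_catalog`.
#' @param path output path.
#' @export
write_modification_catalog <- function(modcat, path) {
  conf <- stats::setNames(modcat$attributes$conformation,
                          modcat$attributes$attribute)
  df <- data.frame(attribute_code = modcat$proteins$attribute,
                   conformation = unname(conf[modcat$proteins$attribute]),
                   protein_id = modcat$proteins$protein_id,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read formula definitions
#'
#' TSV with columns `formula_id`, `member_id`, one row per membership.
#' Members are grouped per formula preserving file order. Every member must
#' resolve against the medicinal catalog; a repeated member within one
#' formula or an empty formula is an error.
#'
#' @param path path to the TSV file.
#' @param catalog the `tcm_catalog` the members must resolve against.
#' @return data.frame with columns `formula_id` and list column `member_ids`.
#' @export
read_formulas <- function(path, catalog) {
  df <- read_tsv_checked(path, c("formula_id", "member_id"))
  if (anyNA(df$formula_id) || anyNA(df$member_id))
    stop("formula_id/member_id may not be missing")
  unknown <- !(df$member_id %in% catalog$medicinal_id)
  if (any(unknown)) {
    i <- which(unknown)[1L]
    stop(sprintf("formula '%s': member '%s' not in the medicinal catalog",
                 df$formula_id[i], df$member_id[i]))
  }
  ids <- unique(df$formula_id)
  members <- lapply(ids, function(f) df$member_id[df$formula_id == f])
  dup <- vapply(members, anyDuplicated, 0L) > 0L
  if (any(dup))
    stop("repeated member within formula(s): ",
         paste(ids[dup], collapse = ", "))
  out <- data.frame(formula_id = ids, stringsAsFactors = FALSE)
  out$member_ids <- members
  out
}

#' Write formula definitions
#' @param formulas data.frame as returned by [read_formulas()].
#' @param path output path.
#' @export
write_formulas <- function(formulas, path) {
  df <- data.frame(
    formula_id = rep(formulas$formula_id, lengths(formulas$member_ids)),
    member_id = unlist(formulas$member_ids),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a phylogenetic tree over medicinals
#'
#' Parses a Newick file whose leaf labels are medicinal ids. Edges without a
#' branch length are assigned length 1 (cladogram convention: cophenetic
#' distance then equals path edge count). Duplicate leaf labels are an
#' error.
#'
#' @param path path to the Newick file.
#' @param catalog optional `tcm_catalog`; when given, all leaves must be
#'   catalog medicinals.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tcm_tree <- function(path, catalog = NULL) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable Newick in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("unparseable Newick in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else {
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  if (any(tree$edge.length <= 0))
    stop("all branch lengths must be positive")
  if (!is.null(catalog)) {
    extra <- setdiff(tree$tip.label, catalog$medicinal_id)
    if (length(extra) > 0L)
      stop("tree leaves absent from catalog: ",
           paste(utils::head(extra, 5L), collapse = ", "))
  }
  tree
}
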