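#' Build modification potency profiles for every medicinal
#'
#' A medicinal modifies attribute X when one of its constituent chemicals
#' interacts with an enzyme of X's family; its X potency is the number of
#' such chemical-protein interaction pairs. Interactions whose action is
#' `unspecified` are tallied as inhibiting (the usual case for small
#' molecule-protein interactions).
#'
#' @param catalog a `tcm_catalog`.
#' @param interactions data.frame from [read_interaction_table()].
#' @param modcat a `modification_catalog`.
#' @param mode `"count"` (potency = pair count; default) or `"signed"`
#'   (potency = activating minus inhibiting pairs).
#' @return Object of class `potency_profiles`: list with `entity_ids`,
#'   matrices `pairs`, `activating`, `inhibiting` (entities x 18), and
#'   `mode`.
#' @export
build_potency_profiles <- function(catalog, interactions, modcat,
                                   mode = c("count", "signed")) {
  mode <- match.arg(mode)
  codes <- attribute_codes()
  n <- nrow(catalog)
  mk <- function() matrix(0L, n, length(codes),
                          dimnames = list(catalog$medicinal_id, codes))
  A <- mk(); Inh <- mk()
  if (nrow(interactions) > 0L && n > 0L) {
    chem_map <- data.frame(
      medicinal_id = rep(catalog$medicinal_id, lengths(catalog$chemical_ids)),
      chemical_id = unlist(catalog$chemical_ids),
      stringsAsFactors = FALSE)
    prot_map <- data.frame(protein_id = modcat$proteins$protein_id,
                           attribute = modcat$proteins$attribute,
                           stringsAsFactors = FALSE)
    hits <- merge(interactions, chem_map, by = "chemical_id")
    hits <- merge(hits, prot_map, by = "protein_id")
    if (nrow(hits) > 0L) {
      hits$inhibiting <- hits$action %in% c("inhibition", "unspecified")
      tab <- function(sel) {
        t <- table(factor(hits$medicinal_id[sel], levels = catalog$medicinal_id),
                   factor(hits$attribute[sel], levels = codes))
        matrix(as.integer(t), n, length(codes),
               dimnames = list(catalog$medicinal_id, codes))
      }
      A <- tab(!hits$inhibiting)
      Inh <- tab(hits$inhibiting)
    }
  }
  new_potency_profiles(catalog$medicinal_id, A, Inh, mode)
}

new_potency_profiles <- function(ids, activating, inhibiting, mode) {
  out <- list(entity_ids = ids,
              pairs = activating + inhibiting,
              activating = activating,
              inhibiting = inhibiting,
              mode = mode)
  class(out) <- "potency_profiles"
  out
}

#' Potency profile of a single medicinal
#'
#' Convenience wrapper over [build_potency_profiles()] for one record.
#'
#' @param medicinal_id id present in `catalog`.
#' @inheritParams build_potency_profiles
#' @return named numeric vector of 18 potencies plus attributes
#'   `activating` and `inhibiting`.
#' @export
build_potency_profile <- function(medicinal_id, catalog, interactions, modcat,
                                  mode = c("count", "signed")) {
  mode <- match.arg(mode)
  stopifnot(medicinal_id %in% catalog$medicinal_id)
  p <- build_potency_profiles(catalog[catalog$medicinal_id == medicinal_id, ],
                              interactions, modcat, mode)
  v <- potency_matrix(p, mode)[1L, ]
  attr(v, "activating") <- p$activating[1L, ]
  attr(v, "inhibiting") <- p$inhibiting[1L, ]
  v
}

#' @export
print.potency_profiles <- function(x, ...) {
  cat("Potency profiles:", length(x$entity_ids), "entities x",
      ncol(x$pairs), "attributes;",
      sum(rowSums(x$pairs) > 0), "histone-modifying\n")
  invisible(x)
}

#' Which entities are histone-modifying?
#'
#' An entity is histone-modifying when at least one of the 18 attributes
#' has a positive interaction-pair count (the ambivalent ATP attribute
#' counts).
#'
#' @param profiles a `potency_profiles`.
#' @return named logical vector.
#' @export
is_histone_modifying <- function(profiles) {
  stats::setNames(rowSums(profiles$pairs) > 0, profiles$entity_ids)
}

#' Potency matrix (entities x 18 attributes)
#'
#' @param profiles a `potency_profiles`.
#' @param mode `"count"` (pair counts) or `"signed"` (activating minus
#'   inhibiting); defaults to the profiles' own mode.
#' @return numeric matrix with rows in catalog order and columns in the
#'   fixed [attribute_codes()] order.
#' @export
potency_matrix <- function(profiles, mode = NULL) {
  if (is.null(mode)) mode <- profiles$mode
  mode <- match.arg(mode, c("count", "signed"))
  m <- if (mode == "count") profiles$pairs
       else profiles$activating - profiles$inhibiting
  storage.mode(m) <- "double"
  m
}

#' Chromatin condensing / unpacking / poising classification
#'
#' Tallies, per entity and per chemistry class (`me`, `ph`, `ac`, `all`),
#' the heterochromatic versus euchromatic modifications it makes and labels
#' the entity by the net over all attributes: `condensing` (net > 0),
#' `unpacking` (net < 0), `poising` (net 0 with at least one attribute
#' touched) or `non_modifying`. The ambivalent ATP attribute counts toward
#' histone-modifying status but contributes to neither side of the net.
#'
#' @param profiles a `potency_profiles`.
#' @param modcat a `modification_catalog`.
#' @param granularity `"distinct_modifications"` (default; an attribute
#'   counts once when touched) or `"interaction_pairs"` (pair counts).
#' @param direction `"count"` (default; every pair counts toward the
#'   attribute's conformation) or `"direction_aware"` (an activating pair
#'   counts toward the attribute's conformation, an inhibiting pair toward
#'   the opposite one).
#' @return data.frame of class `chromatin_calls` with per-class `net`,
#'   `het`, `eu` columns and a `label` column.
#' @export
chromatin_call <- function(profiles, modcat,
                           granularity = c("distinct_modifications",
                                           "interaction_pairs"),
                           direction = c("count", "direction_aware")) {
  granularity <- match.arg(granularity)
  direction <- match.arg(direction)
  conf <- stats::setNames(modcat$attributes$conformation,
                          modcat$attributes$attribute)
  classes <- modification_classes()
  weight <- function(m) {
    if (granularity == "distinct_modifications") (m > 0) + 0 else m + 0
  }
  out <- data.frame(entity_id = profiles$entity_ids,
                    stringsAsFactors = FALSE)
  for (cl in names(classes)) {
    attrs <- classes[[cl]]
    het_attrs <- attrs[conf[attrs] == "heterochromatic"]
    eu_attrs <- attrs[conf[attrs] == "euchromatic"]
    if (direction == "count") {
      het <- rowSums(weight(profiles$pairs[, het_attrs, drop = FALSE]))
      eu <- rowSums(weight(profiles$pairs[, eu_attrs, drop = FALSE]))
    } else {
      het <- rowSums(weight(profiles$activating[, het_attrs, drop = FALSE])) +
        rowSums(weight(profiles$inhibiting[, eu_attrs, drop = FALSE]))
      eu <- rowSums(weight(profiles$activating[, eu_attrs, drop = FALSE])) +
        rowSums(weight(profiles$inhibiting[, het_attrs, drop = FALSE]))
    }
    out[[paste0(cl, "_het")]] <- het
    out[[paste0(cl, "_eu")]] <- eu
    out[[paste0(cl, "_net")]] <- het - eu
  }
  touched <- rowSums(profiles$pairs) > 0
  out$label <- ifelse(!touched, "non_modifying",
                      ifelse(out$all_net > 0, "condensing",
                             ifelse(out$all_net < 0, "unpacking", "poising")))
  class(out) <- c("chromatin_calls", "data.frame")
  out
}

#' Correlate TCM scores with one attribute's potency
#'
#' Pearson correlation between a TCM score (cold-hot, yin-yang or
#' flavor-only) and the modification potency of one attribute, restricted
#' to histone-modifying medicinals with a non-missing score. The two-sided
#' P comes from the exact t transform with n - 2 degrees of freedom.
#'
#' @param scores data.frame from [score_catalog()].
#' @param profiles a `potency_profiles` over the same catalog.
#' @param attribute_code one of [attribute_codes()].
#' @param score_mode which score column to use: `"cold_hot"`, `"yinyang"`
#'   or `"flavor"`.
#' @param mode potency mode passed to [potency_matrix()].
#' @return one-row data.frame: `attribute`, `score_mode`, `r`, `p`, `n`.
#' @export
correlate_scores_with_potency <- function(scores, profiles, attribute_code,
                                          score_mode = c("cold_hot",
                                                         "yinyang",
                                                         "flavor"),
                                          mode = NULL) {
  score_mode <- match.arg(score_mode)
  stopifnot(attribute_code %in% attribute_codes())
  m <- potency_matrix(profiles, mode)
  keep <- is_histone_modifying(profiles)
  s <- scores[[score_mode]][match(profiles$entity_ids, scores$medicinal_id)]
  keep <- keep & !is.na(s)
  x <- s[keep]
  y <- m[keep, attribute_code]
  if (length(x) < 3L) stop("need at least 3 usable medicinals")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in score or potency for ", attribute_code)
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(attribute = attribute_code, score_mode = score_mode,
             r = unname(ct$estimate), p = ct$p.value, n = length(x),
             stringsAsFactors = FALSE)
}

#' Correlation screen over all 18 attributes
#'
#' Runs [correlate_scores_with_potency()] for every attribute at the
#' per-attribute significance threshold `alpha` (no multiple-testing
#' correction, by design; the `significant` flag is a per-attribute
#' screen). Attributes whose potency has zero variance among the usable
#' medicinals yield an `NA` row.
#'
#' @inheritParams correlate_scores_with_potency
#' @param alpha per-attribute significance threshold (default 0.05).
#' @return data.frame with one row per attribute and a `significant` flag.
#' @export
correlation_screen <- function(scores, profiles,
                               score_mode = c("cold_hot", "yinyang",
                                              "flavor"),
                               alpha = 0.05, mode = NULL) {
  score_mode <- match.arg(score_mode)
  rows <- lapply(attribute_codes(), function(a) {
    tryCatch(correlate_scores_with_potency(scores, profiles, a, score_mode,
                                           mode),
             error = function(e)
               data.frame(attribute = a, score_mode = score_mode,
                          r = NA_real_, p = NA_real_, n = NA_integer_,
                          stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}

#' Materia-medica-wide summary of chromatin calls
#'
#' Fraction of medicinals that are histone-modifying and, among those, the
#' condensing/unpacking/poising class fractions.
#'
#' @param calls a `chromatin_calls` data.frame for the whole catalog.
#' @return list with `n_total`, `n_modifying`, `frac_modifying`, and
#'   `class_fractions` (named vector over the three classes; `NA` when no
#'   medicinal is modifying).
#' @export
materia_medica_summary <- function(calls) {
  if (nrow(calls) == 0L) stop("empty catalog")
  n <- nrow(calls)
  mod <- calls$label != "non_modifying"
  nm <- sum(mod)
  cf <- if (nm == 0L) {
    c(condensing = NA_real_, unpacking = NA_real_, poising = NA_real_)
  } else {
    c(condensing = sum(calls$label == "condensing") / nm,
      unpacking = sum(calls$label == "unpacking") / nm,
      poising = sum(calls$label == "poising") / nm)
  }
  list(n_total = n, n_modifying = nm, frac_modifying = nm / n,
       class_fractions = cf)
}

#' Write chromatin calls (with potencies) to TSV
#' @param calls a `chromatin_calls` data.frame.
#' @param profiles the matching `potency_profiles`.
#' @param path output path.
#' @export
write_profiles_tsv <- function(calls, profiles, path) {
  m <- potency_matrix(profiles)
  df <- cbind(calls[, "entity_id", drop = FALSE], as.data.frame(m),
              calls[, setdiff(names(calls), "entity_id")])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
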