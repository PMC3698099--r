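#' Synthetic-bundle generator configuration
#'
#' Bundles every tunable of the synthetic data generator that emulates the
#' inputs of the analysis: a Yule tree over medicinals, Brownian-motion
#' nature traits with independent tip noise, yin/yang-composed flavors,
#' per-medicinal chemical sets, enzyme families per modification attribute,
#' a chemical-protein interaction table with plantable score-potency
#' associations, and formulas with plantable chromatin-class homophily.
#'
#' Defaults define the study conditions used throughout the test suite;
#' they were fixed once by a design-time power analysis (see the methods
#' vignette) and emulate a materia medica in which roughly two fifths of
#' medicinals are histone-modifying.
#'
#' @param n_medicinals number of medicinals (>= 4).
#' @param n_chemicals_per_medicinal integer range (min, max) of constituent
#'   chemicals per medicinal.
#' @param n_enzymes_per_attribute integer range of enzyme-family size per
#'   modification attribute.
#' @param sigma_bm Brownian rate of the latent nature trait per unit branch
#'   length.
#' @param trait_noise_sd standard deviation of independent tip noise added
#'   to the Brownian trait (controls the phylogenetic signal-to-noise;
#'   0 makes the trait purely phylogenetic).
#' @param na_fraction fraction of medicinals left without a nature
#'   annotation.
#' @param flavor_nature_corr logistic slope tying the yang-flavor
#'   probability to the nature score (0 = independent).
#' @param planted_associations data.frame with columns `attribute`,
#'   `direction` (+1: hot-enriched, -1: cold-enriched) and `effect_size`
#'   (interaction-rate multiplier slope per unit of scaled nature score).
#' @param group_boost rate multiplier (added to 1) for the chemistry group
#'   each medicinal preferentially uses; plants the group-correlated usage
#'   visible in attribute clustering. 0 disables.
#' @param base_interaction_rate per chemical-enzyme pair inclusion
#'   probability before multipliers.
#' @param conformation_coherence boost factor planting per-medicinal
#'   chromatin tendency: each medicinal leans heterochromatic or
#'   euchromatic (50/50) and its preferred conformation's attributes get
#'   rate multiplier `1 + conformation_coherence`. Makes medicinals
#'   conformation-coherent (mostly condensing or mostly unpacking), the
#'   regime in which formula mixing is informative; 0 disables.
#' @param activity_dispersion sdlog of a per-medicinal lognormal
#'   interaction-rate multiplier (median 1). Emulates the highly skewed
#'   interaction coverage of real chemical-protein databases, producing a
#'   few very potent medicinals among many weak ones; 0 disables.
#' @param action_mix probabilities of activation / inhibition / unspecified
#'   for included pairs.
#' @param formula_count number of formulas.
#' @param formula_sizes integer vector formulas sizes are drawn from
#'   uniformly.
#' @param homophily_strength probability in `[0, 1]` that each subsequent
#'   formula member is drawn from the first member's chromatin class.
#' @param seed mandatory integer seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_medicinals = 300L,
                             n_chemicals_per_medicinal = c(2L, 5L),
                             n_enzymes_per_attribute = c(2L, 10L),
                             sigma_bm = 1.5,
                             trait_noise_sd = 1,
                             na_fraction = 0.1,
                             flavor_nature_corr = 0.5,
                             planted_associations = data.frame(
                               attribute = "H3K9", direction = -1,
                               effect_size = 3,
                               stringsAsFactors = FALSE),
                             group_boost = 4,
                             base_interaction_rate = 5e-4,
                             conformation_coherence = 3,
                             activity_dispersion = 1,
                             action_mix = c(activation = 0.2,
                                            inhibition = 0.5,
                                            unspecified = 0.3),
                             formula_count = 100L,
                             formula_sizes = 4:12,
                             homophily_strength = 0.8,
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_medicinals >= 4L,
            length(n_chemicals_per_medicinal) == 2L,
            length(n_enzymes_per_attribute) == 2L,
            sigma_bm >= 0, trait_noise_sd >= 0,
            na_fraction >= 0, na_fraction < 1,
            group_boost >= 0,
            base_interaction_rate >= 0, base_interaction_rate <= 1,
            conformation_coherence >= 0, activity_dispersion >= 0,
            abs(sum(action_mix) - 1) < 1e-8,
            homophily_strength >= 0, homophily_strength <= 1,
            formula_count >= 1L)
  if (!is.null(planted_associations) && nrow(planted_associations) > 0L) {
    stopifnot(all(c("attribute", "direction", "effect_size") %in%
                    names(planted_associations)))
    bad <- setdiff(planted_associations$attribute, attribute_codes())
    if (length(bad) > 0L)
      stop("planted association for unknown attribute: ",
           paste(bad, collapse = ", "))
  }
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

YANG_FLAVORS <- c("sweet", "mild sweet", "pungent", "mild pungent", "plain")
YIN_FLAVORS <- c("sour", "mild sour", "bitter", "mild bitter",
                 "salty", "mild salty")

#' Simulate the phylogeny and TCM annotations
#'
#' Grows a Yule (pure-birth) tree over the medicinals, evolves a latent
#' continuous trait by Brownian motion from a root value of 0, adds
#' independent tip noise, and discretizes the tip values into the seven
#' nature tokens by equal-probability bins (so token frequencies are
#' balanced). Flavors (1-3 tokens) are drawn with the yang-token
#' probability tied logistically to the nature score. A configured
#' fraction of medicinals is left without a nature annotation.
#'
#' @param config a [generator_config()].
#' @return list with `tree` (a `phylo`) and `catalog` (a `tcm_catalog`
#'   including simulated chemical ids).
#' @export
simulate_tree_and_traits <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_medicinals
  ids <- sprintf("M%04d", seq_len(n))
  tree <- ape::rphylo(n, birth = 1, death = 0)
  tree$tip.label <- ids
  bm <- if (config$sigma_bm > 0)
    ape::rTraitCont(tree, model = "BM", sigma = config$sigma_bm,
                    root.value = 0)
  else stats::setNames(rep(0, n), ids)
  trait <- bm[ids] + stats::rnorm(n, 0, config$trait_noise_sd)

  if (stats::sd(trait) == 0) {
    nature <- rep("neutral", n)  # degenerate trait: everything in root bin
  } else {
    edges <- stats::quantile(trait, probs = seq(0, 1, length.out = 8L))
    edges[1L] <- -Inf; edges[8L] <- Inf
    nature <- NATURE_TOKENS[cut(trait, breaks = unique(edges),
                                labels = FALSE, include.lowest = TRUE)]
  }
  n_na <- round(config$na_fraction * n)
  if (n_na > 0) nature[sample.int(n, n_na)] <- NA

  ns <- ifelse(is.na(nature), 0, nature_score(nature))
  p_yang <- stats::plogis(config$flavor_nature_corr * ns)
  flavors <- lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1L)
    pools <- ifelse(stats::runif(k) < p_yang[i], "yang", "yin")
    toks <- unlist(lapply(pools, function(p)
      sample(if (p == "yang") YANG_FLAVORS else YIN_FLAVORS, 1L)))
    unique(toks)
  })

  k_chem <- sample(config$n_chemicals_per_medicinal[1L]:
                     config$n_chemicals_per_medicinal[2L], n, replace = TRUE)
  chem_ids <- split(sprintf("C%06d", seq_len(sum(k_chem))),
                    rep(seq_len(n), k_chem))

  catalog <- data.frame(medicinal_id = ids,
                        scientific_name = sprintf("Species synthetica %d",
                                                  seq_len(n)),
                        nature = nature, stringsAsFactors = FALSE)
  catalog$lineage <- rep(list(character(0)), n)
  catalog$flavors <- flavors
  catalog$chemical_ids <- unname(chem_ids)
  list(tree = tree, catalog = new_tcm_catalog(catalog))
}

#' Simulate enzyme families for the 18 attributes
#'
#' @param config a [generator_config()].
#' @return a [modification_catalog()] with synthetic protein ids.
#' @export
simulate_modification_catalog <- function(config) {
  set.seed(config$seed + 1L)
  rng <- config$n_enzymes_per_attribute
  k <- sample(rng[1L]:rng[2L], 18L, replace = TRUE)
  codes <- attribute_codes()
  modification_catalog(data.frame(
    protein_id = sprintf("P_%s_%02d", rep(codes, k),
                         unlist(lapply(k, seq_len))),
    attribute = rep(codes, k), stringsAsFactors = FALSE))
}

#' Simulate the chemical-protein interaction table
#'
#' Every chemical-enzyme pair enters the table independently at
#' `base_interaction_rate`, modulated per medicinal by (i) the planted
#' score-potency associations — for a planted `(attribute, direction,
#' effect_size)`, the rate for that attribute is multiplied by
#' `max(0, 1 + effect_size * direction * score/3)`, enriching the stated
#' side of the cold-hot scale — and (ii) a preferred chemistry group per
#' medicinal whose attributes get rate multiplier `1 + group_boost`.
#' Actions are sampled from the configured mix.
#'
#' @param sim output of [simulate_tree_and_traits()].
#' @param modcat a `modification_catalog`.
#' @param config a [generator_config()].
#' @return interaction data.frame (`chemical_id`, `protein_id`, `action`).
#' @export
simulate_interactions <- function(sim, modcat, config) {
  set.seed(config$seed + 2L)
  catalog <- sim$catalog
  n <- nrow(catalog)
  codes <- attribute_codes()
  prot <- attribute_proteins(modcat)
  groups <- modification_classes()[c("ac", "ph", "me")]
  groups$me <- c(groups$me, "ATP")  # remodeling rides with methylation

  score <- ifelse(is.na(catalog$nature), 0, nature_score(catalog$nature))
  # per-medicinal x attribute rate multiplier
  mult <- matrix(1, n, 18L, dimnames = list(catalog$medicinal_id, codes))
  pa <- config$planted_associations
  if (!is.null(pa) && nrow(pa) > 0L) {
    for (i in seq_len(nrow(pa))) {
      m <- pmax(0, 1 + pa$effect_size[i] * pa$direction[i] * score / 3)
      mult[, pa$attribute[i]] <- mult[, pa$attribute[i]] * m
    }
  }
  if (config$group_boost > 0) {
    pref <- sample(names(groups), n, replace = TRUE)
    for (g in names(groups))
      mult[pref == g, groups[[g]]] <-
        mult[pref == g, groups[[g]]] * (1 + config$group_boost)
  }
  if (config$conformation_coherence > 0) {
    conf <- chromatin_conformations()
    het_attrs <- names(conf)[conf == "heterochromatic"]
    eu_attrs <- names(conf)[conf == "euchromatic"]
    lean_het <- sample(c(TRUE, FALSE), n, replace = TRUE)
    mult[lean_het, het_attrs] <-
      mult[lean_het, het_attrs] * (1 + config$conformation_coherence)
    mult[!lean_het, eu_attrs] <-
      mult[!lean_het, eu_attrs] * (1 + config$conformation_coherence)
  }
  if (config$activity_dispersion > 0)
    mult <- mult * stats::rlnorm(n, 0, config$activity_dispersion)

  rows <- vector("list", 18L)
  chems <- catalog$chemical_ids
  k_chem <- lengths(chems)
  med_of_chem <- rep(seq_len(n), k_chem)
  all_chems <- unlist(chems)
  for (a in seq_along(codes)) {
    enz <- prot[[codes[a]]]
    # one Bernoulli per (chemical, enzyme); rate depends on the chemical's
    # medicinal through the multiplier matrix
    p <- pmin(1, config$base_interaction_rate * mult[med_of_chem, a])
    hit <- stats::runif(length(all_chems) * length(enz)) <
      rep(p, times = length(enz))
    if (any(hit)) {
      idx <- which(hit)
      rows[[a]] <- data.frame(
        chemical_id = all_chems[(idx - 1L) %% length(all_chems) + 1L],
        protein_id = enz[(idx - 1L) %/% length(all_chems) + 1L],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(chemical_id = character(0), protein_id = character(0),
                      action = character(0), stringsAsFactors = FALSE))
  out$action <- sample(names(config$action_mix), nrow(out), replace = TRUE,
                       prob = config$action_mix)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Simulate formulas with chromatin-class homophily
#'
#' Formula sizes are drawn uniformly from `formula_sizes`. The first member
#' is uniform over all medicinals; each subsequent member is, with
#' probability `homophily_strength`, drawn from the first member's
#' chromatin class, otherwise uniformly. Members are distinct. When a
#' homophilous draw finds its class pool exhausted it falls back to a
#' uniform draw, except at `homophily_strength = 1` where exhaustion is an
#' error (no fallback exists by construction).
#'
#' @param calls `chromatin_calls` for the catalog.
#' @param config a [generator_config()].
#' @return formulas data.frame (`formula_id`, list column `member_ids`).
#' @export
simulate_formulas <- function(calls, config) {
  set.seed(config$seed + 3L)
  ids <- calls$entity_id
  labels <- stats::setNames(calls$label, ids)
  sizes <- config$formula_sizes[sample.int(length(config$formula_sizes),
                                           config$formula_count,
                                           replace = TRUE)]
  members <- lapply(sizes, function(sz) {
    first <- sample(ids, 1L)
    pool_class <- ids[labels == labels[first]]
    chosen <- first
    while (length(chosen) < sz) {
      from_class <- stats::runif(1L) < config$homophily_strength
      pool <- if (from_class) setdiff(pool_class, chosen)
              else setdiff(ids, chosen)
      if (from_class && length(pool) == 0L) {
        if (config$homophily_strength >= 1)
          stop("chromatin class '", labels[first],
               "' too small for formula size ", sz)
        pool <- setdiff(ids, chosen)
      }
      if (length(pool) == 0L)
        stop("medicinal pool too small for formula size ", sz)
      chosen <- c(chosen, sample(pool, 1L))
    }
    chosen
  })
  out <- data.frame(formula_id = sprintf("F%04d",
                                         seq_len(config$formula_count)),
                    stringsAsFactors = FALSE)
  out$member_ids <- members
  out
}

#' Generate a complete synthetic input bundle
#'
#' Runs the whole generator and, when `out_dir` is given, writes every file
#' the readers consume (medicinals.tsv, interactions.tsv,
#' modifications.tsv, formulas.tsv, tree.nwk) plus a manifest.json
#' recording the configuration and seed. The bundle round-trips through
#' the readers unchanged.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory, or `NULL` for an in-memory bundle only.
#' @return list of class `tcm_bundle`: `tree`, `catalog`, `modcat`,
#'   `interactions`, `formulas`, `config`, and `files` when written.
#' @export
generate_bundle <- function(config, out_dir = NULL) {
  sim <- simulate_tree_and_traits(config)
  modcat <- simulate_modification_catalog(config)
  interactions <- simulate_interactions(sim, modcat, config)
  profiles <- build_potency_profiles(sim$catalog, interactions, modcat)
  calls <- chromatin_call(profiles, modcat)
  formulas <- simulate_formulas(calls, config)
  bundle <- list(tree = sim$tree, catalog = sim$catalog, modcat = modcat,
                 interactions = interactions, formulas = formulas,
                 config = config)
  class(bundle) <- "tcm_bundle"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_medicinal_catalog(sim$catalog, p("medicinals.tsv"))
    write_interaction_table(interactions, p("interactions.tsv"))
    write_modification_catalog(modcat, p("modifications.tsv"))
    write_formulas(formulas, p("formulas.tsv"))
    ape::write.tree(sim$tree, p("tree.nwk"))
    manifest <- config
    manifest$planted_associations <- as.list(config$planted_associations)
    jsonlite::write_json(unclass(manifest), p("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    bundle$files <- vapply(c("medicinals.tsv", "interactions.tsv",
                             "modifications.tsv", "formulas.tsv",
                             "tree.nwk", "manifest.json"), p, "")
  }
  bundle
}

#' @export
print.tcm_bundle <- function(x, ...) {
  cat("Synthetic TCM bundle:", nrow(x$catalog), "medicinals,",
      nrow(x$interactions), "interactions,", nrow(x$formulas),
      "formulas (seed", x$config$seed, ")\n")
  invisible(x)
}
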