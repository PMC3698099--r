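#' Aggregate member profiles into formula profiles
#'
#' A formula's attribute array is the elementwise sum of the attribute
#' arrays of its composing medicinals.
#'
#' @param formulas data.frame from [read_formulas()].
#' @param profiles `potency_profiles` over the member catalog.
#' @return a `potency_profiles` whose entities are the formulas.
#' @export
formula_profiles <- function(formulas, profiles) {
  missing <- setdiff(unlist(formulas$member_ids), profiles$entity_ids)
  if (length(missing) > 0L)
    stop("no profile for member(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  sum_rows <- function(M) {
    t(vapply(formulas$member_ids, function(ids) {
      colSums(M[match(ids, profiles$entity_ids), , drop = FALSE])
    }, numeric(ncol(M))))
  }
  A <- sum_rows(profiles$activating)
  Inh <- sum_rows(profiles$inhibiting)
  rownames(A) <- rownames(Inh) <- formulas$formula_id
  new_potency_profiles(formulas$formula_id, A, Inh, profiles$mode)
}

#' Profile of one formula
#' @param member_ids character vector of medicinal ids.
#' @param profiles `potency_profiles` containing all members.
#' @return named numeric vector of 18 summed pair counts.
#' @export
formula_profile <- function(member_ids, profiles) {
  f <- data.frame(formula_id = "F", stringsAsFactors = FALSE)
  f$member_ids <- list(member_ids)
  formula_profiles(f, profiles)$pairs[1L, ]
}

#' Is a formula histone-modifying?
#'
#' A formula is histone-modifying when at least one of its composing
#' medicinals is.
#'
#' @param formulas data.frame from [read_formulas()].
#' @param member_modifying named logical from [is_histone_modifying()] over
#'   the member catalog.
#' @return logical vector aligned with `formulas`.
#' @export
formula_is_histone_modifying <- function(formulas, member_modifying) {
  vapply(formulas$member_ids,
         function(ids) any(member_modifying[ids]), TRUE)
}

# normalized net heterochromatinization fraction per class:
# f = (het - eu)/(het + eu), 0 when the class is untouched
hetero_fraction <- function(calls, class) {
  het <- calls[[paste0(class, "_het")]]
  eu <- calls[[paste0(class, "_eu")]]
  tot <- het + eu
  ifelse(tot == 0, 0, (het - eu) / tot)
}

#' Heterochromatinization difference of formulas versus their members
#'
#' For each chemistry class (`me`, `ph`, `ac`, `all`), compares the
#' normalized net heterochromatinization fraction
#' `f = (n_het - n_eu)/(n_het + n_eu)` of the pooled formula with the mean
#' `f` of its histone-modifying members:
#' `Delta = f(formula) - mean_members f`. `Delta` is bounded in `[-2, 2]`.
#'
#' @param formulas data.frame from [read_formulas()]; every formula must
#'   have at least one histone-modifying member.
#' @param member_calls `chromatin_calls` over the member catalog.
#' @param formula_calls `chromatin_calls` over the formulas (from
#'   [chromatin_call()] on [formula_profiles()]).
#' @param member_modifying named logical from [is_histone_modifying()].
#' @return data.frame `formula_id`, `class`, `delta` (long format).
#' @export
heterochromatinization_difference <- function(formulas, member_calls,
                                              formula_calls,
                                              member_modifying) {
  ok <- formula_is_histone_modifying(formulas, member_modifying)
  if (!all(ok))
    stop("formula(s) without any histone-modifying member: ",
         paste(formulas$formula_id[!ok], collapse = ", "))
  classes <- names(modification_classes())
  member_f <- vapply(classes, function(cl) hetero_fraction(member_calls, cl),
                     numeric(nrow(member_calls)))
  if (nrow(member_calls) == 1L) member_f <- matrix(member_f, nrow = 1L)
  rownames(member_f) <- member_calls$entity_id
  formula_f <- vapply(classes, function(cl) hetero_fraction(formula_calls, cl),
                      numeric(nrow(formula_calls)))
  if (nrow(formula_calls) == 1L) formula_f <- matrix(formula_f, nrow = 1L,
                                                     dimnames = list(NULL, classes))
  rownames(formula_f) <- formula_calls$entity_id
  rows <- lapply(seq_len(nrow(formulas)), function(i) {
    ids <- formulas$member_ids[[i]]
    ids <- ids[member_modifying[ids]]
    mean_f <- colMeans(member_f[ids, , drop = FALSE])
    data.frame(formula_id = formulas$formula_id[i], class = classes,
               delta = unname(formula_f[formulas$formula_id[i], ] - mean_f),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate size-matched random control formulas
#'
#' Each control is a uniform sample without replacement of `size` medicinals
#' from the pool of medicinals making up the real formulas. When
#' `target_median_modifying` is given, the whole control set is accepted
#' only if the median count of histone-modifying members across controls
#' matches it; otherwise the set is redrawn (up to `max_redraws`).
#'
#' When the real formulas are more enriched in histone-modifying members
#' than uniform pool draws can reproduce (the regime the analysis is
#' designed to detect), the rejection scheme cannot terminate. With
#' `method = "auto"` (default) it then falls back to composition-matched
#' draws: each control's modifying-member count is bootstrapped from the
#' real formulas' counts and its members are sampled uniformly within the
#' modifying and non-modifying strata of the pool, after which the median
#' acceptance check is applied as before. `method = "reject"` forces the
#' pure rejection scheme (and errors when unsatisfiable, reporting the
#' achieved versus target median); `method = "condition"` forces the
#' stratified construction.
#'
#' @param pool character vector of medicinal ids (the union of real
#'   formulas' members).
#' @param n_controls number of control formulas.
#' @param size members per control (typically the real formulas' median
#'   size).
#' @param seed integer seed; the control set is fully reproducible from it.
#' @param member_modifying named logical over the pool (needed when
#'   `target_median_modifying` is given).
#' @param target_median_modifying target median count of histone-modifying
#'   members, or `NULL` to skip the constraint.
#' @param max_redraws redraw budget for the constraint.
#' @param tolerance accepted deviation from the target median (default 0.5:
#'   the median of an even number of real formulas can be a half-integer
#'   that an odd-sized control set can never attain exactly).
#' @param method `"auto"`, `"reject"` or `"condition"` (see Details).
#' @param real_modifying_counts integer vector of modifying-member counts
#'   of the real formulas; required for the stratified construction.
#' @return data.frame like [read_formulas()] output with ids `CTRL0001`, ...
#' @export
generate_control_formulas <- function(pool, n_controls, size, seed,
                                      member_modifying = NULL,
                                      target_median_modifying = NULL,
                                      max_redraws = 100L, tolerance = 0.5,
                                      method = c("auto", "reject",
                                                 "condition"),
                                      real_modifying_counts = NULL) {
  method <- match.arg(method)
  pool <- unique(pool)
  if (size > length(pool))
    stop("control size exceeds pool size")
  if (n_controls < 1L) stop("n_controls must be >= 1")
  set.seed(seed)

  draw_uniform <- function() lapply(seq_len(n_controls),
                                    function(i) sample(pool, size))
  draw_stratified <- function() {
    mod_pool <- pool[member_modifying[pool]]
    non_pool <- setdiff(pool, mod_pool)
    ks <- sample(real_modifying_counts, n_controls, replace = TRUE)
    ks <- pmin(pmax(ks, size - length(non_pool)),
               min(size, length(mod_pool)))
    lapply(ks, function(k)
      sample(c(sample(mod_pool, k), sample(non_pool, size - k))))
  }
  set_median <- function(members)
    stats::median(vapply(members, function(ids)
      sum(member_modifying[ids]), 0L))

  attempt <- function(draw, budget, on_fail) {
    for (r in seq_len(budget)) {
      members <- draw()
      if (is.null(target_median_modifying)) return(members)
      achieved <- set_median(members)
      if (abs(achieved - target_median_modifying) <= tolerance)
        return(members)
      if (r == budget) return(on_fail(achieved))
    }
  }
  fail_hard <- function(achieved)
    stop(sprintf(paste0("control constraint unsatisfiable after %d ",
                        "redraws: achieved median modifying %s, target %s"),
                 max_redraws, achieved, target_median_modifying))

  members <- if (method == "condition") {
    if (is.null(real_modifying_counts))
      stop("stratified construction needs real_modifying_counts")
    attempt(draw_stratified, max_redraws, fail_hard)
  } else if (method == "reject") {
    attempt(draw_uniform, max_redraws, fail_hard)
  } else {
    first <- attempt(draw_uniform, max_redraws, function(a) NULL)
    if (!is.null(first)) first
    else {
      if (is.null(real_modifying_counts))
        stop("rejection scheme unsatisfiable and no real_modifying_counts ",
             "available for the stratified fallback")
      attempt(draw_stratified, max_redraws, fail_hard)
    }
  }
  out <- data.frame(formula_id = sprintf("CTRL%04d", seq_len(n_controls)),
                    stringsAsFactors = FALSE)
  out$member_ids <- members
  out
}

#' Compare real and control heterochromatinization differences
#'
#' Per chemistry class, a two-sided rank-sum (Wilcoxon) comparison of
#' `|Delta|` between real and control formulas. The direction flag is set
#' when the real median `|Delta|` is below the control median, i.e. when
#' forming real formulas changes the heterochromatic property less than
#' expected under random assembly.
#'
#' @param real_delta,control_delta long data.frames from
#'   [heterochromatinization_difference()].
#' @return Object of class `synergy_report`: per-class summary data.frame
#'   plus the two Delta tables.
#' @export
synergy_comparison <- function(real_delta, control_delta) {
  if (nrow(real_delta) == 0L || nrow(control_delta) == 0L)
    stop("both Delta lists must be non-empty")
  classes <- names(modification_classes())
  summary <- do.call(rbind, lapply(classes, function(cl) {
    r <- abs(real_delta$delta[real_delta$class == cl])
    c0 <- abs(control_delta$delta[control_delta$class == cl])
    p <- if (length(r) < 2L || length(c0) < 2L ||
             (stats::sd(r) == 0 && stats::sd(c0) == 0 &&
              stats::median(r) == stats::median(c0))) 1
         else suppressWarnings(stats::wilcox.test(r, c0)$p.value)
    data.frame(class = cl,
               median_abs_real = stats::median(r),
               median_abs_control = stats::median(c0),
               p = p,
               direction = stats::median(r) < stats::median(c0),
               stringsAsFactors = FALSE)
  }))
  out <- list(summary = summary, real_delta = real_delta,
              control_delta = control_delta,
              n_real = length(unique(real_delta$formula_id)),
              n_controls = length(unique(control_delta$formula_id)))
  class(out) <- "synergy_report"
  out
}

#' @export
print.synergy_report <- function(x, digits = 3, ...) {
  cat("Formula synergy (", x$n_real, " real vs ", x$n_controls,
      " control formulas)\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-3s median |D| real %.3f vs control %.3f, p = %.*g%s\n",
                s$class[i], s$median_abs_real[i], s$median_abs_control[i],
                digits, s$p[i],
                if (s$direction[i]) "  [real closer to zero]" else ""))
  invisible(x)
}

#' Full formula-synergy analysis
#'
#' Computes real-formula Delta values (restricted to histone-modifying
#' formulas), draws size- and composition-matched random controls from the
#' real member pool, computes control Delta values, and compares the two.
#'
#' @param formulas data.frame from [read_formulas()].
#' @param profiles `potency_profiles` over the member catalog.
#' @param modcat a `modification_catalog`.
#' @param n_controls number of controls (default 199).
#' @param seed integer seed for the control draw.
#' @param granularity,direction passed to [chromatin_call()]. The synergy
#'   default is `interaction_pairs`: the normalized net fraction responds
#'   to the mixing of counteracting medicinals only when members are
#'   weighted by their interaction intensity (a pooled formula tracks its
#'   dominant member), whereas under distinct-mark tallies pooling and
#'   averaging nearly coincide by construction and the contrast is blind
#'   to mixing.
#' @return a `synergy_report` (see [synergy_comparison()]), with elements
#'   `median_size` and `median_modifying` added.
#' @export
synergy_analysis <- function(formulas, profiles, modcat, n_controls = 199L,
                             seed = 1L,
                             granularity = "interaction_pairs",
                             direction = "count") {
  member_mod <- is_histone_modifying(profiles)
  mod_f <- formula_is_histone_modifying(formulas, member_mod)
  real <- formulas[mod_f, , drop = FALSE]
  if (nrow(real) == 0L) stop("no histone-modifying formula")
  member_calls <- chromatin_call(profiles, modcat, granularity, direction)
  fp <- formula_profiles(real, profiles)
  f_calls <- chromatin_call(fp, modcat, granularity, direction)
  real_delta <- heterochromatinization_difference(real, member_calls,
                                                  f_calls, member_mod)
  pool <- unique(unlist(real$member_ids))
  med_size <- stats::median(lengths(real$member_ids))
  med_mod <- stats::median(vapply(real$member_ids,
                                  function(ids) sum(member_mod[ids]), 0L))
  controls <- generate_control_formulas(
    pool, n_controls, size = as.integer(round(med_size)), seed = seed,
    member_modifying = member_mod, target_median_modifying = med_mod,
    real_modifying_counts = vapply(real$member_ids,
                                   function(ids) sum(member_mod[ids]), 0L))
  ctrl_mod <- formula_is_histone_modifying(controls, member_mod)
  controls <- controls[ctrl_mod, , drop = FALSE]
  cp <- formula_profiles(controls, profiles)
  c_calls <- chromatin_call(cp, modcat, granularity, direction)
  control_delta <- heterochromatinization_difference(controls, member_calls,
                                                     c_calls, member_mod)
  rep <- synergy_comparison(real_delta, control_delta)
  rep$median_size <- med_size
  rep$median_modifying <- med_mod
  rep$control_seed <- seed
  rep
}

#' Serialize a synergy report
#' @param report a `synergy_report`.
#' @param json_path path for the JSON summary.
#' @param delta_path optional path for the long Delta TSV
#'   (`formula_id`, `class`, `delta`, `is_control`).
#' @export
write_synergy_report <- function(report, json_path, delta_path = NULL) {
  jsonlite::write_json(
    list(summary = report$summary, n_real = report$n_real,
         n_controls = report$n_controls,
         median_size = report$median_size,
         median_modifying = report$median_modifying,
         control_seed = report$control_seed),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(delta_path)) {
    d <- rbind(cbind(report$real_delta, is_control = FALSE),
               cbind(report$control_delta, is_control = TRUE))
    utils::write.table(d, delta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(json_path)
}
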